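// Metropolis Monte Carlo kernel for the two-sublattice lattice binary
// mixture.  Single-site species flips (semi-grand canonical ensemble) on
// an L x L periodic square lattice split into two column strips.
//
// All energies are per kBT.  The RNG is a self-contained xorshift64*
// stream so that a given seed reproduces the trajectory bit-for-bit,
// independently of R's RNG state.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Xorshift64s {
  uint64_t s;
  explicit Xorshift64s(uint64_t seed) {
    // avoid the all-zero state; scramble small seeds
    s = seed * 2654435761ULL + 0x9E3779B97F4A7C15ULL;
    if (s == 0) s = 0x106689D45497FDB5ULL;
  }
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

// pair energy of occupations a, b
inline double bondE(int a, int b, double uaa, double uab, double ubb) {
  return uaa * (a & b) + uab * ((a + b) - 2 * (a & b)) +
         ubb * ((1 - a) & (1 - b));
}

}  // namespace

// [[Rcpp::export]]
List mc_run_cpp(int L, int c, bool cross_boundary,
                double uaa, double uab, double ubb,
                double dmu, double du1, double du2,
                int sweeps, int burnin, int stride,
                int seed, int init_code) {
  const int N = L * L;
  std::vector<int> n(N);
  std::vector<int> seg(N);       // 1 or 2 by column
  for (int col = 0; col < L; ++col)
    for (int row = 0; row < L; ++row)
      seg[row + col * L] = (col < c) ? 1 : 2;

  Xorshift64s rng(static_cast<uint64_t>(static_cast<int64_t>(seed)));

  for (int i = 0; i < N; ++i) {
    if (init_code == 0) n[i] = 0;                     // all_b
    else if (init_code == 1) n[i] = 1;                // all_a
    else n[i] = rng.unif() < 0.5 ? 0 : 1;             // random
  }

  const double field[3] = {0.0, du1 - dmu, du2 - dmu};

  // neighbor table: 4 neighbors per site (periodic), with a validity
  // flag used when cross-segment bonds are excluded
  std::vector<int> nbr(4 * N);
  std::vector<char> nbr_ok(4 * N);
  for (int col = 0; col < L; ++col) {
    for (int row = 0; row < L; ++row) {
      int i = row + col * L;
      int idx[4] = {
        row + ((col + 1) % L) * L,        // right
        row + ((col - 1 + L) % L) * L,    // left
        ((row + 1) % L) + col * L,        // down
        ((row - 1 + L) % L) + col * L     // up
      };
      for (int k = 0; k < 4; ++k) {
        nbr[4 * i + k] = idx[k];
        nbr_ok[4 * i + k] =
            (cross_boundary || seg[i] == seg[idx[k]]) ? 1 : 0;
      }
    }
  }

  // initial total energy: right + down bonds once each, plus fields
  double E = 0.0;
  for (int col = 0; col < L; ++col) {
    for (int row = 0; row < L; ++row) {
      int i = row + col * L;
      int jr = row + ((col + 1) % L) * L;
      int jd = ((row + 1) % L) + col * L;
      if (cross_boundary || seg[i] == seg[jr])
        E += bondE(n[i], n[jr], uaa, uab, ubb);
      E += bondE(n[i], n[jd], uaa, uab, ubb);
      E += field[seg[i]] * n[i];
    }
  }

  const int n1_sites = c * L, n2_sites = (L - c) * L;
  long long sum1 = 0, sum2 = 0;
  for (int i = 0; i < N; ++i) (seg[i] == 1 ? sum1 : sum2) += n[i];

  long long attempts = 0, accepts = 0;
  std::vector<double> n1_series, n2_series, n_series, e_series;
  n_series.reserve((sweeps - burnin) / stride + 1);

  for (int sweep = 0; sweep < sweeps; ++sweep) {
    for (int a = 0; a < N; ++a) {
      int i = static_cast<int>(rng.unif() * N);
      if (i >= N) i = N - 1;
      int ni = n[i], nf = 1 - ni;
      double dE = field[seg[i]] * (nf - ni);
      for (int k = 0; k < 4; ++k) {
        if (!nbr_ok[4 * i + k]) continue;
        int nj = n[nbr[4 * i + k]];
        dE += bondE(nf, nj, uaa, uab, ubb) -
              bondE(ni, nj, uaa, uab, ubb);
      }
      ++attempts;
      bool accept = dE <= 0.0 || rng.unif() < std::exp(-dE);
      if (accept) {
        n[i] = nf;
        E += dE;
        ++accepts;
        (seg[i] == 1 ? sum1 : sum2) += nf - ni;
      }
    }
    if (sweep >= burnin && (sweep - burnin) % stride == 0) {
      n1_series.push_back(n1_sites > 0
                              ? static_cast<double>(sum1) / n1_sites
                              : NA_REAL);
      n2_series.push_back(n2_sites > 0
                              ? static_cast<double>(sum2) / n2_sites
                              : NA_REAL);
      n_series.push_back(static_cast<double>(sum1 + sum2) / N);
      e_series.push_back(E / N);
    }
  }

  IntegerVector config(N);
  for (int i = 0; i < N; ++i) config[i] = n[i];

  return List::create(
      _["n1_series"] = n1_series, _["n2_series"] = n2_series,
      _["n_series"] = n_series, _["e_series"] = e_series,
      _["acceptance"] = static_cast<double>(accepts) / attempts,
      _["config"] = config);
}
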