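## Configuration, serialization and command-line glue.
##
## Every CLI behavior is a thin shell over an exported function; data go
## to files, diagnostics to stderr.  CSV numeric formatting keeps full
## double precision (17 significant digits) so round trips are
## value-identical.

.known_config_keys <- c("T_bar", "T_over_Tc", "q1", "dU21_over_kBTc",
                        "Xa", "Uaa", "Uab", "Ubb", "kBT", "backend",
                        "regime", "seed")

#' Read a run configuration file
#'
#' JSON or YAML key-value file.  Recognized keys: \code{T_bar} or
#' \code{T_over_Tc} (mutually exclusive), \code{q1},
#' \code{dU21_over_kBTc}, \code{Xa}, \code{backend}, \code{regime},
#' \code{seed}, and optionally the raw energies \code{Uaa}, \code{Uab},
#' \code{Ubb}, \code{kBT} (mutually exclusive with the reduced
#' temperature keys).  Unknown keys are rejected.
#'
#' The affinity contrast is accepted in units of \eqn{k_B T_c} (the
#' natural scale for diagrams normalized by \eqn{T/T_c}) and converted
#' where needed to per-\eqn{k_B T} via
#' \eqn{\Delta U^{2,1}/k_BT = (\Delta U^{2,1}/k_BT_c) \cdot (T_c/T)}.
#'
#' @param path Path to a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return Named list of validated configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(cfg), .known_config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  raw <- c("Uaa", "Uab", "Ubb", "kBT")
  has_raw <- any(raw %in% names(cfg))
  has_reduced <- any(c("T_bar", "T_over_Tc") %in% names(cfg))
  if (has_raw && has_reduced)
    stop("raw energies (Uaa, Uab, Ubb, kBT) and reduced temperatures ",
         "(T_bar / T_over_Tc) are mutually exclusive")
  if (all(c("T_bar", "T_over_Tc") %in% names(cfg)))
    stop("supply only one of T_bar and T_over_Tc")
  if (has_raw && !all(raw %in% names(cfg)))
    stop("raw parametrization requires all of Uaa, Uab, Ubb, kBT")
  cfg
}

#' Convert an affinity contrast from kBTc units to per-kBT
#'
#' @param du21_over_kBTc Contrast in units of \eqn{k_B T_c}.
#' @param t_over_tc Temperature as a fraction of \eqn{T_c}.
#' @return The contrast per \eqn{k_B T} at that temperature.
#' @export
du21_per_kBT <- function(du21_over_kBTc, t_over_tc) {
  stopifnot(is.finite(du21_over_kBTc), is.finite(t_over_tc),
            t_over_tc > 0)
  du21_over_kBTc / t_over_tc
}

#' Write a binodal or phase-diagram table to CSV
#'
#' Full-precision (17 significant digits) so that reading the file back
#' reproduces the doubles exactly.
#'
#' @param x Data frame.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_table_csv <- function(x, path) {
  xx <- as.data.frame(lapply(x, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }), stringsAsFactors = FALSE)
  # keep NA cells blank
  for (j in seq_along(xx)) xx[[j]][is.na(x[[j]])] <- ""
  write.csv(xx, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a table written by \code{\link{write_table_csv}}
#'
#' @param path CSV file path.
#' @return Data frame with numeric columns restored.
#' @export
read_table_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Generate the package's deterministic test fixtures
#'
#' Writes small plain-text fixtures: a geometry round-trip table
#' (contact angle, area fraction, reduced volume), tiny-lattice
#' enumeration cases with their exact averages, and a coarse
#' phase-diagram grid.
#'
#' @param outdir Output directory (created if absent).
#' @param seed Seed for the enumeration-case parameters.
#' @return Character vector of the files written, invisibly.
#' @export
generate_fixtures <- function(outdir, seed = 12345L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  theta <- c(pi / 6, pi / 4, pi / 2, 2 * pi / 3, 5 * pi / 6, pi)
  geom <- data.frame(
    theta = theta,
    q1 = q1_from_angle(theta),
    v = vapply(theta, function(th) cap_geometry(th)$v, numeric(1)))
  f <- file.path(outdir, "geometry_roundtrip.csv")
  write_table_csv(geom, f); files <- c(files, f)

  set.seed(seed)
  cases <- data.frame(
    L = 3L, c = c(0L, 1L, 2L, 3L),
    tbar = round(runif(4, 1.5, 4), 3),
    dmu = round(runif(4, -1, 1), 3),
    du1 = c(0, 0, -0.5, 0.5),
    du2 = c(0, -2, 0.5, -0.5))
  cases$n1_mean <- NA_real_; cases$n2_mean <- NA_real_
  cases$n_mean <- NA_real_
  for (k in seq_len(nrow(cases))) {
    sp <- lattice_spec(cases$L[k], cases$c[k])
    pp <- mc_params(tbar = cases$tbar[k], dmu = cases$dmu[k],
                    du1 = cases$du1[k], du2 = cases$du2[k])
    ex <- enumerate_exact(sp, pp)
    cases$n1_mean[k] <- ex$n1_mean
    cases$n2_mean[k] <- ex$n2_mean
    cases$n_mean[k] <- ex$n_mean
  }
  f <- file.path(outdir, "enumeration_cases.csv")
  write_table_csv(cases, f); files <- c(files, f)

  pd <- build_diagram(seq(0.2, 1.05, length.out = 18), q1 = 0.7,
                      du21 = 50, backend = "exact-limit",
                      regime = "large")
  f <- file.path(outdir, "diagram_grid.csv")
  write_table_csv(as.data.frame(pd), f); files <- c(files, f)

  invisible(files)
}

.cli_usage <- function() {
  message(
    "usage: memphase <subcommand> [options]\n",
    "subcommands:\n",
    "  binodal  --backend {exact,meanfield} --tbar-min X --tbar-max X",
    " --n N --out F\n",
    "  diagram  --q1 X --du21 X --backend B [--regime small|large]",
    " --t-min X --t-max X --n N --out F\n",
    "  classify --xa X --t-over-tc X --q1 X --du21 X --backend B",
    " [--regime R] [--out F]\n",
    "  geometry (--theta-deg X | --v X | --q1 X) [--out F]\n",
    "  adhesion --kappa-J X --W-mJ-per-m2 X --Lstar-um X [--out F]\n",
    "  mc       --L N --q1 X --tbar X --dmu X --du1 X --du2 X",
    " --sweeps N --burnin N --seed N --out F\n",
    "  fixtures --out DIR\n",
    "  --version")
}

.parse_flags <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(argv) || startsWith(argv[i + 1L], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- argv[i + 1L]
      i <- i + 2L
    }
  }
  out
}

.flag_num <- function(flags, name, default = NULL) {
  if (is.null(flags[[name]])) {
    if (is.null(default)) stop("missing required flag --", name)
    return(default)
  }
  v <- suppressWarnings(as.numeric(flags[[name]]))
  if (is.na(v)) stop("flag --", name, " must be numeric")
  v
}

.emit <- function(obj, out_path) {
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                          pretty = TRUE, na = "null")
  if (is.null(out_path)) cat(txt, "\n") else writeLines(txt, out_path)
}

#' Command-line entry point
#'
#' Dispatches the subcommands \code{binodal}, \code{diagram},
#' \code{classify}, \code{geometry}, \code{adhesion}, \code{mc} and
#' \code{fixtures}; see the shipped script
#' \code{system.file("cli", "memphase.R", package = "memphase")}.
#' Returns (rather than calls) the exit status so it is testable.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status: 0 success, 1 physics/domain error,
#'   2 usage error.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) { .cli_usage(); return(2L) }
  if (argv[1] == "--version") {
    cat(sprintf("memphase %s (table schema 1)\n",
                as.character(packageVersion("memphase"))))
    return(0L)
  }
  sub <- argv[1]
  known <- c("binodal", "diagram", "classify", "geometry", "adhesion",
             "mc", "fixtures")
  if (!sub %in% known) { .cli_usage(); return(2L) }
  flags <- tryCatch(.parse_flags(argv[-1]),
                    error = function(e) { message(conditionMessage(e));
                      NULL })
  if (is.null(flags)) return(2L)
  status <- tryCatch({
    switch(sub,
      binodal = cli_binodal(flags),
      diagram = cli_diagram(flags),
      classify = cli_classify(flags),
      geometry = cli_geometry(flags),
      adhesion = cli_adhesion(flags),
      mc = cli_mc(flags),
      fixtures = cli_fixtures(flags))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}

cli_binodal <- function(flags) {
  backend <- switch(as.character(flags$backend %||% "exact"),
                    exact = "exact-limit", meanfield = "meanfield",
                    stop("--backend must be exact or meanfield"))
  tmin <- .flag_num(flags, "tbar-min")
  tmax <- .flag_num(flags, "tbar-max")
  n <- as.integer(.flag_num(flags, "n", 100))
  tb <- seq(tmin, tmax, length.out = n)
  tc <- if (backend == "meanfield") mf_tc() else ising_tc()
  b <- if (backend == "meanfield") mf_binodals(tb) else exact_binodals(tb)
  if (n == 1L) b <- data.frame(tbar = tb, x_beta = b$x_beta,
                               x_alpha = b$x_alpha)
  tab <- data.frame(T_bar = b$tbar, T_over_Tc = b$tbar / tc,
                    x_beta = b$x_beta, x_alpha = b$x_alpha)
  if (is.null(flags$out)) stop("missing required flag --out")
  write_table_csv(tab, flags$out)
  message("wrote ", nrow(tab), " rows to ", flags$out)
}

cli_diagram <- function(flags) {
  backend <- switch(as.character(flags$backend %||% "meanfield"),
                    exact = "exact-limit", `exact-limit` = "exact-limit",
                    meanfield = "meanfield",
                    stop("--backend must be exact or meanfield"))
  regime <- as.character(flags$regime %||% "small")
  tmin <- .flag_num(flags, "t-min", 0.05)
  tmax <- .flag_num(flags, "t-max", 1.05)
  n <- as.integer(.flag_num(flags, "n", 200))
  pd <- build_diagram(seq(tmin, tmax, length.out = n),
                      q1 = .flag_num(flags, "q1"),
                      du21 = .flag_num(flags, "du21"),
                      backend = backend, regime = regime)
  tab <- data.frame(T_over_Tc = pd$t_over_tc,
                    seg1_lo = pd$seg1_lo, seg1_hi = pd$seg1_hi,
                    seg2_lo = pd$seg2_lo, seg2_hi = pd$seg2_hi,
                    uni_lo = pd$uni_lo, uni_hi = pd$uni_hi)
  if (is.null(flags$out)) stop("missing required flag --out")
  if (grepl("\\.json$", flags$out)) .emit(tab, flags$out)
  else write_table_csv(tab, flags$out)
  message("wrote diagram (", nrow(tab), " temperatures) to ", flags$out)
}

cli_classify <- function(flags) {
  backend <- switch(as.character(flags$backend %||% "meanfield"),
                    exact = "exact-limit", `exact-limit` = "exact-limit",
                    meanfield = "meanfield",
                    stop("--backend must be exact or meanfield"))
  eos <- membrane_eos(backend, t_over_tc = .flag_num(flags, "t-over-tc"))
  st <- solve_state(.flag_num(flags, "xa"), .flag_num(flags, "q1"),
                    .flag_num(flags, "du21"), eos,
                    regime = as.character(flags$regime %||% "small"))
  .emit(unclass(st)[c("Xa", "q1", "du21", "Xa1", "Xa2", "phase",
                      "whole_membrane")],
        flags$out)
}

cli_geometry <- function(flags) {
  given <- c(theta = !is.null(flags[["theta-deg"]]),
             v = !is.null(flags$v), q1 = !is.null(flags$q1))
  if (sum(given) != 1)
    stop("give exactly one of --theta-deg, --v, --q1")
  theta <- if (given["theta"]) {
    .flag_num(flags, "theta-deg") * pi / 180
  } else if (given["v"]) {
    v <- .flag_num(flags, "v")
    if (v == 1) pi else
      uniroot(function(th) cap_geometry(th)$v - v, c(1e-9, pi),
              tol = 1e-14)$root
  } else {
    q1 <- .flag_num(flags, "q1")
    if (q1 <= 0.5 || q1 > 1) stop("q1 must lie in (1/2, 1]")
    acos(2 / q1 - 3)
  }
  g <- cap_geometry(theta)
  .emit(list(theta_deg = theta * 180 / pi, theta_rad = theta,
             q1 = g$q1, v = g$v, A1_over_A = g$A1 / g$A,
             A2_over_A = g$A2 / g$A),
        flags$out)
}

cli_adhesion <- function(flags) {
  kappa <- .flag_num(flags, "kappa-J")
  W <- .flag_num(flags, "W-mJ-per-m2") * 1e-3   # to J/m^2
  Lstar <- .flag_num(flags, "Lstar-um") * 1e-6  # to m
  Wstar <- strong_adhesion_threshold(kappa, Lstar)
  .emit(list(Rco_m = contact_radius(kappa, W),
             Wstar_mJ_per_m2 = Wstar * 1e3,
             Wstar_kBT_per_100nm2 = kBT_room(Wstar * (1e-7)^2),
             kappa_kBT = kBT_room(kappa),
             strong = abs(W) > Wstar),
        flags$out)
}

cli_mc <- function(flags) {
  L <- as.integer(.flag_num(flags, "L"))
  q1 <- .flag_num(flags, "q1", 0)
  cc <- as.integer(round(q1 * L))
  sp <- lattice_spec(L, cc)
  pp <- mc_params(tbar = .flag_num(flags, "tbar"),
                  dmu = .flag_num(flags, "dmu", 0),
                  du1 = .flag_num(flags, "du1", 0),
                  du2 = .flag_num(flags, "du2", 0),
                  sweeps = as.integer(.flag_num(flags, "sweeps", 2000)),
                  burnin = as.integer(.flag_num(flags, "burnin", 200)),
                  seed = as.integer(.flag_num(flags, "seed", 12345)))
  res <- metropolis_run(sp, pp)
  .emit(unclass(res)[c("n1_mean", "n1_se", "n2_mean", "n2_se",
                       "n_mean", "m_mean", "e_mean", "acceptance")],
        flags$out)
}

cli_fixtures <- function(flags) {
  if (is.null(flags$out)) stop("missing required flag --out")
  files <- generate_fixtures(flags$out)
  message("wrote ", length(files), " fixture files to ", flags$out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
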