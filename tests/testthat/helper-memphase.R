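# shared helpers for the memphase test suite

# frozen high-precision oracle values (computed once with an independent
# arbitrary-precision evaluator of the closed forms)
TC_EXACT <- 2.2691853142130220        # 2 / log(1 + sqrt(2))
UPS_2 <- 0.91131937787749598          # [1 - sinh(1)^-4]^(1/8)
XBETA_2 <- 0.044340311061252011       # (1 - UPS_2) / 2
V_HEMISPHERE <- 0.769800358919501     # reduced volume of a half-sphere

# random valid interaction parameters with J > 0
random_interaction <- function() {
  repeat {
    u <- runif(3, -2, 2)
    J <- (2 * u[2] - u[1] - u[3]) / 4
    if (J > 0.05) {
      return(interaction_params(Uaa = u[1], Uab = u[2], Ubb = u[3],
                                kBT = runif(1, 0.5, 3)))
    }
  }
}

# lever-rule residual of a segment state
lever_residual <- function(st) {
  st$q1 * st$Xa1 + (1 - st$q1) * st$Xa2 - st$Xa
}
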