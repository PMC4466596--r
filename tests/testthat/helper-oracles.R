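# Shared fixtures and independent oracle implementations used across the
# suite.  Oracles are written from the model definitions directly and do
# not call the package's corresponding implementation path.

ref_couplings <- function(...) effective_couplings(rule_params(...))

# Independent line-by-line transcription of the effective-coupling
# formulas (loop-structured rather than vectorised, and phrased via the
# inhibitory-rate linearisation), used to cross-check effective_couplings().
oracle_couplings <- function(s_nmda = 1, s_gaba = 1) {
  C_E <- 0.8; C_I <- 0.2; C_ext <- 800; f <- 0.15
  c_I <- 615; I_I <- 177; g_I2 <- 1.7876; r0 <- 11.3721
  V_E <- -53.4; V_I <- -51.1; V_rev <- -70
  r_ext <- 3; r_ns <- 2
  tau_GABA <- 0.010; tau_AMPA <- 0.002; tau_NMDA <- 100
  gamma <- 0.641
  w_plus <- 1.68
  w_minus <- 1 - f * (w_plus - 1) / (1 - f)
  mg_gate <- 0.91; eta <- 0.076
  gN_E <- s_nmda * 0.3 / (1 + mg_gate * exp(-0.062 * V_E) / 3.57)
  gN_I <- 0.258 / (1 + mg_gate * exp(-0.062 * V_I) / 3.57)
  # inhibitory loop: current on I -> rate change -> GABA current on E
  gaba_drive <- s_gaba * 1.3 * (V_E - V_rev) * tau_GABA
  loop <- function(current_on_I) {
    gaba_drive * C_I * (c_I * eta / g_I2) * current_on_I
  }
  J_N11 <- loop(gN_I * V_I * f * C_E) - gN_E * V_E * f * C_E * w_plus
  J_N12 <- gN_E * V_E * f * C_E * w_minus - loop(gN_I * V_I * f * C_E)
  J_A11 <- loop(0.086 * V_I * tau_AMPA * f * C_E) -
    0.1 * V_E * tau_AMPA * f * C_E * w_plus
  J_A12 <- 0.1 * V_E * tau_AMPA * f * C_E * w_minus -
    loop(0.086 * V_I * tau_AMPA * f * C_E)
  l <- loop(0.00162 * V_I * tau_AMPA * C_ext) -
    0.0021 * V_E * tau_AMPA * C_ext
  ns <- (1 - 2 * f) * C_E
  m <- loop(0.086 * V_I * tau_AMPA * ns) -
    0.1 * V_E * tau_AMPA * ns * w_minus
  n <- loop(gN_I * V_I * ns) - gN_E * V_E * ns * w_minus
  z <- gamma * tau_NMDA * r_ns / 1000
  psi_ns <- z / (1 + z)
  I0 <- l * r_ext + m * r_ns + n * psi_ns +
    gaba_drive * C_I * eta * (I_I / g_I2 - r0)
  list(J_N11 = J_N11, J_N12 = J_N12, J_A11 = J_A11, J_A12 = J_A12,
       I0 = I0, w_minus = w_minus)
}

# independent transcription of the noise-free gating right-hand side
oracle_rule_drift <- function(cpl, S1, S2, I1 = 0, I2 = 0) {
  H <- function(x_self, x_other) {
    a <- 239400 * cpl$J_A11 + 270
    b <- 97000 * cpl$J_A11 + 108
    d <- -30 * cpl$J_A11 + 0.154
    fA <- 0
    if (x_other > 0.4) fA <- cpl$J_A12 * (-276 * x_other + 106)
    u <- a * x_self - fA - b
    if (abs(u) < 1e-9) 1 / d else u / (1 - exp(-d * u))
  }
  x1 <- cpl$J_N11 * S1 - cpl$J_N12 * S2 + cpl$I0 + I1
  x2 <- cpl$J_N11 * S2 - cpl$J_N12 * S1 + cpl$I0 + I2
  r1 <- H(x1, x2)
  r2 <- H(x2, x1)
  c(-S1 / 100 + (1 - S1) * 0.641 * r1 / 1000,
    -S2 / 100 + (1 - S2) * 0.641 * r2 / 1000)
}

# independent transcription of the reduced decision drift
oracle_decision_drift <- function(beta, X, Y, Z, dI, alpha = 1,
                                  tau = 100) {
  c((alpha * (dI[1] - dI[2]) / 2 + beta * X * Z) / tau,
    (alpha * (dI[3] - dI[4]) / 2 - beta * Y * Z) / tau,
    (alpha * (dI[1] + dI[2] - dI[3] - dI[4]) / 4 +
       beta * (X^2 - Y^2) / 4) / tau)
}

# brute-force exact multinomial p-value by full outcome enumeration
oracle_multinomial_p <- function(observed, probs) {
  N <- sum(observed)
  probs <- probs / sum(probs)
  grid <- expand.grid(x1 = 0:N, x2 = 0:N, x3 = 0:N)
  grid <- grid[rowSums(grid) <= N, ]
  grid$x4 <- N - rowSums(grid)
  pmf <- apply(grid, 1, function(x) stats::dmultinom(x, prob = probs))
  p0 <- stats::dmultinom(observed, prob = probs)
  sum(pmf[pmf <= p0 * (1 + 1e-12)])
}

# two-sided binomial exact test by the same at-most-as-likely rule
oracle_binomial_p <- function(k, n, q) {
  pmf <- stats::dbinom(0:n, n, q)
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-12)])
}

# a tiny deterministic behaviour log built by hand (no simulation)
toy_log <- function() {
  tibble::tibble(
    trial = 1:8,
    condition = c("baseline", "baseline", "baseline", "distractor",
                  "baseline", "switch", "baseline", "ambiguous"),
    upper_digit = c(3L, 4L, 7L, 2L, 8L, 3L, 1L, 6L),
    lower_digit = c(NA, NA, NA, 9L, NA, 8L, NA, 2L),
    gray_upper = c(127L, 127L, 127L, 180L, 127L, 75L, 127L, 127L),
    gray_lower = c(NA, NA, NA, 75L, NA, 180L, NA, 120L),
    decision = c("odd", "even", "odd", "even", "even", "gt5", "odd",
                 "none"),
    rt_ms = c(512, 640, 587, 701, 633, 905, 498, NA),
    correct = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
}
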