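#' Effective transfer function of a selective population
#'
#' Firing rate of a selective excitatory population as a function of its
#' own effective input current and the other population's current.  The
#' AMPA-mediated self-coupling enters through current-dependent gain,
#' threshold and curvature coefficients
#' `a = 239400 J_A_self + 270`, `b = 97000 J_A_self + 108`,
#' `d = -30 J_A_self + 0.154`, and the cross-population AMPA contribution
#' `f_A = J_A_cross (-276 x_other + 106)` switches on only above
#' `x_other = 0.4` (Heaviside with `theta(0) = 0`).  The removable
#' singularity of `u / (1 - exp(-d u))` at `u = 0` takes its limit value
#' `1/d`.
#'
#' @param x_self,x_other effective input currents (nA); vectorised.
#' @param j_a_self,j_a_cross AMPA-mediated effective couplings.
#' @return Firing rate(s) in Hz (non-negative).
#' @export
rate_transfer <- function(x_self, x_other, j_a_self, j_a_cross) {
  a <- 239400 * j_a_self + 270
  b <- 97000 * j_a_self + 108
  d <- -30 * j_a_self + 0.154
  f_a <- ifelse(x_other > 0.4, j_a_cross * (-276 * x_other + 106), 0)
  u <- a * x_self - f_a - b
  ifelse(abs(u) < 1e-9, 1 / d, u / (1 - exp(-d * u)))
}

#' Deterministic drift of the rule module
#'
#' Noise-free right-hand side of the two-dimensional gating dynamics
#' `dS_i/dt = -S_i/tau_NMDA + (1 - S_i) gamma r_i / 1000` with rates from
#' [rate_transfer()] at the effective currents
#' `x_1 = J_N11 S1 - J_N12 S2 + I0 + I1` (and symmetrically for `x_2`).
#' Time is in ms, rates in Hz.
#'
#' @param couplings an [effective_couplings()] object.
#' @param S1,S2 synaptic gating variables; vectorised.
#' @param I1,I2 selective input currents (nA).
#' @return A tibble with columns `S1`, `S2`, `dS1`, `dS2`, `r1`, `r2`.
#' @export
rule_drift <- function(couplings, S1, S2, I1 = 0, I2 = 0) {
  x1 <- couplings$J_N11 * S1 - couplings$J_N12 * S2 + couplings$I0 + I1
  x2 <- couplings$J_N22 * S2 - couplings$J_N21 * S1 + couplings$I0 + I2
  r1 <- rate_transfer(x1, x2, couplings$J_A11, couplings$J_A12)
  r2 <- rate_transfer(x2, x1, couplings$J_A22, couplings$J_A21)
  tibble(
    S1 = S1, S2 = S2,
    dS1 = -S1 / couplings$tau_NMDA + (1 - S1) * couplings$gamma * r1 / 1000,
    dS2 = -S2 / couplings$tau_NMDA + (1 - S2) * couplings$gamma * r2 / 1000,
    r1 = r1, r2 = r2
  )
}

#' Relax the noise-free rule module to a fixed point
#'
#' Integrates the deterministic dynamics from a starting state until the
#' drift norm falls below `tol` (used e.g. to initialise trials at the
#' rule-1 attractor from (0.8, 0.1)).
#'
#' @param couplings an [effective_couplings()] object.
#' @param init length-2 starting state `(S1, S2)`.
#' @param I1,I2 constant selective inputs during relaxation.
#' @param dt integration step (ms).
#' @param max_ms maximum integration time (ms).
#' @param tol drift-norm convergence tolerance.
#' @return A tibble with one row: `S1`, `S2`, `r1`, `r2`, `t_settle`.
#' @export
settle_rule <- function(couplings, init = c(0.8, 0.1), I1 = 0, I2 = 0,
                        dt = 0.5, max_ms = 2000, tol = 1e-8) {
  out <- cpp_settle_rule(cpl_vec(couplings), init[1], init[2], I1, I2,
                         dt, max_ms, tol)
  tibble(S1 = out[1], S2 = out[2], r1 = out[3], r2 = out[4],
         t_settle = out[5])
}

#' Simulate the stochastic rule module
#'
#' Euler-Maruyama integration of the gating variables with
#' Ornstein-Uhlenbeck noise (time constant `tau_AMPA = 2` ms, diffusion
#' parameter `sigma_rule`, exactly discretised so the stationary noise
#' variance is `sigma_rule^2/2`).  Gating variables are clamped to [0, 1]
#' after every step.
#'
#' @param couplings an [effective_couplings()] object.
#' @param sigma_rule OU diffusion parameter.
#' @param init length-2 initial state.
#' @param inputs either `NULL` (no selective input), a length-2 numeric
#'   `c(I1, I2)` applied for the whole run, or a tibble with columns
#'   `t_on`, `t_off`, `I1`, `I2` defining piecewise-constant input windows
#'   (ms).
#' @param duration run length (ms); must be a multiple of `dt`.
#' @param dt step (ms); refused above `tau_AMPA/2 = 1` ms.
#' @param seed integer seed.
#' @param thin record every `thin`-th step.
#' @return A tibble of class `rule_trajectory` with columns `t`, `S1`,
#'   `S2`, `r1`, `r2`, `noise1`, `noise2`.
#' @examples
#' cpl <- effective_couplings(rule_params())
#' tr <- simulate_rule(cpl, sigma_rule = 0, init = c(0.8, 0.1),
#'                     duration = 500, seed = 1)
#' tail(tr, 1)
#' @export
simulate_rule <- function(couplings, sigma_rule = 0.1, init = c(0.1, 0.1),
                          inputs = NULL, duration = 2000, dt = 0.5,
                          seed = 1, thin = 1L) {
  if (dt > couplings$tau_AMPA / 2) {
    stop("dt must not exceed tau_AMPA/2 = ", couplings$tau_AMPA / 2, " ms")
  }
  n_steps <- round(duration / dt)
  if (abs(n_steps * dt - duration) > 1e-9) {
    stop("duration must be a multiple of dt")
  }
  I1 <- numeric(n_steps)
  I2 <- numeric(n_steps)
  if (!is.null(inputs)) {
    if (is.numeric(inputs) && length(inputs) == 2) {
      I1[] <- inputs[1]
      I2[] <- inputs[2]
    } else {
      stopifnot(all(c("t_on", "t_off", "I1", "I2") %in% names(inputs)))
      tgrid <- (seq_len(n_steps) - 1) * dt
      for (i in seq_len(nrow(inputs))) {
        on <- tgrid >= inputs$t_on[i] & tgrid < inputs$t_off[i]
        I1[on] <- I1[on] + inputs$I1[i]
        I2[on] <- I2[on] + inputs$I2[i]
      }
    }
  }
  m <- cpp_simulate_rule(cpl_vec(couplings), abs(sigma_rule),
                         init[1], init[2], I1, I2, dt,
                         couplings$tau_AMPA, as.integer(seed),
                         as.integer(thin))
  out <- tibble(t = m[, 1], S1 = m[, 2], S2 = m[, 3],
                r1 = m[, 4], r2 = m[, 5],
                noise1 = m[, 6], noise2 = m[, 7])
  class(out) <- c("rule_trajectory", class(out))
  attr(out, "sigma_rule") <- abs(sigma_rule)
  attr(out, "dt") <- dt
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Locate fixed points of the noise-free rule module
#'
#' Multi-start Newton root finding on the deterministic drift (default: a
#' 5 x 5 grid of starts over the unit square), merging duplicates within
#' 1e-6 and classifying stability by the sign of the Jacobian eigenvalue
#' real parts.  At standard parameters and zero inputs the module has
#' exactly three stable states: a symmetric low-rate spontaneous state and
#' two high-activity rule states that map onto each other under exchange
#' of the populations.
#'
#' @param couplings an [effective_couplings()] object.
#' @param I1,I2 selective input currents.
#' @param n_starts starts per axis.
#' @param tol Newton convergence tolerance on the drift norm.
#' @return A tibble with columns `S1`, `S2`, `r1`, `r2`, `stable`, sorted
#'   by `S1`.  Empty (with a warning) if no start converged.
#' @examples
#' fp <- find_fixed_points(effective_couplings(rule_params()))
#' fp[fp$stable, ]
#' @export
find_fixed_points <- function(couplings, I1 = 0, I2 = 0, n_starts = 5,
                              tol = 1e-10) {
  drift2 <- function(S) {
    d <- rule_drift(couplings, S[1], S[2], I1, I2)
    c(d$dS1, d$dS2)
  }
  grid <- seq(0.02, 0.98, length.out = n_starts)
  starts <- as.matrix(expand.grid(S1 = grid, S2 = grid))
  fps <- NULL
  for (i in seq_len(nrow(starts))) {
    S <- starts[i, ]
    ok <- FALSE
    for (it in 1:200) {
      f0 <- drift2(S)
      if (sqrt(sum(f0^2)) < tol) { ok <- TRUE; break }
      h <- 1e-7
      J <- cbind((drift2(S + c(h, 0)) - f0) / h,
                 (drift2(S + c(0, h)) - f0) / h)
      step <- tryCatch(solve(J, -f0), error = function(e) NULL)
      if (is.null(step)) break
      # damped Newton keeps iterates in a sane region
      if (max(abs(step)) > 0.5) step <- step * 0.5 / max(abs(step))
      S <- S + step
      if (any(!is.finite(S)) || any(S < -0.2) || any(S > 1.2)) break
    }
    if (!ok) next
    if (!is.null(fps) &&
        any(sqrt((fps[, 1] - S[1])^2 + (fps[, 2] - S[2])^2) < 1e-6)) next
    f0 <- drift2(S)
    h <- 1e-6
    J <- cbind((drift2(S + c(h, 0)) - f0) / h,
               (drift2(S + c(0, h)) - f0) / h)
    ev <- eigen(J, only.values = TRUE)$values
    fps <- rbind(fps, c(S, as.numeric(all(Re(ev) < 0))))
  }
  if (is.null(fps)) {
    warning("no fixed point converged")
    return(tibble(S1 = numeric(), S2 = numeric(), r1 = numeric(),
                  r2 = numeric(), stable = logical()))
  }
  rates <- rule_drift(couplings, fps[, 1], fps[, 2], I1, I2)
  out <- tibble(S1 = fps[, 1], S2 = fps[, 2],
                r1 = rates$r1, r2 = rates$r2,
                stable = fps[, 3] > 0)
  dplyr::arrange(out, .data$S1)
}

#' Classify the stable states of the rule module
#'
#' Labels the stable fixed points as `spontaneous` (symmetric, low rate),
#' `rule1` (S1 dominant) or `rule2` (S2 dominant).
#'
#' @param fixed_points output of [find_fixed_points()].
#' @return The input tibble restricted to stable rows with a `state`
#'   column.
#' @export
classify_states <- function(fixed_points) {
  st <- dplyr::filter(fixed_points, .data$stable)
  st$state <- dplyr::case_when(
    abs(st$S1 - st$S2) < 1e-4 ~ "spontaneous",
    st$S1 > st$S2 ~ "rule1",
    TRUE ~ "rule2"
  )
  st
}

#' Sample path of the Ornstein-Uhlenbeck noise process
#'
#' Exposes the exactly-discretised OU update used inside all simulators
#' (`x <- x e^{-dt/tau} + sigma/sqrt(2) sqrt(1 - e^{-2 dt/tau}) z`), whose
#' stationary variance is `sigma^2/2`.
#'
#' @param sigma diffusion parameter.
#' @param tau time constant (ms).
#' @param n_steps number of steps.
#' @param dt step (ms).
#' @param seed integer seed.
#' @return Numeric vector of the process values.
#' @export
ou_path <- function(sigma, tau = 2, n_steps = 1e5, dt = 0.5, seed = 1) {
  cpp_ou_path(sigma, tau, as.integer(n_steps), dt, as.integer(seed))
}
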