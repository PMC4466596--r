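#' Parameters of the reduced decision module
#'
#' The four-choice winner-take-all decision network is reduced to a
#' three-dimensional nonlinear drift-diffusion process in amplitudes
#' `(X, Y, Z)`.  `alpha` scales the external inputs (fixed at 1 in the
#' fitted model, where any scale is absorbed by the input parameters),
#' `beta` sets the strength of the quadratic winner-take-all terms,
#' `sigma_decision` the OU noise amplitude, and `threshold` the value the
#' population projections must cross for a decision (10, in the reduced
#' rate-equivalent units).  `tau` is the NMDA time constant (ms) on the
#' left-hand side of the amplitude equations.
#'
#' @param beta nonlinear term strength.
#' @param sigma_decision OU diffusion parameter (canonicalised by absolute
#'   value).
#' @param c_plus feed-forward weight from the rule populations.
#' @param alpha input scaling (default 1).
#' @param threshold decision threshold (default 10).
#' @param tau time constant in ms (default 100).
#' @return An object of class `decision_params`.
#' @export
decision_params <- function(beta = 0.1, sigma_decision = 0.03,
                            c_plus = 0.01, alpha = 1, threshold = 10,
                            tau = 100) {
  stopifnot(threshold > 0, tau > 0)
  structure(list(beta = beta, sigma_decision = abs(sigma_decision),
                 c_plus = c_plus, alpha = alpha, threshold = threshold,
                 tau = tau),
            class = "decision_params")
}

#' Deterministic drift of the decision module
#'
#' Amplitude equations of the reduction at the bifurcation of the
#' spontaneous state:
#' \deqn{\tau \dot X = \alpha (\delta I_1 - \delta I_2)/2 + \beta X Z}
#' \deqn{\tau \dot Y = \alpha (\delta I_3 - \delta I_4)/2 - \beta Y Z}
#' \deqn{\tau \dot Z = \alpha (\delta I_1 + \delta I_2 - \delta I_3 -
#'   \delta I_4)/4 + \beta (X^2 - Y^2)/4}
#' The origin is the spontaneous state; the four population directions
#' form a symmetric tetrahedron.
#'
#' @param params a [decision_params()] object.
#' @param X,Y,Z reduced amplitudes; vectorised.
#' @param dI1,dI2,dI3,dI4 per-population input increments.
#' @return A tibble with columns `dX`, `dY`, `dZ` (per ms).
#' @export
decision_drift <- function(params, X, Y, Z,
                           dI1 = 0, dI2 = 0, dI3 = 0, dI4 = 0) {
  a <- params$alpha
  b <- params$beta
  tibble(
    dX = (a * 0.5 * (dI1 - dI2) + b * X * Z) / params$tau,
    dY = (a * 0.5 * (dI3 - dI4) - b * Y * Z) / params$tau,
    dZ = (a * 0.25 * (dI1 + dI2 - dI3 - dI4) +
            b * 0.25 * (X^2 - Y^2)) / params$tau
  )
}

#' Project the reduced decision state onto the four populations
#'
#' Coefficients of the state on the directions corresponding to the
#' increase of a single selective population (the corners of the
#' tetrahedron): `p1 = X/2 + Z/2`, `p2 = -X/2 + Z/2`, `p3 = Y/2 - Z/2`,
#' `p4 = -Y/2 - Z/2`.  They sum to zero for every state.
#'
#' @param X,Y,Z reduced amplitudes; vectorised.
#' @return A tibble with columns `p1`..`p4`.
#' @export
project_populations <- function(X, Y, Z) {
  tibble(p1 = 0.5 * X + 0.5 * Z,
         p2 = -0.5 * X + 0.5 * Z,
         p3 = 0.5 * Y - 0.5 * Z,
         p4 = -0.5 * Y - 0.5 * Z)
}

#' Simulate one decision process
#'
#' Integrates the stochastic amplitude equations from the spontaneous
#' state (0, 0, 0), feeding the stimulus inputs `D` and the top-down rule
#' rates (times `c_plus`) only while the stimulus is on.  The first
#' population projection to cross the threshold determines the decision
#' and the crossing time is the reaction time; if no projection crosses by
#' the end of the trial the decision is `none` (coded 0).  If two
#' projections cross within one step the larger projection wins.
#'
#' @param params a [decision_params()] object.
#' @param D length-4 stimulus inputs to the four pools (the fitted model
#'   uses `c(D11, 0, D12, 0)`; incorrect-feature inputs are fixed at 0).
#' @param rule_rates either a tibble with columns `r1`, `r2` sampled at
#'   `dt` covering at least the stimulus window, or a length-2 numeric of
#'   constant rates.
#' @param stim_ms stimulus duration (ms).
#' @param trial_ms trial duration (ms).
#' @param dt step (ms), at most 1 ms.
#' @param seed integer seed.
#' @param keep_trajectory record the full (X, Y, Z) path.
#' @return A list with `decision` (0-4), `rt` (ms or NA) and optionally
#'   `trajectory` (a tibble `t`, `X`, `Y`, `Z`, `p1`..`p4`).
#' @export
simulate_decision <- function(params, D = c(0, 0, 0, 0),
                              rule_rates = c(0, 0), stim_ms = 900,
                              trial_ms = 2000, dt = 0.5, seed = 1,
                              keep_trajectory = FALSE) {
  stopifnot(dt <= 1, length(D) == 4)
  n_stim <- round(stim_ms / dt)
  if (is.data.frame(rule_rates)) {
    r1 <- rule_rates$r1
    r2 <- rule_rates$r2
  } else {
    r1 <- rep(rule_rates[1], n_stim)
    r2 <- rep(rule_rates[2], n_stim)
  }
  if (length(r1) < n_stim) {
    stop("rule_rates must cover the stimulus window")
  }
  res <- cpp_simulate_decision(params$alpha, params$beta,
                               params$sigma_decision, params$threshold,
                               params$tau, as.numeric(D), params$c_plus,
                               r1, r2, stim_ms, trial_ms, dt, 2,
                               as.integer(seed), isTRUE(keep_trajectory))
  out <- list(decision = res$decision,
              rt = if (res$decision > 0) res$rt else NA_real_)
  if (keep_trajectory) {
    tr <- res$trajectory
    colnames(tr) <- c("t", "X", "Y", "Z", "p1", "p2", "p3", "p4")
    out$trajectory <- as_tibble(as.data.frame(tr))
  }
  out
}
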