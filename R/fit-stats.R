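#' Condition-wise behavioural summary statistics
#'
#' Reduces trial-level behaviour to the sufficient statistics of the
#' likelihood: per condition, the counts of the four pool-coded decisions
#' (1 correct parity, 2 incorrect parity, 3 correct magnitude, 4 incorrect
#' magnitude) over responded trials, the reaction-time sample of every
#' (condition, decision) cell, and the number of non-responses.  Labelled
#' behaviour logs are pool-coded using each trial's digits; ambiguous
#' trials are excluded.
#'
#' @param x a `behavior_log` (see [simulate_session()],
#'   [read_behavior_log()]) or `behavior_sample` (see
#'   [simulate_dataset()]).
#' @return An object of class `behavior_summary`: a list with `counts`
#'   (condition x decision matrix), `rts` (nested list of reaction-time
#'   vectors), `n_none` and `n_total` (named per condition).
#' @export
summarize_behavior <- function(x) {
  conds <- intersect(c("baseline", "distractor", "switch"),
                     unique(x$condition))
  if (inherits(x, "behavior_sample") || is.integer(x$decision) ||
      is.numeric(x$decision)) {
    pool <- as.integer(x$decision)
    rt <- x$rt
  } else {
    validate_log(x)
    par_up <- ifelse(x$upper_digit %% 2 == 1, "odd", "even")
    mag_digit <- ifelse(is.na(x$lower_digit), x$upper_digit, x$lower_digit)
    mag <- ifelse(mag_digit > 5, "gt5", "lt5")
    pool <- dplyr::case_when(
      x$decision == "none" ~ 0L,
      x$decision %in% c("odd", "even") & x$decision == par_up ~ 1L,
      x$decision %in% c("odd", "even") ~ 2L,
      x$decision == mag ~ 3L,
      TRUE ~ 4L
    )
    rt <- x$rt_ms
  }
  counts <- matrix(0L, nrow = length(conds), ncol = 4,
                   dimnames = list(conds, paste0("pool", 1:4)))
  rts <- setNames(vector("list", length(conds)), conds)
  n_none <- setNames(integer(length(conds)), conds)
  n_total <- setNames(integer(length(conds)), conds)
  for (cc in conds) {
    i <- x$condition == cc
    n_total[cc] <- sum(i)
    n_none[cc] <- sum(i & pool == 0L)
    counts[cc, ] <- tabulate(pool[i], nbins = 4)
    rts[[cc]] <- lapply(1:4, function(p) rt[i & pool == p])
  }
  structure(list(counts = counts, rts = rts, n_none = n_none,
                 n_total = n_total),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat("Behavioural summary (responded-trial decision counts)\n")
  print(x$counts)
  if (any(x$n_none > 0)) {
    cat("non-responses:", paste(names(x$n_none), x$n_none, sep = "="), "\n")
  }
  invisible(x)
}

#' Exact multinomial goodness-of-fit p-value
#'
#' Probability, under a multinomial with category rates `probs`, of
#' observing the data `observed` or any outcome at most as probable:
#' `P = sum over {x : P(x) <= P(x0)} P(x)`, evaluated by exact enumeration
#' of all compositions of `N = sum(observed)` into four categories in log
#' space.  Floating-point probability ties are included with relative
#' tolerance 1e-12.
#'
#' @param observed integer vector of category counts (length 4).
#' @param probs category rates (non-negative, renormalised to sum 1).
#' @return The exact p-value in [0, 1]; `N = 0` returns 1 by convention.
#' @examples
#' exact_multinomial_p(c(1, 1, 1, 1), rep(0.25, 4))  # modal outcome: p = 1
#' @export
exact_multinomial_p <- function(observed, probs) {
  stopifnot(length(observed) == length(probs), length(observed) == 4,
            all(observed >= 0), all(probs >= 0), sum(probs) > 0)
  observed <- as.integer(round(observed))
  N <- sum(observed)
  if (N == 0) return(1)
  probs <- probs / sum(probs)
  lp <- ifelse(probs > 0, log(probs), -Inf)
  lfact <- lgamma(seq_len(N + 1))  # lfact[k+1] = log k!
  xlogp <- function(x, lpi) ifelse(x == 0L, 0, x * lpi)
  logpmf4 <- function(x1, x2, x3, x4) {
    lfact[N + 1] -
      lfact[x1 + 1] - lfact[x2 + 1] - lfact[x3 + 1] - lfact[x4 + 1] +
      xlogp(x1, lp[1]) + xlogp(x2, lp[2]) + xlogp(x3, lp[3]) +
      xlogp(x4, lp[4])
  }
  lp0 <- logpmf4(observed[1], observed[2], observed[3], observed[4])
  if (lp0 == -Inf) return(0)
  cutoff <- lp0 + log1p(1e-12)
  total <- 0
  for (x1 in 0:N) {
    m <- N - x1
    x2 <- rep.int(0:m, m:0 + 1L)
    x3 <- sequence(m:0 + 1L) - 1L
    x4 <- m - x2 - x3
    lpx <- logpmf4(x1, x2, x3, x4)
    keep <- lpx <= cutoff
    if (any(keep)) total <- total + sum(exp(lpx[keep]))
  }
  min(max(total, 0), 1)
}

#' Scaled two-sample Kolmogorov-Smirnov statistic
#'
#' Supremum distance between the empirical CDFs of two samples, scaled by
#' `sqrt(n m / (n + m))` so that its null distribution is asymptotically
#' the Kolmogorov distribution.
#'
#' @param sample_a,sample_b non-empty numeric samples.
#' @return The scaled statistic `D >= 0`.
#' @export
ks2_statistic <- function(sample_a, sample_b) {
  n <- length(sample_a)
  m <- length(sample_b)
  if (n == 0 || m == 0) stop("KS statistic undefined for empty samples")
  pts <- sort(c(sample_a, sample_b))
  Fa <- findInterval(pts, sort(sample_a)) / n
  Fb <- findInterval(pts, sort(sample_b)) / m
  max(abs(Fa - Fb)) * sqrt(n * m / (n + m))
}

#' Asymptotic Kolmogorov survival probability
#'
#' Probability of observing a scaled two-sample KS statistic at least `D`
#' under the null hypothesis of a common underlying distribution (Brownian
#' bridge limit).  For small `D` the theta-series form of the Kolmogorov
#' CDF, `F(D) = sqrt(2 pi)/D * sum_k exp(-(2k-1)^2 pi^2 / (8 D^2))`, is
#' used with `p = 1 - F(D)`; for large `D` the equivalent alternating
#' series `p = 2 sum_k (-1)^(k-1) exp(-2 k^2 D^2)`.  Series are truncated
#' when terms fall below 1e-12 and the result is clamped to [0, 1];
#' `p(0) = 1`.
#'
#' @param D scaled statistic (non-negative); vectorised.
#' @return p-value(s) in [0, 1].
#' @export
ks2_probability <- function(D) {
  one <- function(d) {
    if (!is.finite(d)) return(0)
    if (d < 0.05) return(1)   # F(d) < 1e-170 here
    if (d < 1) {
      s <- 0
      for (k in 1:20) {
        term <- exp(-(2 * k - 1)^2 * pi^2 / (8 * d^2))
        s <- s + term
        if (term < 1e-12) break
      }
      p <- 1 - sqrt(2 * pi) / d * s
    } else {
      s <- 0
      for (k in 1:20) {
        term <- (-1)^(k - 1) * exp(-2 * k^2 * d^2)
        s <- s + term
        if (abs(term) < 1e-12) break
      }
      p <- 2 * s
    }
    min(max(p, 0), 1)
  }
  vapply(D, one, numeric(1))
}

#' Gaussian shrinkage priors for the fitted parameter set
#'
#' Independent Gaussian priors, mean 1 for the two conductance scalings
#' and 0 for everything else, standard deviation 0.07 throughout.
#'
#' @return A tibble with columns `param`, `mu`, `sigma`.
#' @export
default_priors <- function() {
  nm <- names(fitted_params())
  tibble(param = nm,
         mu = ifelse(nm %in% c("s_nmda", "s_gaba"), 1, 0),
         sigma = 0.07)
}

log_prior <- function(params, priors = default_priors()) {
  params <- as_fitted_params(params)
  mu <- setNames(priors$mu, priors$param)[names(params)]
  sg <- setNames(priors$sigma, priors$param)[names(params)]
  sum(stats::dnorm(as.numeric(params), mu, sg, log = TRUE))
}

#' Composite log-likelihood of behavioural data given simulations
#'
#' The likelihood combines, per condition, a multinomial factor for the
#' subject's decision counts with category rates given by the simulated
#' decision probabilities, and, per (condition, decision) cell, the
#' two-sample Kolmogorov-Smirnov probability that the subject's and the
#' simulated reaction-time samples share an underlying distribution.
#' Simulated category rates are floored at `1/(2 n_sim)` (then
#' renormalised) so that observed-but-unsimulated decisions keep the
#' likelihood finite; KS factors enter only for cells with at least
#' `min_cell` reaction times on both sides; non-responses are excluded
#' (the multinomial is over the four response categories).
#'
#' @param subject a [summarize_behavior()] of the subject's data.
#' @param simulated a [summarize_behavior()] of model simulations
#'   (recommended: at least 256 trials per condition).
#' @param min_cell minimum per-cell sample size for a KS factor.
#' @return The log-likelihood (scalar).
#' @export
log_likelihood <- function(subject, simulated, min_cell = 3) {
  stopifnot(inherits(subject, "behavior_summary"),
            inherits(simulated, "behavior_summary"))
  conds <- rownames(subject$counts)
  missing_conds <- setdiff(conds, rownames(simulated$counts))
  if (length(missing_conds)) {
    stop("condition(s) absent from simulation: ",
         paste(missing_conds, collapse = ", "))
  }
  ll <- 0
  for (cc in conds) {
    obs <- subject$counts[cc, ]
    n_sim <- max(sum(simulated$counts[cc, ]), 1L)
    probs <- pmax(simulated$counts[cc, ] / n_sim, 1 / (2 * n_sim))
    probs <- probs / sum(probs)
    N <- sum(obs)
    if (N > 0) {
      ll <- ll + lgamma(N + 1) - sum(lgamma(obs + 1)) +
        sum(ifelse(obs == 0, 0, obs * log(probs)))
    }
    for (p in 1:4) {
      rs <- subject$rts[[cc]][[p]]
      rm <- simulated$rts[[cc]][[p]]
      if (length(rs) >= min_cell && length(rm) >= min_cell) {
        pv <- ks2_probability(ks2_statistic(rm, rs))
        ll <- ll + log(max(pv, 1e-300))
      }
    }
  }
  ll
}

#' Unnormalised log-posterior of a parameter set
#'
#' Simulates `n_sim` fresh trials per condition at `params`, scores the
#' subject's summary statistics with [log_likelihood()], and adds the
#' Gaussian shrinkage prior.  The likelihood is stochastic (re-simulated
#' at every call) unless the seed is held fixed.
#'
#' @param params a [fitted_params()] vector.
#' @param subject a [summarize_behavior()] of the subject's data.
#' @param priors prior table (see [default_priors()]).
#' @param n_sim simulated trials per condition.
#' @param seed integer seed for the simulation.
#' @param dt integration step (ms).
#' @return The unnormalised log-posterior (scalar).
#' @export
log_posterior <- function(params, subject, priors = default_priors(),
                          n_sim = 256, seed = 1, dt = 0.5) {
  sim <- simulate_dataset(params, n_per_condition = n_sim, seed = seed,
                          dt = dt)
  log_likelihood(subject, summarize_behavior(sim)) +
    log_prior(params, priors)
}
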