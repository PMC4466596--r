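#' Metropolis-Hastings sampling of the behavioural posterior
#'
#' Random-walk Metropolis-Hastings on the 13-dimensional parameter space
#' with an isotropic Gaussian proposal (`sigma_mh`, applied to every
#' coordinate) and the pseudo-marginal posterior of [log_posterior()]:
#' the likelihood is re-simulated with fresh noise at every evaluation
#' (set `common_random_numbers = TRUE` to hold the simulation seed fixed
#' across the chain, a lower-variance but approximate alternative).
#'
#' @param subject a [summarize_behavior()] of the subject's data.
#' @param priors prior table (see [default_priors()]).
#' @param n_steps chain length.
#' @param sigma_mh proposal standard deviation (default 0.01).
#' @param n_sim simulated trials per condition per evaluation.
#' @param seed integer seed (drives both proposals and simulations).
#' @param init starting parameter vector (default: prior means).
#' @param dt integration step (ms).
#' @param common_random_numbers reuse one simulation seed throughout.
#' @return An object of class `mh_chain`: list with `samples` (steps x 13
#'   matrix), `log_post`, `accepted` (logical), `acceptance_rate`, `seed`.
#' @export
metropolis_hastings <- function(subject, priors = default_priors(),
                                n_steps = 1000, sigma_mh = 0.01,
                                n_sim = 256, seed = 1, init = NULL,
                                dt = 0.5, common_random_numbers = FALSE) {
  stopifnot(n_steps >= 1)
  if (is.null(init)) {
    init <- as_fitted_params(setNames(priors$mu, priors$param))
  } else {
    init <- as_fitted_params(init)
  }
  p <- length(init)
  samples <- matrix(NA_real_, n_steps, p,
                    dimnames = list(NULL, names(init)))
  log_post <- numeric(n_steps)
  accepted <- logical(n_steps)
  theta <- as.numeric(init)
  sim_seed <- function(k) {
    if (common_random_numbers) derive_seed(seed, 1) else derive_seed(seed, k)
  }
  lp <- log_posterior(as_fitted_params(setNames(theta, names(init))),
                      subject, priors, n_sim, sim_seed(0), dt)
  with_seed(derive_seed(seed, 999983), {
    for (k in seq_len(n_steps)) {
      prop <- theta + rnorm(p, 0, sigma_mh)
      lp_prop <- log_posterior(
        as_fitted_params(setNames(prop, names(init))),
        subject, priors, n_sim, sim_seed(k), dt
      )
      if (log(runif(1)) < lp_prop - lp) {
        theta <- prop
        lp <- lp_prop
        accepted[k] <- TRUE
      }
      samples[k, ] <- theta
      log_post[k] <- lp
    }
  })
  rate <- mean(accepted)
  if (n_steps >= 10000 && rate == 0) {
    warning("chain accepted no proposals over ", n_steps, " steps")
  }
  structure(list(samples = samples, log_post = log_post,
                 accepted = accepted, acceptance_rate = rate,
                 seed = as.integer(seed), n_sim = n_sim,
                 sigma_mh = sigma_mh),
            class = "mh_chain")
}

#' @export
print.mh_chain <- function(x, ...) {
  cat("Metropolis-Hastings chain:", nrow(x$samples), "steps, acceptance",
      sprintf("%.1f%%", 100 * x$acceptance_rate), "\n")
  invisible(x)
}

#' Pool chains after burn-in
#'
#' Drops the first `burn_in` steps of every chain and concatenates the
#' remainders.
#'
#' @param chains a list of `mh_chain` objects (or a single chain).
#' @param burn_in steps to discard per chain.
#' @return A list of class `mh_pool` with `samples` and `log_post`.
#' @export
combine_and_burn <- function(chains, burn_in = 0) {
  if (inherits(chains, "mh_chain")) chains <- list(chains)
  stopifnot(length(chains) >= 1,
            length(unique(vapply(chains, function(c) ncol(c$samples),
                                 integer(1)))) == 1)
  keep <- lapply(chains, function(ch) {
    n <- nrow(ch$samples)
    stopifnot(burn_in < n)
    list(s = ch$samples[(burn_in + 1):n, , drop = FALSE],
         l = ch$log_post[(burn_in + 1):n])
  })
  structure(list(samples = do.call(rbind, lapply(keep, `[[`, "s")),
                 log_post = unlist(lapply(keep, `[[`, "l")),
                 n_chains = length(chains), burn_in = burn_in),
            class = "mh_pool")
}

#' Marginal kernel-density MAP estimate
#'
#' For every parameter, a Gaussian kernel density (Silverman bandwidth,
#' 512 grid points spanning the sampled range extended by 10 %) is fitted
#' to the pooled marginal; the MAP is the density argmax and the spread is
#' summarised by the full width at half maximum.  Degenerate (constant)
#' marginals return the constant with FWHM 0.
#'
#' @param pool an [combine_and_burn()] pool (or matrix of samples).
#' @return An object of class `posterior_summary`: tibble with columns
#'   `param`, `map`, `fwhm`, plus the density curves in
#'   `attr(, "densities")`.
#' @export
map_estimate <- function(pool) {
  samples <- if (is.matrix(pool)) pool else pool$samples
  stopifnot(nrow(samples) >= 1)
  nm <- colnames(samples)
  dens <- vector("list", ncol(samples))
  names(dens) <- nm
  res <- lapply(seq_len(ncol(samples)), function(j) {
    x <- samples[, j]
    rng <- range(x)
    if (diff(rng) < 1e-12) {
      return(tibble(param = nm[j], map = rng[1], fwhm = 0))
    }
    pad <- 0.1 * diff(rng)
    d <- stats::density(x, n = 512, from = rng[1] - pad, to = rng[2] + pad)
    dens[[j]] <<- tibble(param = nm[j], value = d$x, density = d$y)
    i_max <- which.max(d$y)
    half <- d$y[i_max] / 2
    above <- d$y >= half
    fwhm <- diff(range(d$x[above]))
    tibble(param = nm[j], map = d$x[i_max], fwhm = fwhm)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("posterior_summary", class(out))
  attr(out, "densities") <- dplyr::bind_rows(dens)
  out
}

#' Extract the MAP parameter vector
#'
#' @param summary a [map_estimate()] result.
#' @return A [fitted_params()] vector.
#' @export
map_params <- function(summary) {
  as_fitted_params(setNames(summary$map, summary$param))
}

#' Fit the model to one subject's behaviour
#'
#' Convenience wrapper running `n_chains` Metropolis-Hastings chains,
#' pooling them after burn-in, and computing the marginal MAP estimates.
#' The defaults are desk-scale; the published protocol (2 chains of 1e6
#' steps, 5e4 burn-in, 1024 simulated trials per condition per
#' evaluation) is available via `paper_scale()`.
#'
#' @param subject a behaviour log or [summarize_behavior()] summary.
#' @param priors prior table.
#' @param n_chains,n_steps,burn_in,n_sim,sigma_mh sampling settings.
#' @param seed integer seed.
#' @param dt integration step (ms).
#' @param common_random_numbers hold one simulation seed fixed across
#'   the whole fit (pilot and chains).  This removes the pseudo-marginal
#'   likelihood noise, at the cost of conditioning on one noise
#'   realisation; recommended for short desk-scale chains, whose
#'   acceptance otherwise collapses under the likelihood noise.
#' @param init chain initialisation: `"pilot"` (default) starts all
#'   chains, with proposal-scale jitter, from the best of `n_pilot`
#'   posterior evaluations at candidates drawn from a widened prior
#'   (three prior standard deviations); `"prior"` starts at the prior
#'   means; a named numeric vector is used as-is.  The pilot search
#'   avoids the non-responding plateau around the all-zero prior mean,
#'   where no simulated projection ever reaches threshold and the
#'   likelihood carries no gradient.
#' @param n_pilot candidate count for the pilot search.
#' @return A list of class `mh_fit`: `chains`, `pool`, `posterior`
#'   (a [map_estimate()] tibble), `map` (a [fitted_params()] vector).
#' @export
fit_behavior <- function(subject, priors = default_priors(),
                         n_chains = 2, n_steps = 20000,
                         burn_in = ceiling(n_steps / 10), n_sim = 256,
                         sigma_mh = 0.01, seed = 1, dt = 0.5,
                         init = c("pilot", "prior"), n_pilot = 96,
                         common_random_numbers = FALSE) {
  if (!inherits(subject, "behavior_summary")) {
    subject <- summarize_behavior(subject)
  }
  if (!is.numeric(init)) init <- match.arg(init)
  start <- if (is.numeric(init)) {
    as_fitted_params(init)
  } else if (identical(init, "pilot")) {
    pilot_start(subject, priors, n_pilot = n_pilot,
                n_sim = min(n_sim, 64), seed = derive_seed(seed, 17),
                dt = dt, common_random_numbers = common_random_numbers)
  } else {
    as_fitted_params(setNames(priors$mu, priors$param))
  }
  chains <- lapply(seq_len(n_chains), function(i) {
    jitter <- with_seed(derive_seed(seed, 23 * i), rnorm(13, 0, sigma_mh))
    metropolis_hastings(subject, priors, n_steps, sigma_mh, n_sim,
                        seed = derive_seed(seed, 7919 * i), dt = dt,
                        init = as_fitted_params(
                          setNames(as.numeric(start) + jitter,
                                   names(start))),
                        common_random_numbers = common_random_numbers)
  })
  pool <- combine_and_burn(chains, burn_in)
  # only |sigma| enters the dynamics, so the posterior over the noise
  # amplitudes is sign-symmetric; canonicalise before density estimation
  for (sc in intersect(c("sigma_rule", "sigma_decision"),
                       colnames(pool$samples))) {
    pool$samples[, sc] <- abs(pool$samples[, sc])
  }
  post <- map_estimate(pool)
  structure(list(chains = chains, pool = pool, posterior = post,
                 map = map_params(post), seed = as.integer(seed)),
            class = "mh_fit")
}

#' @export
print.mh_fit <- function(x, ...) {
  cat("Behavioural model fit:", length(x$chains), "chain(s),",
      nrow(x$pool$samples), "pooled samples\n")
  print(as.data.frame(x$posterior), digits = 4)
  invisible(x)
}

#' Paper-scale sampling settings
#'
#' The published protocol: two chains of one million steps each, 50,000
#' burn-in, 1024 simulated trials per condition per likelihood evaluation,
#' proposal standard deviation 0.01.
#'
#' @return A named list that can be spliced into [fit_behavior()].
#' @export
paper_scale <- function() {
  list(n_chains = 2, n_steps = 1000000, burn_in = 50000, n_sim = 1024,
       sigma_mh = 0.01)
}

#' Goodness-of-fit battery for a fitted parameter set
#'
#' Simulates the model at `params` and tests, per condition, the
#' subject's decision counts against the simulated decision rates with
#' the exact multinomial test, and, per (condition, decision) cell with
#' enough reaction times on both sides, the subject's against the
#' simulated reaction-time distribution with the two-sample
#' Kolmogorov-Smirnov probability (at least six tests per subject with
#' the standard design).
#'
#' @param subject a behaviour log or [summarize_behavior()] summary.
#' @param params the fitted (e.g. MAP) parameter vector.
#' @param n_sim simulated trials per condition.
#' @param seed integer seed.
#' @param min_cell minimum per-cell reaction-time count for a KS test.
#' @param dt integration step (ms).
#' @return A tibble with columns `test` (`multinomial`/`ks`), `condition`,
#'   `decision` (pool index, NA for multinomial tests) and `p`.
#' @export
goodness_of_fit <- function(subject, params, n_sim = 1024, seed = 1,
                            min_cell = 3, dt = 0.5) {
  if (!inherits(subject, "behavior_summary")) {
    subject <- summarize_behavior(subject)
  }
  sim <- summarize_behavior(
    simulate_dataset(params, n_per_condition = n_sim, seed = seed, dt = dt)
  )
  out <- list()
  for (cc in rownames(subject$counts)) {
    n_s <- max(sum(sim$counts[cc, ]), 1L)
    probs <- pmax(sim$counts[cc, ] / n_s, 1 / (2 * n_s))
    probs <- probs / sum(probs)
    out[[length(out) + 1]] <- tibble(
      test = "multinomial", condition = cc, decision = NA_integer_,
      p = exact_multinomial_p(subject$counts[cc, ], probs)
    )
    for (p in 1:4) {
      rs <- subject$rts[[cc]][[p]]
      rm <- sim$rts[[cc]][[p]]
      if (length(rs) >= min_cell && length(rm) >= min_cell) {
        out[[length(out) + 1]] <- tibble(
          test = "ks", condition = cc, decision = p,
          p = ks2_probability(ks2_statistic(rm, rs))
        )
      }
    }
  }
  dplyr::bind_rows(out)
}


# coarse posterior search used to initialise chains
pilot_start <- function(subject, priors, n_pilot = 96, n_sim = 64,
                        seed = 1, dt = 0.5,
                        common_random_numbers = FALSE) {
  nm <- priors$param
  cands <- with_seed(seed, {
    lapply(seq_len(n_pilot), function(k) {
      setNames(rnorm(length(nm), priors$mu, 3 * priors$sigma), nm)
    })
  })
  cands <- c(list(setNames(priors$mu, nm)), cands)
  scores <- vapply(seq_along(cands), function(k) {
    sim_seed <- if (common_random_numbers) derive_seed(seed, 1) else
      derive_seed(seed, k)
    log_posterior(as_fitted_params(cands[[k]]), subject, priors,
                  n_sim = n_sim, seed = sim_seed, dt = dt)
  }, numeric(1))
  as_fitted_params(cands[[which.max(scores)]])
}
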