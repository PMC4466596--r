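test_that("exact multinomial test agrees with brute-force enumeration and its edge cases", {
  expect_equal(exact_multinomial_p(c(1, 1, 1, 1), rep(0.25, 4)), 1)
  expect_equal(exact_multinomial_p(c(0, 0, 0, 0), rep(0.25, 4)), 1)
  expect_equal(exact_multinomial_p(c(0, 0, 0, 2), c(0.5, 0.3, 0.2, 0)), 0)

  set.seed(31)
  for (k in 1:12) {
    N <- sample(2:8, 1)
    probs <- runif(4)
    probs <- probs / sum(probs)
    obs <- as.vector(stats::rmultinom(1, N, probs))
    expect_equal(exact_multinomial_p(obs, probs),
                 oracle_multinomial_p(obs, probs), tolerance = 1e-10)
    # joint category permutation leaves the p-value unchanged
    perm <- sample(4)
    expect_equal(exact_multinomial_p(obs[perm], probs[perm]),
                 exact_multinomial_p(obs, probs), tolerance = 1e-12)
  }

  # reduces to the two-sided exact binomial on two live categories
  for (k in 1:6) {
    q <- runif(1, 0.1, 0.9)
    n <- sample(5:40, 1)
    x <- rbinom(1, n, q)
    expect_equal(exact_multinomial_p(c(x, n - x, 0, 0), c(q, 1 - q, 0, 0)),
                 oracle_binomial_p(x, n, q), tolerance = 1e-10)
  }
})

test_that("KS statistic and probability match the reference implementation", {
  expect_equal(ks2_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  n <- 10
  expect_equal(ks2_statistic(1:n, 1:n + 100), sqrt(n / 2))
  expect_error(ks2_statistic(numeric(0), 1:3), "empty")

  expect_equal(ks2_probability(0), 1)
  expect_equal(ks2_probability(50), 0)
  D <- seq(0.05, 4, by = 0.05)
  expect_true(all(diff(ks2_probability(D)) <= 1e-12))

  set.seed(8)
  for (k in 1:100) {
    a <- rnorm(sample(20:200, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(20:200, 1), mean = runif(1, 0, 1))
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(ks2_statistic(a, b),
                 unname(ref$statistic) *
                   sqrt(length(a) * length(b) / (length(a) + length(b))),
                 tolerance = 1e-10)
    expect_equal(ks2_probability(ks2_statistic(a, b)),
                 ref$p.value, tolerance = 1e-3)
  }
})

test_that("the composite likelihood has the stated product structure", {
  mk_summary <- function(counts, rts) {
    conds <- rownames(counts)
    structure(list(counts = counts,
                   rts = setNames(rts, conds),
                   n_none = setNames(rep(0L, length(conds)), conds),
                   n_total = setNames(rowSums(counts), conds)),
              class = "behavior_summary")
  }
  rt_cell <- list(c(400, 500, 600, 700), numeric(0), numeric(0),
                  numeric(0))
  counts <- matrix(c(60, 20, 15, 5), 1, 4,
                   dimnames = list("baseline", paste0("pool", 1:4)))
  subj <- mk_summary(counts, list(rt_cell))
  simc <- mk_summary(counts * 4, list(rt_cell))  # proportional counts
  ll <- log_likelihood(subj, simc)
  # identical RT samples make every KS factor one, so the remainder is
  # exactly the multinomial log-pmf at the simulated rates
  probs <- pmax(counts * 4 / 400, 1 / 800)
  probs <- probs / sum(probs)
  expect_equal(ll, stats::dmultinom(counts[1, ], prob = probs,
                                    log = TRUE), tolerance = 1e-10)

  counts2 <- rbind(counts, switch = c(30, 5, 60, 5))
  rownames(counts2) <- c("baseline", "switch")
  subj2 <- mk_summary(counts2, list(rt_cell, rt_cell))
  simc2 <- mk_summary(counts2 * 4, list(rt_cell, rt_cell))
  ll2 <- log_likelihood(subj2, simc2)
  probs2 <- pmax(counts2[2, ] * 4 / 400, 1 / 800)
  probs2 <- probs2 / sum(probs2)
  # one extra condition adds exactly one extra multinomial factor
  expect_equal(ll2 - ll, stats::dmultinom(counts2[2, ], prob = probs2,
                                          log = TRUE), tolerance = 1e-10)
  # a subject condition the simulation lacks is an error
  expect_error(log_likelihood(subj2, simc), "absent")
})

test_that("the shrinkage prior peaks at its mean and drops quadratically", {
  pr <- default_priors()
  expect_identical(pr$mu[pr$param == "s_nmda"], 1)
  expect_true(all(pr$sigma == 0.07))
  at_mode <- ruleflex:::log_prior(
    as_fitted_params(setNames(pr$mu, pr$param)), pr)
  moved <- as_fitted_params(setNames(pr$mu, pr$param))
  moved[["s_nmda"]] <- 1 + 3 * 0.07
  expect_equal(at_mode - ruleflex:::log_prior(moved, pr), 4.5,
               tolerance = 1e-10)
})

test_that("the stochastic posterior is reproducible under a seed and favours the generating parameters", {
  p <- reference_params()
  session <- generate_session(seed = 41)
  subj <- summarize_behavior(simulate_session(session, p, seed = 42))
  lp1 <- log_posterior(p, subj, n_sim = 64, seed = 9)
  lp2 <- log_posterior(p, subj, n_sim = 64, seed = 9)
  expect_identical(lp1, lp2)

  p_bad <- p
  p_bad[["d11"]] <- p[["d11"]] * 2
  p_bad[["d12"]] <- p[["d12"]] * 2
  p_bad[["i1_base"]] <- p[["i1_base"]] * 2
  diffs <- vapply(1:20, function(k) {
    log_posterior(p, subj, n_sim = 64, seed = 100 + k) -
      log_posterior(p_bad, subj, n_sim = 64, seed = 100 + k)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
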