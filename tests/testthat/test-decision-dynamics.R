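test_that("decision drift is zero at the origin, symmetric under pool relabelling and matches a duplicate transcription", {
  dp <- decision_params(beta = 0.4, sigma_decision = 0, c_plus = 0)
  d0 <- decision_drift(dp, 0, 0, 0)
  expect_identical(unlist(d0), c(dX = 0, dY = 0, dZ = 0))

  set.seed(5)
  for (k in 1:20) {
    s <- rnorm(3)
    dI <- runif(4, 0, 0.3)
    d <- decision_drift(dp, s[1], s[2], s[3], dI[1], dI[2], dI[3], dI[4])
    expect_equal(unname(unlist(d)),
                 oracle_decision_drift(dp$beta, s[1], s[2], s[3], dI),
                 tolerance = 1e-12)
    # swapping pools 1 and 2 with X -> -X leaves the system form-invariant
    dsw <- decision_drift(dp, -s[1], s[2], s[3], dI[2], dI[1], dI[3], dI[4])
    expect_equal(c(dsw$dX, dsw$dY, dsw$dZ), c(-d$dX, d$dY, d$dZ),
                 tolerance = 1e-12)
    # swapping the pairs (1,2) and (3,4) with X <-> Y, Z -> -Z
    dpair <- decision_drift(dp, s[2], s[1], -s[3],
                            dI[3], dI[4], dI[1], dI[2])
    expect_equal(c(dpair$dX, dpair$dY, dpair$dZ),
                 c(d$dY, d$dX, -d$dZ), tolerance = 1e-12)
  }
})

test_that("population projections are the tetrahedron coordinates and sum to zero", {
  expect_identical(unlist(project_populations(0, 0, 0)),
                   c(p1 = 0, p2 = 0, p3 = 0, p4 = 0))
  p <- project_populations(1, 0, 1)
  expect_identical(unlist(p), c(p1 = 1, p2 = 0, p3 = -0.5, p4 = -0.5))
  set.seed(2)
  pr <- project_populations(rnorm(50), rnorm(50), rnorm(50))
  expect_lt(max(abs(pr$p1 + pr$p2 + pr$p3 + pr$p4)), 1e-12)
})

test_that("noise-free decisions diverge in finite time and are threshold-insensitive", {
  dp0 <- decision_params(beta = 0.4, sigma_decision = 0, c_plus = 0)
  none <- simulate_decision(dp0, D = c(0, 0, 0, 0))
  expect_identical(none$decision, 0L)
  expect_true(is.na(none$rt))

  drive <- c(0.3, 0, 0, 0)
  lo <- simulate_decision(dp0, D = drive, dt = 0.1)
  hi <- simulate_decision(decision_params(beta = 0.4, sigma_decision = 0,
                                          c_plus = 0, threshold = 100),
                          D = drive, dt = 0.1)
  expect_identical(lo$decision, 1L)
  expect_identical(hi$decision, 1L)
  expect_lt((hi$rt - lo$rt) / lo$rt, 0.10)

  tr <- simulate_decision(dp0, D = drive, keep_trajectory = TRUE)
  # trajectory is truncated at passage, with the winning projection
  # accelerating into the threshold
  expect_equal(max(tr$trajectory$t), tr$rt)
  expect_true(all(diff(tail(tr$trajectory$p1, 200)) > 0))
})

test_that("symmetric inputs give equiprobable choices and drive increases own-choice probability", {
  cpl <- ref_couplings()
  dsym <- ruleflex:::cpp_simulate_trials(
    ruleflex:::cpl_vec(cpl), 0, 0.14, 0.14, 0, 0,
    rep(0.2, 4), 0, 1, 0.5, 0.5, 10, 100, 8000, 900, 2000, 0.5, 2,
    101, FALSE)
  counts <- tabulate(dsym[, 1], nbins = 4)
  n <- sum(counts)
  # binomial 99% band around 1/4 per choice
  band <- 2.576 * sqrt(0.25 * 0.75 * n)
  expect_true(all(abs(counts - n / 4) < band))

  # permutation equivariance: relabelling pools 1 and 2 swaps their rates
  dperm <- ruleflex:::cpp_simulate_trials(
    ruleflex:::cpl_vec(cpl), 0, 0.14, 0.14, 0, 0,
    c(0.25, 0.15, 0, 0), 0, 1, 0.5, 0.5, 10, 100, 4000, 900, 2000, 0.5,
    2, 102, FALSE)
  dswap <- ruleflex:::cpp_simulate_trials(
    ruleflex:::cpl_vec(cpl), 0, 0.14, 0.14, 0, 0,
    c(0.15, 0.25, 0, 0), 0, 1, 0.5, 0.5, 10, 100, 4000, 900, 2000, 0.5,
    2, 103, FALSE)
  p_perm <- tabulate(dperm[, 1], 4) / nrow(dperm)
  p_swap <- tabulate(dswap[, 1], 4) / nrow(dswap)
  se <- sqrt(0.5 / 4000)
  expect_lt(abs(p_perm[1] - p_swap[2]), 3 * se)
  expect_lt(abs(p_perm[2] - p_swap[1]), 3 * se)

  # monotonicity in the own-pool drive
  probs <- sapply(c(0.1, 0.2, 0.3), function(d11) {
    m <- ruleflex:::cpp_simulate_trials(
      ruleflex:::cpl_vec(cpl), 0, 0.14, 0.14, 0, 0,
      c(d11, 0.1, 0.1, 0.1), 0, 1, 0.5, 0.5, 10, 100, 3000, 900, 2000,
      0.5, 2, 104, FALSE)
    mean(m[, 1] == 1)
  })
  expect_true(all(diff(probs) > 0))
})

test_that("reaction times under stimulus drive are right-skewed", {
  dp <- decision_params(beta = 0.55, sigma_decision = 0.6, c_plus = 0)
  rts <- vapply(1:800, function(i) {
    simulate_decision(dp, D = c(0.2, 0, 0, 0), seed = i)$rt
  }, numeric(1))
  rts <- rts[!is.na(rts)]
  skew <- mean((rts - mean(rts))^3) / sd(rts)^3
  expect_gt(skew, 0)
})
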