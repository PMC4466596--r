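test_that("effective couplings satisfy the printed identities and match an independent transcription", {
  pc <- physio_constants()
  expect_equal(round(pc$w_minus, 2), 0.88)

  for (sv in list(c(1, 1), c(1.1, 0.9), c(0.8, 1.3))) {
    cpl <- ref_couplings(s_nmda = sv[1], s_gaba = sv[2])
    expect_identical(cpl$J_N22, cpl$J_N11)
    expect_identical(cpl$J_N21, cpl$J_N12)
    expect_identical(cpl$J_A22, cpl$J_A11)
    expect_identical(cpl$J_A21, cpl$J_A12)
    orc <- oracle_couplings(sv[1], sv[2])
    expect_equal(cpl$J_N11, orc$J_N11, tolerance = 1e-12)
    expect_equal(cpl$J_N12, orc$J_N12, tolerance = 1e-12)
    expect_equal(cpl$J_A11, orc$J_A11, tolerance = 1e-12)
    expect_equal(cpl$J_A12, orc$J_A12, tolerance = 1e-12)
    expect_equal(cpl$I0, orc$I0, tolerance = 1e-12)
  }
  expect_error(physio_constants(nonsense = 1), "unknown")
  expect_error(physio_constants(g_I2 = -1), "positive")
})

test_that("transfer function handles its singular point, linear tail and the Heaviside convention", {
  cpl <- ref_couplings()
  a <- 239400 * cpl$J_A11 + 270
  b <- 97000 * cpl$J_A11 + 108
  d <- -30 * cpl$J_A11 + 0.154
  # numerator exactly zero -> limit value 1/d
  x0 <- b / a
  expect_equal(rate_transfer(x0, 0, cpl$J_A11, cpl$J_A12), 1 / d,
               tolerance = 1e-6)
  # large input with the other population below threshold: H ~ a x - b
  x <- 2
  expect_equal(rate_transfer(x, 0.2, cpl$J_A11, cpl$J_A12), a * x - b,
               tolerance = 1e-8)
  # theta(0) = 0: at exactly 0.4 the cross term contributes nothing
  expect_identical(rate_transfer(0.5, 0.4, cpl$J_A11, cpl$J_A12),
                   rate_transfer(0.5, 0.1, cpl$J_A11, cpl$J_A12))
  expect_false(isTRUE(all.equal(
    rate_transfer(0.5, 0.41, cpl$J_A11, cpl$J_A12),
    rate_transfer(0.5, 0.1, cpl$J_A11, cpl$J_A12))))
  expect_true(all(rate_transfer(seq(-1, 2, 0.1), 0.3,
                                cpl$J_A11, cpl$J_A12) >= 0))
})

test_that("rule drift vanishes at fixed points, respects symmetry and matches a duplicate transcription", {
  cpl <- ref_couplings()
  fp <- find_fixed_points(cpl)
  for (i in seq_len(nrow(fp))) {
    d <- rule_drift(cpl, fp$S1[i], fp$S2[i])
    expect_lt(max(abs(c(d$dS1, d$dS2))), 1e-10)
  }
  d <- rule_drift(cpl, 0.37, 0.37, I1 = 0.05, I2 = 0.05)
  expect_equal(d$dS1, d$dS2)
  set.seed(11)
  for (k in 1:20) {
    S <- runif(2)
    I <- runif(2, -0.05, 0.1)
    d <- rule_drift(cpl, S[1], S[2], I[1], I[2])
    expect_equal(c(d$dS1, d$dS2),
                 oracle_rule_drift(cpl, S[1], S[2], I[1], I[2]),
                 tolerance = 1e-12)
  }
})

test_that("rule module has exactly three stable states with the expected structure", {
  cpl <- ref_couplings()
  fp <- find_fixed_points(cpl)
  st <- classify_states(fp)
  expect_identical(nrow(st), 3L)
  expect_setequal(st$state, c("spontaneous", "rule1", "rule2"))
  sp <- st[st$state == "spontaneous", ]
  expect_equal(sp$r1, sp$r2, tolerance = 1e-8)
  expect_equal(sp$r1, 3, tolerance = 1)   # low-rate state near 3 Hz
  r1 <- st[st$state == "rule1", ]
  r2 <- st[st$state == "rule2", ]
  # the two high states map onto each other under population exchange
  expect_equal(c(r1$S1, r1$S2, r1$r1, r1$r2),
               c(r2$S2, r2$S1, r2$r2, r2$r1), tolerance = 1e-6)
  expect_gt(r1$r1, 10)
})

test_that("small conductance perturbations preserve the attractor repertoire", {
  up_n <- classify_states(find_fixed_points(ref_couplings(s_nmda = 1.005)))
  expect_true(all(c("rule1", "rule2") %in% up_n$state))
  up_g <- classify_states(find_fixed_points(ref_couplings(s_gaba = 1.005)))
  expect_true("spontaneous" %in% up_g$state)
})

test_that("noise-free trajectories settle on fixed points and honour the step-size contract", {
  cpl <- ref_couplings()
  st <- classify_states(find_fixed_points(cpl))
  r1 <- st[st$state == "rule1", ]
  tr <- simulate_rule(cpl, sigma_rule = 0, init = c(0.8, 0.1),
                      duration = 3000, seed = 1, thin = 40)
  last <- tail(tr, 1)
  expect_equal(c(last$S1, last$S2), c(r1$S1, r1$S2), tolerance = 1e-4)
  # monotone approach to the attractor (after an initial transient)
  dist <- sqrt((tr$S1 - r1$S1)^2 + (tr$S2 - r1$S2)^2)
  expect_true(all(diff(dist[-(1:3)]) <= 1e-12))

  sp <- st[st$state == "spontaneous", ]
  tr2 <- simulate_rule(cpl, sigma_rule = 0, init = c(sp$S1, sp$S2),
                       duration = 500, seed = 1)
  expect_lt(max(abs(tr2$S1 - sp$S1)), 1e-8)
  expect_lt(max(abs(tr2$S2 - sp$S2)), 1e-8)

  expect_error(simulate_rule(cpl, dt = 1.5), "tau_AMPA/2")
  expect_error(simulate_rule(cpl, duration = 100.3, dt = 0.5), "multiple")
  t_a <- simulate_rule(cpl, 0.1, duration = 200, seed = 9)
  t_b <- simulate_rule(cpl, 0.1, duration = 200, seed = 9)
  expect_identical(t_a, t_b)
})

test_that("the Ornstein-Uhlenbeck noise reaches its stated stationary variance", {
  x <- ou_path(sigma = 0.2, tau = 2, n_steps = 4e5, dt = 0.5, seed = 3)
  x <- x[-(1:1000)]
  expect_equal(var(x), 0.2^2 / 2, tolerance = 0.05)
})
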