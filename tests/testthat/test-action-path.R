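test_that("the effective potential matches its definition and scales with noise", {
  cpl <- ref_couplings()
  fp <- classify_states(find_fixed_points(cpl))
  # at a fixed point |F| = 0, so V reduces to half the divergence
  for (i in seq_len(nrow(fp))) {
    h <- 1e-5
    div <- 1000 * (
      (ruleflex:::rule_field(cpl, fp$S1[i] + h, fp$S2[i])$F1 -
         ruleflex:::rule_field(cpl, fp$S1[i] - h, fp$S2[i])$F1) / (2 * h) +
        (ruleflex:::rule_field(cpl, fp$S1[i], fp$S2[i] + h)$F2 -
           ruleflex:::rule_field(cpl, fp$S1[i], fp$S2[i] - h)$F2) / (2 * h))
    expect_equal(effective_potential_v(cpl, fp$S1[i], fp$S2[i], 0.1),
                 div / 2, tolerance = 1e-6)
  }
  set.seed(21)
  S1 <- runif(20, 0.05, 0.95)
  S2 <- runif(20, 0.05, 0.95)
  # independent recomputation with a different differencing step
  D <- (0.1 / 2)^2
  f <- ruleflex:::rule_field(cpl, S1, S2)
  h2 <- 1e-6
  div2 <- 1000 * (
    (ruleflex:::rule_field(cpl, S1 + h2, S2)$F1 -
       ruleflex:::rule_field(cpl, S1 - h2, S2)$F1) / (2 * h2) +
      (ruleflex:::rule_field(cpl, S1, S2 + h2)$F2 -
         ruleflex:::rule_field(cpl, S1, S2 - h2)$F2) / (2 * h2))
  V_ref <- 1e6 * (f$F1^2 + f$F2^2) / (4 * D) + div2 / 2
  expect_equal(effective_potential_v(cpl, S1, S2, 0.1), V_ref,
               tolerance = 1e-6)
  # halving sigma quadruples the kinetic term but not the divergence term
  V1 <- effective_potential_v(cpl, S1, S2, 0.1)
  V2 <- effective_potential_v(cpl, S1, S2, 0.05)
  expect_equal(V2 - div2 / 2, 4 * (V1 - div2 / 2), tolerance = 1e-6)
})

test_that("the discretised action behaves like a line integral", {
  cpl <- ref_couplings()
  sig <- 0.1
  Dd <- (sig / 2)^2
  # degenerate path of coincident nodes
  p0 <- rbind(c(0.3, 0.3), c(0.3, 0.3))
  expect_equal(hj_action(p0, cpl, sig, E_eff = 5)$action, 0)

  path <- cbind(seq(0.55, 0.05, length.out = 51),
                seq(0.05, 0.55, length.out = 51) ^ 1.2)
  fwd <- hj_action(path, cpl, sig, E_eff = 8)
  bwd <- hj_action(path[51:1, ], cpl, sig, E_eff = 8)
  mid <- (path[-1, ] + path[-51, ]) / 2
  dl <- sqrt(rowSums(diff(path)^2))
  V <- effective_potential_v(cpl, mid[, 1], mid[, 2], sig)
  sym_part <- 2 * sum(sqrt(pmax(8 + V, 0) / Dd) * dl)
  # reversal flips only the drift-projection term
  expect_equal(fwd$action + bwd$action, sym_part, tolerance = 1e-8)

  # quadrature convergence on a fixed smooth path
  dense <- cbind(seq(0.55, 0.05, length.out = 201),
                 seq(0.05, 0.55, length.out = 201) ^ 1.2)
  a50 <- hj_action(path, cpl, sig, E_eff = 8)$action
  a200 <- hj_action(dense, cpl, sig, E_eff = 8)$action
  expect_lt(abs(a50 - a200) / abs(a200), 0.01)
})

test_that("minimal-action paths are symmetric, pass the spontaneous basin and beat the straight line", {
  L <- fp_steady_state(rule_params(sigma_rule = 0.1), n = 64, dt = 10)
  A <- minimize_path_action(L)   # default 50 line elements
  g <- glance(A)
  expect_true(all(g$converged))
  # direction symmetry of the minimal action under symmetric parameters
  expect_lt(abs(g$action[1] - g$action[2]) / g$action[1], 1e-3)
  # mirror-image optimal paths under population exchange
  f <- as.matrix(A$rule1_to_rule2$path)
  b <- as.matrix(A$rule2_to_rule1$path)
  expect_lt(max(abs(f - b[, 2:1])), 2 * L$h)
  # the path crosses the diagonal inside the basin of attraction of the
  # spontaneous state: the crossing point relaxes onto it
  mins <- landscape_minima(L)
  sp <- mins[mins$state == "spontaneous", ]
  cross <- f[which.min(abs(f[, 1] - f[, 2])), ]
  st <- settle_rule(L$couplings, init = cross, max_ms = 20000)
  expect_lt(sqrt((st$S1 - sp$S1)^2 + (st$S2 - sp$S2)^2), 0.05)
  # optimality and discretisation uniformity
  straight <- ruleflex:::polyline(rbind(f[1, ], f[nrow(f), ]), 51)
  expect_lte(A$rule1_to_rule2$action,
             hj_action(straight, L$couplings, 0.1, A$E_eff)$action)
  expect_lt(g$dl_cv[1], 0.05)

  # the penalty is regularisation, not physics
  A2 <- minimize_path_action(L, penalty = 2e5, directions = "forward")
  expect_lt(abs(A2$rule1_to_rule2$action - A$rule1_to_rule2$action) /
              A$rule1_to_rule2$action, 0.01)
})

test_that("the minimal action tracks noise and NMDA scaling in opposite directions", {
  act <- function(sN = 1, sig = 0.1) {
    L <- fp_steady_state(rule_params(sN, 1, sig), n = 48, dt = 10)
    minimize_path_action(L, n_elements = 30,
                         directions = "forward")$rule1_to_rule2$action
  }
  sweep_sigma <- vapply(c(0.09, 0.10, 0.11, 0.125, 0.15), function(s)
    act(sig = s), numeric(1))
  expect_true(all(diff(sweep_sigma) < 0))
  sweep_nmda <- vapply(c(0.9975, 1, 1.0025, 1.005), function(s)
    act(sN = s), numeric(1))
  expect_true(all(diff(sweep_nmda) > 0))
})
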