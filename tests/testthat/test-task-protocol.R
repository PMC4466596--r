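test_that("generated sessions satisfy the design constraints exhaustively", {
  s <- generate_session(seed = 4)
  expect_identical(nrow(s), 300L)
  expect_identical(sum(s$condition == "baseline"), 240L)
  expect_identical(sum(s$condition == "distractor"), 20L)
  expect_identical(sum(s$condition == "switch"), 20L)
  expect_identical(sum(s$condition == "ambiguous"), 20L)
  crit <- which(s$condition != "baseline")
  gaps <- diff(c(0, crit)) - 1
  expect_true(all(gaps >= 3 & gaps <= 6))
  expect_false(any(c(s$upper_digit, na.omit(s$lower_digit)) == 5))
  # cue brightness rules
  d <- s[s$condition == "distractor", ]
  expect_true(all(d$gray_upper >= 169 & d$gray_upper <= 195))
  expect_true(all(d$gray_lower == 255L - d$gray_upper))
  w <- s[s$condition == "switch", ]
  expect_true(all(w$gray_lower >= 169 & w$gray_lower <= 195))
  expect_true(all(w$gray_upper == 255L - w$gray_lower))
  a <- s[s$condition == "ambiguous", ]
  expect_true(all(a$gray_lower >= 117 & a$gray_lower <= 137))
  # rule-consistent correct decisions
  b <- s[s$condition %in% c("baseline", "distractor"), ]
  expect_true(all(b$correct_decision ==
                    ifelse(b$upper_digit %% 2 == 1, "odd", "even")))
  expect_true(all(w$correct_decision ==
                    ifelse(w$lower_digit > 5, "gt5", "lt5")))

  expect_identical(generate_session(seed = 4), s)
  expect_false(identical(generate_session(seed = 5), s))
  expect_error(session_design(n_baseline = 100), "unsatisfiable")
})

test_that("condition inputs follow the condition table", {
  p <- fitted_params(i1_base = 0.04, ibar_dist = 0.02, di_dist = 0,
                     ibar_switch = 0.01, di_switch = 0.06)
  b <- condition_inputs("baseline", p)
  expect_identical(c(b$I1, b$I2), c(0.04, 0))
  d <- condition_inputs("distractor", p)
  expect_equal(d$I1, d$I2)       # zero differential input
  expect_equal(d$I1, 0.06)
  w <- condition_inputs("switch", p)
  expect_equal(w$I2 - w$I1, 0.06)
  expect_equal(w$I1 + w$I2, 2 * (0.04 + 0.01))
  expect_error(condition_inputs("ambiguous", p), "not modelled")
})

test_that("deterministic trials reproduce the stimulus features and refuse ambiguous specs", {
  p0 <- reference_params()
  p0[["sigma_rule"]] <- 0
  p0[["sigma_decision"]] <- 0
  spec <- tibble::tibble(trial = 1L, condition = "baseline",
                         upper_digit = 7L, lower_digit = NA_integer_,
                         gray_upper = 127L, gray_lower = NA_integer_,
                         correct_decision = "odd")
  o1 <- simulate_trial(spec, p0, seed = 1)
  o2 <- simulate_trial(spec, p0, seed = 99)
  expect_identical(o1$decision, "odd")
  expect_identical(o1$rt_ms, o2$rt_ms)   # no stochasticity left
  expect_true(o1$correct)

  spec_even <- spec
  spec_even$upper_digit <- 4L
  spec_even$correct_decision <- "even"
  expect_identical(simulate_trial(spec_even, p0, seed = 1)$decision,
                   "even")

  # deterministic switch trial: the rule module flips and a magnitude
  # decision is taken
  spec_sw <- tibble::tibble(trial = 2L, condition = "switch",
                            upper_digit = 4L, lower_digit = 8L,
                            gray_upper = 80L, gray_lower = 175L,
                            correct_decision = "gt5")
  osw <- simulate_trial(spec_sw, p0, seed = 1)
  expect_true(osw$decision %in% c("gt5", "lt5"))
  expect_identical(osw$decision, "gt5")

  spec_amb <- spec
  spec_amb$condition <- "ambiguous"
  expect_error(simulate_trial(spec_amb, p0), "ambiguous")
})

test_that("simulated datasets are reproducible and accurate in the fitted regime", {
  p <- reference_params()
  d1 <- simulate_dataset(p, n_per_condition = 256, seed = 7)
  d2 <- simulate_dataset(p, n_per_condition = 256, seed = 7)
  expect_identical(d1, d2)
  base <- d1[d1$condition == "baseline", ]
  expect_gt(mean(base$decision == 1), 0.9)
  # non-response bookkeeping: none <=> missing reaction time
  expect_identical(d1$decision == 0, is.na(d1$rt))
})

test_that("condition-wise mean reaction times order baseline < distractor < switch", {
  d <- simulate_dataset(reference_params(), n_per_condition = 5000,
                        seed = 12)
  rt <- tapply(d$rt[d$decision > 0], d$condition[d$decision > 0], mean)
  expect_lt(rt[["baseline"]], rt[["distractor"]])
  expect_lt(rt[["distractor"]], rt[["switch"]])
})

test_that("behaviour logs round-trip through files and are validated", {
  log <- toy_log()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_behavior_log(log, path)
  back <- read_behavior_log(path)
  expect_equal(as.data.frame(back), as.data.frame(log))

  bad <- log
  bad$rt_ms[1] <- 2400
  expect_error(write_behavior_log(bad, path), "line 2")
  bad2 <- log
  bad2$condition[3] <- "oddball"
  expect_error(write_behavior_log(bad2, path), "line 4")

  session <- generate_session(seed = 2)
  full <- simulate_session(session, reference_params(), seed = 3)
  write_behavior_log(full, path)
  expect_identical(sum(read_behavior_log(path)$condition == "baseline"),
                   240L)
})
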