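#' The 13-dimensional fitted parameter set
#'
#' Subject-specific free parameters of the coupled rule/decision model:
#' conductance scalings (`s_nmda`, `s_gaba`), rule-module stimulus inputs
#' (`i1_base` for baseline, mean and differential inputs for distractor
#' and switch trials), bottom-up decision inputs towards the correct
#' parity (`d11`) and magnitude (`d12`) choices, the feed-forward rule
#' weight `c_plus`, the two noise amplitudes and the decision nonlinearity
#' `beta`.  The inputs to the incorrect-feature pools (`D21`, `D22`) and
#' the input scaling `alpha` are fixed (0, 0, 1).
#'
#' Noise amplitudes are canonicalised by absolute value when the model is
#' simulated; raw values are kept so that sampling under priors centred at
#' zero is unaffected.
#'
#' @param s_nmda,s_gaba conductance scalings.
#' @param i1_base baseline-trial input to the rule-1 population.
#' @param d11,d12 bottom-up drifts towards the correct parity/magnitude
#'   choice.
#' @param ibar_dist,di_dist mean and differential rule inputs on
#'   distractor trials.
#' @param ibar_switch,di_switch mean and differential rule inputs on
#'   switch trials.
#' @param c_plus feed-forward rule-to-decision weight.
#' @param sigma_rule,sigma_decision OU diffusion parameters.
#' @param beta decision nonlinearity.
#' @return A named numeric vector of class `fitted_params` (13 entries, in
#'   canonical order).
#' @export
fitted_params <- function(s_nmda = 1, s_gaba = 1, i1_base = 0,
                          d11 = 0, d12 = 0,
                          ibar_dist = 0, di_dist = 0,
                          ibar_switch = 0, di_switch = 0,
                          c_plus = 0, sigma_rule = 0,
                          sigma_decision = 0, beta = 0) {
  x <- c(s_nmda = s_nmda, s_gaba = s_gaba, i1_base = i1_base,
         d11 = d11, d12 = d12, ibar_dist = ibar_dist, di_dist = di_dist,
         ibar_switch = ibar_switch, di_switch = di_switch,
         c_plus = c_plus, sigma_rule = sigma_rule,
         sigma_decision = sigma_decision, beta = beta)
  stopifnot(length(x) == 13, all(is.finite(x)))
  structure(x, class = "fitted_params")
}

#' @rdname fitted_params
#' @details `as_fitted_params()` coerces a named numeric vector (in any
#'   order) to the canonical layout.
#' @param x a named numeric vector with the 13 parameter names.
#' @export
as_fitted_params <- function(x) {
  nm <- names(fitted_params())
  stopifnot(all(nm %in% names(x)))
  structure(setNames(as.numeric(x[nm]), nm), class = "fitted_params")
}

#' Representative fitted parameter set
#'
#' A single parameter vector in the fitted regime used as the package's
#' reference synthetic subject: it produces > 90 % correct baseline
#' decisions, ordered mean reaction times (baseline < distractor <
#' switch), reliable rule switching on switch trials, and the standard
#' potential landscape (`sigma_rule = 0.1`).  See the methods vignette for
#' how these values were chosen.
#'
#' @return A `fitted_params` vector.
#' @export
reference_params <- function() {
  fitted_params(
    s_nmda = 1, s_gaba = 1,
    i1_base = 0.02,
    d11 = 0.24, d12 = 0.15,
    ibar_dist = 0, di_dist = 0.01,
    ibar_switch = 0.02, di_switch = 0.08,
    c_plus = 0.008,
    sigma_rule = 0.1, sigma_decision = 0.9,
    beta = 0.55
  )
}

#' Session design of the stability/flexibility task
#'
#' Defaults follow the scanner task: 300 trials of 2 s (stimuli shown for
#' 900 ms), of which 240 are baseline parity judgements on a single digit
#' and 20 each are distractor, switch and ambiguous two-digit trials, with
#' every critical (non-baseline) trial separated from the next by three to
#' six baseline trials.  Digits are drawn from 1-9 excluding 5; relative
#' digit brightness carries the task cue (distractor: upper brighter, gray
#' value in [169, 195], lower = 255 - upper; switch: mirrored; ambiguous:
#' lower gray value in [117, 137] around the medium gray 127).
#'
#' @param n_baseline,n_distractor,n_switch,n_ambiguous condition counts.
#' @param trial_ms,stim_ms trial and stimulus durations (ms).
#' @param gap_min,gap_max baseline-trial gap bounds between critical
#'   trials.
#' @return An object of class `session_design`.
#' @export
session_design <- function(n_baseline = 240, n_distractor = 20,
                           n_switch = 20, n_ambiguous = 20,
                           trial_ms = 2000, stim_ms = 900,
                           gap_min = 3, gap_max = 6) {
  x <- list(n_baseline = n_baseline, n_distractor = n_distractor,
            n_switch = n_switch, n_ambiguous = n_ambiguous,
            trial_ms = trial_ms, stim_ms = stim_ms,
            gap_min = gap_min, gap_max = gap_max)
  n_crit <- n_distractor + n_switch + n_ambiguous
  if (n_baseline < gap_min * n_crit || n_baseline > gap_max * n_crit) {
    stop("gap constraints unsatisfiable: need between ",
         gap_min * n_crit, " and ", gap_max * n_crit,
         " baseline trials for ", n_crit, " critical trials")
  }
  structure(x, class = "session_design")
}

# run an expression under a local R RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a pseudorandomised session
#'
#' Builds a trial order satisfying the gap constraints (every critical
#' trial preceded by 3-6 baseline trials), samples digits and gray values
#' per the design, and records the rule-consistent correct decision for
#' every non-ambiguous trial.  Deterministic under the seed.
#'
#' @param design a [session_design()].
#' @param seed integer seed.
#' @return A tibble of class `session` with columns `trial`, `condition`,
#'   `upper_digit`, `lower_digit`, `gray_upper`, `gray_lower`,
#'   `correct_decision`.
#' @examples
#' s <- generate_session(seed = 1)
#' table(s$condition)
#' @export
generate_session <- function(design = session_design(), seed = 1) {
  stopifnot(inherits(design, "session_design"))
  digits <- c(1:4, 6:9)
  with_seed(seed, {
    n_crit <- design$n_distractor + design$n_switch + design$n_ambiguous
    # gap vector with fixed sum: start from a feasible constant split,
    # then exchange units between random pairs within the bounds
    base_gap <- design$n_baseline / n_crit
    gaps <- rep(floor(base_gap), n_crit)
    rem <- design$n_baseline - sum(gaps)
    if (rem > 0) gaps[seq_len(rem)] <- gaps[seq_len(rem)] + 1
    for (k in seq_len(50 * n_crit)) {
      ij <- sample.int(n_crit, 2)
      if (gaps[ij[1]] < design$gap_max && gaps[ij[2]] > design$gap_min) {
        gaps[ij[1]] <- gaps[ij[1]] + 1
        gaps[ij[2]] <- gaps[ij[2]] - 1
      }
    }
    crit <- sample(rep(c("distractor", "switch", "ambiguous"),
                       c(design$n_distractor, design$n_switch,
                         design$n_ambiguous)))
    condition <- unlist(lapply(seq_len(n_crit), function(i) {
      c(rep("baseline", gaps[i]), crit[i])
    }))
    n <- length(condition)
    upper <- sample(digits, n, replace = TRUE)
    lower <- ifelse(condition == "baseline", NA_integer_,
                    sample(digits, n, replace = TRUE))
    gray_upper <- rep(127L, n)
    gray_lower <- rep(NA_integer_, n)
    bright <- sample(169:195, n, replace = TRUE)
    i <- condition == "distractor"
    gray_upper[i] <- bright[i]
    gray_lower[i] <- 255L - bright[i]
    i <- condition == "switch"
    gray_lower[i] <- bright[i]
    gray_upper[i] <- 255L - bright[i]
    i <- condition == "ambiguous"
    gray_lower[i] <- sample(117:137, sum(i), replace = TRUE)
    correct <- dplyr::case_when(
      condition %in% c("baseline", "distractor") & upper %% 2 == 1 ~ "odd",
      condition %in% c("baseline", "distractor") ~ "even",
      condition == "switch" & lower > 5 ~ "gt5",
      condition == "switch" ~ "lt5",
      TRUE ~ NA_character_
    )
    out <- tibble(trial = seq_len(n), condition = condition,
                  upper_digit = as.integer(upper),
                  lower_digit = as.integer(lower),
                  gray_upper = gray_upper, gray_lower = gray_lower,
                  correct_decision = correct)
    class(out) <- c("session", class(out))
    attr(out, "design") <- design
    attr(out, "seed") <- as.integer(seed)
    out
  })
}

#' Condition-dependent rule-module inputs
#'
#' Maps a task condition to the selective input currents applied to the
#' rule populations while the stimulus is on: baseline trials drive only
#' the rule-1 population with `i1_base`; distractor trials add a shared
#' component plus a differential favouring rule 1
#' (`I1 = i1_base + ibar_dist + di_dist/2`,
#' `I2 = i1_base + ibar_dist - di_dist/2`); switch trials mirror the
#' differential towards rule 2.  The ambiguous condition is not modelled.
#'
#' @param condition one of `"baseline"`, `"distractor"`, `"switch"`.
#' @param params a [fitted_params()] vector.
#' @return A tibble with columns `I1`, `I2`.
#' @export
condition_inputs <- function(condition, params) {
  params <- as_fitted_params(params)
  if (!condition %in% c("baseline", "distractor", "switch")) {
    stop("condition '", condition, "' is not modelled")
  }
  switch(condition,
    baseline = tibble(I1 = params[["i1_base"]], I2 = 0),
    distractor = tibble(
      I1 = params[["i1_base"]] + params[["ibar_dist"]] + 0.5 * params[["di_dist"]],
      I2 = params[["i1_base"]] + params[["ibar_dist"]] - 0.5 * params[["di_dist"]]
    ),
    switch = tibble(
      I1 = params[["i1_base"]] + params[["ibar_switch"]] - 0.5 * params[["di_switch"]],
      I2 = params[["i1_base"]] + params[["ibar_switch"]] + 0.5 * params[["di_switch"]]
    )
  )
}

# stimulus inputs to the four decision pools by condition; pools are
# (1 correct parity, 2 incorrect parity, 3 correct magnitude, 4 incorrect
# magnitude); incorrect-feature inputs are fixed at zero
decision_inputs <- function(condition, params) {
  params <- as_fitted_params(params)
  if (condition == "baseline") {
    c(params[["d11"]], 0, 0, 0)
  } else {
    c(params[["d11"]], 0, params[["d12"]], 0)
  }
}

# settle the rule module at the rule-1 attractor for a parameter vector
rule1_state <- function(params, dt = 0.5) {
  params <- as_fitted_params(params)
  cpl <- effective_couplings(rule_params(params[["s_nmda"]],
                                         params[["s_gaba"]]))
  st <- settle_rule(cpl, init = c(0.8, 0.1), dt = dt)
  list(couplings = cpl, S1 = st$S1, S2 = st$S2)
}

# batch-simulate pool-coded trials of one condition; returns a tibble
# (condition, decision, rt, energy)
sim_condition <- function(state, params, condition, n, seed, dt = 0.5,
                          record_energy = FALSE,
                          trial_ms = 2000, stim_ms = 900) {
  params <- as_fitted_params(params)
  ci <- condition_inputs(condition, params)
  D <- decision_inputs(condition, params)
  m <- cpp_simulate_trials(
    cpl_vec(state$couplings), abs(params[["sigma_rule"]]),
    state$S1, state$S2, ci$I1, ci$I2, D, params[["c_plus"]],
    1, params[["beta"]], abs(params[["sigma_decision"]]), 10, 100,
    as.integer(n), stim_ms, trial_ms, dt, 2, as.integer(seed),
    isTRUE(record_energy)
  )
  tibble(condition = condition,
         decision = as.integer(m[, 1]),
         rt = m[, 2],
         energy = m[, 3])
}

#' Simulate one task trial
#'
#' Runs the full coupled model for a single trial specification: the rule
#' module starts at the rule-1 attractor (noise-free relaxation from
#' (0.8, 0.1)), stimulus inputs drive both modules for 900 ms, and the
#' decision module's first threshold crossing yields the decision and
#' reaction time.
#'
#' @param spec a one-row session tibble (see [generate_session()]); the
#'   ambiguous condition is refused.
#' @param params a [fitted_params()] vector.
#' @param seed integer seed.
#' @param dt integration step (ms).
#' @return A one-row tibble: the spec plus `decision` (odd/even/gt5/lt5/
#'   none), `rt_ms` and `correct`.
#' @export
simulate_trial <- function(spec, params, seed = 1, dt = 0.5) {
  stopifnot(nrow(spec) == 1)
  if (spec$condition == "ambiguous") {
    stop("ambiguous trials are not modelled")
  }
  state <- rule1_state(params, dt = dt)
  out <- sim_condition(state, params, spec$condition, 1, seed, dt)
  label_outcome(spec, out$decision, out$rt)
}

# map a pool index (0 = none) to a decision label given the trial digits
pool_label <- function(spec, pool) {
  par_up <- ifelse(spec$upper_digit %% 2 == 1, "odd", "even")
  par_alt <- ifelse(par_up == "odd", "even", "odd")
  mag_digit <- ifelse(is.na(spec$lower_digit), spec$upper_digit,
                      spec$lower_digit)
  mag <- ifelse(mag_digit > 5, "gt5", "lt5")
  mag_alt <- ifelse(mag == "gt5", "lt5", "gt5")
  dplyr::case_when(
    pool == 1 ~ par_up,
    pool == 2 ~ par_alt,
    pool == 3 ~ mag,
    pool == 4 ~ mag_alt,
    TRUE ~ "none"
  )
}

label_outcome <- function(spec, pool, rt) {
  decision <- pool_label(spec, pool)
  correct <- !is.na(spec$correct_decision) & decision == spec$correct_decision
  dplyr::bind_cols(spec,
                   tibble(decision = decision, rt_ms = rt,
                          correct = correct))
}

#' Simulate a behavioural dataset (condition-wise trial batches)
#'
#' Simulates `n_per_condition` independent trials of each modelled
#' condition at one parameter set, keeping decisions pool-coded (1 correct
#' parity, 2 incorrect parity, 3 correct magnitude, 4 incorrect magnitude,
#' 0 none).  This is the sampling primitive behind the likelihood.
#'
#' @param params a [fitted_params()] vector.
#' @param n_per_condition trials per condition (scalar or named vector
#'   with entries baseline/distractor/switch).
#' @param seed integer seed.
#' @param dt integration step (ms).
#' @param record_energy also record the per-trial spike-rate integral.
#' @return A tibble of class `behavior_sample` with columns `condition`,
#'   `decision`, `rt`, `energy`.
#' @examples
#' \donttest{
#' d <- simulate_dataset(reference_params(), n_per_condition = 64, seed = 1)
#' table(d$condition, d$decision)
#' }
#' @export
simulate_dataset <- function(params, n_per_condition = 1024, seed = 1,
                             dt = 0.5, record_energy = FALSE) {
  conds <- c("baseline", "distractor", "switch")
  n <- n_per_condition
  if (length(n) == 1) n <- setNames(rep(n, 3), conds)
  stopifnot(all(n >= 1))
  state <- rule1_state(params, dt = dt)
  out <- dplyr::bind_rows(lapply(seq_along(conds), function(i) {
    sim_condition(state, params, conds[i], n[[conds[i]]],
                  derive_seed(seed, i), dt, record_energy)
  }))
  class(out) <- c("behavior_sample", class(out))
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Simulate a full session into a behavioural log
#'
#' Applies the coupled model to every non-ambiguous trial of a generated
#' session (ambiguous trials are recorded with decision `none`, matching
#' their exclusion from the model) and labels pool-coded decisions with
#' the trial's digits.
#'
#' @param session a [generate_session()] tibble.
#' @param params a [fitted_params()] vector.
#' @param seed integer seed.
#' @param dt integration step (ms).
#' @return A tibble of class `behavior_log`: the session plus `decision`,
#'   `rt_ms`, `correct`.
#' @export
simulate_session <- function(session, params, seed = 1, dt = 0.5) {
  state <- rule1_state(params, dt = dt)
  out <- session
  out$decision <- "none"
  out$rt_ms <- NA_real_
  out$correct <- FALSE
  for (cond in c("baseline", "distractor", "switch")) {
    idx <- which(session$condition == cond)
    if (!length(idx)) next
    sim <- sim_condition(state, params, cond, length(idx),
                         derive_seed(seed, match(cond, c("baseline",
                                                         "distractor",
                                                         "switch"))), dt)
    lab <- label_outcome(session[idx, ], sim$decision, sim$rt)
    out$decision[idx] <- lab$decision
    out$rt_ms[idx] <- lab$rt_ms
    out$correct[idx] <- lab$correct
  }
  class(out) <- unique(c("behavior_log", class(out)))
  attr(out, "params") <- as_fitted_params(params)
  attr(out, "seed") <- as.integer(seed)
  out
}

log_columns <- c("trial", "condition", "upper_digit", "lower_digit",
                 "gray_upper", "gray_lower", "decision", "rt_ms",
                 "correct")

validate_log <- function(x) {
  missing_cols <- setdiff(log_columns, names(x))
  if (length(missing_cols)) {
    stop("behaviour log lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad_cond <- which(!x$condition %in%
                      c("baseline", "distractor", "switch", "ambiguous"))
  if (length(bad_cond)) {
    stop("unknown condition at line ", bad_cond[1] + 1L,
         ": '", x$condition[bad_cond[1]], "'")
  }
  bad_dec <- which(!x$decision %in% c("odd", "even", "gt5", "lt5", "none"))
  if (length(bad_dec)) {
    stop("unknown decision at line ", bad_dec[1] + 1L,
         ": '", x$decision[bad_dec[1]], "'")
  }
  bad_rt <- which(x$decision != "none" &
                    (is.na(x$rt_ms) | x$rt_ms <= 0 | x$rt_ms > 2000))
  if (length(bad_rt)) {
    stop("reaction time out of (0, 2000] at line ", bad_rt[1] + 1L)
  }
  invisible(x)
}

#' Read and write behavioural log files
#'
#' The canonical interchange format is UTF-8 tab-separated text with a
#' header row and columns `trial`, `condition`, `upper_digit`,
#' `lower_digit`, `gray_upper`, `gray_lower`, `decision`, `rt_ms`,
#' `correct`; a missing lower digit is an empty field.  Reading validates
#' conditions, decisions and reaction times and reports the offending line
#' number on failure; a write/read round trip preserves all fields.
#'
#' @param path file path.
#' @param log a behaviour-log tibble (see [simulate_session()]).
#' @return `read_behavior_log()` returns a tibble of class
#'   `behavior_log`; `write_behavior_log()` returns `path` invisibly.
#' @export
read_behavior_log <- function(path) {
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(
      trial = readr::col_integer(),
      condition = readr::col_character(),
      upper_digit = readr::col_integer(),
      lower_digit = readr::col_integer(),
      gray_upper = readr::col_integer(),
      gray_lower = readr::col_integer(),
      decision = readr::col_character(),
      rt_ms = readr::col_double(),
      correct = readr::col_logical()
    ),
    progress = FALSE
  )
  probs <- readr::problems(x)
  if (nrow(probs)) {
    stop("malformed behaviour log at line ", probs$row[1], ": ",
         probs$expected[1])
  }
  validate_log(x)
  class(x) <- unique(c("behavior_log", class(x)))
  x
}

#' @rdname read_behavior_log
#' @export
write_behavior_log <- function(log, path) {
  validate_log(log)
  readr::write_tsv(log[, log_columns], path, progress = FALSE)
  invisible(path)
}

#' Fraction of the 8-bit brightness range used by ambiguous cues
#'
#' Ambiguous trials draw the lower digit's gray value from an inclusive
#' integer interval around the medium gray 127; this helper reports the
#' covered fraction of the 256-level brightness range (8.2 % for the
#' default [117, 137]).
#'
#' @param design a [session_design()] (the interval is fixed by the task).
#' @return A single number in (0, 1).
#' @export
ambiguous_gray_fraction <- function(design = session_design()) {
  length(117:137) / 256
}
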