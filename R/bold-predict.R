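#' Normalised trial energy table
#'
#' Simulates trials of every modelled condition and averages the
#' spike-rate integral `int (r1 + r2) dt` of the rule module over the
#' trial, per (condition, decision) cell, as a proxy for the module's
#' energy consumption.  Entries are normalised to the correct-baseline
#' cell (pool 1), which is therefore exactly 1; cells without simulated
#' trials fall back to their condition mean.  Ambiguous trials are not
#' simulated and carry no energy.
#'
#' @param params a [fitted_params()] vector.
#' @param n_per_cell simulated trials per condition (>= 1024 recommended
#'   for stable cell means).
#' @param seed integer seed.
#' @param dt integration step (ms).
#' @return A tibble of class `energy_table` with columns `condition`,
#'   `decision` (pool index; 0 = none), `n`, `energy` (normalised).
#' @export
trial_energy_table <- function(params, n_per_cell = 1024, seed = 1,
                               dt = 0.5) {
  sim <- simulate_dataset(params, n_per_condition = n_per_cell,
                          seed = seed, dt = dt, record_energy = TRUE)
  cells <- dplyr::summarise(
    dplyr::group_by(sim, .data$condition, .data$decision),
    n = dplyr::n(), energy = mean(.data$energy), .groups = "drop"
  )
  ref <- cells$energy[cells$condition == "baseline" & cells$decision == 1]
  if (!length(ref) || !is.finite(ref) || ref <= 0) {
    stop("no correct baseline trials simulated; cannot normalise")
  }
  # complete the (condition x decision) grid; empty cells take the
  # condition mean
  grid <- tidyr::expand_grid(condition = unique(sim$condition),
                             decision = 0:4)
  cells <- dplyr::left_join(grid, cells, by = c("condition", "decision"))
  cells <- dplyr::mutate(
    dplyr::group_by(cells, .data$condition),
    n = dplyr::coalesce(.data$n, 0L),
    energy = dplyr::coalesce(.data$energy,
                             mean(.data$energy, na.rm = TRUE))
  )
  cells <- dplyr::ungroup(cells)
  cells$energy <- cells$energy / ref
  out <- cells[, c("condition", "decision", "n", "energy")]
  class(out) <- c("energy_table", class(out))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "params") <- as_fitted_params(params)
  out
}

#' Assemble the pre-convolution energy timecourse of a session
#'
#' Builds the rule module's hypothetical energy timecourse for a session:
#' each non-ambiguous trial contributes its (condition, decision) energy
#' over the trial (by default as a boxcar spanning the full 2-s trial,
#' since trials are contiguous; `event = "stimulus"` restricts the boxcar
#' to the 900-ms stimulus window and `event = "impulse"` places a single
#' impulse at trial onset).  Ambiguous trials contribute nothing.  The
#' sampled series is then z-scored; a constant series (e.g. an
#' all-correct-baseline session) z-scores to all zeros.
#'
#' @param log a behaviour log (see [simulate_session()]).
#' @param table a [trial_energy_table()].
#' @param sample_dt sampling interval of the fine grid (s).
#' @param trial_s trial duration (s).
#' @param stim_s stimulus duration (s), for `event = "stimulus"`.
#' @param event event model; see above.
#' @return A tibble with columns `time_s`, `energy` (z-scored series).
#' @export
assemble_timecourse <- function(log, table, sample_dt = 0.1,
                                trial_s = 2, stim_s = 0.9,
                                event = c("trial", "stimulus",
                                          "impulse")) {
  event <- match.arg(event)
  validate_log(log)
  pool <- summarize_pool(log)
  total_s <- max(log$trial) * trial_s       # trials are contiguous
  tgrid <- seq(0, total_s - sample_dt, by = sample_dt)
  series <- numeric(length(tgrid))
  keep <- log$condition != "ambiguous"
  key <- paste(table$condition, table$decision)
  energy <- setNames(table$energy, key)
  for (k in which(keep)) {
    e <- energy[paste(log$condition[k], pool[k])]
    if (is.na(e)) e <- 0
    onset <- (log$trial[k] - 1) * trial_s
    bins <- switch(event,
      impulse = round(onset / sample_dt) + 1,
      stimulus = seq(round(onset / sample_dt) + 1,
                     round((onset + stim_s) / sample_dt)),
      trial = seq(round(onset / sample_dt) + 1,
                  round((onset + trial_s) / sample_dt))
    )
    series[bins] <- series[bins] + e
  }
  s <- sd(series)
  z <- if (s < 1e-12) series * 0 else (series - mean(series)) / s
  tibble(time_s = tgrid, energy = z)
}

# pool-code the decisions of a labelled log (0 = none)
summarize_pool <- function(log) {
  par_up <- ifelse(log$upper_digit %% 2 == 1, "odd", "even")
  mag_digit <- ifelse(is.na(log$lower_digit), log$upper_digit,
                      log$lower_digit)
  mag <- ifelse(mag_digit > 5, "gt5", "lt5")
  dplyr::case_when(
    log$decision == "none" ~ 0L,
    log$decision %in% c("odd", "even") & log$decision == par_up ~ 1L,
    log$decision %in% c("odd", "even") ~ 2L,
    log$decision == mag ~ 3L,
    TRUE ~ 4L
  )
}

#' Canonical double-gamma haemodynamic response function
#'
#' The SPM-convention canonical HRF: a gamma density peaking around 5-6 s
#' minus a later undershoot gamma scaled by `1/ratio`, truncated at
#' `length_s` and normalised to unit sum on the evaluation grid.
#'
#' @param t time points (s) at which to evaluate.
#' @param peak_delay,under_delay delays of response and undershoot (s).
#' @param peak_disp,under_disp dispersions (s).
#' @param ratio peak-to-undershoot ratio.
#' @return Amplitudes at `t` (not normalised; normalisation happens on
#'   the sampled kernel in [convolve_regressor()]).
#' @export
hrf_canonical <- function(t, peak_delay = 6, under_delay = 16,
                          peak_disp = 1, under_disp = 1, ratio = 6) {
  h <- stats::dgamma(t, shape = peak_delay / peak_disp,
                     scale = peak_disp) -
    stats::dgamma(t, shape = under_delay / under_disp,
                  scale = under_disp) / ratio
  h[t < 0] <- 0
  h
}

#' Convolve an energy timecourse into a BOLD regressor
#'
#' Linearly convolves the z-scored energy series with the unit-sum
#' canonical HRF sampled on the same fine grid (kernel length 32 s) and
#' downsamples the result to the scanner's repetition-time grid.
#'
#' @param series a tibble from [assemble_timecourse()] (columns `time_s`,
#'   `energy`).
#' @param tr repetition time (s).
#' @param hrf_length_s kernel length (s).
#' @param ... HRF shape parameters passed to [hrf_canonical()].
#' @return A tibble of class `bold_regressor` with columns `time_s`,
#'   `value`, carrying the fine-grid convolution and HRF settings as
#'   attributes.
#' @export
convolve_regressor <- function(series, tr = 2, hrf_length_s = 32, ...) {
  stopifnot(all(c("time_s", "energy") %in% names(series)))
  sample_dt <- series$time_s[2] - series$time_s[1]
  tk <- seq(0, hrf_length_s, by = sample_dt)
  kernel <- hrf_canonical(tk, ...)
  ksum <- sum(kernel)
  if (abs(ksum) > 1e-12) kernel <- kernel / ksum
  conv <- stats::convolve(series$energy, rev(kernel), type = "open")
  conv <- conv[seq_along(series$energy)]
  idx <- round(seq(0, max(series$time_s), by = tr) / sample_dt) + 1
  idx <- idx[idx <= length(conv)]
  out <- tibble(time_s = (idx - 1) * sample_dt, value = conv[idx])
  class(out) <- c("bold_regressor", class(out))
  attr(out, "fine") <- tibble(time_s = series$time_s, value = conv)
  attr(out, "hrf") <- c(list(tr = tr, sample_dt = sample_dt,
                             length_s = hrf_length_s), list(...))
  out
}

#' Predict a subject's BOLD regressor from a behaviour log
#'
#' End-to-end wrapper: energy table at `params`, impulse timecourse from
#' the log, z-scoring, HRF convolution and downsampling to the TR grid.
#'
#' @param log a behaviour log.
#' @param params a [fitted_params()] vector (typically the MAP estimate).
#' @param n_per_cell simulated trials per condition for the energy table.
#' @param tr repetition time (s).
#' @param sample_dt fine sampling interval (s).
#' @param seed integer seed.
#' @return A [convolve_regressor()] tibble.
#' @export
predict_bold <- function(log, params, n_per_cell = 1024, tr = 2,
                         sample_dt = 0.1, seed = 1) {
  table <- trial_energy_table(params, n_per_cell = n_per_cell,
                              seed = seed)
  series <- assemble_timecourse(log, table, sample_dt = sample_dt)
  reg <- convolve_regressor(series, tr = tr)
  attr(reg, "seed") <- as.integer(seed)
  reg
}

#' Write and read a BOLD regressor file
#'
#' Two-column tab-separated text (`time_s`, `value`) with `#`-prefixed
#' header lines recording the HRF settings and seed, suitable as a GLM
#' regressor.
#'
#' @param regressor a `bold_regressor` tibble.
#' @param path file path.
#' @return `write_regressor()` returns `path` invisibly;
#'   `read_regressor()` returns a tibble `time_s`, `value`.
#' @export
write_regressor <- function(regressor, path) {
  hrf <- attr(regressor, "hrf")
  hdr <- c(
    paste0("# hrf: ", paste(names(hrf), unlist(hrf), sep = "=",
                            collapse = " ")),
    paste0("# seed: ", attr(regressor, "seed") %||% NA)
  )
  writeLines(hdr, path)
  readr::write_tsv(regressor[, c("time_s", "value")], path,
                   append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_regressor
#' @export
read_regressor <- function(path) {
  readr::read_tsv(path, comment = "#",
                  col_types = readr::cols(time_s = readr::col_double(),
                                          value = readr::col_double()),
                  progress = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
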