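#' Tidy a Metropolis-Hastings chain
#'
#' @param x an `mh_chain`.
#' @param ... unused.
#' @return A long tibble with columns `step`, `param`, `value`.
#' @export
tidy.mh_chain <- function(x, ...) {
  df <- as_tibble(as.data.frame(x$samples))
  df$step <- seq_len(nrow(df))
  tidyr::pivot_longer(df, -"step", names_to = "param",
                      values_to = "value")
}

#' @rdname tidy.mh_chain
#' @export
glance.mh_chain <- function(x, ...) {
  tibble(n_steps = nrow(x$samples),
         acceptance_rate = x$acceptance_rate,
         n_sim = x$n_sim, sigma_mh = x$sigma_mh, seed = x$seed)
}

#' Tidy a pooled-chain fit
#'
#' @param x an `mh_fit`.
#' @param ... unused.
#' @return `tidy()`: the posterior summary (param, map, fwhm) augmented
#'   with posterior means and standard deviations; `glance()`: one row of
#'   fit-level statistics.
#' @export
tidy.mh_fit <- function(x, ...) {
  s <- x$pool$samples
  dplyr::mutate(as_tibble(x$posterior),
                mean = colMeans(s)[.data$param],
                sd = apply(s, 2, sd)[.data$param])
}

#' @rdname tidy.mh_fit
#' @export
glance.mh_fit <- function(x, ...) {
  tibble(n_chains = length(x$chains),
         n_pooled = nrow(x$pool$samples),
         burn_in = x$pool$burn_in,
         acceptance_rate = mean(vapply(x$chains,
                                       function(c) c$acceptance_rate,
                                       numeric(1))),
         max_log_post = max(x$pool$log_post))
}

#' Tidy a posterior summary
#'
#' @param x a `posterior_summary`.
#' @param ... unused.
#' @return The underlying tibble (param, map, fwhm).
#' @export
tidy.posterior_summary <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Tidy a potential landscape
#'
#' @param x a `potential_landscape`.
#' @param ... unused.
#' @return `tidy()`: long tibble `S1`, `S2`, `Pss`, `U`; `glance()`: one
#'   row with grid size, diffusion coefficient, convergence metadata.
#' @export
tidy.potential_landscape <- function(x, ...) {
  grid <- expand.grid(S1 = x$s1, S2 = x$s2)
  tibble(S1 = grid$S1, S2 = grid$S2,
         Pss = as.vector(x$Pss), U = as.vector(x$U))
}

#' @rdname tidy.potential_landscape
#' @export
glance.potential_landscape <- function(x, ...) {
  tibble(n_grid = length(x$s1), D = x$D,
         sigma_rule = x$params$sigma_rule,
         s_nmda = x$params$s_nmda, s_gaba = x$params$s_gaba,
         iterations = x$iterations, converged = x$converged,
         mass = sum(x$Pss) * x$h^2)
}

#' Tidy a minimal-action result
#'
#' @param x an `action_result`.
#' @param ... unused.
#' @return `tidy()`: the optimised path nodes of both directions
#'   (`direction`, `node`, `S1`, `S2`); `glance()`: one row per direction
#'   with the action and convergence diagnostics.
#' @export
tidy.action_result <- function(x, ...) {
  parts <- list(dplyr::mutate(x$rule1_to_rule2$path,
                              direction = "rule1_to_rule2",
                              node = dplyr::row_number()))
  if (!is.null(x$rule2_to_rule1)) {
    parts <- c(parts, list(dplyr::mutate(x$rule2_to_rule1$path,
                                         direction = "rule2_to_rule1",
                                         node = dplyr::row_number())))
  }
  dplyr::bind_rows(parts)[, c("direction", "node", "S1", "S2")]
}

#' @rdname tidy.action_result
#' @export
glance.action_result <- function(x, ...) {
  dirs <- list(rule1_to_rule2 = x$rule1_to_rule2,
               rule2_to_rule1 = x$rule2_to_rule1)
  dirs <- dirs[!vapply(dirs, is.null, logical(1))]
  tibble(direction = names(dirs),
         action = vapply(dirs, `[[`, numeric(1), "action"),
         kinetic_time = vapply(dirs, `[[`, numeric(1), "kinetic_time"),
         dl_cv = vapply(dirs, `[[`, numeric(1), "dl_cv"),
         converged = vapply(dirs, `[[`, logical(1), "converged"),
         E_eff = x$E_eff, sigma_rule = x$sigma_rule)
}
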