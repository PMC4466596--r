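#' Run the full analysis pipeline for one synthetic or supplied subject
#'
#' Executes the package's stages in order -- session simulation (or log
#' loading), behavioural fitting, potential-landscape reconstruction,
#' minimal-action estimation and BOLD-regressor prediction -- writing one
#' artifact per stage plus a JSON manifest with the seeds, settings and
#' MD5 hashes of every output.  A single root seed is expanded into
#' per-stage seeds by a fixed counter scheme, so a config reproduces its
#' artifacts exactly.
#'
#' @param config either a YAML file path or a named list with (all
#'   optional) entries `seed`, `out_dir`, `log` (path to an existing
#'   behaviour log; otherwise a session is simulated at
#'   `params`/[reference_params()]), `params` (named list of
#'   [fitted_params()] overrides), `scale` (`"desk"` or `"paper"`), `fit`
#'   (list of [fit_behavior()] overrides), `landscape` (list: `n`, `dt`,
#'   `tol`), `action` (list: `n_elements`, `penalty`), `bold` (list:
#'   `n_per_cell`, `tr`).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  known <- c("seed", "out_dir", "log", "params", "scale", "fit",
             "landscape", "action", "bold")
  bad <- setdiff(names(config), known)
  if (length(bad)) {
    stop("unknown config entries: ", paste(bad, collapse = ", "))
  }
  seed <- config$seed %||% 1
  out_dir <- config$out_dir %||% "ruleflex-run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scale <- config$scale %||% "desk"
  fit_cfg <- if (identical(scale, "paper")) paper_scale() else
    list(n_chains = 2, n_steps = 2000, burn_in = 200, n_sim = 128,
         sigma_mh = 0.01)
  fit_cfg[names(config$fit)] <- config$fit
  params <- do.call(fitted_params,
                    modifyList(as.list(unclass(reference_params())),
                               config$params %||% list()))

  # stage 1: behaviour log
  if (!is.null(config$log)) {
    log <- read_behavior_log(config$log)
  } else {
    session <- generate_session(seed = derive_seed(seed, 1))
    log <- simulate_session(session, params, seed = derive_seed(seed, 2))
  }
  log_path <- file.path(out_dir, "behavior_log.tsv")
  write_behavior_log(log, log_path)

  # stage 2: fit
  fit <- fit_behavior(log, n_chains = fit_cfg$n_chains,
                      n_steps = fit_cfg$n_steps,
                      burn_in = fit_cfg$burn_in, n_sim = fit_cfg$n_sim,
                      sigma_mh = fit_cfg$sigma_mh,
                      seed = derive_seed(seed, 3))
  fit_path <- file.path(out_dir, "posterior.tsv")
  readr::write_tsv(fit$posterior, fit_path, progress = FALSE)
  chain_path <- file.path(out_dir, "chain_samples.tsv")
  readr::write_tsv(as_tibble(as.data.frame(fit$pool$samples)),
                   chain_path, progress = FALSE)

  # stage 3: landscape at the fitted rule parameters
  ls_cfg <- modifyList(list(n = 96, dt = 10, tol = 1e-9),
                       config$landscape %||% list())
  map <- fit$map
  sigma_ls <- max(abs(map[["sigma_rule"]]), 0.05)  # landscapes need noise
  L <- fp_steady_state(rule_params(map[["s_nmda"]], map[["s_gaba"]],
                                   sigma_ls),
                       n = ls_cfg$n, dt = ls_cfg$dt, tol = ls_cfg$tol)
  ls_path <- file.path(out_dir, "landscape.tsv")
  readr::write_tsv(tidy(L), ls_path, progress = FALSE)

  # stage 4: minimal action
  ac_cfg <- modifyList(list(n_elements = 50, penalty = 1e5),
                       config$action %||% list())
  A <- minimize_path_action(L, n_elements = ac_cfg$n_elements,
                            penalty = ac_cfg$penalty)
  ac_path <- file.path(out_dir, "action.json")
  jsonlite::write_json(
    list(E_eff = A$E_eff,
         rule1_to_rule2 = list(action = A$rule1_to_rule2$action,
                               converged = A$rule1_to_rule2$converged,
                               path = A$rule1_to_rule2$path),
         rule2_to_rule1 = list(action = A$rule2_to_rule1$action,
                               converged = A$rule2_to_rule1$converged,
                               path = A$rule2_to_rule1$path)),
    ac_path, auto_unbox = TRUE, digits = NA)

  # stage 5: BOLD regressor
  bd_cfg <- modifyList(list(n_per_cell = 1024, tr = 2),
                       config$bold %||% list())
  reg <- predict_bold(log, map, n_per_cell = bd_cfg$n_per_cell,
                      tr = bd_cfg$tr, seed = derive_seed(seed, 4))
  reg_path <- file.path(out_dir, "bold_regressor.tsv")
  write_regressor(reg, reg_path)

  files <- c(log = log_path, posterior = fit_path, chain = chain_path,
             landscape = ls_path, action = ac_path, bold = reg_path)
  manifest <- list(
    package = "ruleflex",
    version = as.character(utils::packageVersion("ruleflex")),
    seed = seed, scale = scale, fit = fit_cfg,
    landscape = ls_cfg, action = ac_cfg, bold = bd_cfg,
    files = as.list(setNames(unname(tools::md5sum(files)), names(files)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  invisible(list(log = log, fit = fit, landscape = L, action = A,
                 bold = reg, manifest = manifest))
}
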