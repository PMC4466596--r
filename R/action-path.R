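# internal: effective potential V and drift on arbitrary points
action_field <- function(cpl, S1, S2, Dd, h = 1e-5) {
  # per-second drift, matching the landscape convention; the five
  # stencil evaluations (centre + 4 divergence offsets) are batched into
  # one vectorised field call
  m <- length(S1)
  f <- rule_field(cpl,
                  c(S1, S1 + h, S1 - h, S1, S1),
                  c(S2, S2, S2, S2 + h, S2 - h))
  i0 <- seq_len(m)
  divF <- 1000 * ((f$F1[m + i0] - f$F1[2 * m + i0]) / (2 * h) +
                    (f$F2[3 * m + i0] - f$F2[4 * m + i0]) / (2 * h))
  F1 <- 1000 * f$F1[i0]
  F2 <- 1000 * f$F2[i0]
  list(F1 = F1, F2 = F2, V = (F1^2 + F2^2) / (4 * Dd) + 0.5 * divF)
}

#' Effective potential of the Hamilton-Jacobi action
#'
#' `V(S) = |F(S)|^2 / (4 D) + (div F)(S) / 2` with the noise-free drift
#' `F` of the input-free rule module, `D = (sigma_rule/2)^2`, and the
#' divergence by central differences (step 1e-5).  At a fixed point
#' `V = (div F)/2` exactly.
#'
#' @param couplings an [effective_couplings()] object.
#' @param S1,S2 evaluation points; vectorised.
#' @param sigma_rule OU diffusion parameter (must be non-zero).
#' @param h finite-difference step for the divergence.
#' @return Numeric vector of potential values.
#' @export
effective_potential_v <- function(couplings, S1, S2, sigma_rule,
                                  h = 1e-5) {
  Dd <- (abs(sigma_rule) / 2)^2
  stopifnot(Dd > 0)
  action_field(couplings, S1, S2, Dd, h)$V
}

# raw action of a discretised path (matrix of nodes), evaluated at
# segment midpoints; returns the line integral and the clipped count
path_action <- function(path, cpl, Dd, E_eff) {
  m <- nrow(path)
  dvec <- path[-1, , drop = FALSE] - path[-m, , drop = FALSE]
  dl <- sqrt(rowSums(dvec^2))
  mid <- (path[-1, , drop = FALSE] + path[-m, , drop = FALSE]) / 2
  fld <- action_field(cpl, mid[, 1], mid[, 2], Dd)
  tx <- ifelse(dl > 0, dvec[, 1] / dl, 0)
  ty <- ifelse(dl > 0, dvec[, 2] / dl, 0)
  F_l <- fld$F1 * tx + fld$F2 * ty
  ev <- E_eff + fld$V
  n_clipped <- sum(ev < 0)
  ev[ev < 0] <- 0
  list(action = sum((sqrt(ev / Dd) - F_l / (2 * Dd)) * dl),
       dl = dl, n_clipped = n_clipped,
       kinetic_time = sum(dl / (2 * sqrt(pmax(Dd * ev, 1e-300)))))
}

#' Hamilton-Jacobi action of a discretised transition path
#'
#' Line integral `S = sum [ sqrt((E_eff + V)/D) - F_l/(2D) ] dl` over the
#' path's segments (midpoint rule), where `F_l` is the drift component
#' along the path and `D = (sigma_rule/2)^2`.  Negative `E_eff + V`
#' (possible only through discretisation error when `E_eff` is chosen as
#' `-min V`) is clipped at zero with a warning.
#'
#' @param path a numeric matrix (or data frame) of path nodes, columns
#'   `S1`, `S2`.
#' @param couplings an [effective_couplings()] object.
#' @param sigma_rule OU diffusion parameter.
#' @param E_eff effective energy; see [minimize_path_action()].
#' @return A list with `action`, `kinetic_time`, segment lengths `dl` and
#'   `n_clipped`.
#' @export
hj_action <- function(path, couplings, sigma_rule, E_eff) {
  path <- as.matrix(path)[, 1:2, drop = FALSE]
  Dd <- (abs(sigma_rule) / 2)^2
  stopifnot(Dd > 0, nrow(path) >= 2)
  out <- path_action(path, couplings, Dd, E_eff)
  if (out$n_clipped > 0) {
    warning(out$n_clipped, " segment(s) with E_eff + V < 0 clipped at 0")
  }
  out
}

# linearly interpolated polyline through the given anchor points
polyline <- function(anchors, n_nodes) {
  anchors <- as.matrix(anchors)
  seg <- sqrt(rowSums(diff(anchors)^2))
  cum <- c(0, cumsum(seg))
  tt <- seq(0, cum[length(cum)], length.out = n_nodes)
  cbind(approx(cum, anchors[, 1], xout = tt)$y,
        approx(cum, anchors[, 2], xout = tt)$y)
}

#' Minimal-action transition paths between the rule attractors
#'
#' Minimises the discretised Hamilton-Jacobi action over the interior
#' nodes of a path connecting the two rule minima of the potential
#' landscape (50 line elements by default), with a penalty of `1e5` on
#' the variance of the segment lengths to keep the discretisation uniform
#' (the penalty is excluded from the reported action).  The effective
#' energy is fixed at `E_eff = -min V` over the landscape grid (the
#' longest kinetic time).  Both transition directions are optimised, each
#' from two initialisations: the straight line and a polyline through the
#' spontaneous minimum; the lower-action solution per direction is
#' returned.
#'
#' @param landscape a [fp_steady_state()] result (provides the endpoints,
#'   the parameters and the diffusion coefficient).
#' @param n_elements number of line elements (nodes - 1).
#' @param penalty weight on the segment-length variance.
#' @param maxit BFGS iteration cap per optimisation.
#' @param directions `"both"` (default) or `"forward"` to optimise only
#'   the rule-1 to rule-2 transition (halves the cost in parameter
#'   sweeps that only track one direction).
#' @return An object of class `action_result`: list with per-direction
#'   entries (`rule1_to_rule2`, `rule2_to_rule1`) carrying `action`,
#'   `path` (tibble), `kinetic_time`, `converged`, plus `E_eff` and the
#'   settings.  With `directions = "forward"` the backward entry is
#'   `NULL`.
#' @examples
#' \donttest{
#' L <- fp_steady_state(rule_params(sigma_rule = 0.1), n = 48)
#' A <- minimize_path_action(L, n_elements = 20)
#' glance(A)
#' }
#' @export
minimize_path_action <- function(landscape, n_elements = 50,
                                 penalty = 1e5, maxit = 5000,
                                 directions = c("both", "forward")) {
  directions <- match.arg(directions)
  stopifnot(inherits(landscape, "potential_landscape"))
  cpl <- landscape$couplings
  Dd <- landscape$D
  stopifnot(Dd > 0)
  mins <- landscape_minima(landscape)
  need <- c("rule1", "rule2", "spontaneous")
  if (!all(need %in% mins$state)) {
    stop("landscape lacks the required minima: found only ",
         paste(mins$state, collapse = ", "))
  }
  pt <- function(state) {
    r <- mins[mins$state == state, ]
    c(r$S1[1], r$S2[1])
  }
  # E_eff from the whole grid (interior nodes)
  gi <- expand.grid(S1 = landscape$s1[2:(length(landscape$s1) - 1)],
                    S2 = landscape$s2[2:(length(landscape$s2) - 1)])
  Vgrid <- action_field(cpl, gi$S1, gi$S2, Dd)$V
  E_eff <- -min(Vgrid)
  n_nodes <- n_elements + 1
  run_dir <- function(a, b) {
    inits <- list(polyline(rbind(a, b), n_nodes),
                  polyline(rbind(a, pt("spontaneous"), b), n_nodes))
    best <- NULL
    for (init in inits) {
      obj <- function(v) {
        path <- rbind(a, matrix(v, ncol = 2), b)
        pa <- path_action(path, cpl, Dd, E_eff)
        pa$action + penalty * var(pa$dl)
      }
      v0 <- as.numeric(init[2:(n_nodes - 1), ])
      fit <- optim(v0, obj, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-9))
      path <- rbind(a, matrix(fit$par, ncol = 2), b)
      pa <- path_action(path, cpl, Dd, E_eff)
      cand <- list(action = pa$action,
                   path = tibble(S1 = path[, 1], S2 = path[, 2]),
                   kinetic_time = pa$kinetic_time,
                   n_clipped = pa$n_clipped,
                   dl_cv = sd(pa$dl) / mean(pa$dl),
                   converged = fit$convergence == 0)
      if (is.null(best) || cand$action < best$action) best <- cand
    }
    best
  }
  fwd <- run_dir(pt("rule1"), pt("rule2"))
  bwd <- if (directions == "both") run_dir(pt("rule2"), pt("rule1")) else NULL
  if (!fwd$converged && (is.null(bwd) || !bwd$converged) &&
      directions == "both") {
    warning("path optimiser failed to converge from all starts")
  }
  structure(list(rule1_to_rule2 = fwd, rule2_to_rule1 = bwd,
                 E_eff = E_eff, n_elements = n_elements,
                 penalty = penalty, minima = mins,
                 sigma_rule = landscape$params$sigma_rule),
            class = "action_result")
}

#' @export
print.action_result <- function(x, ...) {
  cat("Minimal-action rule transitions (E_eff =",
      format(x$E_eff, digits = 4), ")\n")
  cat(sprintf("  rule1 -> rule2: S = %.4f%s\n", x$rule1_to_rule2$action,
              if (x$rule1_to_rule2$converged) "" else " (not converged)"))
  if (!is.null(x$rule2_to_rule1)) {
    cat(sprintf("  rule2 -> rule1: S = %.4f%s\n", x$rule2_to_rule1$action,
                if (x$rule2_to_rule1$converged) "" else " (not converged)"))
  }
  invisible(x)
}
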