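# internal: drift field without tibble overhead (hot path for the
# Fokker-Planck operator and the action integrand)
rule_field <- function(cpl, S1, S2) {
  x1 <- cpl$J_N11 * S1 - cpl$J_N12 * S2 + cpl$I0
  x2 <- cpl$J_N22 * S2 - cpl$J_N21 * S1 + cpl$I0
  r1 <- rate_transfer(x1, x2, cpl$J_A11, cpl$J_A12)
  r2 <- rate_transfer(x2, x1, cpl$J_A22, cpl$J_A21)
  list(F1 = -S1 / cpl$tau_NMDA + (1 - S1) * cpl$gamma * r1 / 1000,
       F2 = -S2 / cpl$tau_NMDA + (1 - S2) * cpl$gamma * r2 / 1000)
}

#' Implicit Fokker-Planck update operator of the rule module
#'
#' Assembles the sparse implicit (backward-in-time, centred-in-space)
#' update matrix for the Fokker-Planck equation of the input-free rule
#' module, `dP/dt = -div(F P) + D laplace P`, in conservative
#' finite-volume form on a cell-centred grid over the unit square with
#' no-flux walls (the gating variables are confined to [0, 1], matching
#' the clamped trajectory simulator).  Face fluxes use centred averages,
#' so the interior stencil is the standard second-order BTCS
#' discretisation `(I + dt ((div F) + F . grad - D laplace)) P_{n+1} =
#' P_n`.  The stochastic analysis runs in seconds (drift per s) with
#' diffusion coefficient `D = (sigma_rule / 2)^2`.
#'
#' @param couplings an [effective_couplings()] object.
#' @param sigma_rule OU diffusion parameter.
#' @param n grid cells per axis.
#' @param dt implicit time step (ms).
#' @return A list with the sparse implicit matrix `A` (cells, S1 index
#'   fastest), the cell-centre axis `s`, spacing `h`, diffusion `D`, and
#'   the per-second drift fields `F1`, `F2` at the cell centres.
#' @export
fp_operator <- function(couplings, sigma_rule, n = 128, dt = 10) {
  h <- 1 / n
  s <- (seq_len(n) - 0.5) * h
  Dd <- (abs(sigma_rule) / 2)^2
  dt <- dt / 1000                       # step in seconds
  grid <- expand.grid(S1 = s, S2 = s)   # column-major: S1 fastest
  f <- rule_field(couplings, grid$S1, grid$S2)
  F1 <- matrix(f$F1, n, n) * 1000
  F2 <- matrix(f$F2, n, n) * 1000
  idx <- function(i, j) (j - 1L) * n + i
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  diag_vals <- rep(1, n * n)            # identity part of I - dt L
  # vertical faces between cells (i, j) and (i + 1, j): drift at the face
  faces <- expand.grid(i = seq_len(n - 1), j = seq_len(n))
  Ff <- rule_field(couplings, faces$i * h, (faces$j - 0.5) * h)$F1 * 1000
  kL <- idx(faces$i, faces$j)           # cell left of the face
  kR <- idx(faces$i + 1, faces$j)
  # flux J = Ff (P_L + P_R)/2 - D (P_R - P_L)/h leaves L, enters R;
  # L-matrix contributions, negated into A = I - dt L below
  aLL <- -(Ff / 2 + Dd / h) / h
  aLR <- -(Ff / 2 - Dd / h) / h
  aRL <- +(Ff / 2 + Dd / h) / h
  aRR <- +(Ff / 2 - Dd / h) / h
  rows <- c(rows, kL, kR); cols <- c(cols, kR, kL)
  vals <- c(vals, -dt * aLR, -dt * aRL)
  dd <- numeric(n * n)
  dd[kL] <- dd[kL] - dt * aLL
  add2 <- numeric(n * n); add2[kR] <- -dt * aRR
  dd <- dd + add2
  # horizontal faces between (i, j) and (i, j + 1)
  faces <- expand.grid(i = seq_len(n), j = seq_len(n - 1))
  Ff <- rule_field(couplings, (faces$i - 0.5) * h, faces$j * h)$F2 * 1000
  kL <- idx(faces$i, faces$j)
  kR <- idx(faces$i, faces$j + 1)
  aLL <- -(Ff / 2 + Dd / h) / h
  aLR <- -(Ff / 2 - Dd / h) / h
  aRL <- +(Ff / 2 + Dd / h) / h
  aRR <- +(Ff / 2 - Dd / h) / h
  rows <- c(rows, kL, kR); cols <- c(cols, kR, kL)
  vals <- c(vals, -dt * aLR, -dt * aRL)
  dd[kL] <- dd[kL] - dt * aLL
  add2 <- numeric(n * n); add2[kR] <- -dt * aRR
  dd <- dd + add2
  rows <- c(rows, seq_len(n * n))
  cols <- c(cols, seq_len(n * n))
  vals <- c(vals, diag_vals + dd)
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(n * n, n * n))
  list(A = A, s = s, h = h, D = Dd, F1 = F1, F2 = F2, n = n, dt = dt)
}

#' Steady state of the rule module's Fokker-Planck equation
#'
#' Propagates an initially uniform density with the implicit BTCS scheme
#' of [fp_operator()], renormalising after every step, until the density
#' change rate `max |P_{k+1} - P_k| / dt` drops below `tol`.  Because the
#' implicit scheme is unconditionally stable, the step size may be grown
#' geometrically once the transient has passed (`accelerate = TRUE`),
#' which shortens the approach to the slow inter-basin equilibration
#' without changing the fixed point of the iteration.
#'
#' @param params a [rule_params()] object (`sigma_rule` sets the diffusion
#'   coefficient `D = (sigma_rule/2)^2`).
#' @param n grid points per axis.
#' @param dt initial implicit step (ms).
#' @param tol convergence tolerance on `max |dP| / dt`.
#' @param max_iter iteration cap.
#' @param accelerate grow `dt` (x10, capped at 1e7 ms) every 50 iterations
#'   while unconverged.
#' @param consts physiological constants.
#' @return An object of class `potential_landscape`: list with axes `s1`,
#'   `s2`, the normalised steady-state density `Pss` (n x n, zero on the
#'   boundary), the generalized potential `U = -ln Pss` (shifted to
#'   minimum 0), the diffusion coefficient `D`, `params`, `couplings`,
#'   and convergence metadata.
#' @examples
#' \donttest{
#' L <- fp_steady_state(rule_params(sigma_rule = 0.1), n = 48)
#' landscape_minima(L)
#' }
#' @export
fp_steady_state <- function(params = rule_params(), n = 128, dt = 10,
                            tol = 1e-9, max_iter = 20000,
                            accelerate = TRUE,
                            consts = physio_constants()) {
  stopifnot(dt > 0, tol > 0)
  if (!inherits(params, "rule_params")) params <- do.call(rule_params, params)
  cpl <- effective_couplings(params, consts)
  op <- fp_operator(cpl, params$sigma_rule, n = n, dt = dt)
  P <- rep(1, n * n)
  P <- P / (sum(P) * op$h^2)
  fac <- Matrix::lu(op$A)
  iterations <- 0
  converged <- FALSE
  cur_dt <- dt
  repeat {
    Pn <- as.numeric(Matrix::solve(fac, P))
    Pn[Pn < 0] <- 0
    Pn <- Pn / (sum(Pn) * op$h^2)
    res <- max(abs(Pn - P)) / cur_dt
    P <- Pn
    iterations <- iterations + 1
    if (res < tol) { converged <- TRUE; break }
    if (iterations >= max_iter) break
    if (accelerate && iterations %% 50 == 0 && cur_dt < 1e7) {
      cur_dt <- cur_dt * 10
      op <- fp_operator(cpl, params$sigma_rule, n = n, dt = cur_dt)
      fac <- Matrix::lu(op$A)
    }
  }
  if (!converged) {
    stop("Fokker-Planck iteration did not converge: residual ",
         format(max(abs(P)) , digits = 3), " after ", iterations,
         " steps")
  }
  Pss <- matrix(P, n, n)
  U <- -log(pmax(Pss, 1e-300))
  U <- U - min(U)
  structure(list(s1 = op$s, s2 = op$s, Pss = Pss, U = U, D = op$D,
                 params = params, couplings = cpl, h = op$h,
                 iterations = iterations, converged = converged,
                 dt_final = cur_dt, tol = tol),
            class = "potential_landscape")
}

#' @export
print.potential_landscape <- function(x, ...) {
  cat(sprintf(
    "Potential landscape: %d x %d grid, D = %.4g, %d iterations\n",
    length(x$s1), length(x$s2), x$D, x$iterations))
  invisible(x)
}

#' Generalized potential from a steady-state density
#'
#' The Boltzmann-type potential `U = -ln Pss`, floored at 1e-300 before
#' the logarithm and shifted so its minimum is 0 (the potential is only
#' defined up to an additive constant).
#'
#' @param landscape a [fp_steady_state()] result (or a density matrix).
#' @return The potential matrix.
#' @export
potential_from_pss <- function(landscape) {
  P <- if (is.matrix(landscape)) landscape else landscape$Pss
  U <- -log(pmax(P, 1e-300))
  U - min(U)
}

#' Locate and classify the minima of a potential landscape
#'
#' Finds grid-local minima of `U` (8-neighbourhood) restricted to cells
#' with non-vanishing density, and labels them `spontaneous` (near the
#' diagonal at low gating), `rule1` (S1 dominant) or `rule2`.
#'
#' @param landscape a [fp_steady_state()] result.
#' @param min_density density floor for candidate cells (relative to the
#'   maximum of `Pss`).
#' @return A tibble with columns `state`, `S1`, `S2`, `i`, `j`, `U`.
#' @export
landscape_minima <- function(landscape, min_density = 1e-12) {
  P <- landscape$Pss
  n <- nrow(P)
  # pad with an infinite rim so edge cells can qualify
  U <- matrix(Inf, n + 2, n + 2)
  U[2:(n + 1), 2:(n + 1)] <- landscape$U
  ii <- 2:(n + 1)
  ctr <- U[ii, ii]
  is_min <- ctr <= U[ii - 1, ii] & ctr <= U[ii + 1, ii] &
    ctr <= U[ii, ii - 1] & ctr <= U[ii, ii + 1] &
    ctr <= U[ii - 1, ii - 1] & ctr <= U[ii + 1, ii + 1] &
    ctr <= U[ii - 1, ii + 1] & ctr <= U[ii + 1, ii - 1] &
    P > min_density * max(P)
  w <- which(is_min, arr.ind = TRUE)
  if (!nrow(w)) return(tibble(state = character(), S1 = numeric(),
                              S2 = numeric(), i = integer(),
                              j = integer(), U = numeric()))
  i <- w[, 1]
  j <- w[, 2]
  out <- tibble(S1 = landscape$s1[i], S2 = landscape$s2[j],
                i = i, j = j, U = landscape$U[cbind(i, j)])
  out$state <- dplyr::case_when(
    abs(out$S1 - out$S2) < 0.15 ~ "spontaneous",
    out$S1 > out$S2 ~ "rule1",
    TRUE ~ "rule2"
  )
  # keep the deepest representative per state
  out <- dplyr::slice_min(dplyr::group_by(out, .data$state), .data$U,
                          n = 1, with_ties = FALSE)
  dplyr::select(dplyr::ungroup(out), "state", "S1", "S2", "i", "j", "U")
}

#' Walker-ensemble occupancy histogram of the landscape SDE
#'
#' Direct Euler-Maruyama simulation of the white-noise stochastic
#' equation underlying the landscape analysis, `dS/dt = F(S) +
#' sqrt(2 D) xi(t)` (time in seconds, `D = (sigma_rule/2)^2`), as an
#' ensemble of independent walkers started uniformly on the unit square
#' (the sampling picture behind the steady-state density).  Occupancy
#' after a per-walker burn-in is accumulated on an `nbin` x `nbin` grid.
#' This is the direct-simulation cross-check of [fp_steady_state()].
#'
#' @param params a [rule_params()] object.
#' @param n_walkers independent trajectories.
#' @param n_steps steps per walker.
#' @param burn_steps discarded initial steps per walker.
#' @param dt_s Euler-Maruyama step (seconds).
#' @param nbin histogram bins per axis.
#' @param seed integer seed.
#' @param consts physiological constants.
#' @return An `nbin` x `nbin` matrix of occupancy probabilities (sums
#'   to 1).
#' @export
simulate_landscape_histogram <- function(params = rule_params(),
                                         n_walkers = 256,
                                         n_steps = 80000,
                                         burn_steps = 40000,
                                         dt_s = 5e-4, nbin = 32,
                                         seed = 1,
                                         consts = physio_constants()) {
  if (!inherits(params, "rule_params")) params <- do.call(rule_params, params)
  cpl <- effective_couplings(params, consts)
  H <- cpp_eq9_histogram(cpl_vec(cpl), params$sigma_rule,
                         as.integer(n_walkers), n_steps, burn_steps,
                         dt_s, as.integer(seed), as.integer(nbin))
  H / sum(H)
}

#' Jensen-Shannon divergence between two occupancy distributions
#'
#' Used to compare the Fokker-Planck steady state with a direct
#' simulation histogram on a common coarse grid (both renormalised).
#'
#' @param p,q non-negative matrices or vectors of equal length.
#' @return The divergence in nats (0 for identical distributions,
#'   bounded by log 2).
#' @export
js_divergence <- function(p, q) {
  p <- as.vector(p) / sum(p)
  q <- as.vector(q) / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Coarsen a gridded density to a smaller grid
#'
#' Aggregates an `n` x `n` matrix into `nbin` x `nbin` cells by summation
#' (cell-membership by node position), for comparisons against binned
#' occupancy histograms.
#'
#' @param mat square matrix of non-negative weights.
#' @param nbin target bins per axis.
#' @param axis optional node positions in [0, 1] (defaults to a uniform
#'   grid including the endpoints).
#' @return An `nbin` x `nbin` matrix normalised to sum 1.
#' @export
coarsen_grid <- function(mat, nbin = 32, axis = NULL) {
  n <- nrow(mat)
  if (is.null(axis)) axis <- seq(0, 1, length.out = n)
  bin <- pmin(pmax(floor(axis * nbin) + 1, 1), nbin)
  out <- matrix(0, nbin, nbin)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[bin[i], bin[j]] <- out[bin[i], bin[j]] + mat[i, j]
    }
  }
  out / sum(out)
}
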