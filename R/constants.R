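#' Physiological constants of the rule module
#'
#' Fixed biophysical scalars of the reduced two-population working-memory
#' (rule) module: relative population sizes, f-I curve constants, mean
#' membrane voltages, synaptic time constants and conductances, and the
#' structural weights of the selective populations.  All values default to
#' the published parameter set of the underlying mean-field reduction;
#' individual constants can be overridden by name.
#'
#' Units: conductances in microsiemens, voltages in mV, rates in Hz, time
#' constants in ms.  `c_E`/`c_I` are f-I gains in Hz/nA, `g_E` is in
#' seconds.  Two dimensionless calibration constants of the reduction are
#' exposed as well: `mg_gate`, the weight of the magnesium-block
#' attenuation of the NMDA conductances, and `eta_gain`, the closed-loop
#' gain of the shared inhibitory population (its open-loop f-I gain
#' `c_I/g_I2` is attenuated by its own GABAergic self-inhibition).  See the
#' methods vignette for how these two were fixed.
#'
#' @param ... named overrides for any constant, e.g. `w_plus = 1.7`.
#'
#' @return An object of class `physio_constants`: a named list of scalars.
#'   The derived depressed weight `w_minus = 1 - f (w_plus - 1)/(1 - f)` is
#'   included.
#' @examples
#' pc <- physio_constants()
#' pc$w_minus  # 0.88 at the default coding level and potentiated weight
#' @export
physio_constants <- function(...) {
  x <- list(
    C_E = 0.8, C_I = 0.2, C_ext = 800, f = 0.15,
    c_E = 310, g_E = 0.16, I_E = 125,
    c_I = 615, I_I = 177,
    V_E = -53.4, V_I = -51.1, V_I_rev = -70,
    r_ext = 3, r_ns = 2, r0 = 11.3721,
    tau_GABA = 10, tau_AMPA = 2, tau_NMDA = 100,
    g_I2 = 1.7876,
    g_AMPAext_E = 0.0021, g_AMPA_E = 0.1, g_NMDA_E = 0.3, g_GABA_E = 1.3,
    g_AMPAext_I = 0.00162, g_AMPA_I = 0.086, g_NMDA_I = 0.258, g_GABA_I = 1,
    w_plus = 1.68, gamma = 0.641,
    mg_gate = 0.91, eta_gain = 0.076
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(x))
    if (length(bad)) {
      stop("unknown physiological constant(s): ", paste(bad, collapse = ", "))
    }
    x[names(dots)] <- dots
  }
  pos <- setdiff(names(x), c("V_E", "V_I", "V_I_rev"))
  if (any(!vapply(x, is.numeric, logical(1))) ||
      any(unlist(x[pos]) <= 0)) {
    stop("physiological constants must be numeric and (voltages aside) strictly positive")
  }
  if (abs(x$C_E + x$C_I - 1) > 1e-12) {
    stop("C_E + C_I must equal 1")
  }
  x$w_minus <- 1 - x$f * (x$w_plus - 1) / (1 - x$f)
  structure(x, class = "physio_constants")
}

#' Rule-module parameters
#'
#' The three subject-specific parameters of the rule module: dimensionless
#' scalings of the NMDA and GABA conductances and the diffusion parameter
#' of the Ornstein-Uhlenbeck noise added to the synaptic gating dynamics.
#' Negative `sigma_rule` values are canonicalised by absolute value (the
#' shrinkage priors are centred at zero and only the squared diffusion
#' enters the dynamics).
#'
#' @param s_nmda scaling of the excitatory NMDA conductance (default 1).
#' @param s_gaba scaling of the GABA conductance onto excitatory cells
#'   (default 1).
#' @param sigma_rule OU diffusion parameter (default 0.1, the standard
#'   landscape value).
#' @return An object of class `rule_params`.
#' @export
rule_params <- function(s_nmda = 1, s_gaba = 1, sigma_rule = 0.1) {
  stopifnot(is.numeric(s_nmda), is.numeric(s_gaba), is.numeric(sigma_rule))
  structure(list(s_nmda = s_nmda, s_gaba = s_gaba,
                 sigma_rule = abs(sigma_rule)),
            class = "rule_params")
}

#' Effective couplings of the reduced rule module
#'
#' Collapses the synaptic architecture (recurrent NMDA and AMPA excitation,
#' shared GABAergic inhibition with a linearised inhibitory population,
#' non-selective and external drive) into the effective connection
#' parameters of the two-variable reduction: NMDA-mediated couplings
#' `J_N11`, `J_N12` (with `J_N22 = J_N11`, `J_N21 = J_N12` by symmetry),
#' AMPA-mediated couplings `J_A11`, `J_A12` entering the transfer function,
#' and the baseline input current `I0` with its composition coefficients
#' `l`, `m`, `n` multiplying the external, non-selective-AMPA and
#' non-selective-NMDA rates.
#'
#' The inhibitory loop enters every coupling through the gain
#' `G = g_GABA_E (V_E - V_I_rev) tau_GABA/1000 * C_I c_I eta_gain / g_I2`,
#' and the NMDA conductances are attenuated by the voltage-dependent
#' magnesium-block factor `1 + mg_gate exp(-0.062 V)/3.57`.
#'
#' @param params a [rule_params()] object (only the conductance scalings
#'   are used here).
#' @param consts a [physio_constants()] object.
#' @return An object of class `effective_couplings`: a named list with all
#'   couplings and intermediates (`J_N11`, `J_N12`, `J_A11`, `J_A12`, `I0`,
#'   `l`, `m`, `n`, `psi_ns`, `g_NMDAeff_E`, `g_NMDAeff_I`, `w_minus`,
#'   `gamma`, `tau_NMDA`, `tau_AMPA`).
#' @examples
#' cpl <- effective_couplings(rule_params())
#' cpl$J_N11
#' @export
effective_couplings <- function(params = rule_params(),
                                consts = physio_constants()) {
  stopifnot(inherits(consts, "physio_constants"))
  if (!inherits(params, "rule_params")) params <- do.call(rule_params, params)
  cn <- consts
  mg <- function(V) 1 + cn$mg_gate * exp(-0.062 * V) / 3.57
  g_NMDAeff_E <- params$s_nmda * cn$g_NMDA_E / mg(cn$V_E)
  g_NMDAeff_I <- cn$g_NMDA_I / mg(cn$V_I)
  pre <- params$s_gaba * cn$g_GABA_E * (cn$V_E - cn$V_I_rev) * cn$tau_GABA / 1000
  G <- pre * cn$C_I * cn$c_I * cn$eta_gain / cn$g_I2
  tA <- cn$tau_AMPA / 1000
  fCE <- cn$f * cn$C_E
  nsCE <- (1 - 2 * cn$f) * cn$C_E
  J_N11 <- G * g_NMDAeff_I * cn$V_I * fCE - g_NMDAeff_E * cn$V_E * fCE * cn$w_plus
  J_N12 <- g_NMDAeff_E * cn$V_E * fCE * cn$w_minus - G * g_NMDAeff_I * cn$V_I * fCE
  J_A11 <- G * cn$g_AMPA_I * cn$V_I * tA * fCE - cn$g_AMPA_E * cn$V_E * tA * fCE * cn$w_plus
  J_A12 <- cn$g_AMPA_E * cn$V_E * tA * fCE * cn$w_minus - G * cn$g_AMPA_I * cn$V_I * tA * fCE
  l <- G * cn$g_AMPAext_I * cn$V_I * tA * cn$C_ext - cn$g_AMPAext_E * cn$V_E * tA * cn$C_ext
  m <- G * cn$g_AMPA_I * cn$V_I * tA * nsCE - cn$g_AMPA_E * cn$V_E * tA * nsCE * cn$w_minus
  n <- G * g_NMDAeff_I * cn$V_I * nsCE - g_NMDAeff_E * cn$V_E * nsCE * cn$w_minus
  z <- cn$gamma * cn$tau_NMDA * cn$r_ns / 1000
  psi_ns <- z / (1 + z)
  I0 <- l * cn$r_ext + m * cn$r_ns + n * psi_ns +
    pre * cn$C_I * cn$eta_gain * (cn$I_I / cn$g_I2 - cn$r0)
  vals <- c(J_N11, J_N12, J_A11, J_A12, I0, l, m, n)
  if (any(!is.finite(vals))) {
    stop("invalid physiological constants: non-finite effective coupling")
  }
  structure(list(
    J_N11 = J_N11, J_N12 = J_N12, J_N22 = J_N11, J_N21 = J_N12,
    J_A11 = J_A11, J_A12 = J_A12, J_A22 = J_A11, J_A21 = J_A12,
    I0 = I0, l = l, m = m, n = n, psi_ns = psi_ns,
    g_NMDAeff_E = g_NMDAeff_E, g_NMDAeff_I = g_NMDAeff_I,
    w_minus = cn$w_minus, gamma = cn$gamma,
    tau_NMDA = cn$tau_NMDA, tau_AMPA = cn$tau_AMPA
  ), class = "effective_couplings")
}

#' @export
print.effective_couplings <- function(x, ...) {
  cat("Effective rule-module couplings\n")
  cat(sprintf("  J_N11 = %.5f  J_N12 = %.5f  (nA)\n", x$J_N11, x$J_N12))
  cat(sprintf("  J_A11 = %.3e  J_A12 = %.3e  (nA/Hz)\n", x$J_A11, x$J_A12))
  cat(sprintf("  I0    = %.5f  (nA)\n", x$I0))
  invisible(x)
}

# internal: fixed-order vector handed to the compiled integrators
cpl_vec <- function(cpl) {
  c(cpl$J_N11, cpl$J_N12, cpl$J_A11, cpl$J_A12, cpl$I0,
    cpl$gamma, cpl$tau_NMDA)
}
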