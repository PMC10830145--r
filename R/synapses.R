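# Two-state kinetic synapses (AMPA, NMDA with magnesium block, GABA-A)
# and the tonic GABA-A conductance.

#' Synapse specification
#'
#' Two-state kinetic conductance with rise and decay time constants
#' `tau1 < tau2`, peak-normalized to `g_max`.  Defaults follow the dSPN
#' model: AMPA 350 pS (1.9/4.8 ms, 0 mV), NMDA 752.5 pS (5.5/231 ms, 0 mV,
#' magnesium block), GABA-A 1000 pS (0.5/7.5 ms, -60 mV).
#'
#' @param kind one of "AMPA", "NMDA", "GABAA".
#' @param g_max peak conductance, pS.
#' @param tau1,tau2 rise/decay time constants, ms (`tau2 > tau1 > 0`).
#' @param e_rev reversal potential, mV.
#' @return list of class `synapse_spec`.
#' @export
synapse_spec <- function(kind = c("AMPA", "NMDA", "GABAA"),
                         g_max = NULL, tau1 = NULL, tau2 = NULL,
                         e_rev = NULL) {
  kind <- match.arg(kind)
  def <- switch(kind,
    AMPA  = list(g_max = 350,   tau1 = 1.9, tau2 = 4.8, e_rev = 0,
                 mg_block = FALSE),
    NMDA  = list(g_max = 752.5, tau1 = 5.5, tau2 = 231, e_rev = 0,
                 mg_block = TRUE),
    GABAA = list(g_max = 1000,  tau1 = 0.5, tau2 = 7.5, e_rev = -60,
                 mg_block = FALSE))
  if (!is.null(g_max)) def$g_max <- g_max
  if (!is.null(tau1)) def$tau1 <- tau1
  if (!is.null(tau2)) def$tau2 <- tau2
  if (!is.null(e_rev)) def$e_rev <- e_rev
  if (def$tau1 <= 0 || def$tau2 <= def$tau1)
    stop("require tau2 > tau1 > 0")
  if (def$g_max < 0) stop("g_max must be >= 0")
  def$kind <- kind
  class(def) <- "synapse_spec"
  def
}

#' Two-state synaptic conductance waveform
#'
#' `g(t) = g_max * N * (exp(-t/tau2) - exp(-t/tau1))` with `N` chosen so
#' the peak (at `t = tau1*tau2/(tau2-tau1) * log(tau2/tau1)`) equals
#' `g_max`.
#'
#' @param spec a `synapse_spec`.
#' @param t_since_onset time(s) since onset, ms (>= 0).
#' @return conductance in nS.
#' @export
syn_conductance <- function(spec, t_since_onset) {
  stopifnot(all(t_since_onset >= 0))
  if (spec$tau2 <= spec$tau1) stop("require tau2 > tau1")
  tp <- syn_peak_time(spec)
  norm <- 1 / (exp(-tp / spec$tau2) - exp(-tp / spec$tau1))
  g_pS <- spec$g_max * norm *
    (exp(-t_since_onset / spec$tau2) - exp(-t_since_onset / spec$tau1))
  g_pS * 1e-3
}

#' Time of peak of the two-state conductance (ms)
#' @param spec a `synapse_spec`.
#' @export
syn_peak_time <- function(spec)
  spec$tau1 * spec$tau2 / (spec$tau2 - spec$tau1) * log(spec$tau2 / spec$tau1)

#' NMDA magnesium unblock fraction
#'
#' Exponential voltage dependence `1 / (1 + [Mg]/k * exp(-gamma * V))`,
#' monotonically increasing in V and saturating at 1.
#'
#' @param v membrane potential, mV.
#' @param mg_mM extracellular magnesium, mM.
#' @param k_mM,gamma_per_mV block constants.
#' @return unblocked fraction in `[0, 1]`.
#' @export
mg_unblock <- function(v, mg_mM = 1, k_mM = 3.57, gamma_per_mV = 0.062)
  1 / (1 + (mg_mM / k_mM) * exp(-gamma_per_mV * v))

#' Tonic GABA-A conductance specification
#'
#' A spatially uniform, continuously open chloride conductance over soma
#' and dendrites, reversing at -60 mV; densities up to 3e-2 S/cm2 are
#' explored in the tonic sweep.
#'
#' @param density S/cm2 (>= 0).
#' @param e_rev reversal potential, mV.
#' @export
tonic_gaba <- function(density, e_rev = -60) {
  if (density < 0) stop("negative tonic density")
  structure(list(density = density, e_rev = e_rev), class = "tonic_gaba")
}

#' Apply (set) a tonic GABA-A conductance on a system
#'
#' Every somatic and dendritic compartment receives an ohmic conductance of
#' `tonic$density` times its membrane area, reversing at `tonic$e_rev`.
#' The tonic conductance is *set*, not accumulated, so the call is
#' idempotent; density 0 removes it.
#'
#' @param system an `spn_system` from [build_system()].
#' @param tonic a `tonic_gaba`.
#' @return the modified system.
#' @export
apply_tonic <- function(system, tonic) {
  stopifnot(inherits(system, "spn_system"), inherits(tonic, "tonic_gaba"))
  g <- numeric(system$n_comp)
  memb <- system$comp_kind %in% c("soma", "dendrite")
  g[memb] <- tonic$density * system$area_cm2[memb] * 1e6  # uS
  system$g_tonic_uS <- g
  system$e_tonic_mV <- tonic$e_rev
  system$tonic_density <- tonic$density
  system
}
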