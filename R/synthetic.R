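# Synthetic data generators: perforated-patch style response-vs-voltage
# datasets with a known reversal potential, closed-form reference traces
# for the metric tests, and the one-call calibrated dSPN model.

#' Specification for a synthetic response-versus-voltage dataset
#'
#' Emulates the structure of perforated-patch reversal measurements: a
#' linear response through the true reversal potential plus Gaussian noise,
#' sampled per cell per holding potential on a 5 mV grid.
#'
#' @param true_reversal mV.
#' @param true_slope response units per mV.
#' @param noise_sd response-unit standard deviation (>= 0); the default
#'   puts the per-potential-mean regression in the R^2 ~ 0.9 regime at
#'   `n_cells = 5`.
#' @param n_cells number of cells.
#' @param potentials holding potentials, mV (5 mV grid in -80..-50).
#' @param seed integer.
#' @export
ephys_gen_spec <- function(true_reversal = -60, true_slope = 0.7,
                           noise_sd = 3.7, n_cells = 5,
                           potentials = seq(-70, -50, by = 5), seed = 1L) {
  stopifnot(noise_sd >= 0, all(potentials >= -80), all(potentials <= -50))
  structure(list(true_reversal = true_reversal, true_slope = true_slope,
                 noise_sd = noise_sd, n_cells = n_cells,
                 potentials = potentials, seed = as.integer(seed)),
            class = "ephys_gen_spec")
}

#' Generate a synthetic response-versus-voltage dataset
#'
#' `response = true_slope * (V - true_reversal) + N(0, noise_sd)` for every
#' cell at every holding potential; deterministic per seed.
#'
#' @param spec an `ephys_gen_spec`.
#' @return data frame (cell_id, condition, holding_mV, response) with the
#'   generating seed in attribute `seed`.
#' @export
gen_ephys_dataset <- function(spec = ephys_gen_spec()) {
  stopifnot(inherits(spec, "ephys_gen_spec"))
  set.seed(spec$seed)
  grid <- expand.grid(cell_id = seq_len(spec$n_cells),
                      holding_mV = spec$potentials)
  grid$condition <- "baseline"
  grid$response <- spec$true_slope * (grid$holding_mV - spec$true_reversal) +
    stats::rnorm(nrow(grid), 0, spec$noise_sd)
  structure(grid[, c("cell_id", "condition", "holding_mV", "response")],
            seed = spec$seed)
}

#' Closed-form reference traces for metric tests
#'
#' `exponential_psp`: instantaneous rise to `peak` then exponential decay
#' with `tau` (quarterdrop = tau * log(4/3)).  `plateau`: flat-top response
#' of given `duration` with exponential flanks.  `additive_pair`: two PSPs
#' and their exact sum, for linearity checks.
#'
#' @param kind waveform family.
#' @param peak mV over baseline.
#' @param tau ms decay constant.
#' @param duration ms plateau duration.
#' @param baseline mV.
#' @param t_on stimulus time, ms.
#' @param dt sample interval, ms.
#' @param t_max trace length, ms.
#' @return for `additive_pair`, a list of three traces; otherwise a list
#'   with `t` and `v`.
#' @export
gen_reference_traces <- function(kind = c("exponential_psp", "plateau",
                                          "additive_pair"),
                                 peak = 5, tau = 50, duration = 150,
                                 baseline = -84, t_on = 50, dt = 0.025,
                                 t_max = 600) {
  kind <- match.arg(kind)
  stopifnot(peak > 0, tau > 0, duration > 0, dt > 0)
  t <- seq(0, t_max, by = dt)
  psp <- function(amp, on, tau_d)
    ifelse(t < on, 0, amp * exp(-(t - on) / tau_d))
  if (kind == "exponential_psp")
    return(list(t = t, v = baseline + psp(peak, t_on, tau)))
  if (kind == "plateau") {
    v <- baseline + ifelse(t < t_on, 0,
                    ifelse(t <= t_on + duration, peak,
                           peak * exp(-(t - t_on - duration) / 2)))
    return(list(t = t, v = v))
  }
  # coincident onsets so the combined amplitude is exactly the sum
  a <- psp(peak, t_on, tau)
  b <- psp(peak * 0.6, t_on, tau * 0.5)
  list(first = list(t = t, v = baseline + a),
       second = list(t = t, v = baseline + b),
       combined = list(t = t, v = baseline + a + b))
}

#' Build the calibrated default dSPN model
#'
#' One-call assembly: synthetic morphology with spines, packaged channel
#' table, leak calibration, and a cached settled resting state shared by
#' the protocol runners.  The reference dendrite for clustered-input
#' protocols is the most distal eligible section.
#'
#' @param seed morphology seed.
#' @param config a `sim_config`; `axial_resistivity = 100` together with
#'   `gsyn_scale = 1.6` gives the low-Ra variant.
#' @param params `morpho_params` overrides.
#' @param channel_table optional `channel_table`.
#' @param gsyn_scale scale on synaptic peak conductances.
#' @param glut_threshold clustered-input spike threshold used by dependent
#'   protocols; computed lazily by [threshold_search()] when first needed
#'   unless supplied.
#' @return list of class `spn_model`.
#' @export
default_model <- function(seed = 1L, config = sim_config(),
                          params = morpho_params(seed = seed),
                          channel_table = default_channel_table(),
                          gsyn_scale = 1, glut_threshold = 15L) {
  morph <- generate_morphology(params)
  membrane <- build_membrane(morph, channel_table)
  base_system <- build_system(morph, membrane, active_spines = NULL,
                              config = config, gsyn_scale = gsyn_scale)
  base <- settle(base_system)

  model <- list(morph = morph, membrane = membrane, config = config,
                base_system = base_system, base_state = base$state,
                rmp = base$rmp, gsyn_scale = gsyn_scale,
                syn = list(ampa = synapse_spec("AMPA"),
                           nmda = synapse_spec("NMDA"),
                           gaba = synapse_spec("GABAA")),
                glut_threshold = as.integer(glut_threshold),
                seed = seed)
  class(model) <- "spn_model"
  targets <- target_dendrites(model)
  if (nrow(targets) < 1)
    stop("calibration failure: no dendrite can host the clustered protocol")
  model$reference_dendrite <- targets$section_id[nrow(targets)]
  model
}

#' @export
print.spn_model <- function(x, ...) {
  cat("spn_model (seed", x$seed, ")\n")
  print(x$morph)
  cat(sprintf("  settled rest %.2f mV, reference dendrite %d\n",
              x$rmp, x$reference_dendrite))
  invisible(x)
}
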