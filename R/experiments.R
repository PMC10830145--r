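# Named experiments: one entry point per simulation study, each writing a
# tidy CSV and a run manifest.  The analysis/ scripts in the repository are
# thin drivers over these functions.

experiment_names <- c("fig5_distance_scan", "fig5_onsite_timing",
                      "fig5_offsite", "fig6_onsite", "fig6_offsite",
                      "fig7_tonic", "fig8_impedance", "s2_ra_variant",
                      "s3_onpath", "s4_nmda_ko", "s4_12dend", "thresholds")

# small rolling hash for the manifest's config fingerprint
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 216613626
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%08x", h)
}

#' Tonic-conductance grid (S/cm2): 1-3 steps per decade, 1e-6 to 3e-2
#' @export
tonic_grid <- function() c(1e-6, 3e-6, 1e-5, 3e-5, 1e-4, 3e-4, 1e-3, 3e-3,
                           1e-2, 3e-2)

#' Quarterdrop versus path distance across all eligible dendrites
#'
#' Delivers the suprathreshold clustered input (default 18 spines at 1 ms)
#' to every dendrite able to host it and records the dendritic quarterdrop.
#'
#' @param model an `spn_model`.
#' @param n_glut clustered inputs per dendrite.
#' @param spike_cutoff_ms classification cutoff.
#' @return data frame (section_id, mid_path, quarterdrop, spike).
#' @export
distance_scan <- function(model, n_glut = 18, spike_cutoff_ms = 40) {
  targets <- target_dendrites(model, n_required = n_glut)
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    sec <- targets$section_id[i]
    glut <- clustered_glutamate(model, sec, n_glut)
    tr <- run_synaptic_protocol(model, glut = glut,
                                record_sections = list(dend = c(sec, 0.5)))
    qd <- quarterdrop(tr, t_last_stim = attr(tr, "t_last_glut"),
                      t_first_stim = attr(tr, "t_first_glut"),
                      column = "dend")
    data.frame(section_id = sec, mid_path = targets$mid_path[i],
               quarterdrop = as.numeric(qd),
               spike = classify_spike(qd, spike_cutoff_ms))
  })
  do.call(rbind, rows)
}

#' Local PSP amplitude and 10 Hz impedance versus GABA synapse count
#'
#' The conductance of `n` GABA-A synapses (peak conductance each) is held
#' open as a steady local shunt either at the recording dendrite's midpoint
#' (on-site) or spread over distal off-site dendrites, and the local
#' impedance at 10 Hz is measured at the recording site.
#'
#' @param model an `spn_model`.
#' @param counts GABA synapse counts.
#' @param mode "onsite" or "offsite".
#' @param frequency Hz.
#' @return data frame (mode, n_syn, dv_mV, impedance_MOhm).
#' @export
impedance_vs_gaba <- function(model, counts = c(0, 1, 3, 6, 12, 24),
                              mode = c("onsite", "offsite"),
                              frequency = 10) {
  mode <- match.arg(mode)
  dendrite <- model$reference_dendrite
  sys <- model$base_system
  rec_comp <- compartment_at(sys, dendrite, 0.5)
  g_unit <- model$syn$gaba$g_max * 1e-6 * model$gsyn_scale  # uS per synapse
  sites <- if (mode == "onsite") rec_comp else
    vapply(distal_terminals(model, 4, exclude_dendrite = dendrite),
           function(s) compartment_at(sys, s, 0.5), 0L)
  rmp <- model$rmp
  rows <- lapply(counts, function(n) {
    s2 <- sys
    g <- numeric(s2$n_comp)
    g[sites] <- n * g_unit / length(sites)   # synapses shared across sites
    s2$g_tonic_uS <- g
    s2$e_tonic_mV <- model$syn$gaba$e_rev
    st <- settle(s2, settle_ms = 500)
    z <- measure_impedance(s2, rec_comp, frequency = frequency,
                           init_state = st$state)
    v_site <- simulate(s2, duration = 1, record = rec_comp,
                       init_state = st$state)$v
    data.frame(mode = mode, n_syn = n,
               dv_mV = v_site[nrow(v_site), 1] - rmp,
               impedance_MOhm = z)
  })
  do.call(rbind, rows)
}

#' Run a named simulation experiment
#'
#' Each experiment reproduces one of the package's simulation studies and
#' writes a tidy CSV plus a JSON run manifest (command, config hash, seed,
#' outputs, package version) under `out_dir`.
#'
#' @param name experiment name; unknown names raise an error listing the
#'   valid ones.
#' @param model an `spn_model` (built from `seed` when NULL).
#' @param seed model seed when `model` is NULL.
#' @param out_dir output directory, or NULL to skip writing.
#' @param ... overrides passed to the underlying routine.
#' @return the experiment's result data frame (invisibly when writing).
#' @export
run_experiment <- function(name, model = NULL, seed = 1L, out_dir = NULL,
                           ...) {
  if (!name %in% experiment_names)
    stop("unknown experiment '", name, "'; valid names: ",
         paste(experiment_names, collapse = ", "))
  if (is.null(model)) model <- default_model(seed = seed)
  dend <- model$reference_dendrite

  res <- switch(name,
    fig5_distance_scan = distance_scan(model, ...),
    fig5_onsite_timing = timing_sweep(model, dend, n_glut = 18,
                                      gaba_mode = "onsite", repeats = 5,
                                      delta_t_values = seq(-10, 80, 10),
                                      ...)$results,
    fig5_offsite = timing_sweep(model, dend, n_glut = 15,
                                gaba_mode = "offsite4x3",
                                delta_t_values = 10, ...)$results,
    fig6_onsite = timing_sweep(model, dend, n_glut = 15,
                               gaba_mode = "onsite", repeats = 4, ...)$results,
    fig6_offsite = timing_sweep(model, dend, n_glut = 15,
                                gaba_mode = "offsite4x3", ...)$results,
    fig7_tonic = tonic_sweep(model, tonic_grid(), ...),
    fig8_impedance = rbind(impedance_vs_gaba(model, mode = "onsite", ...),
                           impedance_vs_gaba(model, mode = "offsite", ...)),
    s2_ra_variant = {
      m2 <- default_model(seed = model$seed,
                          config = sim_config(axial_resistivity = 100),
                          gsyn_scale = 1.6)
      ts <- threshold_search(m2, "glutamate", lo = 10, hi = 22)
      data.frame(variant = "Ra100_gsyn1.6", glut_threshold = as.integer(ts))
    },
    s3_onpath = timing_sweep(model, dend, n_glut = 15,
                             gaba_mode = "onpath_proximal", ...)$results,
    s4_nmda_ko = {
      glut <- clustered_glutamate(model, dend, 15, t0 = 10)
      gaba <- phasic_gaba(model, "offsite4x3", glut_dendrite = dend, t0 = 0)
      tr <- run_synaptic_protocol(model, glut = glut, gaba = gaba,
                                  nmda_on = FALSE,
                                  record_sections = list(dend = c(dend, 0.5)))
      qd <- quarterdrop(tr, t_last_stim = attr(tr, "t_last_glut"),
                        t_first_stim = attr(tr, "t_first_gaba"),
                        column = "dend")
      data.frame(nmda_on = FALSE, quarterdrop = as.numeric(qd),
                 spike = classify_spike(qd))
    },
    s4_12dend = timing_sweep(model, dend, n_glut = 15,
                             gaba_mode = "offsite12x1", ...)$results,
    thresholds = {
      tg <- threshold_search(model, "glutamate", lo = 10, hi = 22)
      tgaba <- threshold_search(model, "gaba12", lo = 4, hi = 16,
                                n_glut = as.integer(tg) - 1L)
      data.frame(family = c("glutamate", "gaba12"),
                 threshold = c(as.integer(tg), as.integer(tgaba)))
    })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    csv <- file.path(out_dir, paste0(name, ".csv"))
    num <- vapply(res, is.numeric, TRUE)
    res_out <- res
    res_out[num] <- lapply(res_out[num], signif, digits = 6)
    utils::write.csv(res_out, csv, row.names = FALSE)
    manifest <- list(command = name,
                     config_hash = fnv1a(list(model$config, model$seed)),
                     seed = model$seed,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     outputs = csv,
                     package_version =
                       as.character(utils::packageVersion("spnsim")))
    jsonlite::write_json(manifest,
                         file.path(out_dir, paste0(name, "_manifest.json")),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(res))
  }
  res
}
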