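# shared fixtures: the calibrated model is expensive, build it once per
# test run; small passive systems are built on demand

.fixtures <- new.env(parent = emptyenv())

get_model1 <- function() {
  if (is.null(.fixtures$model1))
    .fixtures$model1 <- default_model(seed = 1)
  .fixtures$model1
}

# channel table with every density zeroed: a purely passive membrane
zeroed_channel_table <- function() {
  ct <- default_channel_table()
  for (nm in names(ct$channels))
    for (rg in c("soma", "dend"))
      ct$channels[[nm]]$rules[[rg]]$gmax <- 0
  ct
}

# isopotential passive sphere with R = r_MOhm, C = c_pF
passive_sphere <- function(r_MOhm = 100, c_pF = 100, e_pas = -70) {
  r_um <- sqrt(c_pF / 0.01 / (4 * pi))
  m <- generate_morphology(morpho_params(n_primary = 0L, soma_radius = r_um))
  sys <- build_system(m, build_membrane(m, zeroed_channel_table()),
                      config = sim_config(v_rest = e_pas))
  sys$g_pas_uS[] <- 1 / r_MOhm
  sys$e_pas_mV[] <- e_pas
  sys
}

# single unbranched passive cable with a tiny (near-sealed) somatic end
passive_cable <- function(length_um = 400, g_pas_Scm2 = 1e-4, e_pas = -70) {
  p <- morpho_params(n_primary = 1L, n_levels = 1L,
                     total_dendritic_length = length_um,
                     primary_length = length_um,
                     max_path_target = length_um + 1,
                     capacitance_target_pF = 20, diam_profile = c(2, 2),
                     spine_density = 0, soma_radius = 1)
  m <- generate_morphology(p)
  sys <- build_system(m, build_membrane(m, zeroed_channel_table()),
                      config = sim_config(v_rest = e_pas))
  sys$g_pas_uS[] <- g_pas_Scm2 * sys$area_cm2 * 1e6
  sys$e_pas_mV[] <- e_pas
  sys
}

run_quarterdrop <- function(model, glut, gaba = NULL, tonic = 0,
                            nmda_on = TRUE) {
  sec <- glut$section_id[1]
  tr <- run_synaptic_protocol(model, glut = glut, gaba = gaba,
                              tonic_density = tonic, nmda_on = nmda_on,
                              record_sections = list(dend = c(sec, 0.5)))
  quarterdrop(tr, t_last_stim = attr(tr, "t_last_glut"),
              t_first_stim = min(attr(tr, "t_first_glut"),
                                 attr(tr, "t_first_gaba"), na.rm = TRUE),
              column = "dend")
}
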