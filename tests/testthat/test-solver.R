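test_that("a passive compartment obeys Ohm's law and its RC time constant", {
  sys <- passive_sphere(100, 100)  # R = 100 MOhm, C = 100 pF, tau = 10 ms
  tr <- simulate(sys, duration = 200, record = 1,
                 iclamp = data.frame(comp = 1, amp_pA = 100, t0 = 20,
                                     t1 = 200))
  dv <- unname(tr$v[nrow(tr$v), 1] + 70)
  expect_equal(dv, 10, tolerance = 0.005)          # I*R within 0.5%
  i_tau <- which.min(abs(tr$t - 30))               # one tau after onset
  expect_equal(unname(tr$v[i_tau, 1] + 70) / dv, 1 - exp(-1),
               tolerance = 0.01)

  pc <- passive_characterize(sys, step_pA = -200, step_ms = 300)
  expect_equal(pc$rmp, -70, tolerance = 1e-6)
  expect_equal(pc$input_resistance, 100, tolerance = 0.01)
  expect_equal(pc$tau_m, 10, tolerance = 0.02)
})

test_that("steady-state attenuation along a sealed passive cable matches cosh", {
  sys2 <- passive_cable(length_um = 400, g_pas_Scm2 = 1e-4)
  # diameter recovered from segment lateral area = pi * d * len
  diam <- sys2$area_cm2[2] / (pi * (sys2$comp_path[3] - sys2$comp_path[2]) *
                                1e-4) * 1e4  # um
  lambda_cm <- sqrt(diam * 1e-4 / (4 * 200 * 1e-4))
  tip <- which.max(sys2$comp_path)
  mid <- which.min(abs(sys2$comp_path - max(sys2$comp_path) / 2))
  tr <- simulate(sys2, duration = 800, record = c(tip = tip, mid = mid),
                 iclamp = data.frame(comp = tip, amp_pA = 50, t0 = 50,
                                     t1 = 800))
  vt <- unname(tr$v[nrow(tr$v), "tip"] + 70)
  vm <- unname(tr$v[nrow(tr$v), "mid"] + 70)
  l <- 400e-4
  analytic <- cosh((l / 2) / lambda_cm) / cosh(l / lambda_cm)
  expect_equal(vm / vt, analytic, tolerance = 0.02)
})

test_that("the passive system is linear: superposition of current injections", {
  sys <- passive_cable(300, 1e-4)
  tip <- which.max(sys$comp_path)
  mid <- which.min(abs(sys$comp_path - 150))
  run <- function(ic) simulate(sys, duration = 150, record = c(m = mid),
                               iclamp = ic)$v[, 1] + 70
  va <- run(data.frame(comp = tip, amp_pA = 40, t0 = 10, t1 = 150))
  vb <- run(data.frame(comp = mid, amp_pA = -25, t0 = 30, t1 = 100))
  vab <- run(data.frame(comp = c(tip, mid), amp_pA = c(40, -25),
                        t0 = c(10, 30), t1 = c(150, 100)))
  expect_lt(max(abs(vab - (va + vb))) / max(abs(va + vb)), 0.005)
})

test_that("membrane charge balance closes against the current integral", {
  sys <- passive_sphere(100, 100)
  tr <- simulate(sys, duration = 30, record = 1,
                 iclamp = data.frame(comp = 1, amp_pA = 100, t0 = 0, t1 = 30))
  v <- tr$v[, 1]
  i_net <- 0.1 - 0.01 * (v + 70)                    # nA
  q_int <- sum((head(i_net, -1) + tail(i_net, -1)) / 2 * diff(tr$t))
  q_cap <- 0.1 * (v[length(v)] - v[1])              # nF * mV = pC
  expect_equal(q_cap, q_int, tolerance = 0.005)
})

test_that("halving the time step barely changes the integrated voltages", {
  model <- get_model1()
  dend <- model$reference_dendrite
  glut <- clustered_glutamate(model, dend, 10)     # standard subthreshold run
  sys <- build_system(model$morph, model$membrane,
                      active_spines = sort(unique(glut$spine)),
                      config = model$config)
  st <- spnsim:::extend_state(sys, model$base_state)
  heads <- sys$spine_head_comp[match(glut$spine, sys$active_spines)]
  ev <- rbind(syn_events(sys, heads, glut$onset + 20, synapse_spec("AMPA")),
              syn_events(sys, heads, glut$onset + 20, synapse_spec("NMDA")))
  rec <- c(soma = soma_compartment(sys),
           dend = compartment_at(sys, dend, 0.5))
  t1 <- simulate(sys, ev, duration = 200, record = rec, init_state = st)
  t2 <- simulate(sys, ev, duration = 200, record = rec, init_state = st,
                 dt = 0.0125, record_every = 2L)
  expect_lt(max(abs(t1$v - t2$v)), 0.1)
})

test_that("system assembly counts compartments and conserves capacitance", {
  model <- get_model1()
  sys0 <- model$base_system
  segs <- segmentize(model$morph)
  expect_equal(sys0$n_comp, nrow(segs))
  # folding all ~5500 passive spines keeps whole-cell capacitance at 180 pF
  expect_equal(sum(sys0$cap_nF) * 1e3, 180, tolerance = 0.01)

  # 15 explicit spines add exactly 30 compartments
  glut <- clustered_glutamate(model, model$reference_dendrite, 15)
  sys15 <- build_system(model$morph, model$membrane,
                        active_spines = sort(unique(glut$spine)),
                        config = model$config)
  expect_equal(sys15$n_comp, nrow(segs) + 30)
  expect_equal(sum(sys15$cap_nF) * 1e3, 180, tolerance = 0.01)
  expect_error(build_system(model$morph, model$membrane,
                            active_spines = c(1L, 999999L)),
               "never placed")

  # a segment whose folded spine area equals its own area doubles its
  # capacitance: verify the folding arithmetic on a real segment
  sp <- model$morph$spines
  seg_areas <- segs$area_um2
  k <- 300  # a dendritic segment with spines
  on_k <- sum(sp$section_id == segs$section_id[k] &
                sp$path >= segs$path[k] - segs$length[k] / 2 &
                sp$path < segs$path[k] + segs$length[k] / 2)
  skip_if(on_k == 0)
  fold <- 1 + on_k * spnsim:::spine_area_um2() / seg_areas[k]
  expect_equal(sys0$cap_nF[k] * 1e3, seg_areas[k] * 0.01 * fold,
               tolerance = 0.05)
})

test_that("impedance magnitude matches the RC closed form and falls with a shunt", {
  sys <- passive_sphere(100, 100)
  z10 <- measure_impedance(sys, 1, frequency = 10)
  expect_equal(z10, 100 / sqrt(1 + (2 * pi * 10 * 0.01)^2), tolerance = 0.01)
  # DC limit: at 1 Hz the magnitude approaches the input resistance
  z1 <- measure_impedance(sys, 1, frequency = 1, n_cycles = 3,
                          transient_cycles = 1)
  expect_equal(z1, 100 / sqrt(1 + (2 * pi * 1 * 0.01)^2), tolerance = 0.015)
  expect_error(measure_impedance(sys, 1, frequency = 0), "frequency")

  # a local shunt strictly decreases |Z| at the same site
  sys_shunt <- sys
  sys_shunt$g_tonic_uS[1] <- 0.005
  z_shunt <- measure_impedance(sys_shunt, 1, frequency = 10)
  expect_lt(z_shunt, z10)
})

test_that("simulation is deterministic and divergence is reported", {
  sys <- passive_sphere()
  ev <- syn_events(sys, 1, 5, synapse_spec("AMPA"))
  t1 <- simulate(sys, ev, duration = 50, record = 1)
  t2 <- simulate(sys, ev, duration = 50, record = 1)
  expect_identical(t1$v, t2$v)
  bad <- sys
  bad$g_pas_uS[] <- -0.05   # non-physical negative conductance blows up
  expect_error(simulate(bad, duration = 80, record = 1,
                        iclamp = data.frame(comp = 1, amp_pA = 50, t0 = 0,
                                            t1 = 80)), "diverged")
})
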