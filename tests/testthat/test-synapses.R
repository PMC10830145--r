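test_that("two-state conductance is zero at onset and peaks at g_max", {
  sp <- synapse_spec("AMPA", g_max = 500, tau1 = 1, tau2 = 4)
  expect_equal(syn_conductance(sp, 0), 0)
  tp <- syn_peak_time(sp)
  expect_equal(tp, (4 / 3) * log(4), tolerance = 1e-12)  # ~1.848 ms
  expect_equal(syn_conductance(sp, tp), 0.5)             # 500 pS = 0.5 nS
  expect_lt(syn_conductance(sp, 200), 1e-6)              # decays away
  # doubling g_max doubles the waveform without changing its shape
  sp2 <- synapse_spec("AMPA", g_max = 1000, tau1 = 1, tau2 = 4)
  tt <- seq(0, 30, 0.25)
  expect_equal(syn_conductance(sp2, tt), 2 * syn_conductance(sp, tt))
  expect_error(synapse_spec("AMPA", tau1 = 4, tau2 = 1), "tau")
})

test_that("synapse defaults carry the dSPN conductances and reversals", {
  expect_equal(synapse_spec("AMPA")$g_max, 350)
  expect_equal(synapse_spec("NMDA")$g_max, 752.5)
  expect_equal(synapse_spec("AMPA")$e_rev, 0)
  expect_equal(synapse_spec("NMDA")$e_rev, 0)
  gaba <- synapse_spec("GABAA")
  expect_equal(gaba$g_max, 1000)
  expect_equal(gaba$e_rev, -60)
  expect_true(synapse_spec("NMDA")$mg_block)
})

test_that("magnesium unblock is monotone, saturating, and 0.781 at 0 mV", {
  expect_equal(mg_unblock(0), 1 / (1 + 1 / 3.57), tolerance = 1e-12)
  expect_gt(mg_unblock(100), 0.99)
  expect_lt(mg_unblock(-80), mg_unblock(-40))
  v <- seq(-120, 60, 1)
  expect_true(all(diff(mg_unblock(v)) > 0))
  expect_true(all(mg_unblock(v) >= 0 & mg_unblock(v) <= 1))
})

test_that("synaptic current reverses sign exactly at the reversal potential", {
  # GABA-A is depolarizing below -60 mV and hyperpolarizing above it
  for (v0 in c(-84, -70)) {
    sys <- passive_sphere(100, 100, e_pas = v0)
    ev <- syn_events(sys, 1, 10, synapse_spec("GABAA"))
    tr <- simulate(sys, ev, duration = 60, record = 1)
    expect_gt(max(tr$v[, 1]), v0 + 0.01)   # depolarizing
    expect_gt(min(tr$v[, 1]), v0 - 1e-6)
  }
  sys <- passive_sphere(100, 100, e_pas = -40)
  ev <- syn_events(sys, 1, 10, synapse_spec("GABAA"))
  tr <- simulate(sys, ev, duration = 60, record = 1)
  expect_lt(min(tr$v[, 1]), -40 - 0.01)    # hyperpolarizing above -60
  expect_lt(max(tr$v[, 1]), -40 + 1e-6)
})

test_that("an NMDA event with zero conductance leaves the trace untouched", {
  sys <- passive_sphere()
  ev <- syn_events(sys, 1, 10, synapse_spec("NMDA", g_max = 0))
  tr0 <- simulate(sys, duration = 60, record = 1)
  tr1 <- simulate(sys, ev, duration = 60, record = 1)
  expect_equal(tr1$v, tr0$v)
})

test_that("tonic GABA is set idempotently and shifts rest monotonically", {
  sys <- passive_sphere(100, 100, e_pas = -80)
  s0 <- apply_tonic(sys, tonic_gaba(0))
  tr <- simulate(s0, duration = 100, record = 1)
  expect_equal(unname(tr$v[nrow(tr$v), 1]), -80, tolerance = 1e-6)

  # setting twice equals setting once (no accumulation)
  s1 <- apply_tonic(apply_tonic(sys, tonic_gaba(1e-4)), tonic_gaba(1e-4))
  s2 <- apply_tonic(sys, tonic_gaba(1e-4))
  expect_identical(s1$g_tonic_uS, s2$g_tonic_uS)

  rests <- vapply(c(1e-5, 1e-4, 1e-3, 1e-2), function(d) {
    s <- apply_tonic(sys, tonic_gaba(d))
    tr <- simulate(s, duration = 300, record = 1)
    unname(tr$v[nrow(tr$v), 1])
  }, 0)
  expect_true(all(diff(rests) > 0))        # strictly increasing with density
  expect_lt(abs(rests[4] - (-60)), 1)      # large density pins rest at E_GABA
  expect_error(tonic_gaba(-1), "negative")
})
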