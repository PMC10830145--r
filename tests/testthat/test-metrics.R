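test_that("quarterdrop recovers its closed forms on synthetic waveforms", {
  # instantaneous rise then exponential decay: tau * log(4/3)
  tr <- gen_reference_traces("exponential_psp", peak = 5, tau = 50,
                             t_on = 50)
  qd <- quarterdrop(tr, t_last_stim = 50)
  expect_equal(as.numeric(qd), 50 * log(4 / 3), tolerance = 0.005)

  # linear decay at rate r from the peak: 0.25 * P / r
  t <- seq(0, 400, 0.025)
  P <- 8; r <- 0.05
  v <- -84 + ifelse(t < 100, 0, pmax(0, P - r * (t - 100)))
  qd2 <- quarterdrop(list(t = t, v = v), t_last_stim = 100)
  expect_equal(as.numeric(qd2), 0.25 * P / r, tolerance = 0.005)

  # invariant to adding a constant to the whole trace
  qd3 <- quarterdrop(list(t = t, v = v + 17.3), t_last_stim = 100)
  expect_equal(as.numeric(qd3), as.numeric(qd2))

  # never dropping within the trace is flagged unresolved
  v4 <- -84 + ifelse(t < 100, 0, 5)
  qd4 <- quarterdrop(list(t = t, v = v4), t_last_stim = 100)
  expect_true(is.na(qd4))
  expect_true(attr(qd4, "unresolved"))
  expect_error(quarterdrop(list(t = t, v = v), t_last_stim = 500), "ends")
})

test_that("spike classification applies the quarterdrop cutoff", {
  expect_false(classify_spike(5))
  expect_true(classify_spike(120))
  expect_identical(classify_spike(c(10, 45, NA), cutoff_ms = 40),
                   c(FALSE, TRUE, FALSE))
  tr <- gen_reference_traces("plateau", peak = 20, duration = 150, t_on = 50)
  expect_true(classify_spike(quarterdrop(tr, t_last_stim = 50)))
})

test_that("P-measures reduce correctly in degenerate and additive cases", {
  base <- -84
  t <- seq(0, 500, 0.025)
  psp <- function(amp, on, tau) ifelse(t < on, 0, amp * exp(-(t - on) / tau))
  glut <- list(t = t, v = base + psp(5, 100, 40))
  flat <- list(t = t, v = rep(base, length(t)))

  # GABA identically at baseline: P2 = P3 and ratios equal 1 when the
  # combined response is the glutamate response
  pm <- p_measures(glut, flat, glut, window = c(50, 500))
  expect_equal(pm$p2, pm$p3)
  expect_equal(pm$ratio_p3_p1, 1)

  # exactly additive traces are scored linear: P2/P1 = 1 where the
  # glutamate peak dominates
  gaba <- list(t = t, v = base + psp(2, 20, 8))
  comb <- list(t = t, v = glut$v + gaba$v - base)
  pm2 <- p_measures(glut, gaba, comb, window = c(10, 500))
  expect_equal(pm2$ratio_p2_p1, 1, tolerance = 1e-6)

  # misaligned time bases are rejected
  short <- list(t = t[-1], v = glut$v[-1])
  expect_error(p_measures(short, gaba, comb), "time base")
})

test_that("P3 exceeds P2 whenever the underlying GABA potential is depolarizing", {
  base <- -84
  t <- seq(0, 500, 0.025)
  psp <- function(amp, on, tau) ifelse(t < on, 0, amp * exp(-(t - on) / tau))
  glut <- list(t = t, v = base + psp(5, 100, 40))
  for (dt_g in c(60, 90, 105)) {
    gaba <- list(t = t, v = base + psp(3, dt_g, 30))
    comb <- list(t = t, v = glut$v + gaba$v - base)
    pm <- p_measures(glut, gaba, comb, window = c(50, 500))
    expect_gte(pm$p3, pm$p2)
  }
})

test_that("linearity scatter classifies ratios around unity", {
  out <- linearity_scatter(c(4, 4, 4), c(4, 6, 3.5))
  expect_identical(out$classification, c("linear", "supralinear", "sublinear"))
  expect_equal(out$ratio, c(1, 1.5, 0.875))
  expect_error(linearity_scatter(c(0, 1), c(1, 1)), "zero")

  pair <- gen_reference_traces("additive_pair")
  amp <- function(x) max(x$v) - x$v[1]
  out2 <- linearity_scatter(amp(pair$first) + amp(pair$second),
                            amp(pair$combined))
  expect_identical(out2$classification, "linear")
})
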