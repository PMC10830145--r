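test_that("spatial density rules evaluate their closed forms", {
  uni <- list(kind = "uniform", gmax = 0.3)
  expect_equal(eval_distribution(uni, c(0, 50, 300)), rep(0.3, 3))

  sig <- list(kind = "sigmoidal", a4 = 0.2, a5 = 0.8, a6 = 60, a7 = 10,
              gmax = 0.5)
  # at x = a6 the sigmoid is at half: (a4 + a5/2) * gmax
  expect_equal(eval_distribution(sig, 60), (0.2 + 0.4) * 0.5)
  # a7 > 0 with a5 > 0 decreases monotonically in x
  g <- eval_distribution(sig, seq(0, 300, 5))
  expect_true(all(diff(g) < 0))

  ex <- list(kind = "exponential", a4 = 0.7, a5 = 0, a6 = 10, a7 = 30,
             gmax = 2)
  expect_equal(eval_distribution(ex, c(0, 100, 250)), rep(1.4, 3))

  expect_error(eval_distribution(list(kind = "sigmoidal", a4 = 1, a5 = 1,
                                      a6 = 0, a7 = 0, gmax = 1), 10), "a7")
})

test_that("the default channel table covers all 14 somatodendritic channels", {
  ct <- default_channel_table()
  expect_setequal(names(ct$channels),
                  c("naf", "nap", "kaf", "kas", "kir", "kdr", "sk", "bk",
                    "cav12", "cav13", "cav22", "cav23", "cav32", "cav33"))
  mm <- build_membrane(get_model1()$morph, ct)
  expect_true(all(mm$density >= 0))
  # the inward rectifier is present on soma and dendrites
  expect_true(all(mm$density[, "kir"] > 0))
  # calcium channels are flagged for GHK permeability
  expect_true(ct$channels$cav13$ghk)
  expect_false(ct$channels$kir$ghk)
})

test_that("membrane map assigns each segment the rule value at its path distance", {
  m <- get_model1()$morph
  ct <- default_channel_table()
  mm <- build_membrane(m, ct)
  segs <- mm$segments
  i <- which(segs$kind == "dendrite")[c(1, 100, 400)]
  expect_equal(mm$density[i, "kaf"],
               eval_distribution(ct$channels$kaf$rules$dend, segs$path[i]))
  # uniform-only table gives identical densities everywhere
  mm0 <- build_membrane(m, zeroed_channel_table())
  expect_true(all(mm0$density == 0))
  # a missing regional rule is an error
  ct2 <- ct
  ct2$channels$kir$rules$dend <- NULL
  expect_error(build_membrane(m, ct2), "kir")
})

test_that("gates relax exponentially to steady state and stay in [0,1]", {
  ct <- default_channel_table()
  kir <- ct$channels$kir
  st <- advance_gates(kir, state = NULL, v = -120)  # starts near 1
  expect_gt(st["m"], 0.8)
  # relax at fixed depolarized voltage toward a small steady state
  tau <- gate_curves(kir$gates[[1]], -40)$tau
  inf <- gate_curves(kir$gates[[1]], -40)$inf
  x <- st
  for (k in 1:100) x <- advance_gates(kir, x, v = -40, dt = tau / 4)
  expect_equal(unname(x["m"]), inf, tolerance = 1e-6)
  # any voltage trajectory keeps every gate in [0, 1]
  for (ch in ct$channels) {
    st <- advance_gates(ch, state = NULL, v = -84)
    for (v in c(-100, 30, -80, 0, -120, 50)) {
      st <- advance_gates(ch, st, v = v, ca = 1e-3, dt = 0.5)
      expect_true(all(st >= 0 & st <= 1))
    }
  }
})

test_that("gate updates under a time-varying voltage converge at first order", {
  ct <- default_channel_table()
  naf <- ct$channels$naf
  vpath <- function(t) -80 + 60 * sin(t / 5)
  run <- function(dt) {
    x <- advance_gates(naf, state = NULL, v = vpath(0))
    for (t in seq(dt, 20, by = dt)) x <- advance_gates(naf, x, vpath(t), dt = dt)
    x
  }
  x1 <- run(0.2); x2 <- run(0.1); x4 <- run(0.05)
  e1 <- max(abs(x1 - x4)); e2 <- max(abs(x2 - x4))
  expect_lt(e2, e1)           # halving dt reduces the error
  expect_gt(e1 / e2, 1.5)     # roughly first-order
})

test_that("SK is mostly closed at resting calcium", {
  ct <- default_channel_table()
  st <- advance_gates(ct$channels$sk, state = NULL, v = -84,
                      ca = ct$calcium$rest_mM)
  expect_lt(st["z"], 0.5)     # below half-activation at rest
  st_hi <- advance_gates(ct$channels$sk, state = NULL, v = -84, ca = 0.01)
  expect_gt(st_hi["z"], 0.9)
})
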