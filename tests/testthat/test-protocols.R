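test_that("clustered glutamate builds ordered events moving away from the soma", {
  model <- get_model1()
  dend <- model$reference_dendrite
  ev <- clustered_glutamate(model, dend, 18)
  expect_equal(nrow(ev), 18)
  expect_equal(diff(ev$onset), rep(1, 17))          # exactly 1 ms spacing
  expect_true(all(diff(ev$path) > 0))               # moving distally
  # the cluster starts at about two-thirds of the section
  s <- model$morph$sections
  j <- match(dend, s$id)
  expect_gte((ev$path[1] - s$path0[j]) / s$length[j], 2 / 3)

  expect_equal(nrow(clustered_glutamate(model, dend, 0)), 0)
  expect_error(clustered_glutamate(model, dend, 500), "spines")
  # builders are pure: identical arguments give identical event lists
  expect_identical(ev, clustered_glutamate(model, dend, 18))
})

test_that("phasic GABA patterns produce the printed synapse counts", {
  model <- get_model1()
  dend <- model$reference_dendrite

  on <- phasic_gaba(model, "onsite", glut_dendrite = dend)
  expect_equal(nrow(on), 12)                        # 3 x 4 at one site
  expect_equal(unique(on$section_id), dend)
  expect_equal(sort(unique(on$onset)), 0:3)
  expect_equal(as.numeric(table(on$onset)), rep(3, 4))

  off <- phasic_gaba(model, "offsite4x3", glut_dendrite = dend)
  expect_equal(nrow(off), 12)                       # 4 dendrites x burst of 3
  expect_equal(length(unique(off$section_id)), 4)
  expect_false(dend %in% off$section_id)

  o12 <- phasic_gaba(model, "offsite12x1", glut_dendrite = dend)
  expect_equal(nrow(o12), 12)                       # one per dendrite
  expect_equal(length(unique(o12$section_id)), 12)
  expect_equal(unique(o12$onset), 0)
  expect_false(dend %in% o12$section_id)

  expect_equal(nrow(phasic_gaba(model, "onsite", glut_dendrite = dend,
                                group_size = 0)), 0)
  expect_equal(nrow(phasic_gaba(model, "none")), 0)

  # on-path proximal mode targets the parent section
  onp <- phasic_gaba(model, "onpath_proximal", glut_dendrite = dend)
  s <- model$morph$sections
  expect_equal(unique(onp$section_id), s$parent_id[match(dend, s$id)])
})

test_that("off-site selection avoids the stimulated dendrite's entire path", {
  model <- get_model1()
  dend <- model$reference_dendrite
  s <- model$morph$sections
  ancestors <- integer(0); i <- dend
  repeat {
    p <- s$parent_id[match(i, s$id)]
    if (s$kind[match(p, s$id)] == "soma") break
    ancestors <- c(ancestors, p); i <- p
  }
  off <- phasic_gaba(model, "offsite4x3", glut_dendrite = dend)
  expect_false(any(off$section_id %in% c(dend, ancestors)))
})

test_that("timing sweep returns one summation row per offset plus references", {
  model <- get_model1()
  dend <- model$reference_dendrite
  sw <- timing_sweep(model, dend, n_glut = 5, gaba_mode = "onsite",
                     delta_t_values = c(-10, 0, 10), duration_post = 150)
  expect_equal(nrow(sw$results), 3)
  expect_equal(sw$results$delta_t, c(-10, 0, 10))
  expect_named(sw$reference, c("glut", "gaba"))
  expect_true(all(is.finite(sw$results$ratio_p2_p1)))
  expect_true(all(sw$results$p1 > 0))
})

test_that("the run manifest records command, seed, hash and outputs", {
  model <- get_model1()
  out <- tempfile()
  res <- run_experiment("s4_nmda_ko", model = model, out_dir = out)
  expect_false(res$spike)
  man <- jsonlite::read_json(file.path(out, "s4_nmda_ko_manifest.json"))
  expect_equal(man$command, "s4_nmda_ko")
  expect_equal(man$seed, 1)
  expect_match(man$config_hash, "^[0-9a-f]{8}$")
  expect_true(file.exists(man$outputs))
  expect_error(run_experiment("not_an_experiment"), "valid names")
})
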