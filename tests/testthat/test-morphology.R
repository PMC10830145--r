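test_that("path distance is zero at the soma centre and additive along the tree", {
  m <- get_model1()$morph
  expect_equal(path_distance(m, 1, 0), 0)
  expect_equal(path_distance(m, 1, 1), 6.010)

  # additivity: a terminal section's midpoint equals the sum of ancestor
  # lengths plus the soma radius plus half its own length
  s <- m$sections
  term <- s$id[s$kind == "dendrite" & !(s$id %in% s$parent_id)][1]
  acc <- 0; i <- term
  repeat {
    j <- match(i, s$id)
    p <- s$parent_id[j]
    if (s$kind[match(p, s$id)] == "soma") break
    acc <- acc + s$length[match(p, s$id)]
    i <- p
  }
  expect_equal(path_distance(m, term, 0.5),
               6.010 + acc + 0.5 * s$length[match(term, s$id)])
  expect_error(path_distance(m, 99999L), "unknown section")
})

test_that("a chain of known section lengths accumulates path distance through SWC", {
  # soma radius 6.010 with a straight 50 + 80 + 40 um chain
  swc <- c("1 1 0 0 0 6.010 -1",
           "2 3 0 0 0 1.0 1", "3 3 50 0 0 0.9 2",
           "4 3 50 0 0 0.9 3", "5 3 130 0 0 0.8 4",
           "6 3 130 0 0 0.8 5", "7 3 170 0 0 0.7 6")
  f <- tempfile(fileext = ".swc")
  writeLines(swc, f)
  m <- read_swc(f)
  # unbranched samples merge into a single cable section of summed length
  expect_equal(nrow(m$sections), 2L)
  last <- m$sections$id[nrow(m$sections)]
  expect_equal(path_distance(m, last, 1.0), 6.010 + 50 + 80 + 40)
})

test_that("generated morphology hits the calibration targets", {
  m <- get_model1()$morph
  p <- m$params
  expect_lt(abs(max_path_distance(m) - p$max_path_target) /
              p$max_path_target, 0.02)
  expect_lt(abs(total_capacitance_pF(m) - 180) / 180, 0.05)
  # enough spiny terminal sections for the clustered-input protocols
  expect_gte(nrow(target_dendrites(get_model1(), n_required = 18)), 50)
  # ~700 dendritic segments
  segs <- segmentize(m)
  expect_gt(sum(segs$kind == "dendrite"), 550)
  expect_lt(sum(segs$kind == "dendrite"), 850)
})

test_that("zero-dendrite morphology is a bare sphere with exact capacitance", {
  m <- generate_morphology(morpho_params(n_primary = 0L, soma_radius = 10))
  expect_equal(nrow(m$sections), 1L)
  expect_equal(total_capacitance_pF(m), 4 * pi * 100 * 0.01)
})

test_that("morphology generation is seed-deterministic and seed-sensitive", {
  m1 <- generate_morphology(morpho_params(seed = 7))
  m2 <- generate_morphology(morpho_params(seed = 7))
  m3 <- generate_morphology(morpho_params(seed = 8))
  expect_identical(m1$sections, m2$sections)
  expect_identical(m1$spines, m2$spines)
  expect_false(isTRUE(all.equal(m1$sections$length, m3$sections$length)))
  # different seed, same calibration surface
  expect_lt(abs(total_capacitance_pF(m3) - 180) / 180, 0.05)
  expect_lt(abs(max_path_distance(m3) - 265.268) / 265.268, 0.02)
})

test_that("infeasible generator parameters are rejected with the constraint", {
  expect_error(generate_morphology(morpho_params(max_path_target = 20)),
               "max_path_target")
  expect_error(generate_morphology(
    morpho_params(total_dendritic_length = 50)), "total_dendritic_length")
  expect_error(generate_morphology(
    morpho_params(capacitance_target_pF = 30)), "capacitance_target_pF")
})

test_that("spine placement follows the floor(eligible length x density) rule", {
  # exactly 100 um of eligible dendrite at 1.711/um -> 171 spines
  p <- morpho_params(n_primary = 1L, n_levels = 1L,
                     total_dendritic_length = 123.99,
                     primary_length = 123.99, max_path_target = 130,
                     capacitance_target_pF = 10, diam_profile = c(1, 1),
                     spine_density = 1.711, soma_radius = 6.01)
  m <- generate_morphology(p)
  expect_equal(nrow(m$spines), 171L)
  expect_true(all(m$spines$path >= 30))

  # a dendrite entirely within the 30 um floor carries no spines
  expect_equal(nrow(place_spines(generate_morphology(
    morpho_params(n_primary = 1L, n_levels = 1L,
                  total_dendritic_length = 20, primary_length = 20,
                  max_path_target = 27, capacitance_target_pF = 6,
                  diam_profile = c(1, 1), spine_density = 1.711)))), 0L)

  # doubling density doubles the count (up to rounding carry)
  n1 <- nrow(place_spines(m, 1.711, 30))
  n2 <- nrow(place_spines(m, 3.422, 30))
  expect_lte(abs(n2 - 2 * n1), 1)
  expect_error(place_spines(m, -1, 30), "density")
})

test_that("SWC round trip preserves topology, lengths and radii", {
  m <- get_model1()$morph
  f <- tempfile(fileext = ".swc")
  write_swc(m, f)
  m2 <- read_swc(f)
  expect_equal(nrow(m2$sections), nrow(m$sections))
  ord <- order(m$sections$length)
  ord2 <- order(m2$sections$length)
  expect_equal(m2$sections$length[ord2], m$sections$length[ord],
               tolerance = 1e-5)
  expect_equal(sort(m2$sections$diam_prox), sort(m$sections$diam_prox),
               tolerance = 1e-5)
  expect_equal(max_path_distance(m2), max_path_distance(m), tolerance = 1e-5)
  # spine sidecar travels along
  expect_equal(nrow(m2$spines), nrow(m$spines))

  # single-soma file
  f2 <- tempfile(fileext = ".swc")
  writeLines("1 1 0 0 0 5.0 -1", f2)
  expect_equal(nrow(read_swc(f2)$sections), 1L)
})

test_that("malformed SWC input is rejected with its line number", {
  f <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5.0 -1", "2 3 10 0 0"), f)
  expect_error(read_swc(f), "line 2")
  writeLines(c("1 1 0 0 0 5.0 -1", "2 3 10 0 0 1.0 9"), f)
  expect_error(read_swc(f), "orphan parent")
})
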