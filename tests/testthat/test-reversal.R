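test_that("preprocessing applies junction correction, binning and rounding", {
  s <- data.frame(holding_mV = c(-58.7, -50, -71.2), response = c(1.23, 0.75,
                                                                  -0.75))
  out <- preprocess_ephys(s)
  expect_equal(out$holding_mV, c(-60, -50, -70))
  # 0.5-unit rounding, ties away from zero
  expect_equal(out$response, c(1.0, 1.0, -1.0))

  # junction offset shifts before binning: raw -50 with -10 offset -> -60
  out2 <- preprocess_ephys(data.frame(holding_mV = -50, response = 0),
                           junction_offset_mV = -10)
  expect_equal(out2$holding_mV, -60)
  expect_error(preprocess_ephys(data.frame(holding_mV = -30, response = 0)),
               "outside")
})

test_that("reversal regression on per-voltage means recovers exact lines", {
  s <- data.frame(holding_mV = c(-70, -60, -50), response = c(-10, 0, 10))
  fit <- estimate_reversal(s)
  expect_equal(fit$slope, 1)
  expect_equal(fit$x_intercept, -60)
  expect_equal(fit$r_squared, 1)

  # the regression runs on per-potential means, not raw samples
  s2 <- rbind(s, data.frame(holding_mV = c(-70, -50), response = c(-12, 12)))
  fit2 <- estimate_reversal(s2)
  expect_equal(fit2$x_intercept, -60, tolerance = 1e-9)

  # equivariance: shifting all potentials by c shifts the intercept by c
  s3 <- s; s3$holding_mV <- s3$holding_mV + 7
  expect_equal(estimate_reversal(s3)$x_intercept, -53, tolerance = 1e-9)

  expect_error(estimate_reversal(data.frame(holding_mV = -60,
                                            response = 1:3)), "distinct")
  expect_error(estimate_reversal(data.frame(holding_mV = c(-70, -50),
                                            response = c(2, 2))), "slope")
})

test_that("exact signed-rank p-values match closed forms for one-signed pairs", {
  # six positive differences: p = 2/2^6
  out6 <- wilcoxon_signed_rank_exact(differences = c(1, 2, 3, 4, 5, 6))
  expect_equal(out6$p_value, 0.03125)
  expect_equal(out6$n, 6)
  # five: p = 2/2^5
  out5 <- wilcoxon_signed_rank_exact(differences = -c(1.5, 2, 0.3, 4, 1))
  expect_equal(out5$p_value, 0.0625)
  # a perfectly antisymmetric pattern sits at the distribution centre
  out0 <- wilcoxon_signed_rank_exact(differences = c(1, -1.5, 2, -2.5, 3,
                                                     -3.5, 4, -4.5))
  expect_gt(out0$p_value, 0.8)
  # zero differences are dropped before ranking
  outz <- wilcoxon_signed_rank_exact(before = c(1, 2, 3, 4, 5, 6, 7),
                                     after = c(2, 3, 4, 5, 6, 7, 7))
  expect_equal(outz$n, 6)
  expect_equal(outz$p_value, 0.03125)
  expect_error(wilcoxon_signed_rank_exact(differences = c(0, 0)), "zero")
})

test_that("enumeration agrees with the reference implementation for n <= 10", {
  set.seed(42)
  for (n in c(4, 5, 7, 10)) {
    for (rep in 1:5) {
      d <- round(rnorm(n), 2)
      d <- d[d != 0]
      if (length(d) < 3 || any(duplicated(abs(d)))) next
      mine <- wilcoxon_signed_rank_exact(differences = d)$p_value
      ref <- stats::wilcox.test(d, exact = TRUE)$p.value
      expect_equal(mine, ref, tolerance = 1e-12)
    }
  }
})
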