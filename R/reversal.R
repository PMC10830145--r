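# Reversal-potential estimation from tabulated recordings, with the
# rounding/binning conventions of perforated-patch analysis, plus the
# exact small-sample Wilcoxon signed-rank test.

#' Preprocess holding-potential / response samples
#'
#' Holding potentials are corrected for the liquid junction potential and
#' snapped to the nearest 5 mV bin centre; responses are rounded
#' half-away-from-zero to the measurement unit (0.5 pA for currents,
#' 0.5 mV for potential changes).
#'
#' @param samples data frame with columns `holding_mV` and `response`
#'   (extra columns pass through).
#' @param junction_offset_mV added to the holding potentials.
#' @param rounding_unit response rounding unit.
#' @param bin_centers mV bin centres (5 mV increments).
#' @param max_bin_distance samples further than this from every bin centre
#'   are an error.
#' @return the data frame with `holding_mV` binned and `response` rounded.
#' @export
preprocess_ephys <- function(samples, junction_offset_mV = 0,
                             rounding_unit = 0.5,
                             bin_centers = seq(-70, -50, by = 5),
                             max_bin_distance = 2.5) {
  stopifnot(rounding_unit > 0)
  v <- samples$holding_mV + junction_offset_mV
  d <- abs(outer(v, bin_centers, "-"))
  nearest <- apply(d, 1, which.min)
  if (any(apply(d, 1, min) > max_bin_distance + 1e-9))
    stop("sample outside all bins after junction correction")
  samples$holding_mV <- bin_centers[nearest]
  samples$response <- round_half_away(samples$response, rounding_unit)
  samples
}

# round to the nearest unit, ties away from zero (0.75 -> 1.0, -0.75 -> -1.0)
round_half_away <- function(x, unit) {
  sign(x) * floor(abs(x) / unit + 0.5) * unit
}

#' Estimate a reversal potential by regression on per-voltage means
#'
#' Ordinary least squares of the mean response at each distinct holding
#' potential against the potential; the reversal potential is the
#' x-intercept and R^2 is computed on the per-potential means.
#'
#' @param samples data frame with `holding_mV` and `response` (typically
#'   from [preprocess_ephys()]).
#' @return list of class `reversal_fit`: `slope`, `intercept`,
#'   `x_intercept` (mV), `r_squared`, `means` (the regression points).
#' @export
estimate_reversal <- function(samples) {
  v <- sort(unique(samples$holding_mV))
  if (length(v) < 2)
    stop("need >= 2 distinct holding potentials for a reversal fit")
  m <- vapply(v, function(vi)
    mean(samples$response[samples$holding_mV == vi]), 0)
  fit <- stats::lm(m ~ v)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (abs(slope) < .Machine$double.eps^0.5)
    stop("zero slope: x-intercept undefined")
  r2 <- 1 - sum(residuals(fit)^2) / sum((m - mean(m))^2)
  structure(list(slope = slope, intercept = intercept,
                 x_intercept = -intercept / slope, r_squared = r2,
                 means = data.frame(holding_mV = v, mean_response = m)),
            class = "reversal_fit")
}

#' @export
print.reversal_fit <- function(x, ...) {
  cat(sprintf("reversal fit: slope %.3f, x-intercept %.2f mV, R^2 %.3f\n",
              x$slope, x$x_intercept, x$r_squared))
  invisible(x)
}

#' Exact two-sided Wilcoxon signed-rank test
#'
#' Enumerates all 2^n sign assignments of the ranked absolute differences
#' (zero differences dropped, ties mid-ranked) and returns the exact
#' two-sided p-value for the observed positive-rank sum: twice the smaller
#' tail, capped at 1.
#'
#' @param before,after paired samples (or give `differences` directly).
#' @param differences optional paired differences, overriding before/after.
#' @param max_n enumeration guard.
#' @return list with `p_value`, `statistic` (W+), `n` (non-zero pairs).
#' @export
wilcoxon_signed_rank_exact <- function(before = NULL, after = NULL,
                                       differences = NULL, max_n = 25L) {
  d <- if (!is.null(differences)) differences else after - before
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero")
  if (n > max_n) stop("n too large for exact enumeration (", n, " > ",
                      max_n, ")")
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])

  # distribution of W+ over all 2^n sign assignments
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_low <- mean(w_all <= w_obs + 1e-9)
  p_high <- mean(w_all >= w_obs - 1e-9)
  p <- min(1, 2 * min(p_low, p_high))
  list(p_value = p, statistic = w_obs, n = n)
}
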