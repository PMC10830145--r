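# Trace measurements: quarterdrop duration, dendritic-spike classification,
# P1/P2/P3 summation measures, and the linearity scatter.

# pull one column of an spn_traces object (or accept a plain data frame
# with columns t and v)
trace_tv <- function(trace, column = 1) {
  if (inherits(trace, "spn_traces"))
    list(t = trace$t, v = trace$v[, column])
  else list(t = trace$t, v = trace$v)
}

#' Quarterdrop duration of a response
#'
#' The time from the last stimulation until the membrane potential has
#' dropped by one quarter of its peak amplitude: peak amplitude is
#' `max(V) - baseline` over `t >= t_first_stim`, and the quarterdrop is the
#' first time after `t_last_stim` at which `V <= baseline + 0.75 * peak
#' amplitude`, minus `t_last_stim`.  This is the plateau/spike duration
#' index used throughout the dendritic-integration analysis.
#'
#' @param trace an `spn_traces` (first column used) or list/data frame with
#'   `t` and `v`.
#' @param t_last_stim ms.
#' @param t_first_stim ms; defaults to `t_last_stim`.
#' @param baseline mV; defaults to the mean voltage before the first
#'   stimulus (or the first sample when nothing precedes it).
#' @param window_ms peak search window after the last stimulus.
#' @param column trace column.
#' @return quarterdrop in ms, or `NA` with attribute `unresolved = TRUE` if
#'   the voltage never reaches the three-quarter level within the trace.
#' @export
quarterdrop <- function(trace, t_last_stim, t_first_stim = t_last_stim,
                        baseline = NULL, window_ms = 500, column = 1) {
  tv <- trace_tv(trace, column)
  t <- tv$t; v <- tv$v
  if (max(t) <= t_last_stim) stop("trace ends before the last stimulus")
  if (is.null(baseline)) {
    pre <- t < t_first_stim
    baseline <- if (any(pre)) mean(v[pre]) else v[1]
  }
  sel <- t >= t_first_stim & t <= t_last_stim + window_ms
  peak <- max(v[sel]) - baseline
  if (peak <= 0) return(structure(NA_real_, unresolved = TRUE))
  level <- baseline + 0.75 * peak
  # the drop is sought after the peak (late regenerative responses peak
  # well after the last stimulus), but timed from the last stimulus
  t_peak <- t[sel][which.max(v[sel])]
  after <- which(t > max(t_last_stim, t_peak) & v <= level)
  if (!length(after)) return(structure(NA_real_, unresolved = TRUE))
  t[after[1]] - t_last_stim
}

#' Classify a response as a dendritic spike
#'
#' Plateau potentials separate from ordinary EPSPs as a bimodal
#' quarterdrop distribution; responses at or above the cutoff (default
#' 40 ms, sitting in the empirical gap) count as dendritic spikes.
#'
#' @param quarterdrop_ms quarterdrop duration(s), ms.
#' @param cutoff_ms classification cutoff.
#' @return logical.
#' @export
classify_spike <- function(quarterdrop_ms, cutoff_ms = 40)
  !is.na(quarterdrop_ms) & quarterdrop_ms >= cutoff_ms

#' P1/P2/P3 summation measures
#'
#' `P1` is the peak of the glutamate-alone response over baseline.  With
#' `t*` the time of the combined response's peak, `P3 = combined(t*) -
#' baseline` (amplitude over baseline) and `P2 = combined(t*) -
#' gaba_alone(t*)` (amplitude over the underlying GABAergic potential).
#' Ratios `P2/P1` and `P3/P1` quantify shunting (`< 1`) versus summation
#' (`>= 1`).
#'
#' @param glut_alone,gaba_alone,combined traces on a common time base
#'   (`spn_traces` or lists with `t`, `v`).
#' @param baseline mV; defaults to the pre-window mean of the combined
#'   trace.
#' @param window time window (ms, length 2) searched for peaks; defaults to
#'   the whole trace.
#' @param column trace column.
#' @param delta_t optional timing offset annotation (ms).
#' @return data frame of class `summation_result` with `delta_t`, `p1`,
#'   `p2`, `p3`, `ratio_p2_p1`, `ratio_p3_p1`.
#' @export
p_measures <- function(glut_alone, gaba_alone, combined, baseline = NULL,
                       window = NULL, column = 1, delta_t = NA_real_) {
  g <- trace_tv(glut_alone, column)
  b <- trace_tv(gaba_alone, column)
  m <- trace_tv(combined, column)
  if (length(g$t) != length(m$t) || max(abs(g$t - m$t)) > 1e-9 ||
      length(b$t) != length(m$t) || max(abs(b$t - m$t)) > 1e-9)
    stop("traces are on different time bases")
  if (is.null(window)) window <- range(m$t)
  sel <- m$t >= window[1] & m$t <= window[2]
  if (is.null(baseline)) {
    pre <- m$t < window[1]
    baseline <- if (any(pre)) mean(m$v[pre]) else m$v[1]
  }
  p1 <- max(g$v[sel]) - baseline
  istar <- which(sel)[which.max(m$v[sel])]
  p3 <- m$v[istar] - baseline
  p2 <- m$v[istar] - b$v[istar]
  out <- data.frame(delta_t = delta_t, p1 = p1, p2 = p2, p3 = p3,
                    ratio_p2_p1 = p2 / p1, ratio_p3_p1 = p3 / p1,
                    t_peak = m$t[istar])
  class(out) <- c("summation_result", "data.frame")
  out
}

#' Linearity scatter of combined versus summed responses
#'
#' For each pair, the ratio of the combined-response amplitude to the
#' arithmetic sum of the individual amplitudes classifies the interaction
#' as sublinear, linear or supralinear within a tolerance band around 1.
#'
#' @param arithmetic_sum,combined amplitudes from a common baseline (mV).
#' @param tolerance half-width of the "linear" band on the ratio.
#' @return data frame with `arithmetic_sum`, `combined`, `ratio`,
#'   `classification`.
#' @export
linearity_scatter <- function(arithmetic_sum, combined, tolerance = 0.05) {
  stopifnot(length(arithmetic_sum) == length(combined))
  if (any(arithmetic_sum == 0)) stop("zero arithmetic sum")
  ratio <- combined / arithmetic_sum
  cls <- ifelse(ratio > 1 + tolerance, "supralinear",
                ifelse(ratio < 1 - tolerance, "sublinear", "linear"))
  data.frame(arithmetic_sum = arithmetic_sum, combined = combined,
             ratio = ratio, classification = cls)
}
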