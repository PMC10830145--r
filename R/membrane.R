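# Ion-channel specifications: spatial density rules, gating schemes, and
# assembly of per-segment conductance maps.

#' Evaluate a spatial channel-density rule
#'
#' Density rules follow the striatal projection-neuron model conventions:
#' `sigmoidal` gives `(a4 + a5/(1 + exp((x - a6)/a7))) * gmax`,
#' `exponential` gives `(a4 + a5*exp((x - a6)/a7)) * gmax`, and `uniform`
#' gives `gmax`, with `x` the path distance (um) from the soma centre.
#'
#' @param rule list with `kind` and, for non-uniform kinds, `a4`..`a7`,
#'   plus `gmax` (S/cm2, or cm/s for calcium permeabilities).
#' @param x path distance(s), um.
#' @return density at `x`, same units as `gmax`.
#' @export
eval_distribution <- function(rule, x) {
  stopifnot(x >= 0)
  kind <- match.arg(rule$kind, c("uniform", "sigmoidal", "exponential"))
  if (kind == "uniform") return(rep(rule$gmax, length(x)))
  if (is.null(rule$a7) || rule$a7 == 0)
    stop("a7 must be non-zero for ", kind, " rules")
  val <- switch(kind,
    sigmoidal = rule$a4 + rule$a5 / (1 + exp((x - rule$a6) / rule$a7)),
    exponential = rule$a4 + rule$a5 * exp((x - rule$a6) / rule$a7))
  val * rule$gmax
}

#' Load the default channel table and gating kinetics
#'
#' Reads the packaged YAML tables: 14 somatodendritic channels (Naf, Nap,
#' Kaf, Kas, Kir, Kdr, SK, BK, CaV1.2, CaV1.3, CaV2.2, CaV2.3, CaV3.2,
#' CaV3.3) with per-region spatial rules, plus reversal potentials, the
#' calcium pool, and magnesium-block constants.
#'
#' @param channels_file,kinetics_file optional paths overriding the
#'   packaged tables.
#' @return list of class `channel_table` with elements `channels` (each a
#'   list with `name`, `ion`, `erev` or GHK flag, `gates`, and per-region
#'   `rules`), `ions`, `leak`, `calcium`, `mg_block`, `temp_K`.
#' @export
default_channel_table <- function(channels_file = NULL, kinetics_file = NULL) {
  if (is.null(channels_file))
    channels_file <- system.file("extdata", "channels.yaml", package = "spnsim")
  if (is.null(kinetics_file))
    kinetics_file <- system.file("extdata", "kinetics.yaml", package = "spnsim")
  tab <- yaml::read_yaml(channels_file)
  kin <- yaml::read_yaml(kinetics_file)

  chans <- lapply(names(tab$channels), function(nm) {
    if (is.null(kin[[nm]])) stop("no gating scheme for channel ", nm)
    ion <- kin[[nm]]$ion
    list(name = nm, ion = ion,
         ghk = identical(ion, "ca"),
         erev = if (identical(ion, "ca")) NA_real_ else tab$ions[[ion]],
         gates = kin[[nm]]$gates,
         rules = tab$channels[[nm]])
  })
  names(chans) <- names(tab$channels)
  out <- list(channels = chans, ions = tab$ions, leak = tab$leak,
              calcium = tab$calcium, mg_block = tab$mg_block,
              temp_K = tab$temp_K)
  class(out) <- "channel_table"
  out
}

# translate a channel's gate list into the C++ spec format
gates_for_cpp <- function(gates) {
  lapply(gates, function(g) {
    kind <- match.arg(g$kind, c("voltage", "ca_hill", "bk"))
    if (kind == "voltage") {
      out <- list(kind = 0L, power = as.integer(g$power),
                  vhalf = g$vhalf, slope = g$slope,
                  tau_base = g$tau_base, tau_amp = g$tau_amp)
      if (g$tau_amp != 0) {
        out$tau_vhalf <- g$tau_vhalf
        out$tau_s1 <- g$tau_s1; out$tau_s2 <- g$tau_s2
      }
      out
    } else if (kind == "ca_hill") {
      list(kind = 1L, power = as.integer(g$power), hill = as.integer(g$hill),
           ec50 = g$ec50, tau = g$tau)
    } else {
      list(kind = 2L, power = as.integer(g$power), vhalf = g$vhalf,
           slope = g$slope, ca_ref = g$ca_ref, tau = g$tau)
    }
  })
}

#' Discretize a morphology into segments
#'
#' Splits every section into its `n_segments` equal pieces and returns the
#' per-segment geometry used to assemble conductances: midpoint path
#' distance, midpoint diameter (linear taper), length and lateral area.
#' Segment 1 is the somatic compartment.
#'
#' @param morph an `spn_morphology`.
#' @return data frame with one row per segment.
#' @export
segmentize <- function(morph) {
  s <- morph$sections
  rows <- list()
  for (i in seq_len(nrow(s))) {
    if (s$kind[i] == "soma") {
      rows[[i]] <- data.frame(
        section_id = s$id[i], seg = 1L, kind = "soma",
        arc0 = 0, arc1 = 1, length = s$length[i], diam = s$diam_prox[i],
        path = 0, area_um2 = 4 * pi * morph$soma_radius^2)
      next
    }
    n <- s$n_segments[i]
    a0 <- (seq_len(n) - 1) / n
    a1 <- seq_len(n) / n
    mid <- (a0 + a1) / 2
    dmid <- s$diam_prox[i] + (s$diam_dist[i] - s$diam_prox[i]) * mid
    len <- s$length[i] / n
    rows[[i]] <- data.frame(
      section_id = s$id[i], seg = seq_len(n), kind = "dendrite",
      arc0 = a0, arc1 = a1, length = len, diam = dmid,
      path = s$path0[i] + mid * s$length[i],
      area_um2 = pi * dmid * len)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the per-segment conductance map
#'
#' Evaluates every channel's regional density rule at each segment's path
#' distance.  Dendritic evaluations are capped at the morphology's maximum
#' path distance, matching the reference range over which the rules are
#' defined.
#'
#' @param morph an `spn_morphology`.
#' @param channel_table a `channel_table` (default: packaged table).
#' @return list of class `membrane_map`: `segments` (from [segmentize()]),
#'   `density` matrix (segments x channels, S/cm2 or cm/s), and the
#'   `channel_table`.
#' @export
build_membrane <- function(morph, channel_table = default_channel_table()) {
  segs <- segmentize(morph)
  xmax <- max_path_distance(morph)
  x <- pmin(segs$path, xmax)
  chn <- names(channel_table$channels)
  dens <- matrix(0, nrow(segs), length(chn), dimnames = list(NULL, chn))
  for (nm in chn) {
    rules <- channel_table$channels[[nm]]$rules
    for (region in c("soma", "dend")) {
      idx <- if (region == "soma") segs$kind == "soma"
             else segs$kind == "dendrite"
      if (!any(idx)) next
      if (is.null(rules[[region]]))
        stop("channel ", nm, " has no rule for region '", region, "'")
      dens[idx, nm] <- eval_distribution(rules[[region]], x[idx])
    }
  }
  if (any(dens < 0)) stop("negative channel density produced by a rule")
  out <- list(segments = segs, density = dens, channel_table = channel_table)
  class(out) <- "membrane_map"
  out
}

#' Gate steady state and time constant for a voltage gate
#'
#' @param gate one gate spec (a list from the kinetics table).
#' @param v membrane potential(s), mV.
#' @return data frame with `inf` and `tau` (ms).
#' @export
gate_curves <- function(gate, v) {
  stopifnot(identical(gate$kind, "voltage"))
  m <- gate_curves_cpp(gate$vhalf, gate$slope, gate$tau_base, gate$tau_amp,
                       if (gate$tau_amp != 0) gate$tau_vhalf else 0,
                       if (gate$tau_amp != 0) gate$tau_s1 else 10,
                       if (gate$tau_amp != 0) gate$tau_s2 else 10, v)
  data.frame(inf = m[, 1], tau = m[, 2])
}

# steady-state open fraction for any gate kind
gate_inf_value <- function(gate, v, ca) {
  switch(match.arg(gate$kind, c("voltage", "ca_hill", "bk")),
    voltage = gate_curves(gate, v)$inf,
    ca_hill = {
      cr <- (ca / gate$ec50)^gate$hill
      cr / (1 + cr)
    },
    bk = 1 / (1 + exp(-(v - gate$vhalf) / gate$slope) * (gate$ca_ref / ca)^2))
}

#' Advance a channel's gating state by one time step
#'
#' Rush-Larsen exponential relaxation toward the voltage- (or calcium-)
#' dependent steady state: `x <- x + (inf - x) * (1 - exp(-dt/tau))`.
#' Mirrors the update used inside the compiled solver.
#'
#' @param channel a channel spec from [default_channel_table()].
#' @param state named numeric vector of gate values in `[0, 1]` (names as
#'   in the kinetics table); missing state initializes at steady state.
#' @param v membrane potential, mV.
#' @param ca intracellular calcium, mM.
#' @param dt time step, ms (> 0).
#' @return updated named state vector.
#' @export
advance_gates <- function(channel, state = NULL, v, ca = 5e-5, dt = 0.025) {
  stopifnot(dt > 0)
  gates <- channel$gates
  nms <- vapply(gates, `[[`, "", "name")
  if (is.null(state)) {
    state <- vapply(gates, gate_inf_value, 0, v = v, ca = ca)
    names(state) <- nms
    return(state)
  }
  out <- state
  for (g in gates) {
    inf <- gate_inf_value(g, v, ca)
    tau <- switch(match.arg(g$kind, c("voltage", "ca_hill", "bk")),
                  voltage = gate_curves(g, v)$tau,
                  ca_hill = g$tau, bk = g$tau)
    out[g$name] <- state[g$name] + (inf - state[g$name]) *
      (1 - exp(-dt / tau))
  }
  out
}
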