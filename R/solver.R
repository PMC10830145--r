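# Assembly and integration of the branched compartmental system.

#' Simulation configuration
#'
#' @param dt time step, ms.
#' @param axial_resistivity cytoplasmic resistivity Ra, Ohm cm (200
#'   default; 100 in the low-Ra variant).
#' @param specific_capacitance uF/cm2.
#' @param v_rest resting potential the leak is calibrated to, mV.
#' @param settle_ms settling time simulated before any stimulus.
#' @export
sim_config <- function(dt = 0.025, axial_resistivity = 200,
                       specific_capacitance = 1, v_rest = -84,
                       settle_ms = 1000) {
  stopifnot(dt > 0, axial_resistivity > 0, specific_capacitance > 0)
  structure(list(dt = dt, axial_resistivity = axial_resistivity,
                 specific_capacitance = specific_capacitance,
                 v_rest = v_rest, settle_ms = settle_ms),
            class = "sim_config")
}

#' Build a compartmental system from a morphology and membrane map
#'
#' Segments become compartments ordered parents-before-children (the order
#' required by the O(n) tree solver).  Spines selected in `active_spines`
#' are represented explicitly as two passive compartments (neck then head);
#' the passive load of all remaining spines is folded into the parent
#' segment by scaling its membrane area (hence capacitance and every
#' conductance density attached to it) by `1 + spine_area/segment_area`,
#' which conserves whole-cell capacitance.  The leak conductance of each
#' compartment is then solved so that the assembled cell is at rest exactly
#' at `config$v_rest` with every channel at steady state.
#'
#' @param morph an `spn_morphology` (with spines placed).
#' @param membrane a `membrane_map` from [build_membrane()].
#' @param active_spines integer row indices into `morph$spines` that will
#'   receive synapses (explicit compartments), or `NULL`.
#' @param config a `sim_config`.
#' @param gsyn_scale scale factor applied to synaptic conductances by the
#'   protocol layer (1.6 in the low-Ra variant); stored, not applied here.
#' @return an object of class `spn_system`.
#' @export
build_system <- function(morph, membrane, active_spines = NULL,
                         config = sim_config(), gsyn_scale = 1) {
  segs <- membrane$segments
  dens <- membrane$density
  ctab <- membrane$channel_table
  n_seg <- nrow(segs)
  spines <- morph$spines
  if (!is.null(active_spines)) {
    if (is.null(spines) || !all(active_spines %in% seq_len(nrow(spines))))
      stop("active_spines contains indices of spines that were never placed")
  }

  # segment index for an (section, arc) location
  seg_index <- function(section_id, arc) {
    hit <- which(segs$section_id == section_id &
                 segs$arc0 <= arc & (segs$arc1 >= arc | segs$seg ==
                   max(segs$seg[segs$section_id == section_id])))
    hit[1]
  }

  # parent compartment of each segment
  parent <- integer(n_seg)
  secs <- morph$sections
  for (i in seq_len(n_seg)) {
    if (segs$kind[i] == "soma") { parent[i] <- 0L; next }
    if (segs$seg[i] > 1) { parent[i] <- i - 1L; next }
    psec <- secs$parent_id[match(segs$section_id[i], secs$id)]
    if (secs$kind[match(psec, secs$id)] == "soma") {
      parent[i] <- which(segs$kind == "soma")[1]
    } else {
      parent[i] <- max(which(segs$section_id == psec))
    }
  }

  # spine folding factors
  area <- segs$area_um2
  fold <- rep(1, n_seg)
  if (!is.null(spines) && nrow(spines)) {
    passive_idx <- setdiff(seq_len(nrow(spines)), active_spines)
    if (length(passive_idx)) {
      sp <- spines[passive_idx, ]
      sp_seg <- mapply(seg_index, sp$section_id, sp$arc_position)
      sp_area <- spine_area_um2(sp$head_diameter, sp$head_length,
                                sp$neck_diameter, sp$neck_length)
      add <- tapply(sp_area, factor(sp_seg, levels = seq_len(n_seg)), sum)
      add[is.na(add)] <- 0
      fold <- 1 + as.numeric(add) / area
    }
  }
  area_eff_um2 <- area * fold

  # explicit compartments for active spines: neck then head
  comp_kind <- segs$kind
  comp_path <- segs$path
  comp_len <- segs$length
  comp_diam <- segs$diam
  spine_head_comp <- integer(0)
  if (length(active_spines)) {
    sp <- spines[active_spines, ]
    for (k in seq_len(nrow(sp))) {
      pseg <- seg_index(sp$section_id[k], sp$arc_position[k])
      neck_area <- pi * sp$neck_diameter[k] * sp$neck_length[k]
      head_area <- pi * sp$head_diameter[k] * sp$head_length[k]
      parent <- c(parent, pseg, length(parent) + 1L)
      comp_kind <- c(comp_kind, "spine_neck", "spine_head")
      comp_path <- c(comp_path, sp$path[k] + sp$neck_length[k] / 2,
                     sp$path[k] + sp$neck_length[k] + sp$head_length[k] / 2)
      comp_len <- c(comp_len, sp$neck_length[k], sp$head_length[k])
      comp_diam <- c(comp_diam, sp$neck_diameter[k], sp$head_diameter[k])
      area_eff_um2 <- c(area_eff_um2, neck_area, head_area)
      spine_head_comp <- c(spine_head_comp, length(parent))
    }
  }
  n_comp <- length(parent)
  area_cm2 <- area_eff_um2 * 1e-8
  cap_nF <- area_cm2 * config$specific_capacitance * 1e3

  # axial coupling to parent: series half-resistances between centres
  half_res <- function(len_um, diam_um)  # Ohm
    config$axial_resistivity * (len_um * 1e-4 / 2) /
      (pi * (diam_um * 1e-4)^2 / 4)
  g_ax <- numeric(n_comp)
  for (i in seq_len(n_comp)) {
    p <- parent[i]
    if (p == 0) next
    r <- half_res(comp_len[i], comp_diam[i]) +
         half_res(comp_len[p], comp_diam[p])
    g_ax[i] <- 1e6 / r
  }

  # density matrix extended to spine compartments (no active channels)
  dens_full <- rbind(dens * fold,
                     matrix(0, n_comp - n_seg, ncol(dens),
                            dimnames = list(NULL, colnames(dens))))

  # channel meta for the solver
  chan_cpp <- lapply(ctab$channels, function(ch)
    list(type = if (ch$ghk) 1L else 0L,
         erev = if (ch$ghk) 0 else ch$erev,
         gates = gates_for_cpp(ch$gates)))

  sys <- list(
    parent = as.integer(parent), cap_nF = cap_nF, g_axial_uS = g_ax,
    area_cm2 = area_cm2, density = dens_full,
    comp_kind = comp_kind, comp_path = comp_path,
    comp_section = c(segs$section_id, rep(NA_integer_, n_comp - n_seg)),
    comp_arc = c((segs$arc0 + segs$arc1) / 2, rep(NA_real_, n_comp - n_seg)),
    n_comp = n_comp, n_seg = n_seg,
    spine_head_comp = spine_head_comp, active_spines = active_spines,
    g_tonic_uS = numeric(n_comp), e_tonic_mV = -60, tonic_density = 0,
    temp_K = ctab$temp_K,
    ca_rest_mM = ctab$calcium$rest_mM, ca_tau_ms = ctab$calcium$tau_ms,
    ca_depth_um = ctab$calcium$depth_um, ca_out_mM = ctab$calcium$cao_mM,
    mg_mM = ctab$mg_block$conc_mM, mg_k_mM = ctab$mg_block$k_mM,
    mg_gamma_per_mV = ctab$mg_block$gamma_per_mV,
    channels_cpp = chan_cpp, channel_table = ctab,
    morph = morph, config = config, gsyn_scale = gsyn_scale)
  class(sys) <- "spn_system"

  # leak calibration: zero net ionic current at v_rest in every membrane
  # compartment, with e_pas fixed by the channel table
  e_pas <- ctab$leak$e_pas
  i_rest <- ionic_current_at(sys, config$v_rest)  # nA, outward positive
  g_pas <- if (config$v_rest == e_pas) numeric(n_comp)
           else -i_rest / (config$v_rest - e_pas)
  g_pas[comp_kind %in% c("spine_neck", "spine_head")] <- 0
  g_pas <- pmax(g_pas, 0)  # net-inward compartments would need e_pas < rest
  sys$g_pas_uS <- g_pas
  sys$e_pas_mV <- rep(e_pas, n_comp)
  sys
}

# total steady-state channel current (nA, outward positive) at voltage v
# with calcium at rest; used for leak calibration
ionic_current_at <- function(sys, v) {
  ctab <- sys$channel_table
  ca <- sys$ca_rest_mM
  i <- numeric(sys$n_comp)
  for (nm in colnames(sys$density)) {
    ch <- ctab$channels[[nm]]
    open <- 1
    for (g in ch$gates)
      open <- open * gate_inf_value(g, v, ca)^g$power
    de <- sys$density[, nm]
    if (ch$ghk) {
      i <- i + de * open * ghk_current_Acm2(v, ca, sys$ca_out_mM,
                                            sys$temp_K) * sys$area_cm2 * 1e9
    } else {
      i <- i + de * sys$area_cm2 * 1e6 * open * (v - ch$erev)
    }
  }
  i
}

# GHK calcium current density, A/cm2, concentrations in mM
ghk_current_Acm2 <- function(v_mV, ci_mM, co_mM, temp_K) {
  FARADAY <- 96485.33212; R <- 8.31446
  u <- 2 * (v_mV * 1e-3) * FARADAY / (R * temp_K)
  small <- abs(u) < 1e-6
  g1 <- ifelse(small, 2 * FARADAY * (1 + u / 2),
               2 * FARADAY * u / (1 - exp(-u)))
  g2 <- ifelse(small, 2 * FARADAY * (1 - u / 2),
               2 * FARADAY * u * exp(-u) / (1 - exp(-u)))
  1e-6 * (g1 * ci_mM - g2 * co_mM)
}

#' Locate the compartment holding a (section, arc) position
#' @param system an `spn_system`.
#' @param section_id section id; `arc` fraction along it.
#' @return compartment index (1-based).
#' @export
compartment_at <- function(system, section_id, arc = 0.5) {
  idx <- which(system$comp_section == section_id)
  if (!length(idx)) stop("unknown section id ", section_id)
  idx[which.min(abs(system$comp_arc[idx] - arc))]
}

#' Soma compartment index of a system
#' @param system an `spn_system`.
#' @export
soma_compartment <- function(system) which(system$comp_kind == "soma")[1]

# ------------------------------------------------------------- simulation

empty_events <- function()
  data.frame(comp = integer(0), onset = numeric(0), tau1 = numeric(0),
             tau2 = numeric(0), gmax_uS = numeric(0), erev = numeric(0),
             nmda = numeric(0))

#' Build solver events from stimulus descriptions
#'
#' @param system an `spn_system`.
#' @param comp compartment indices (1-based).
#' @param onset onsets, ms.
#' @param spec a `synapse_spec` (recycled).
#' @return event data frame for [simulate()].
#' @export
syn_events <- function(system, comp, onset, spec) {
  if (!length(comp)) return(empty_events())
  data.frame(comp = comp, onset = onset,
             tau1 = spec$tau1, tau2 = spec$tau2,
             gmax_uS = spec$g_max * 1e-6 * system$gsyn_scale,
             erev = spec$e_rev, nmda = as.numeric(isTRUE(spec$mg_block)))
}

#' Integrate the compartmental system
#'
#' Backward-Euler integration on the tree (unconditionally stable,
#' O(compartments) per step).  Deterministic for fixed inputs.
#'
#' @param system an `spn_system`.
#' @param events event data frame (see [syn_events()]); may be empty.
#' @param duration ms.
#' @param record compartment indices (1-based) to record; named entries
#'   label the traces.
#' @param init_state state list from a previous run (its `$state`), or
#'   `NULL` to start from steady state at `config$v_rest`.
#' @param iclamp data frame (comp, amp_pA, t0, t1) of current steps.
#' @param isine data frame (comp, amp_pA, freq_Hz, t0) of sinusoids.
#' @param dt override of the config time step.
#' @param record_every keep every k-th sample.
#' @return list of class `spn_traces`: `t` (ms), `v` (matrix, mV, one
#'   column per recorded location), `locations`, `state` (for chaining),
#'   `dt`.
#' @export
simulate <- function(system, events = NULL, duration = 500,
                     record = soma_compartment(system), init_state = NULL,
                     iclamp = NULL, isine = NULL, dt = NULL,
                     record_every = 1L) {
  stopifnot(inherits(system, "spn_system"))
  if (is.null(events) || !nrow(events)) events <- empty_events()
  events <- events[order(events$onset), , drop = FALSE]
  if (any(events$comp < 1 | events$comp > system$n_comp))
    stop("event targets a compartment outside the system")
  if (is.null(dt)) dt <- system$config$dt

  cfg <- list(dt = dt, duration = duration,
              record = as.integer(record) - 1L,
              record_every = as.integer(record_every),
              v_init = system$config$v_rest, init_state = init_state)
  if (!is.null(iclamp) && nrow(iclamp))
    cfg$iclamp <- cbind(iclamp$comp - 1, iclamp$amp_pA * 1e-3,
                        iclamp$t0, iclamp$t1)
  if (!is.null(isine) && nrow(isine))
    cfg$isine <- cbind(isine$comp - 1, isine$amp_pA * 1e-3,
                       isine$freq_Hz, isine$t0)

  sysl <- list(parent = as.integer(system$parent) - 1L,  # 0-based, root -1
               cap_nF = system$cap_nF,
               g_axial_uS = system$g_axial_uS, area_cm2 = system$area_cm2,
               g_pas_uS = system$g_pas_uS, e_pas_mV = system$e_pas_mV,
               g_tonic_uS = system$g_tonic_uS, e_tonic_mV = system$e_tonic_mV,
               density = system$density, channels = system$channels_cpp,
               temp_K = system$temp_K, ca_rest_mM = system$ca_rest_mM,
               ca_tau_ms = system$ca_tau_ms, ca_depth_um = system$ca_depth_um,
               ca_out_mM = system$ca_out_mM, mg_mM = system$mg_mM,
               mg_k_mM = system$mg_k_mM,
               mg_gamma_per_mV = system$mg_gamma_per_mV)

  ev <- list(comp = as.numeric(events$comp - 1), onset = events$onset,
             tau1 = events$tau1, tau2 = events$tau2,
             gmax_uS = events$gmax_uS, erev = events$erev,
             nmda = events$nmda)

  out <- simulate_cpp(sysl, ev, cfg)
  labels <- if (!is.null(names(record)) && any(nzchar(names(record))))
    names(record) else paste0("comp", record)
  colnames(out$v) <- labels
  res <- list(t = out$t, v = out$v, locations = record, state = out$state,
              dt = dt * record_every)
  class(res) <- "spn_traces"
  res
}

#' Settle a system to its resting state
#'
#' Runs `settle_ms` (default from the config) with no stimulus and returns
#' the final state for reuse as `init_state`.
#'
#' @param system an `spn_system`.
#' @param settle_ms ms.
#' @param init_state optional starting state.
#' @return list with `state` and `rmp` (final somatic potential, mV).
#' @export
settle <- function(system, settle_ms = NULL, init_state = NULL) {
  if (is.null(settle_ms)) settle_ms <- system$config$settle_ms
  tr <- simulate(system, duration = settle_ms,
                 record = soma_compartment(system),
                 init_state = init_state, record_every = 40L)
  list(state = tr$state, rmp = unname(tr$v[nrow(tr$v), 1]))
}

# map a settled base-system state onto a system extended with spine
# compartments (spines copy their parent segment's voltage)
extend_state <- function(system, base_state) {
  n_base <- length(base_state$v)
  n <- system$n_comp
  if (n == n_base) return(base_state)
  extra <- (n_base + 1):n
  vout <- numeric(n)
  vout[seq_len(n_base)] <- base_state$v
  for (i in extra) vout[i] <- vout[system$parent[i]]  # neck, then head
  ca <- numeric(n)
  ca[seq_len(n_base)] <- base_state$ca
  ca[extra] <- system$ca_rest_mM
  n_gates <- length(base_state$gates) / n_base
  # gates are stored compartment-major (n_gates contiguous per compartment)
  gates <- c(base_state$gates, numeric((n - n_base) * n_gates))
  list(v = vout, ca = ca, gates = gates)
}

#' Passive characterization of a system
#'
#' Settles the cell, then applies a -200 pA somatic step: the
#' rectified-range input resistance is the steady-state deflection over the
#' current, and the membrane time constant comes from a single-exponential
#' fit to the step onset.
#'
#' @param system an `spn_system`.
#' @param step_pA current step amplitude (default -200 pA).
#' @param step_ms step duration.
#' @return list `rmp` (mV), `input_resistance` (MOhm), `tau_m` (ms).
#' @export
passive_characterize <- function(system, step_pA = -200, step_ms = 600) {
  st <- settle(system)
  soma <- soma_compartment(system)
  tr <- simulate(system, duration = step_ms + 100,
                 record = c(soma = soma), init_state = st$state,
                 iclamp = data.frame(comp = soma, amp_pA = step_pA,
                                     t0 = 50, t1 = 50 + step_ms))
  v <- tr$v[, 1]; t <- tr$t
  v0 <- mean(v[t <= 50])
  sel_ss <- t >= 50 + step_ms - 50 & t <= 50 + step_ms
  v_ss <- mean(v[sel_ss])
  rin <- (v_ss - v0) / (step_pA * 1e-3)  # mV / nA = MOhm

  # single-exponential fit over the onset
  on <- t > 50 & t <= 110
  tt <- t[on] - 50
  vv <- v[on]
  fit <- try(suppressWarnings(
    stats::nls(vv ~ vf + (v0 - vf) * exp(-tt / tau),
               start = list(vf = v_ss, tau = 10),
               control = list(warnOnly = TRUE))), silent = TRUE)
  tau <- if (inherits(fit, "try-error")) {
    # log-linear fallback
    y <- (vv - v_ss) / (v0 - v_ss)
    ok <- y > 0.05
    -1 / coef(lm(log(y[ok]) ~ tt[ok]))[2]
  } else coef(fit)[["tau"]]

  # non-settling membrane check: rest drift over the last settle window
  drift <- abs(st$rmp - v0)
  if (drift > 1)
    warning("membrane did not settle (", round(drift, 2), " mV drift)")

  list(rmp = st$rmp, input_resistance = unname(rin), tau_m = unname(tau))
}

#' Local impedance magnitude from a sinusoidal current injection
#'
#' Injects a small sinusoid at `comp`, discards the transient, and
#' projects the last full cycles onto the stimulus quadrature pair.
#'
#' @param system an `spn_system`.
#' @param comp compartment index (see [compartment_at()]).
#' @param frequency Hz (> 0).
#' @param amplitude_pA stimulus amplitude (small, default 5 pA).
#' @param n_cycles cycles simulated; the last `n_cycles - transient_cycles`
#'   are analysed.
#' @param init_state optional settled state.
#' @return impedance magnitude, MOhm.
#' @export
measure_impedance <- function(system, comp, frequency = 10,
                              amplitude_pA = 5, n_cycles = 5,
                              transient_cycles = 2, init_state = NULL) {
  if (frequency <= 0) stop("frequency must be > 0")
  if (is.null(init_state)) init_state <- settle(system)$state
  period <- 1000 / frequency
  dur <- n_cycles * period
  tr <- simulate(system, duration = dur, record = comp,
                 init_state = init_state,
                 isine = data.frame(comp = comp, amp_pA = amplitude_pA,
                                    freq_Hz = frequency, t0 = 0))
  sel <- tr$t > transient_cycles * period
  t <- tr$t[sel]; v <- tr$v[sel, 1]
  s <- sin(2 * pi * frequency * t * 1e-3)
  c_ <- cos(2 * pi * frequency * t * 1e-3)
  fit <- lm(v ~ s + c_)
  amp_mV <- sqrt(sum(coef(fit)[c("s", "c_")]^2))
  amp_mV / (amplitude_pA * 1e-3)  # mV / nA = MOhm
}

#' @export
print.spn_system <- function(x, ...) {
  cat("spn_system:", x$n_comp, "compartments (", x$n_seg, "segments,",
      length(x$spine_head_comp), "explicit spines )\n")
  cat(sprintf("  Ra %g Ohm cm, dt %g ms, v_rest %g mV, tonic %g S/cm2\n",
              x$config$axial_resistivity, x$config$dt, x$config$v_rest,
              x$tonic_density))
  invisible(x)
}
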