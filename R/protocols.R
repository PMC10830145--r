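# The stimulation experiments: clustered glutamatergic input, phasic
# on-site/off-site GABA, timing sweeps, threshold searches and the tonic
# GABA sweep.  Event builders are pure (same arguments, same event list);
# run_synaptic_protocol() resolves targets to compartments and integrates.

#' Dendritic sections eligible for clustered-input protocols
#'
#' Sections carrying at least `n_required` spines at or beyond the
#' stimulation start point (two-thirds of the section length by default),
#' ordered by midpoint path distance.
#'
#' @param model an `spn_model` from [default_model()].
#' @param n_required spines needed beyond the start point.
#' @param start_fraction stimulation start as a fraction of section length.
#' @return data frame (section_id, mid_path, n_spines_available).
#' @export
target_dendrites <- function(model, n_required = 18, start_fraction = 2/3) {
  sp <- model$morph$spines
  s <- model$morph$sections
  d <- s[s$kind == "dendrite", ]
  avail <- vapply(d$id, function(id)
    sum(sp$section_id == id & sp$arc_position >= start_fraction), 0L)
  out <- data.frame(section_id = d$id,
                    mid_path = d$path0 + d$length / 2,
                    terminal = !(d$id %in% s$parent_id),
                    n_spines_available = avail)
  out <- out[out$n_spines_available >= n_required, ]
  out[order(out$mid_path), ]
}

# most distal terminal dendrites, optionally excluding a dendrite and its
# whole root path (ancestors and descendants)
distal_terminals <- function(model, n, exclude_dendrite = NULL) {
  s <- model$morph$sections
  d <- s[s$kind == "dendrite", ]
  term <- d[!(d$id %in% s$parent_id), ]
  if (!is.null(exclude_dendrite)) {
    path_ids <- exclude_dendrite
    i <- exclude_dendrite
    repeat {
      p <- s$parent_id[match(i, s$id)]
      if (is.na(p) || s$kind[match(p, s$id)] == "soma") break
      path_ids <- c(path_ids, p); i <- p
    }
    desc <- exclude_dendrite
    repeat {
      kids <- s$id[!is.na(s$parent_id) & s$parent_id %in% desc]
      new <- setdiff(kids, desc)
      if (!length(new)) break
      desc <- c(desc, new)
    }
    term <- term[!(term$id %in% c(path_ids, desc)), ]
  }
  term <- term[order(term$path0 + term$length / 2, decreasing = TRUE), ]
  if (nrow(term) < n) stop("not enough off-site terminal dendrites")
  term$id[seq_len(n)]
}

#' Arc position of the centre of a stimulated spine cluster
#'
#' @param model an `spn_model`.
#' @param glut events from [clustered_glutamate()].
#' @return mean arc position of the stimulated spines on their section.
#' @export
cluster_arc <- function(model, glut) {
  s <- model$morph$sections
  j <- match(glut$section_id[1], s$id)
  mean((glut$path - s$path0[j]) / s$length[j])
}

#' Clustered glutamatergic stimulation events
#'
#' Activates `n` neighboring spines along one dendrite in succession at
#' `interval` ms, starting at about two-thirds of the section length and
#' moving away from the soma; every event carries co-located AMPA and NMDA
#' conductances on the spine head.
#'
#' @param model an `spn_model`.
#' @param dendrite section id.
#' @param n number of inputs (>= 0).
#' @param interval ms between successive spines.
#' @param start_fraction stimulation start point along the section.
#' @param t0 onset of the first input, ms.
#' @return data frame (spine, section_id, path, onset), ordered by
#'   increasing path distance.
#' @export
clustered_glutamate <- function(model, dendrite, n, interval = 1,
                                start_fraction = 2/3, t0 = 0) {
  if (n == 0)
    return(data.frame(spine = integer(0), section_id = integer(0),
                      path = numeric(0), onset = numeric(0)))
  sp <- model$morph$spines
  cand <- which(sp$section_id == dendrite &
                sp$arc_position >= start_fraction)
  cand <- cand[order(sp$path[cand])]
  if (length(cand) < n)
    stop("dendrite ", dendrite, " has only ", length(cand),
         " spines beyond the start point (need ", n, ")")
  idx <- cand[seq_len(n)]
  data.frame(spine = idx, section_id = dendrite, path = sp$path[idx],
             onset = t0 + (seq_len(n) - 1) * interval)
}

#' Phasic GABAergic stimulation events
#'
#' GABA-A synapses sit on dendritic shaft midpoints.  Modes: `onsite`
#' (bursts of `group_size` simultaneous events repeated `repeats` times at
#' `interval` ms on the glutamate dendrite's midpoint), `offsite4x3`
#' (`n_sites = 4` distal off-path dendrites, each a burst of `group_size`
#' at `interval` ms, sites simultaneous), `offsite12x1` (single synchronous
#' event on each of the `n_sites = 12` most distal off-path dendrites),
#' `onpath_proximal` (like onsite but on the proximal on-path parent
#' section), `none`.
#'
#' @param model an `spn_model`.
#' @param mode stimulation pattern.
#' @param glut_dendrite section id receiving the glutamatergic cluster
#'   (used for site selection and overlap checks).
#' @param group_size synapses per burst instant (onsite/onpath) or per
#'   dendrite (offsite4x3).
#' @param repeats burst repetitions (onsite/onpath modes).
#' @param interval ms within bursts.
#' @param n_sites number of off-site dendrites.
#' @param t0 onset of the first event, ms.
#' @param onsite_arc shaft position of the on-site GABA synapses; defaults
#'   to the section midpoint, and protocol runners pass the midpoint of
#'   the stimulated spine span (the "same dendritic location" as the
#'   glutamatergic cluster) via [cluster_arc()].
#' @return data frame (section_id, arc, onset); one row per synapse
#'   activation.
#' @export
phasic_gaba <- function(model, mode = c("none", "onsite", "offsite4x3",
                                        "offsite12x1", "onpath_proximal"),
                        glut_dendrite = NULL, group_size = 3, repeats = 4,
                        interval = 1, n_sites = NULL, t0 = 0,
                        onsite_arc = 0.5) {
  mode <- match.arg(mode)
  empty <- data.frame(section_id = integer(0), arc = numeric(0),
                      onset = numeric(0))
  if (mode == "none" || group_size == 0) return(empty)
  s <- model$morph$sections
  if (mode == "onsite") {
    onsets <- rep(t0 + (seq_len(repeats) - 1) * interval, each = group_size)
    return(data.frame(section_id = glut_dendrite, arc = onsite_arc,
                      onset = onsets))
  }
  if (mode == "onpath_proximal") {
    parent <- s$parent_id[match(glut_dendrite, s$id)]
    if (is.na(parent) || s$kind[match(parent, s$id)] == "soma")
      stop("glutamate dendrite has no proximal on-path dendrite")
    onsets <- rep(t0 + (seq_len(repeats) - 1) * interval, each = group_size)
    return(data.frame(section_id = parent, arc = 0.5, onset = onsets))
  }
  if (mode == "offsite4x3") {
    if (is.null(n_sites)) n_sites <- 4L
    sites <- distal_terminals(model, n_sites, exclude_dendrite = glut_dendrite)
    out <- do.call(rbind, lapply(sites, function(site)
      data.frame(section_id = site, arc = 0.5,
                 onset = t0 + (seq_len(group_size) - 1) * interval)))
    return(out)
  }
  # offsite12x1
  if (is.null(n_sites)) n_sites <- 12L
  sites <- distal_terminals(model, n_sites, exclude_dendrite = glut_dendrite)
  data.frame(section_id = sites, arc = 0.5, onset = t0)
}

#' Run a combined glutamate/GABA protocol on the model
#'
#' Builds a system with the stimulated spines explicit, restores the
#' cached resting state (or re-settles fully when a tonic conductance is
#' set), applies the events and integrates.
#'
#' @param model an `spn_model`.
#' @param glut events from [clustered_glutamate()] (or NULL).
#' @param gaba events from [phasic_gaba()] (or NULL).
#' @param tonic_density S/cm2 of tonic GABA-A conductance.
#' @param nmda_on if FALSE the NMDA conductance is zero (knockout control).
#' @param record_sections named list of (section_id, arc) recording sites;
#'   the soma is always recorded as column "soma".
#' @param duration_post ms simulated past the last event.
#' @param pre_ms quiet margin before the first event (part of the trace,
#'   used as baseline).
#' @param resettle_ms short re-equilibration after restoring the cached
#'   state.
#' @return `spn_traces` with attributes `t_first_glut`, `t_last_glut`,
#'   `t_first_gaba`, `events`.
#' @export
run_synaptic_protocol <- function(model, glut = NULL, gaba = NULL,
                                  tonic_density = 0, nmda_on = TRUE,
                                  record_sections = NULL,
                                  duration_post = 500, pre_ms = 50,
                                  resettle_ms = 100) {
  has_glut <- !is.null(glut) && nrow(glut) > 0
  has_gaba <- !is.null(gaba) && nrow(gaba) > 0
  active <- if (has_glut) sort(unique(glut$spine)) else NULL

  sys <- build_system(model$morph, model$membrane, active_spines = active,
                      config = model$config, gsyn_scale = model$gsyn_scale)
  if (tonic_density > 0) {
    sys <- apply_tonic(sys, tonic_gaba(tonic_density))
    st <- settle(sys)$state
  } else {
    st <- extend_state(sys, model$base_state)
    if (resettle_ms > 0)
      st <- simulate(sys, duration = resettle_ms, init_state = st,
                     record = soma_compartment(sys),
                     record_every = 40L)$state
  }

  events <- empty_events()
  t_shift <- pre_ms
  if (has_glut) {
    heads <- sys$spine_head_comp[match(glut$spine, sys$active_spines)]
    ampa <- model$syn$ampa; nmda <- model$syn$nmda
    events <- rbind(events,
                    syn_events(sys, heads, glut$onset + t_shift, ampa))
    if (nmda_on)
      events <- rbind(events,
                      syn_events(sys, heads, glut$onset + t_shift, nmda))
  }
  if (has_gaba) {
    comps <- mapply(function(sec, arc) compartment_at(sys, sec, arc),
                    gaba$section_id, gaba$arc)
    events <- rbind(events,
                    syn_events(sys, comps, gaba$onset + t_shift,
                               model$syn$gaba))
  }

  rec <- c(soma = soma_compartment(sys))
  if (!is.null(record_sections))
    for (nm in names(record_sections))
      rec[nm] <- compartment_at(sys, record_sections[[nm]][1],
                                record_sections[[nm]][2])
  dur <- pre_ms + (if (nrow(events)) max(events$onset) - t_shift else 0) +
    duration_post
  tr <- simulate(sys, events = events, duration = dur, record = rec,
                 init_state = st)
  attr(tr, "t_first_glut") <- if (has_glut) min(glut$onset) + t_shift else NA
  attr(tr, "t_last_glut") <- if (has_glut) max(glut$onset) + t_shift else NA
  attr(tr, "t_first_gaba") <- if (has_gaba) min(gaba$onset) + t_shift else NA
  attr(tr, "events") <- events
  tr
}

#' Timing sweep of glutamatergic versus GABAergic input
#'
#' Holds the GABAergic pattern fixed and shifts the glutamatergic cluster
#' by `delta_t = t_GLUT - t_GABA` (negative: glutamate first).  The
#' glutamate-alone and GABA-alone reference runs are computed once and
#' shared across all offsets.
#'
#' @param model an `spn_model`.
#' @param dendrite glutamate target section id.
#' @param n_glut number of clustered inputs.
#' @param gaba_mode,group_size,repeats,n_sites passed to [phasic_gaba()].
#' @param delta_t_values ms offsets.
#' @param measure_at "dendrite" (glutamate site midpoint) or "soma".
#' @param spike_cutoff_ms quarterdrop cutoff for spike classification.
#' @param duration_post ms past the last event in every run.
#' @return list with `results` (one row per delta_t: P-measures,
#'   quarterdrop, spike flag) and `reference` (the two reference traces).
#' @export
timing_sweep <- function(model, dendrite, n_glut = 15,
                         gaba_mode = "offsite4x3", group_size = 3,
                         repeats = 4, n_sites = NULL,
                         delta_t_values = seq(-10, 30, 10),
                         measure_at = c("dendrite", "soma"),
                         spike_cutoff_ms = 40, duration_post = 500) {
  measure_at <- match.arg(measure_at)
  rec <- list(dend = c(dendrite, 0.5))
  colname <- if (measure_at == "dendrite") "dend" else "soma"
  t_gaba <- max(0, -min(delta_t_values))  # keep all onsets >= 0

  glut_ref <- clustered_glutamate(model, dendrite, n_glut, t0 = t_gaba)
  gaba <- phasic_gaba(model, gaba_mode, glut_dendrite = dendrite,
                      group_size = group_size, repeats = repeats,
                      n_sites = n_sites, t0 = t_gaba,
                      onsite_arc = cluster_arc(model, glut_ref))

  # shared reference runs (glutamate-alone P1 is offset-invariant)
  tr_glut <- run_synaptic_protocol(model, glut = glut_ref, gaba = NULL,
                                   record_sections = rec,
                                   duration_post = duration_post)
  tr_gaba <- run_synaptic_protocol(model, glut = NULL, gaba = gaba,
                                   record_sections = rec,
                                   duration_post = duration_post)

  rows <- list()
  for (dtv in delta_t_values) {
    glut <- clustered_glutamate(model, dendrite, n_glut, t0 = t_gaba + dtv)
    tr <- run_synaptic_protocol(model, glut = glut, gaba = gaba,
                                record_sections = rec,
                                duration_post = duration_post)
    rows[[length(rows) + 1]] <-
      summarize_combined(tr, tr_glut, tr_gaba, delta_t = dtv,
                         column = colname, spike_cutoff_ms = spike_cutoff_ms)
  }
  list(results = do.call(rbind, rows),
       reference = list(glut = tr_glut, gaba = tr_gaba))
}

# P-measures + quarterdrop/spike for one combined run against shared
# references; traces may differ in length (padded at the resting tail)
summarize_combined <- function(tr, tr_glut, tr_gaba, delta_t, column,
                               spike_cutoff_ms = 40) {
  n <- min(nrow(tr$v), nrow(tr_glut$v), nrow(tr_gaba$v))
  first_stim <- min(attr(tr, "t_first_glut"), attr(tr, "t_first_gaba"),
                    na.rm = TRUE)
  clip <- function(x) list(t = x$t[seq_len(n)], v = x$v[seq_len(n), column])
  pm <- p_measures(clip(tr_glut), clip(tr_gaba), clip(tr),
                   window = c(first_stim, max(tr$t[seq_len(n)])),
                   delta_t = delta_t)
  qd <- quarterdrop(tr, t_last_stim = attr(tr, "t_last_glut"),
                    t_first_stim = first_stim, column = column)
  pm$quarterdrop <- as.numeric(qd)
  pm$spike <- classify_spike(qd, spike_cutoff_ms)
  pm
}

#' Threshold search over an input count
#'
#' Runs the protocol family at increasing counts and returns the smallest
#' count classified as a dendritic spike (quarterdrop at the dendritic
#' recording site at or above the cutoff).
#'
#' @param model an `spn_model`.
#' @param family `"glutamate"` (count = clustered inputs, no GABA) or
#'   `"gaba12"` (count = number of distal dendrites receiving one GABA
#'   synapse each, leading a fixed just-subthreshold glutamate cluster by
#'   `gaba_lead_ms`).
#' @param lo,hi search range (inclusive).
#' @param dendrite glutamate target; defaults to the model's reference
#'   (most distal eligible) dendrite.
#' @param n_glut glutamate count for the `gaba12` family (defaults to the
#'   model's glutamate threshold minus one).
#' @param gaba_lead_ms GABA lead time for `gaba12` (delta_t = +lead).
#' @param spike_cutoff_ms classification cutoff.
#' @return integer threshold, with attribute `table` of (count, spike).
#' @export
threshold_search <- function(model, family = c("glutamate", "gaba12"),
                             lo, hi, dendrite = NULL, n_glut = NULL,
                             gaba_lead_ms = 10, spike_cutoff_ms = 40) {
  family <- match.arg(family)
  if (is.null(dendrite)) dendrite <- model$reference_dendrite
  rec <- list(dend = c(dendrite, 0.5))
  runs <- data.frame(count = integer(0), quarterdrop = numeric(0),
                     spike = logical(0))
  threshold <- NA_integer_
  for (k in lo:hi) {
    if (family == "glutamate") {
      glut <- clustered_glutamate(model, dendrite, k, t0 = 0)
      tr <- run_synaptic_protocol(model, glut = glut, record_sections = rec)
    } else {
      if (is.null(n_glut)) n_glut <- model$glut_threshold - 1L
      glut <- clustered_glutamate(model, dendrite, n_glut,
                                  t0 = gaba_lead_ms)
      gaba <- phasic_gaba(model, "offsite12x1", glut_dendrite = dendrite,
                          n_sites = k, t0 = 0)
      tr <- run_synaptic_protocol(model, glut = glut, gaba = gaba,
                                  record_sections = rec)
    }
    qd <- quarterdrop(tr, t_last_stim = attr(tr, "t_last_glut"),
                      t_first_stim = min(attr(tr, "t_first_glut"),
                                         attr(tr, "t_first_gaba"),
                                         na.rm = TRUE),
                      column = "dend")
    sp <- classify_spike(qd, spike_cutoff_ms)
    runs <- rbind(runs, data.frame(count = k, quarterdrop = as.numeric(qd),
                                   spike = sp))
    if (sp) { threshold <- k; break }
  }
  if (is.na(threshold))
    stop("no spike transition in [", lo, ", ", hi, "]")
  structure(threshold, table = runs)
}

#' Tonic GABA conductance sweep
#'
#' For each density: the cell is re-settled with the tonic conductance in
#' place, the resting depolarization is measured against the zero-density
#' rest, and the (sub-threshold) glutamatergic cluster response is
#' classified.  All amplitudes are measured from the density's own settled
#' rest.
#'
#' @param model an `spn_model`.
#' @param densities S/cm2, positive and sorted ascending.
#' @param dendrite glutamate target (default: reference dendrite).
#' @param n_glut clustered inputs (default: glutamate threshold minus one).
#' @param nmda_on logical, FALSE for the NMDA-knockout control.
#' @param spike_cutoff_ms classification cutoff.
#' @return data frame (density, dv_rest, rmp, p1, p3, ratio_p3_p1,
#'   quarterdrop, spike).
#' @export
tonic_sweep <- function(model, densities, dendrite = NULL, n_glut = NULL,
                        nmda_on = TRUE, spike_cutoff_ms = 40) {
  stopifnot(all(densities >= 0), !is.unsorted(densities))
  if (is.null(dendrite)) dendrite <- model$reference_dendrite
  if (is.null(n_glut)) n_glut <- model$glut_threshold - 1L
  rec <- list(dend = c(dendrite, 0.5))
  glut <- clustered_glutamate(model, dendrite, n_glut, t0 = 0)

  # zero-density reference
  tr0 <- run_synaptic_protocol(model, glut = glut, nmda_on = nmda_on,
                               record_sections = rec)
  rmp0 <- mean(tr0$v[tr0$t < attr(tr0, "t_first_glut"), "dend"])
  p1_ref <- max(tr0$v[, "dend"]) - rmp0

  rows <- lapply(densities, function(dens) {
    tr <- run_synaptic_protocol(model, glut = glut, tonic_density = dens,
                                nmda_on = nmda_on, record_sections = rec)
    rest <- mean(tr$v[tr$t < attr(tr, "t_first_glut"), "dend"])
    qd <- quarterdrop(tr, t_last_stim = attr(tr, "t_last_glut"),
                      t_first_stim = attr(tr, "t_first_glut"),
                      column = "dend")
    p3 <- max(tr$v[, "dend"]) - rest
    data.frame(density = dens, dv_rest = rest - rmp0, rmp = rest,
               p1 = p1_ref, p3 = p3, ratio_p3_p1 = p3 / p1_ref,
               quarterdrop = as.numeric(qd),
               spike = classify_spike(qd, spike_cutoff_ms))
  })
  out <- do.call(rbind, rows)
  attr(out, "rmp0") <- rmp0
  out
}
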