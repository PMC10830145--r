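# Synthetic SPN morphology: a stylized branched dendritic tree calibrated
# against aggregate passive targets (maximum soma-to-tip path length, total
# dendritic length, whole-cell capacitance) rather than any particular
# reconstruction.

#' Morphology generator parameters
#'
#' Defaults reproduce the aggregate properties of the reconstructed dSPN
#' used for the dendritic-integration simulations: a maximum path distance
#' of 265.268 um from the soma centre, spine density 1.711 per um beyond a
#' 30 um placement floor (circa 5,500 spines), and a whole-cell capacitance
#' of 180 pF at 1 uF/cm^2 once spine membrane is included.
#'
#' @param n_primary number of primary dendrites leaving the soma.
#' @param n_levels branch levels (primary = level 1; each level bifurcates
#'   once into the next, so 4 levels gives 4 + 8 + 16 + 32 = 60 sections).
#' @param total_dendritic_length um of dendrite summed over all sections.
#' @param primary_length um, fixed length of each primary dendrite.
#' @param max_path_target um, soma centre to furthest dendritic tip.
#' @param soma_radius um.
#' @param capacitance_target_pF whole-cell capacitance calibration target
#'   (soma + dendrites + spines at 1 uF/cm^2).
#' @param diam_profile proximal-to-tip diameter knots (um), one per level
#'   boundary (length `n_levels + 1`); rescaled jointly to hit the
#'   capacitance target.
#' @param spine_density spines per um of eligible dendrite.
#' @param spine_min_path um, spines are only placed further than this path
#'   distance from the soma centre.
#' @param length_jitter relative half-width of the uniform jitter applied
#'   to non-primary section lengths before rescaling.
#' @param seg_length_um target segment length used to discretize sections
#'   (chosen so the tree holds about 700 dendritic segments).
#' @param seed integer; the generator is deterministic given the seed.
#' @return a list of class `morpho_params`.
#' @export
morpho_params <- function(n_primary = 4L,
                          n_levels = 4L,
                          total_dendritic_length = 3310.45,
                          primary_length = 25,
                          max_path_target = 265.268,
                          soma_radius = 6.010,
                          capacitance_target_pF = 180,
                          diam_profile = c(1.8, 1.4, 1.1, 0.85, 0.60),
                          spine_density = 1.711,
                          spine_min_path = 30,
                          length_jitter = 0.25,
                          seg_length_um = 4.75,
                          seed = 1L) {
  p <- list(n_primary = as.integer(n_primary), n_levels = as.integer(n_levels),
            total_dendritic_length = total_dendritic_length,
            primary_length = primary_length,
            max_path_target = max_path_target, soma_radius = soma_radius,
            capacitance_target_pF = capacitance_target_pF,
            diam_profile = diam_profile, spine_density = spine_density,
            spine_min_path = spine_min_path, length_jitter = length_jitter,
            seg_length_um = seg_length_um, seed = as.integer(seed))
  class(p) <- "morpho_params"
  if (p$spine_density < 0) stop("spine_density must be >= 0")
  if (p$n_primary > 0 && p$total_dendritic_length <= 0)
    stop("total_dendritic_length must be > 0")
  if (p$n_primary > 0 && length(diam_profile) != p$n_levels + 1)
    stop("diam_profile needs n_levels + 1 knots")
  p
}

# membrane area of a tapered cylindrical section (lateral surface), um^2
section_area_um2 <- function(diam_prox, diam_dist, length)
  pi * (diam_prox + diam_dist) / 2 * length

spine_area_um2 <- function(head_diameter = 0.5, head_length = 0.5,
                           neck_diameter = 0.1, neck_length = 1)
  pi * head_diameter * head_length + pi * neck_diameter * neck_length

#' Generate a calibrated synthetic SPN morphology
#'
#' Builds a tree of `n_primary` dendrites that bifurcate at each level.
#' Non-primary section lengths are drawn with uniform jitter, rescaled so
#' the total dendritic length is exact, and the terminal section on the
#' longest root-to-tip path is stretched (compensated across the other
#' terminals to conserve total length) until the maximum path distance hits
#' its target.  Dendritic diameters follow a tapering per-level profile,
#' scaled so that total membrane capacitance -- soma, dendrites and the
#' spines that `place_spines()` will add -- equals the calibration target.
#'
#' @param params a `morpho_params` list.
#' @return an object of class `spn_morphology`: `sections` data frame
#'   (id, parent_id, kind, level, length, diam_prox, diam_dist, path0,
#'   n_segments), `soma_radius`, `spines` (filled by `place_spines`),
#'   and the generating `params`.
#' @export
generate_morphology <- function(params = morpho_params()) {
  stopifnot(inherits(params, "morpho_params"))
  set.seed(params$seed)
  r <- params$soma_radius

  soma <- data.frame(id = 1L, parent_id = NA_integer_, kind = "soma",
                     level = 0L, length = 2 * r, diam_prox = 2 * r,
                     diam_dist = 2 * r, stringsAsFactors = FALSE)

  if (params$n_primary == 0L) {
    m <- list(sections = cbind(soma, path0 = 0, n_segments = 1L),
              soma_radius = r, spines = NULL, params = params)
    class(m) <- "spn_morphology"
    return(m)
  }

  nl <- params$n_levels
  n_at <- params$n_primary * 2^(0:(nl - 1))      # sections per level
  if (nl > 1 && params$max_path_target <= r + params$primary_length)
    stop("infeasible parameters: max_path_target (", params$max_path_target,
         ") must exceed soma_radius + primary_length (",
         r + params$primary_length, ")")

  # mean non-primary level lengths: mildly increasing distally
  rest_total <- params$total_dendritic_length -
    params$n_primary * params$primary_length
  if (nl > 1) {
    if (rest_total <= 0)
      stop("infeasible parameters: total_dendritic_length too small for ",
           params$n_primary, " primaries of length ", params$primary_length)
    w <- seq(1, 1.2, length.out = nl - 1)          # relative level means
    base <- rest_total * w / sum(n_at[-1] * w)
  }

  # build topology level by level
  secs <- soma
  nid <- 1L
  prev_ids <- integer(0)
  for (lev in 1:nl) {
    parents <- if (lev == 1) rep(1L, params$n_primary)
               else rep(prev_ids, each = 2L)
    len <- if (lev == 1) rep(params$primary_length, params$n_primary)
           else base[lev - 1] * stats::runif(length(parents),
                                             1 - params$length_jitter,
                                             1 + params$length_jitter)
    ids <- nid + seq_along(parents)
    secs <- rbind(secs, data.frame(
      id = as.integer(ids), parent_id = as.integer(parents),
      kind = "dendrite", level = lev, length = len,
      diam_prox = params$diam_profile[lev],
      diam_dist = params$diam_profile[lev + 1],
      stringsAsFactors = FALSE))
    nid <- max(ids)
    prev_ids <- ids
  }

  # rescale non-primary lengths so the total is exact
  np <- secs$kind == "dendrite" & secs$level > 1
  if (any(np))
    secs$length[np] <- secs$length[np] * rest_total / sum(secs$length[np])

  # path distance at the proximal end of each section
  compute_path0 <- function(s) {
    p0 <- numeric(nrow(s))
    for (i in seq_len(nrow(s))) {
      if (s$kind[i] == "soma") { p0[i] <- 0; next }
      par <- s$parent_id[i]
      j <- match(par, s$id)
      p0[i] <- if (s$kind[j] == "soma") r else p0[j] + s$length[j]
    }
    p0
  }

  # stretch the deepest terminal (conserving total length across the other
  # terminals) until max path hits the target; iterate to convergence
  term <- secs$level == nl
  for (iter in if (sum(term) > 1) 1:8 else integer(0)) {
    p0 <- compute_path0(secs)
    tips <- p0 + secs$length
    mx <- max(tips[term])
    delta <- params$max_path_target - mx
    if (abs(delta) < 1e-9) break
    k <- which(term & tips == mx)[1]
    others <- which(term)[which(term) != k]
    secs$length[k] <- secs$length[k] + delta
    secs$length[others] <- secs$length[others] - delta / length(others)
    if (any(secs$length[term] < 2))
      stop("infeasible parameters: max_path_target requires a terminal ",
           "section shorter than 2 um; increase total_dendritic_length")
  }
  secs$path0 <- compute_path0(secs)

  # diameter scaling for the capacitance target (lateral areas, 1 uF/cm^2:
  # 1 um^2 = 0.01 pF)
  dend <- secs$kind == "dendrite"
  elig <- pmax(0, secs$path0[dend] + secs$length[dend] -
                  pmax(secs$path0[dend], params$spine_min_path))
  n_spines <- floor(sum(elig) * params$spine_density)
  c_soma <- 4 * pi * r^2 * 0.01
  c_spines <- n_spines * spine_area_um2() * 0.01
  c_dend_unit <- sum(section_area_um2(secs$diam_prox[dend],
                                      secs$diam_dist[dend],
                                      secs$length[dend])) * 0.01
  s <- (params$capacitance_target_pF - c_soma - c_spines) / c_dend_unit
  if (s <= 0)
    stop("infeasible parameters: capacitance_target_pF (",
         params$capacitance_target_pF, " pF) is below the soma plus spine ",
         "contribution (", round(c_soma + c_spines, 1), " pF)")
  secs$diam_prox[dend] <- secs$diam_prox[dend] * s
  secs$diam_dist[dend] <- secs$diam_dist[dend] * s

  # segmentization: odd per-section counts near the target segment length
  nseg <- pmax(1, round(secs$length / params$seg_length_um))
  nseg <- ifelse(nseg %% 2 == 0, nseg + 1, nseg)
  nseg[secs$kind == "soma"] <- 1L
  secs$n_segments <- as.integer(nseg)

  m <- list(sections = secs, soma_radius = r, spines = NULL, params = params)
  class(m) <- "spn_morphology"
  m$spines <- place_spines(m, params$spine_density, params$spine_min_path)
  m
}

#' Path distance from the soma centre
#'
#' Distance measured along the tree from the centre of the soma; the soma
#' surface is at `soma_radius` and distances add along the unique path to
#' the root.
#'
#' @param morph an `spn_morphology`.
#' @param section_id section id.
#' @param arc_position fraction in 0..1 along the section.
#' @return path distance in um.
#' @export
path_distance <- function(morph, section_id, arc_position = 0.5) {
  s <- morph$sections
  j <- match(section_id, s$id)
  if (any(is.na(j))) stop("unknown section id: ",
                          paste(section_id[is.na(j)], collapse = ", "))
  ifelse(s$kind[j] == "soma", arc_position * morph$soma_radius,
         s$path0[j] + arc_position * s$length[j])
}

#' Maximum soma-to-tip path distance of a morphology (um)
#' @param morph an `spn_morphology`.
#' @export
max_path_distance <- function(morph) {
  s <- morph$sections
  d <- s$kind == "dendrite"
  if (!any(d)) return(morph$soma_radius)
  max(s$path0[d] + s$length[d])
}

#' Place spines on the dendritic tree
#'
#' Spines are placed deterministically at even spacing on all dendrite
#' beyond `min_path` from the soma centre.  Counts are `floor(eligible
#' length x density)` with the fractional remainder carried across sections
#' in id order, so the global count equals `floor(total eligible length x
#' density)`.
#'
#' @param morph an `spn_morphology`.
#' @param density spines per um (>= 0).
#' @param min_path placement floor in um of path distance.
#' @return data frame (section_id, arc_position, path, neck_length,
#'   neck_diameter, head_diameter, head_length), possibly empty.
#' @export
place_spines <- function(morph, density = 1.711, min_path = 30) {
  if (density < 0) stop("density must be >= 0")
  s <- morph$sections
  dend <- which(s$kind == "dendrite")
  out <- list()
  cum <- 0
  for (i in dend) {
    lo_path <- max(s$path0[i], min_path)
    hi_path <- s$path0[i] + s$length[i]
    el <- hi_path - lo_path
    if (el <= 0 || density == 0) next
    new_cum <- cum + el * density
    k <- floor(new_cum) - floor(cum)
    cum <- new_cum
    if (k < 1) next
    pos_path <- lo_path + (seq_len(k) - 0.5) / k * el
    out[[length(out) + 1]] <- data.frame(
      section_id = s$id[i],
      arc_position = (pos_path - s$path0[i]) / s$length[i],
      path = pos_path)
  }
  if (!length(out))
    return(data.frame(section_id = integer(0), arc_position = numeric(0),
                      path = numeric(0), neck_length = numeric(0),
                      neck_diameter = numeric(0), head_diameter = numeric(0),
                      head_length = numeric(0)))
  sp <- do.call(rbind, out)
  sp$neck_length <- 1; sp$neck_diameter <- 0.1
  sp$head_diameter <- 0.5; sp$head_length <- 0.5
  rownames(sp) <- NULL
  sp
}

#' Total membrane capacitance of a morphology (pF)
#'
#' Lateral cylinder areas at 1 uF/cm^2 (0.01 pF per um^2); the soma is an
#' equivalent sphere.  Spine membrane is included when spines are present.
#'
#' @param morph an `spn_morphology`.
#' @param include_spines logical.
#' @export
total_capacitance_pF <- function(morph, include_spines = TRUE) {
  s <- morph$sections
  c_soma <- 4 * pi * morph$soma_radius^2 * 0.01
  d <- s$kind == "dendrite"
  c_dend <- if (any(d))
    sum(section_area_um2(s$diam_prox[d], s$diam_dist[d], s$length[d])) * 0.01
  else 0
  c_sp <- if (include_spines && !is.null(morph$spines) && nrow(morph$spines))
    sum(spine_area_um2(morph$spines$head_diameter, morph$spines$head_length,
                       morph$spines$neck_diameter, morph$spines$neck_length)) *
      0.01
  else 0
  c_soma + c_dend + c_sp
}

# ---------------------------------------------------------------- SWC I/O

#' Write a morphology to SWC (with a CSV spine sidecar)
#'
#' 3-D coordinates are synthesized (straight sections, random orientations
#' seeded from the morphology parameters); only lengths and radii carry
#' electrical meaning.  Each section is emitted as a zero-length proximal
#' sample (carrying the proximal radius) followed by its distal sample, so
#' lengths and both radii survive a round trip.  Spines are not part of the
#' SWC standard and go to `<path>.spines.csv` when present.
#'
#' @param morph an `spn_morphology`.
#' @param path output file.
#' @export
write_swc <- function(morph, path) {
  s <- morph$sections
  seed <- if (!is.null(morph$params)) morph$params$seed else 0L
  set.seed(seed + 7919L)
  dirs <- matrix(stats::rnorm(3 * nrow(s)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))

  lines <- character(0)
  samp <- 0L
  end_xyz <- list(); end_samp <- integer(nrow(s))
  for (i in seq_len(nrow(s))) {
    if (s$kind[i] == "soma") {
      samp <- samp + 1L
      lines <- c(lines, sprintf("%d 1 0 0 0 %.6f -1", samp,
                                morph$soma_radius))
      end_xyz[[i]] <- c(0, 0, 0); end_samp[i] <- samp
      next
    }
    j <- match(s$parent_id[i], s$id)
    origin <- end_xyz[[j]]
    tip <- origin + dirs[i, ] * s$length[i]
    samp <- samp + 1L
    lines <- c(lines, sprintf("%d 3 %.6f %.6f %.6f %.6f %d", samp,
                              origin[1], origin[2], origin[3],
                              s$diam_prox[i] / 2, end_samp[j]))
    prox_samp <- samp
    samp <- samp + 1L
    lines <- c(lines, sprintf("%d 3 %.6f %.6f %.6f %.6f %d", samp,
                              tip[1], tip[2], tip[3], s$diam_dist[i] / 2,
                              prox_samp))
    end_xyz[[i]] <- tip; end_samp[i] <- samp
  }
  writeLines(c("# generated by spnsim", lines), path)
  if (!is.null(morph$spines) && nrow(morph$spines))
    utils::write.csv(morph$spines, paste0(path, ".spines.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' Read a morphology from SWC
#'
#' Accepts well-formed SWC (sample, type, x, y, z, radius, parent).
#' Maximal unbranched chains of same-type samples become sections;
#' zero-length leading segments carry the proximal radius (as written by
#' [write_swc()]).  A `<path>.spines.csv` sidecar is loaded when present.
#'
#' @param path SWC file.
#' @return an `spn_morphology`.
#' @export
read_swc <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  rows <- which(keep)
  if (!length(rows)) stop("no samples in SWC file")
  fields <- strsplit(trimws(raw[rows]), "\\s+")
  bad <- which(vapply(fields, length, 1L) != 7L)
  if (length(bad))
    stop("malformed SWC line ", rows[bad[1]], ": expected 7 fields")
  tab <- do.call(rbind, lapply(fields, as.numeric))
  if (any(!is.finite(tab)))
    stop("malformed SWC line ",
         rows[which(rowSums(!is.finite(tab)) > 0)[1]], ": non-numeric field")
  colnames(tab) <- c("id", "type", "x", "y", "z", "r", "parent")
  ids <- tab[, "id"]
  orphan <- tab[, "parent"] != -1 & !(tab[, "parent"] %in% ids)
  if (any(orphan))
    stop("orphan parent reference at SWC line ", rows[which(orphan)[1]])

  soma_rows <- which(tab[, "type"] == 1)
  if (!length(soma_rows)) stop("SWC has no soma sample (type 1)")
  root <- soma_rows[1]
  soma_radius <- tab[root, "r"]

  sections <- data.frame(id = 1L, parent_id = NA_integer_, kind = "soma",
                         level = 0L, length = 2 * soma_radius,
                         diam_prox = 2 * soma_radius,
                         diam_dist = 2 * soma_radius,
                         stringsAsFactors = FALSE)
  children <- split(seq_len(nrow(tab)),
                    factor(tab[, "parent"], levels = ids))
  kids_of <- function(row) {
    k <- children[[as.character(ids[row])]]
    if (is.null(k)) integer(0) else k
  }
  soma_set <- ids[soma_rows]

  # walk unbranched chains outward from the soma; branch points spawn
  # new sections
  sec_id <- 1L
  queue <- which(tab[, "type"] != 1 & tab[, "parent"] %in% soma_set)
  parent_sec <- rep(1L, length(queue))
  qi <- 1L
  while (qi <= length(queue)) {
    row <- queue[qi]; psec <- parent_sec[qi]; qi <- qi + 1L
    chain <- row
    repeat {
      k <- kids_of(chain[length(chain)])
      if (length(k) != 1) break
      chain <- c(chain, k)
    }
    pts <- tab[chain, , drop = FALSE]
    prow <- match(pts[1, "parent"], ids)
    origin <- tab[prow, c("x", "y", "z")]
    xyz <- rbind(origin, pts[, c("x", "y", "z"), drop = FALSE])
    seglen <- sqrt(rowSums(diff(xyz)^2))
    len <- sum(seglen)
    if (len <= 0) stop("zero-length section at SWC line ", rows[row])
    sec_id <- sec_id + 1L
    sections <- rbind(sections, data.frame(
      id = sec_id, parent_id = psec, kind = "dendrite", level = NA_integer_,
      length = len, diam_prox = 2 * pts[1, "r"],
      diam_dist = 2 * pts[nrow(pts), "r"], stringsAsFactors = FALSE))
    tails <- kids_of(chain[length(chain)])
    if (length(tails)) {
      queue <- c(queue, tails)
      parent_sec <- c(parent_sec, rep(sec_id, length(tails)))
    }
  }

  # path0 and level
  sections$path0 <- 0
  for (i in seq_len(nrow(sections))) {
    if (sections$kind[i] == "soma") next
    j <- match(sections$parent_id[i], sections$id)
    sections$path0[i] <- if (sections$kind[j] == "soma") soma_radius
                         else sections$path0[j] + sections$length[j]
    sections$level[i] <- if (sections$kind[j] == "soma") 1L
                         else sections$level[j] + 1L
  }
  sections$n_segments <- as.integer(pmax(1, 2 * round(sections$length /
                                                        4.75 / 2) + 1))
  sections$n_segments[sections$kind == "soma"] <- 1L

  m <- list(sections = sections, soma_radius = soma_radius, spines = NULL,
            params = NULL)
  class(m) <- "spn_morphology"
  sidecar <- paste0(path, ".spines.csv")
  if (file.exists(sidecar)) m$spines <- utils::read.csv(sidecar)
  m
}

#' @export
print.spn_morphology <- function(x, ...) {
  s <- x$sections
  nd <- sum(s$kind == "dendrite")
  cat("spn_morphology:", nd, "dendritic sections,",
      if (!is.null(x$spines)) nrow(x$spines) else 0, "spines\n")
  cat(sprintf("  total dendritic length %.1f um, max path %.3f um\n",
              sum(s$length[s$kind == "dendrite"]), max_path_distance(x)))
  cat(sprintf("  whole-cell capacitance %.1f pF (with spines)\n",
              total_capacitance_pF(x)))
  invisible(x)
}
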