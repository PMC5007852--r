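#' Generate a phagocytosis scene with known engulfed fraction
#'
#' Places disk-shaped cells, then particle disks centered on cell pixels until
#' the engulfed area reaches \code{round(engulfed_fraction * cell_area)}
#' pixels (the last particle is trimmed so the realized fraction matches the
#' request to within one pixel), plus distractor particles that do not touch
#' any cell.  The stored truth is recomputed from exact pixel counts.
#'
#' @param n_cells number of cells (>= 1; the index is undefined without
#'   cells).
#' @param engulfed_fraction requested engulfed-area fraction in [0, 1].
#' @param dims scene size (y, x) in px.
#' @param cell_radius_px,particle_radius_px disk radii.
#' @param n_distractors particles placed clear of every cell.
#' @param seed optional RNG seed.
#' @return list: \code{cell_mask}, \code{particle_mask},
#'   \code{truth_engulfed_fraction}.
#' @export
generate_phagocytosis_scene <- function(n_cells, engulfed_fraction,
                                        dims = c(256, 256),
                                        cell_radius_px = 14,
                                        particle_radius_px = 3,
                                        n_distractors = 5, seed = NULL) {
  if (n_cells < 1) stop("phagocytic index undefined without cells")
  stopifnot(engulfed_fraction >= 0, engulfed_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  cell <- matrix(FALSE, dims[1], dims[2])
  pad <- cell_radius_px + 2
  for (i in seq_len(n_cells)) {
    cell <- stamp_disk(cell, stats::runif(1, pad, dims[1] - pad),
                       stats::runif(1, pad, dims[2] - pad),
                       cell_radius_px * stats::runif(1, 0.8, 1.2))
  }
  a_cell <- sum(cell)
  target <- round(engulfed_fraction * a_cell)
  particle <- matrix(FALSE, dims[1], dims[2])
  cell_idx <- which(cell)
  guard <- 0L
  while (sum(particle & cell) < target) {
    ctr <- cell_idx[sample.int(length(cell_idx), 1)]
    cy <- ((ctr - 1L) %% dims[1]) + 1L
    cx <- ((ctr - 1L) %/% dims[1]) + 1L
    cand <- stamp_disk(matrix(FALSE, dims[1], dims[2]), cy, cx,
                       particle_radius_px)
    new_in <- which(cand & cell & !particle)
    excess <- (sum(particle & cell) + length(new_in)) - target
    if (excess > 0) new_in <- new_in[seq_len(length(new_in) - excess)]
    particle[new_in] <- TRUE
    particle[cand & !cell] <- TRUE          # spill-over outside cells is fine
    guard <- guard + 1L
    if (guard > 50L * a_cell) stop("failed to reach requested fraction")
  }
  # distractors: particles that never touch a cell
  for (i in seq_len(n_distractors)) {
    for (try in 1:200) {
      cy <- stats::runif(1, particle_radius_px + 1, dims[1] - particle_radius_px)
      cx <- stats::runif(1, particle_radius_px + 1, dims[2] - particle_radius_px)
      cand <- stamp_disk(matrix(FALSE, dims[1], dims[2]), cy, cx,
                         particle_radius_px)
      if (!any(cand & cell)) { particle <- particle | cand; break }
    }
  }
  list(cell_mask = cell, particle_mask = particle,
       truth_engulfed_fraction = sum(particle & cell) / a_cell)
}

#' Generate a binary scent-mark sheet with known preference
#'
#' Blob centers fall inside the target circle with probability
#' \code{target_bias} and uniformly over the arena otherwise; blobs are
#' stamped as disks.  The stored truth preference is the exact pixel-count
#' ratio over the generated sheet.
#'
#' @param n_blobs number of mark blobs (0 gives an undefined, flagged truth).
#' @param target_bias probability that a blob center falls in the target
#'   circle.
#' @param blob_radius_cm mean blob radius (cm); per-blob radii jitter around
#'   it.
#' @param geometry a [mark_geometry()].
#' @param seed optional RNG seed.
#' @return list: \code{sheet} (logical matrix), \code{truth_preference}
#'   (percent, NA with \code{undefined} attribute when empty),
#'   \code{geometry}.
#' @export
generate_mark_sheet <- function(n_blobs = 25, target_bias = 0.5,
                                blob_radius_cm = 0.5,
                                geometry = mark_geometry(), seed = NULL) {
  stopifnot(inherits(geometry, "mark_geometry"), n_blobs >= 0,
            target_bias >= 0, target_bias <= 1)
  if (!is.null(seed)) set.seed(seed)
  ppc <- geometry$px_per_cm
  side <- round(geometry$arena_cm * ppc)
  sheet <- matrix(FALSE, side, side)
  tgt <- geometry$centers[geometry$target_quadrant, ]
  for (i in seq_len(n_blobs)) {
    rad_cm <- blob_radius_cm * stats::runif(1, 0.5, 1.5)
    if (stats::runif(1) < target_bias) {
      # uniform in the target circle, with the whole blob kept inside it
      a <- stats::runif(1, 0, 2 * pi)
      rmax <- max(0, geometry$radius_cm - rad_cm - 1 / ppc)
      r <- rmax * sqrt(stats::runif(1))
      ctr <- tgt + r * c(sin(a), cos(a))
    } else {
      ctr <- stats::runif(2, 0, geometry$arena_cm)
    }
    sheet <- stamp_disk(sheet, ctr[1] * ppc + 0.5, ctr[2] * ppc + 0.5,
                        rad_cm * ppc)
  }
  # truth from an explicit pixel-membership count (kept independent of the
  # assay-side computation)
  total <- sum(sheet)
  if (total == 0) {
    truth <- structure(NA_real_, undefined = TRUE)
  } else {
    co <- which(sheet, arr.ind = TRUE)
    d2 <- ((co[, 1] - 0.5) / ppc - tgt[1])^2 + ((co[, 2] - 0.5) / ppc - tgt[2])^2
    truth <- structure(100 * sum(d2 <= geometry$radius_cm^2) / total,
                       undefined = FALSE)
  }
  list(sheet = sheet, truth_preference = truth, geometry = geometry)
}

#' Track specification
#'
#' @param duration_s recording duration (default 30 min).
#' @param frame_interval_s frame spacing.
#' @param propensity_social,propensity_object,propensity_elsewhere relative
#'   stationary occupancies of the two investigation zones and the rest of
#'   the arena.
#' @param persistence per-frame probability of keeping the current zone state
#'   (bout structure); the stationary occupancy is unaffected.
#' @param geometry an [si_geometry()].
#' @return a \code{track_spec} list.
#' @export
track_spec <- function(duration_s = 1800, frame_interval_s = 0.1,
                       propensity_social = 1, propensity_object = 1,
                       propensity_elsewhere = 8, persistence = 0.98,
                       geometry = si_geometry()) {
  stopifnot(frame_interval_s > 0, duration_s > 0,
            propensity_social >= 0, propensity_object >= 0,
            propensity_elsewhere > 0, persistence >= 0, persistence < 1)
  structure(list(duration_s = duration_s, frame_interval_s = frame_interval_s,
                 propensities = c(social = propensity_social,
                                  object = propensity_object,
                                  elsewhere = propensity_elsewhere),
                 persistence = persistence, geometry = geometry),
            class = "track_spec")
}

#' Generate a locomotion track with known zone dwell times
#'
#' Zone states follow a sticky Markov chain whose stationary distribution is
#' exactly the normalized propensities (with probability \code{persistence}
#' the state is kept, otherwise it is redrawn from the propensity
#' distribution); positions are drawn uniformly within the current zone
#' (investigation annulus, or the arena outside both zones).  Truth dwell
#' durations are exact per-frame membership counts times the frame interval.
#'
#' @param spec a [track_spec()].
#' @param seed optional RNG seed.
#' @return list: \code{track} (tibble t, x, y), \code{truth_dwell_s} (named:
#'   social, object, elsewhere), \code{truth_quotient} (NA + flag when the
#'   object zone is never visited), \code{geometry}.
#' @export
generate_track <- function(spec = track_spec(), seed = NULL) {
  stopifnot(inherits(spec, "track_spec"))
  if (!is.null(seed)) set.seed(seed)
  geom <- spec$geometry
  n <- floor(spec$duration_s / spec$frame_interval_s)
  prob <- spec$propensities / sum(spec$propensities)
  # sticky chain: keep the state with prob persistence, else redraw from the
  # propensity distribution (stationary distribution = prob exactly)
  seg_id <- cumsum(stats::runif(n) >= spec$persistence) + 1L
  draws <- sample(names(prob), max(seg_id), replace = TRUE, prob = prob)
  states <- draws[seg_id]
  r_cyl <- geom$cylinder_radius_cm
  r_zone <- geom$zone_radius_cm
  pos <- matrix(0, n, 2)
  for (zone in c("social", "object")) {
    k <- which(states == zone)
    if (!length(k)) next
    ang <- stats::runif(length(k), 0, 2 * pi)
    r <- sqrt(stats::runif(length(k), r_cyl^2, r_zone^2))
    pos[k, 1] <- geom$centers[zone, 1] + r * sin(ang)
    pos[k, 2] <- geom$centers[zone, 2] + r * cos(ang)
  }
  k <- which(states == "elsewhere")
  while (length(k)) {                    # batched rejection sampling
    cand <- matrix(stats::runif(2 * length(k), 0, geom$arena_cm), ncol = 2)
    d1 <- sqrt((cand[, 1] - geom$centers["social", 1])^2 +
                 (cand[, 2] - geom$centers["social", 2])^2)
    d2 <- sqrt((cand[, 1] - geom$centers["object", 1])^2 +
                 (cand[, 2] - geom$centers["object", 2])^2)
    ok <- d1 > r_zone & d2 > r_zone
    pos[k[ok], ] <- cand[ok, , drop = FALSE]
    k <- k[!ok]
  }
  track <- tibble::tibble(t = (seq_len(n) - 1) * spec$frame_interval_s,
                          x = pos[, 2], y = pos[, 1])
  dwell <- c(social = sum(states == "social"),
             object = sum(states == "object"),
             elsewhere = sum(states == "elsewhere")) * spec$frame_interval_s
  quot <- if (dwell["object"] == 0) structure(NA_real_, undefined = TRUE)
          else structure(unname(dwell["social"] / dwell["object"]),
                         undefined = FALSE)
  list(track = track, truth_dwell_s = dwell, truth_quotient = quot,
       geometry = geom)
}

#' Flow population specification
#'
#' Per-population event counts and per-channel log10 mean/sd.  Channels are
#' the union over populations; missing channels default to mean 1, sd 0.1.
#'
#' @param populations named list; each element a list with \code{n} and
#'   \code{channels} (named list of c(mean, sd) on the log10 scale, sd > 0).
#' @return a \code{flow_spec} list.
#' @export
flow_spec <- function(populations) {
  stopifnot(is.list(populations), length(populations) > 0,
            !is.null(names(populations)))
  for (p in populations) {
    stopifnot(p$n >= 0)
    for (ch in p$channels) stopifnot(length(ch) == 2, ch[2] > 0)
  }
  structure(list(populations = populations), class = "flow_spec")
}

#' Study-like default flow populations
#'
#' A CD11b-hi parent population split into CD45-lo microglia (with a CD68-hi
#' phagocytic subset) and CD45-hi infiltrating macrophages, plus CD11b-lo
#' debris excluded by the parent gate.
#'
#' @param n_events total events.
#' @param frac_cd45hi fraction of the CD11b-hi population that is CD45-hi.
#' @param frac_cd68hi CD68-hi fraction within the CD45-lo microglia.
#' @param sep_sd separation between lo and hi channel means, in sd units.
#' @param sd log10 channel sd.
#' @return a \code{flow_spec}.
#' @export
default_flow_populations <- function(n_events = 10000, frac_cd45hi = 0.10,
                                     frac_cd68hi = 0.25, sep_sd = 8,
                                     sd = 0.15) {
  lo <- 2; hi <- 2 + sep_sd * sd
  n_deb <- round(0.2 * n_events)
  n_p <- n_events - n_deb
  n_mac <- round(frac_cd45hi * n_p)
  n_mg <- n_p - n_mac
  n_mg_hi <- round(frac_cd68hi * n_mg)
  flow_spec(list(
    debris = list(n = n_deb, channels = list(
      CD11b = c(lo, sd), CD45 = c(lo, sd), CD68 = c(lo, sd))),
    microglia_cd68lo = list(n = n_mg - n_mg_hi, channels = list(
      CD11b = c(hi, sd), CD45 = c(lo, sd), CD68 = c(lo, sd))),
    microglia_cd68hi = list(n = n_mg_hi, channels = list(
      CD11b = c(hi, sd), CD45 = c(lo, sd), CD68 = c(hi, sd))),
    macrophage = list(n = n_mac, channels = list(
      CD11b = c(hi, sd), CD45 = c(hi, sd), CD68 = c(lo, sd)))))
}

#' Generate a flow-cytometry event table with truth labels
#'
#' Event intensities are lognormal per channel (normal on log10 scale with
#' the population's mean/sd).  The per-event truth label is retained and the
#' truth fractions are exact label counts.
#'
#' @param spec a [flow_spec()].
#' @param seed optional RNG seed.
#' @return list: \code{events} (tibble, one channel column per channel plus
#'   \code{truth_label}), \code{truth_counts}, \code{truth_fractions}.
#' @export
generate_flow_events <- function(spec = default_flow_populations(),
                                 seed = NULL) {
  stopifnot(inherits(spec, "flow_spec"))
  if (!is.null(seed)) set.seed(seed)
  channels <- unique(unlist(lapply(spec$populations,
                                   function(p) names(p$channels))))
  rows <- lapply(names(spec$populations), function(nm) {
    p <- spec$populations[[nm]]
    if (p$n == 0) return(NULL)
    vals <- lapply(channels, function(ch) {
      pars <- if (ch %in% names(p$channels)) p$channels[[ch]] else c(1, 0.1)
      10^stats::rnorm(p$n, pars[1], pars[2])
    })
    names(vals) <- channels
    out <- tibble::as_tibble(vals)
    out$truth_label <- nm
    out
  })
  events <- dplyr::bind_rows(rows)
  if (nrow(events) == 0) {
    events <- tibble::as_tibble(c(
      stats::setNames(lapply(channels, function(ch) numeric(0)), channels),
      list(truth_label = character(0))))
  }
  counts <- table(factor(events$truth_label, levels = names(spec$populations)))
  list(events = events, truth_counts = as.integer(counts),
       truth_fractions = as.numeric(counts) / max(1, nrow(events)),
       population_names = names(spec$populations))
}
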