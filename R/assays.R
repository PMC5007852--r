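#' Phagocytic index
#'
#' Total engulfed particle area divided by total cell area: the fraction of
#' cell-marker pixels covered by particle signal.  Particle signal outside the
#' cell masks does not count.
#'
#' @param cell_mask logical matrix of cell-marker signal (e.g. CD11b+).
#' @param particle_mask logical matrix of labelled-particle signal.
#' @return fraction in [0, 1].
#' @export
phagocytic_index <- function(cell_mask, particle_mask) {
  stopifnot(identical(dim(cell_mask), dim(particle_mask)))
  a_cell <- sum(cell_mask)
  if (a_cell == 0) stop("zero cell area: phagocytic index undefined")
  sum(particle_mask & cell_mask) / a_cell
}

#' Count cells colocalized with a marker
#'
#' A cell counts as colocalized when its soma centroid (rounded to the
#' nearest pixel) lies inside the marker mask.
#'
#' @param soma_labels integer label matrix of somas (0 = background).
#' @param marker_mask logical matrix of the marker channel.
#' @return integer count.
#' @export
count_colocalized <- function(soma_labels, marker_mask) {
  stopifnot(identical(dim(soma_labels), dim(marker_mask)))
  ids <- setdiff(unique(as.integer(soma_labels)), 0L)
  if (length(ids) == 0) return(0L)
  co <- which(soma_labels > 0, arr.ind = TRUE)
  lab <- soma_labels[soma_labels > 0]
  n <- 0L
  for (id in ids) {
    cy <- round(mean(co[lab == id, 1]))
    cx <- round(mean(co[lab == id, 2]))
    if (marker_mask[cy, cx]) n <- n + 1L
  }
  n
}

#' Count cells within a region window
#'
#' @param soma_labels integer label matrix of somas.
#' @param window c(y0, y1, x0, x1) inclusive bounds; must lie within the
#'   image.
#' @return number of cells whose soma centroid falls inside the window.
#' @export
count_cells <- function(soma_labels, window = c(1, nrow(soma_labels),
                                                1, ncol(soma_labels))) {
  stopifnot(length(window) == 4,
            window[1] >= 1, window[2] <= nrow(soma_labels),
            window[3] >= 1, window[4] <= ncol(soma_labels))
  ids <- setdiff(unique(as.integer(soma_labels)), 0L)
  if (length(ids) == 0) return(0L)
  co <- which(soma_labels > 0, arr.ind = TRUE)
  lab <- soma_labels[soma_labels > 0]
  n <- 0L
  for (id in ids) {
    cy <- mean(co[lab == id, 1]); cx <- mean(co[lab == id, 2])
    if (cy >= window[1] && cy <= window[2] && cx >= window[3] && cx <= window[4])
      n <- n + 1L
  }
  n
}

#' Gate specification
#'
#' Rectangular parent/child gate on event-channel values.  Thresholds apply
#' to the values as given; when gating raw cytometry intensities, transform
#' the table (e.g. asinh) before building the gate, with thresholds on the
#' same scale.
#'
#' @param parent_channel,child_channel column names; must differ.
#' @param parent_min,parent_max,child_min,child_max finite-or-infinite bounds
#'   (events pass when min <= value < max).
#' @return a \code{gate_spec} list.
#' @export
gate_spec <- function(parent_channel, child_channel,
                      parent_min = -Inf, parent_max = Inf,
                      child_min = -Inf, child_max = Inf) {
  if (identical(parent_channel, child_channel))
    stop("child channel must differ from parent channel")
  structure(list(parent_channel = parent_channel, child_channel = child_channel,
                 parent_min = parent_min, parent_max = parent_max,
                 child_min = child_min, child_max = child_max),
            class = "gate_spec")
}

#' Fraction of parent-gated events passing the child gate
#'
#' @param events data frame with one row per event and one column per
#'   channel.
#' @param gate a \code{gate_spec}.
#' @return fraction in [0, 1].
#' @export
gate_fraction <- function(events, gate) {
  stopifnot(inherits(gate, "gate_spec"),
            all(c(gate$parent_channel, gate$child_channel) %in% names(events)))
  pv <- events[[gate$parent_channel]]
  parent <- pv >= gate$parent_min & pv < gate$parent_max
  if (!any(parent)) stop("empty parent population")
  cv <- events[[gate$child_channel]][parent]
  sum(cv >= gate$child_min & cv < gate$child_max) / sum(parent)
}

#' Urine-marking arena geometry
#'
#' Square arena with four circles, one per quadrant, each tangent to the two
#' outer edges of its quadrant; the target circle is centered on the female
#' urine spot.
#'
#' @param arena_cm arena side (cm).
#' @param circle_diameter_cm scoring circle diameter (cm).
#' @param px_per_cm sheet resolution.
#' @param target_quadrant which quadrant (1 = top-left, 2 = top-right,
#'   3 = bottom-left, 4 = bottom-right) holds the female-urine circle.
#' @return a \code{mark_geometry} list with circle centers (cm) and radius.
#' @export
mark_geometry <- function(arena_cm = 46, circle_diameter_cm = 20,
                          px_per_cm = 5, target_quadrant = 1L) {
  r <- circle_diameter_cm / 2
  a <- arena_cm
  centers <- rbind(c(r, r), c(r, a - r), c(a - r, r), c(a - r, a - r))
  stopifnot(target_quadrant %in% 1:4)
  structure(list(arena_cm = a, radius_cm = r, px_per_cm = px_per_cm,
                 centers = centers, target_quadrant = as.integer(target_quadrant)),
            class = "mark_geometry")
}

in_circle <- function(dims, center_cm, radius_cm, px_per_cm) {
  yy <- (matrix(seq_len(dims[1]), dims[1], dims[2]) - 0.5) / px_per_cm
  xx <- (t(matrix(seq_len(dims[2]), dims[2], dims[1])) - 0.5) / px_per_cm
  (yy - center_cm[1])^2 + (xx - center_cm[2])^2 <= radius_cm^2
}

#' Marking preference
#'
#' 100 x (mark pixels inside the target circle) / (mark pixels in the arena).
#' Undefined (NA, flagged) when the sheet carries no marks.
#'
#' @param sheet logical matrix, the binarized scent-mark sheet.
#' @param geometry a \code{mark_geometry}.
#' @return percent in [0, 100] with attribute \code{undefined}; \code{NA}
#'   and \code{undefined = TRUE} when total mark area is zero.
#' @export
marking_preference <- function(sheet, geometry = mark_geometry()) {
  stopifnot(inherits(geometry, "mark_geometry"))
  total <- sum(sheet)
  if (total == 0)
    return(structure(NA_real_, undefined = TRUE))
  circ <- in_circle(dim(sheet), geometry$centers[geometry$target_quadrant, ],
                    geometry$radius_cm, geometry$px_per_cm)
  structure(100 * sum(sheet & circ) / total, undefined = FALSE)
}

#' Social-interaction zone geometry
#'
#' Open-field arena with two cylinders in opposing corners, their walls a
#' fixed distance from the two adjacent arena edges; the investigation zone
#' of each cylinder is the annulus within \code{zone_width_cm} of its wall.
#'
#' @param arena_cm arena side (cm).
#' @param cylinder_diameter_cm cylinder diameter (cm).
#' @param wall_offset_cm distance from cylinder wall to the two adjacent
#'   edges (cm).
#' @param zone_width_cm investigation annulus width beyond the wall (cm).
#' @return an \code{si_geometry} list; construction fails if the two zones
#'   overlap.
#' @export
si_geometry <- function(arena_cm = 50, cylinder_diameter_cm = 10,
                        wall_offset_cm = 10, zone_width_cm = 2) {
  r <- cylinder_diameter_cm / 2
  c1 <- wall_offset_cm + r
  centers <- rbind(social = c(c1, c1),
                   object = c(arena_cm - c1, arena_cm - c1))
  zone_r <- r + zone_width_cm
  if (sqrt(sum((centers[1, ] - centers[2, ])^2)) <= 2 * zone_r)
    stop("investigation zones overlap")
  structure(list(arena_cm = arena_cm, cylinder_radius_cm = r,
                 zone_radius_cm = zone_r, centers = centers),
            class = "si_geometry")
}

track_zone <- function(track, geometry) {
  d_soc <- sqrt((track$y - geometry$centers["social", 1])^2 +
                  (track$x - geometry$centers["social", 2])^2)
  d_obj <- sqrt((track$y - geometry$centers["object", 1])^2 +
                  (track$x - geometry$centers["object", 2])^2)
  ifelse(d_soc <= geometry$zone_radius_cm, "social",
         ifelse(d_obj <= geometry$zone_radius_cm, "object", "elsewhere"))
}

#' Social-interaction quotient
#'
#' Ratio of time spent in the social-cylinder investigation zone to time in
#' the empty-cylinder zone, from per-frame zone membership times the frame
#' interval.  Undefined (NA, flagged) when no frame falls in the object zone.
#'
#' @param track data frame with columns \code{t} (s), \code{x}, \code{y}
#'   (cm).
#' @param geometry an \code{si_geometry}.
#' @return quotient >= 0 with attribute \code{undefined}.
#' @export
si_quotient <- function(track, geometry = si_geometry()) {
  stopifnot(all(c("t", "x", "y") %in% names(track)), nrow(track) >= 2)
  dt <- stats::median(diff(track$t))
  zone <- track_zone(track, geometry)
  t_soc <- sum(zone == "social") * dt
  t_obj <- sum(zone == "object") * dt
  if (t_obj == 0) return(structure(NA_real_, undefined = TRUE))
  structure(t_soc / t_obj, undefined = FALSE)
}
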