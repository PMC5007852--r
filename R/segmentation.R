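#' Segmentation parameters
#'
#' Tunables of the seeded iterative-threshold segmentation.  Fractional
#' quantities (h-maxima depth, threshold step) are expressed relative to the
#' image dynamic range.  Defaults are chosen for 0.42 um/px microglia imagery.
#'
#' @param smoothing_sigma_px Gaussian smoothing applied before seed detection.
#' @param h_maxima_depth regional-maxima prominence as a fraction of the
#'   dynamic range, in (0, 1).  Deep enough that intensity bumps where two
#'   processes cross (which reach roughly twice the smoothed process ridge)
#'   are not promoted to seeds, while somas retain several times this
#'   prominence.
#' @param min_seed_separation_px minimum distance between retained seeds; on
#'   conflict the brighter seed wins.
#' @param min_seed_intensity_frac seeds must reach this fraction of the
#'   smoothed dynamic range above the smoothed minimum; rejects residual
#'   bright spots along processes (wide branch junctions) that survive the
#'   prominence criterion, since somas sit far above them in intensity.
#' @param threshold_step decrement of the threshold ladder, as a fraction of
#'   the dynamic range, in (0, 1).
#' @param growth_stop_ratio stop growing a mask when its area grows by more
#'   than this factor in one step.  Flooding into background is an explosive
#'   (>> 10x) jump; ramified cells show a legitimate ~5-6x jump when the
#'   ladder crosses the process intensity, so the default sits between the
#'   two.
#' @param noise_floor_sd the ladder never descends below a robust background
#'   estimate (median) plus this many robust sds (MAD); thresholding inside
#'   the noise floor is meaningless and only fattens masks.
#' @param area_bounds_px accepted cell mask area range (min, max), px^2.
#' @param border_margin_px masks within this margin of the frame are rejected.
#' @param soma_intensity_fraction soma threshold as a fraction of the seed
#'   peak intensity, in (0, 1).
#' @return a \code{segmentation_params} list.
#' @export
segmentation_params <- function(smoothing_sigma_px = 2, h_maxima_depth = 0.20,
                                min_seed_separation_px = 10,
                                min_seed_intensity_frac = 0.5,
                                threshold_step = 0.05, growth_stop_ratio = 8,
                                noise_floor_sd = 2,
                                area_bounds_px = c(50, 5000),
                                border_margin_px = 2,
                                soma_intensity_fraction = 0.6) {
  stopifnot(h_maxima_depth > 0, h_maxima_depth < 1,
            threshold_step > 0, threshold_step < 1,
            soma_intensity_fraction > 0, soma_intensity_fraction < 1,
            length(area_bounds_px) == 2, area_bounds_px[1] <= area_bounds_px[2])
  structure(list(smoothing_sigma_px = smoothing_sigma_px,
                 h_maxima_depth = h_maxima_depth,
                 min_seed_separation_px = min_seed_separation_px,
                 min_seed_intensity_frac = min_seed_intensity_frac,
                 threshold_step = threshold_step,
                 growth_stop_ratio = growth_stop_ratio,
                 noise_floor_sd = noise_floor_sd,
                 area_bounds_px = area_bounds_px,
                 border_margin_px = border_margin_px,
                 soma_intensity_fraction = soma_intensity_fraction),
            class = "segmentation_params")
}

#' Maximum intensity projection
#'
#' @param stack 3D array (y, x, z) with at least one section.
#' @return matrix: per-pixel maximum over z.
#' @export
max_intensity_project <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (!is.array(stack) || length(dim(stack)) != 3 || dim(stack)[3] < 1)
    stop("stack must be a (y, x, z) array with >= 1 section")
  nz <- dim(stack)[3]
  out <- stack[, , 1]
  for (z in seq_len(nz)[-1]) out <- pmax(out, stack[, , z])
  out
}

#' Detect cell seeds as regional maxima
#'
#' Smooths the projection, applies the h-maxima transform (greyscale
#' reconstruction by dilation of \code{image - h} under \code{image}) and
#' labels its regional-maxima plateaus; each plateau contributes one seed at
#' its centroid (snapped to the nearest plateau pixel).  Seeds closer than
#' \code{min_seed_separation_px} are thinned, keeping the brighter one.
#'
#' @param image 2D projection (matrix).
#' @param params a \code{segmentation_params}.
#' @return tibble with columns \code{y}, \code{x}, \code{peak} (raw image
#'   value at the seed) and \code{smoothed} (smoothed value), ordered by
#'   decreasing smoothed intensity.  Zero rows for flat images.
#' @export
detect_seeds <- function(image, params = segmentation_params()) {
  if (!is.matrix(image) || length(image) == 0) stop("image must be a non-empty matrix")
  empty <- tibble::tibble(y = integer(0), x = integer(0),
                          peak = numeric(0), smoothed = numeric(0))
  rng <- range(image)
  if (diff(rng) == 0) return(empty)
  sm <- EBImage::gblur(image, sigma = params$smoothing_sigma_px,
                       boundary = "replicate")
  sm <- matrix(as.numeric(sm), nrow(image), ncol(image))
  dyn <- diff(range(sm))
  if (dyn == 0) return(empty)
  h <- params$h_maxima_depth * dyn
  hmax <- reconstruct_dilate_cpp(sm - h, sm)
  lab <- regional_maxima_cpp(hmax)
  k <- max(lab)
  if (k == 0) return(empty)
  co <- which(lab > 0, arr.ind = TRUE)
  ids <- lab[lab > 0]
  cy <- tapply(co[, 1], ids, mean)
  cx <- tapply(co[, 2], ids, mean)
  seeds <- t(vapply(seq_len(k), function(i) {
    pix <- co[ids == i, , drop = FALSE]
    d2 <- (pix[, 1] - cy[i])^2 + (pix[, 2] - cx[i])^2
    pix[which.min(d2), ]
  }, numeric(2)))
  sval <- sm[seeds]
  bright <- sval >= min(sm) + params$min_seed_intensity_frac * dyn
  seeds <- seeds[bright, , drop = FALSE]
  sval <- sval[bright]
  if (length(sval) == 0) return(empty)
  ord <- order(sval, decreasing = TRUE)
  seeds <- seeds[ord, , drop = FALSE]
  sval <- sval[ord]
  keep <- logical(nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    prev <- seeds[keep, , drop = FALSE]
    keep[i] <- nrow(prev) == 0 ||
      min(sqrt((prev[, 1] - seeds[i, 1])^2 + (prev[, 2] - seeds[i, 2])^2)) >=
        params$min_seed_separation_px
  }
  tibble::tibble(y = as.integer(seeds[keep, 1]), x = as.integer(seeds[keep, 2]),
                 peak = image[seeds[keep, , drop = FALSE]],
                 smoothed = sval[keep])
}

new_cells <- function(cells, dims) {
  structure(list(cells = cells, dim = dims), class = "micromorph_cells")
}

#' Grow cell masks by iterative thresholding around each seed
#'
#' All seeds share a quantized threshold ladder stepping down from the image
#' maximum by \code{threshold_step} of the dynamic range.  A seed becomes
#' active at the first level at or below its peak; at each level its mask is
#' the connected component containing the seed.  Growth stops when the
#' component would absorb another seed or when the area grows by more than
#' \code{growth_stop_ratio} in one step (flooding); the final mask is the
#' component at the last accepted level, with interior holes filled.  Because
#' every mask is a connected component of some level and absorption stops at
#' the merge level, masks of different seeds are pairwise disjoint by
#' construction.  Seeds whose very first level already floods (planted on
#' background) are flagged with an empty mask.
#'
#' @param image 2D projection the seeds were detected on.
#' @param seeds tibble from [detect_seeds()].
#' @param params a \code{segmentation_params}.
#' @return a \code{micromorph_cells} object; each cell holds its label, seed,
#'   linear-index mask, area and a reason code ("grown" or "background").
#' @export
segment_cells <- function(image, seeds, params = segmentation_params()) {
  dims <- dim(image)
  nseed <- nrow(seeds)
  if (nseed == 0) return(new_cells(list(), dims))
  rngI <- range(image)
  dyn <- diff(rngI)
  if (dyn == 0) stop("image has zero dynamic range")
  step <- params$threshold_step * dyn
  floor_t <- stats::median(image) + params$noise_floor_sd * stats::mad(image)
  bottom <- max(floor_t, rngI[1]) + step / 2
  levels <- if (bottom >= rngI[2]) rngI[2] else seq(rngI[2], bottom, by = -step)
  flood_cap <- 4 * params$area_bounds_px[2]
  sy <- seeds$y; sx <- seeds$x; speak <- seeds$peak
  started <- logical(nseed)
  reason <- rep(NA_character_, nseed)
  prev_cid <- integer(nseed)
  prev_area <- rep(NA_real_, nseed)
  final_mask <- vector("list", nseed)
  lab_prev <- NULL

  finalize_prev <- function(s, lab_prev) {
    if (is.null(lab_prev) || prev_cid[s] == 0L) integer(0)
    else which(lab_prev == prev_cid[s])
  }

  for (t in levels) {
    lab <- EBImage::bwlabel((image >= t) * 1L)
    areas <- tabulate(as.integer(lab))
    cids <- as.integer(lab[cbind(sy, sx)])
    for (s in which(is.na(reason))) {
      if (!started[s]) {
        if (speak[s] < t) next
        started[s] <- TRUE
        cid <- cids[s]
        a <- areas[cid]
        other <- nseed > 1 && any(cids[-s] == cid)
        if (other || a > flood_cap) {
          reason[s] <- "background"
          final_mask[s] <- list(integer(0))
        } else {
          prev_cid[s] <- cid; prev_area[s] <- a
        }
        next
      }
      cid <- cids[s]
      a <- areas[cid]
      other <- nseed > 1 && any(cids[-s] == cid)
      # the ratio criterion only counts when the one-step increment exceeds
      # any plausible cell area: relative growth is large both during normal
      # early growth around the peak and when the ladder crosses the process
      # intensity, but only flooding adds more area than a whole cell at once
      flooded <- a > params$growth_stop_ratio * prev_area[s] &&
        a - prev_area[s] > params$area_bounds_px[2]
      if (other || flooded || a > flood_cap) {
        reason[s] <- "grown"
        final_mask[[s]] <- finalize_prev(s, lab_prev)
      } else {
        prev_cid[s] <- cid; prev_area[s] <- a
      }
    }
    lab_prev <- lab
    if (!anyNA(reason)) break
  }
  for (s in which(is.na(reason))) {      # ladder exhausted while still growing
    reason[s] <- "grown"
    final_mask[[s]] <- finalize_prev(s, lab_prev)
  }

  cells <- lapply(seq_len(nseed), function(s) {
    idx <- final_mask[[s]]
    if (length(idx) > 0) {
      filled <- fill_holes(idx_to_mask(idx, dims))
      idx <- which(filled)
    }
    if (length(idx) == 0 && reason[s] == "grown") reason[s] <- "background"
    list(label = s, seed_y = sy[s], seed_x = sx[s], seed_peak = speak[s],
         seed_smoothed = if ("smoothed" %in% names(seeds)) seeds$smoothed[s]
                         else speak[s],
         mask = idx, area = length(idx), reason = reason[s],
         qc = NA_character_, soma = integer(0), soma_flag = NA_character_)
  })
  new_cells(cells, dims)
}

#' Post-segmentation quality control
#'
#' Rejects masks that are empty (seed on background), split into several
#' components, contain more than one seed, fall outside the area bounds, or
#' touch the border margin.  Accepted masks pass through unchanged.
#'
#' @param cells a \code{micromorph_cells} object from [segment_cells()].
#' @param image the projection (unused by the checks but kept in the stage
#'   signature for parity with the pipeline).
#' @param params a \code{segmentation_params}.
#' @return the same object with \code{qc} set per cell ("accepted" or a
#'   rejection reason) plus a \code{log} tibble attached.
#' @export
qc_masks <- function(cells, image = NULL, params = segmentation_params()) {
  stopifnot(inherits(cells, "micromorph_cells"))
  dims <- cells$dim
  seed_lin <- vapply(cells$cells, function(cl) cl$seed_y + (cl$seed_x - 1L) * dims[1],
                     numeric(1))
  lo <- params$area_bounds_px[1]; hi <- params$area_bounds_px[2]
  m <- params$border_margin_px
  for (i in seq_along(cells$cells)) {
    cl <- cells$cells[[i]]
    qc <- if (length(cl$mask) == 0) {
      "background"
    } else {
      mask <- idx_to_mask(cl$mask, dims)
      co <- which(mask, arr.ind = TRUE)
      nseed_in <- sum(seed_lin %in% cl$mask)
      if (n_components(mask) > 1) "multi_component"
      else if (nseed_in > 1) "multi_soma"
      else if (cl$area < lo) "area_small"
      else if (cl$area > hi) "area_large"
      else if (min(co[, 1]) <= m || min(co[, 2]) <= m ||
               max(co[, 1]) > dims[1] - m || max(co[, 2]) > dims[2] - m) "border"
      else "accepted"
    }
    cells$cells[[i]]$qc <- qc
  }
  cells$log <- tibble::tibble(
    label = vapply(cells$cells, `[[`, integer(1), "label"),
    area = vapply(cells$cells, `[[`, numeric(1), "area"),
    qc = vapply(cells$cells, `[[`, character(1), "qc"))
  cells
}

#' Extract the soma mask of an accepted cell
#'
#' Thresholds the cell's own pixels at \code{soma_intensity_fraction} of the
#' seed peak's elevation above the image background (median), and keeps the
#' connected component containing the seed.  Intended
#' to run on the smoothed projection: smoothing attenuates thin processes
#' geometrically while leaving the wide soma near its full intensity, so the
#' fractional threshold isolates the soma even when raw process intensity is
#' high.  If the thresholded component is empty the seed pixel itself is used
#' and the cell is flagged.
#'
#' @param image the (preferably smoothed) projection.
#' @param cell one element of a \code{micromorph_cells} object.
#' @param params a \code{segmentation_params}.
#' @param dims image dimensions.
#' @param peak seed peak intensity on the same scale as \code{image}.
#' @return list: \code{soma} (linear indices), \code{flag} (NA or
#'   "seed_fallback").
#' @export
extract_soma <- function(image, cell, params = segmentation_params(),
                         dims = dim(image), peak = cell$seed_smoothed) {
  stopifnot(length(cell$mask) > 0)
  if (is.null(peak)) peak <- cell$seed_peak
  bg <- stats::median(image)
  thr <- bg + params$soma_intensity_fraction * (peak - bg)
  sub <- cell$mask[image[cell$mask] >= thr]
  seed_lin <- cell$seed_y + (cell$seed_x - 1L) * dims[1]
  if (!(seed_lin %in% sub))
    return(list(soma = seed_lin, flag = "seed_fallback"))
  m <- idx_to_mask(sub, dims)
  lab <- EBImage::bwlabel(m * 1L)
  list(soma = which(lab == lab[seed_lin]), flag = NA_character_)
}

#' Run the full segmentation stage on one stack
#'
#' Convenience wrapper: projection, seed detection, mask growth, QC and soma
#' extraction.
#'
#' @param stack 3D array (y, x, z) or an already-projected matrix.
#' @param params a \code{segmentation_params}.
#' @return list: \code{cells} (QC'd \code{micromorph_cells} with somas),
#'   \code{seeds}, \code{mip}.
#' @export
segment_scene <- function(stack, params = segmentation_params()) {
  mip <- max_intensity_project(stack)
  seeds <- detect_seeds(mip, params)
  cells <- segment_cells(mip, seeds, params)
  cells <- qc_masks(cells, mip, params)
  smooth <- EBImage::gblur(mip, sigma = params$smoothing_sigma_px,
                           boundary = "replicate")
  smooth <- matrix(as.numeric(smooth), nrow(mip), ncol(mip))
  for (i in seq_along(cells$cells)) {
    if (identical(cells$cells[[i]]$qc, "accepted")) {
      sm <- extract_soma(smooth, cells$cells[[i]], params, dims = cells$dim)
      cells$cells[[i]]$soma <- sm$soma
      cells$cells[[i]]$soma_flag <- sm$flag
    }
  }
  list(cells = cells, seeds = seeds, mip = mip, smoothed = smooth)
}
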