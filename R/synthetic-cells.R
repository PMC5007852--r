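#' Cell shape specification
#'
#' Parametrizes the simulated microglia morphologies: a bright elliptical soma
#' with thickness-tapered, randomly walking processes that branch recursively.
#' The "resting"-like regime uses a small soma with several long ramified
#' processes; the "activated"-like regime a larger soma with few short stubs
#' (amoeboid).
#'
#' @param soma_radius_px soma radius in px (> 0).
#' @param soma_axis_ratio soma ellipse axis ratio (>= 1).
#' @param n_primary_processes number of primary processes (>= 0).
#' @param process_length_px walk length of a primary process in px.
#' @param branch_depth maximum recursive branching depth (>= 0).
#' @param branch_prob probability that a process spawns a branch, in [0, 1].
#' @param process_thickness_px process thickness at its root in px.
#' @param intensity_scale peak soma intensity in arbitrary units.
#' @param process_intensity_frac process intensity as a fraction of the soma
#'   peak; kept below typical soma-threshold fractions so the soma can be
#'   recovered by intensity thresholding.
#' @return a \code{cell_spec} list.
#' @export
cell_spec <- function(soma_radius_px = 6, soma_axis_ratio = 1.25,
                      n_primary_processes = 5, process_length_px = 30,
                      branch_depth = 2, branch_prob = 0.5,
                      process_thickness_px = 3, intensity_scale = 1000,
                      process_intensity_frac = 0.7) {
  if (soma_radius_px <= 0) stop("soma_radius_px must be > 0")
  if (soma_axis_ratio < 1) stop("soma_axis_ratio must be >= 1")
  if (n_primary_processes < 0 || branch_depth < 0) stop("counts must be >= 0")
  if (n_primary_processes > 0 &&
      (process_length_px <= 0 || process_thickness_px <= 0))
    stop("process dimensions must be > 0 where processes exist")
  if (branch_prob < 0 || branch_prob > 1) stop("branch_prob must be in [0, 1]")
  structure(list(
    soma_radius_px = soma_radius_px, soma_axis_ratio = soma_axis_ratio,
    n_primary_processes = n_primary_processes,
    process_length_px = process_length_px, branch_depth = branch_depth,
    branch_prob = branch_prob, process_thickness_px = process_thickness_px,
    intensity_scale = intensity_scale,
    process_intensity_frac = process_intensity_frac), class = "cell_spec")
}

#' Built-in cell regimes
#'
#' @param regime "resting" (ramified) or "activated" (amoeboid, soma radius
#'   1.3x the resting value, few short processes).
#' @return a \code{cell_spec}.
#' @export
cell_regime <- function(regime = c("resting", "activated")) {
  regime <- match.arg(regime)
  switch(regime,
    resting = cell_spec(),
    activated = cell_spec(soma_radius_px = 6 * 1.3, soma_axis_ratio = 1.15,
                          n_primary_processes = 2, process_length_px = 12,
                          branch_depth = 0, branch_prob = 0,
                          process_thickness_px = 3))
}

# maximum plausible reach of a process tree (primary walk + geometric series
# of 0.6-shortened children)
process_reach <- function(spec) {
  if (spec$n_primary_processes == 0) return(0)
  spec$process_length_px * sum(0.6^(0:spec$branch_depth))
}

#' Generate one synthetic cell
#'
#' Draws a single cell on its own canvas: an elliptical soma at unit relative
#' intensity plus tapered random-walk processes at
#' \code{process_intensity_frac}.  The returned true parameters are the six
#' morphometric quantities computed from the noiseless mask.
#'
#' @param spec a \code{cell_spec}.
#' @param seed optional integer seed (sets the global RNG).
#' @param pixel_size_um pixel size used for the true parameters.
#' @return list with \code{cell_mask}, \code{soma_mask} (logical matrices),
#'   \code{intensity} (relative, soma = 1), \code{center} (soma center, row/col)
#'   and \code{truth} (one-row morphometric tibble).
#' @export
generate_cell <- function(spec, seed = NULL, pixel_size_um = 0.42) {
  stopifnot(inherits(spec, "cell_spec"))
  if (!is.null(seed)) set.seed(seed)
  a <- spec$soma_radius_px * sqrt(spec$soma_axis_ratio)
  ext <- ceiling(a + process_reach(spec) + spec$process_thickness_px) + 4L
  side <- 2L * ext + 1L
  ctr <- ext + 1L
  soma <- matrix(FALSE, side, side)
  proc <- matrix(FALSE, side, side)

  # elliptical soma with random orientation
  b <- spec$soma_radius_px / sqrt(spec$soma_axis_ratio)
  th <- stats::runif(1, 0, pi)
  yy <- matrix(seq_len(side) - ctr, side, side)
  xx <- t(yy)
  u <- xx * cos(th) + yy * sin(th)
  v <- -xx * sin(th) + yy * cos(th)
  soma[(u / a)^2 + (v / b)^2 <= 1] <- TRUE

  # tapered random-walk processes with recursive branching
  walk <- function(pos, heading, len, thick, depth) {
    len <- max(1L, round(len))
    for (s in seq_len(len)) {
      heading <- heading + stats::rnorm(1, 0, 0.2)
      pos <- pos + c(sin(heading), cos(heading))
      taper <- 1 - 0.4 * (s / len)
      proc <<- stamp_disk(proc, pos[1], pos[2], max(0.9, thick / 2 * taper))
      if (depth > 0 && stats::runif(1) < spec$branch_prob / len) {
        walk(pos, heading + sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.1),
             len * 0.6, thick * 0.8, depth - 1)
      }
    }
  }
  n <- spec$n_primary_processes
  if (n > 0) {
    base_ang <- 2 * pi * (seq_len(n) - 1) / n + stats::runif(1, 0, 2 * pi)
    for (i in seq_len(n)) {
      ang <- base_ang[i] + stats::rnorm(1, 0, 0.25)
      # start just inside the soma boundary so the process is connected
      rad <- a * b / sqrt((b * cos(ang - th))^2 + (a * sin(ang - th))^2)
      pos <- c(ctr + 0.9 * rad * sin(ang), ctr + 0.9 * rad * cos(ang))
      walk(pos, ang, spec$process_length_px, spec$process_thickness_px,
           spec$branch_depth)
    }
  }

  cell <- soma | proc
  # keep the component containing the soma center (stray fragments cannot
  # arise from the walk construction, but guard anyway)
  lab <- EBImage::bwlabel(cell * 1L)
  cell <- lab == lab[ctr, ctr]
  soma <- soma & cell
  intensity <- matrix(0, side, side)
  intensity[cell] <- spec$process_intensity_frac
  intensity[soma] <- 1
  truth <- measure_cell(cell, soma, pixel_size_um)
  list(cell_mask = cell, soma_mask = soma, intensity = intensity,
       center = c(ctr, ctr), truth = truth)
}

#' Scene preset
#'
#' Describes a full synthetic field: cell regime, density, stack geometry
#' (default: 10 optical sections 1 um apart at 0.42 um/px, matching typical
#' confocal acquisition of microglia), background and noise model.  SNR is
#' defined as (peak soma intensity - background mean) / background sd.
#'
#' @param name regime name, passed to [cell_regime()] unless
#'   \code{cell_spec} is given.
#' @param n_cells number of cells to place.
#' @param cell_spec optional explicit \code{cell_spec} overriding the regime.
#' @param spec_cv lognormal coefficient of variation applied per cell to soma
#'   radius and process length.
#' @param min_center_spacing_px minimum distance between soma centers.
#' @param stack_shape c(z, y, x) voxel counts.
#' @param pixel_size_um,z_step_um voxel geometry.
#' @param background_level background mean intensity.
#' @param snr scene signal-to-noise ratio.
#' @param poisson_gain photons per intensity unit for shot noise.
#' @param rng_seed integer seed; scenes regenerate bit-identically from
#'   (preset, seed).
#' @return a \code{scene_preset} list.
#' @export
scene_preset <- function(name = c("resting", "activated"), n_cells = 30,
                         cell_spec = NULL, spec_cv = 0.1,
                         min_center_spacing_px = 55,
                         stack_shape = c(10, 512, 512),
                         pixel_size_um = 0.42, z_step_um = 1,
                         background_level = 60, snr = 8, poisson_gain = 0.2,
                         rng_seed = 1L) {
  name <- match.arg(name)
  spec <- if (is.null(cell_spec)) cell_regime(name) else cell_spec
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  # sanity: the field must be able to hold n_cells at the requested spacing
  # (hexagonal packing bound)
  capacity <- prod(stack_shape[2:3]) / (0.25 * sqrt(3) * min_center_spacing_px^2)
  if (n_cells > capacity)
    stop("stack too small to hold n_cells at min_center_spacing_px")
  structure(list(name = name, n_cells = n_cells, cell_spec = spec,
                 spec_cv = spec_cv,
                 min_center_spacing_px = min_center_spacing_px,
                 stack_shape = stack_shape, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um, background_level = background_level,
                 snr = snr, poisson_gain = poisson_gain,
                 rng_seed = as.integer(rng_seed)), class = "scene_preset")
}

#' Render a synthetic fluorescence scene
#'
#' Places cells at random non-overlapping positions (rejection sampling with
#' bounded retries), renders each onto its home optical section and the two
#' neighbouring sections with Gaussian axial falloff, applies mild per-section
#' attenuation, Poisson shot noise on signal and additive Gaussian background.
#' Ground truth is stored at projection level: 2D cell/soma label images and
#' the six true shape parameters measured from the noiseless placed masks.
#'
#' @param preset a \code{scene_preset}.
#' @return a \code{synthetic_scene} list: \code{stack} (y, x, z array),
#'   \code{truth_labels}, \code{truth_soma_labels} (integer matrices),
#'   \code{truth} (per-cell tibble), \code{preset}, \code{seed}.
#' @export
render_scene <- function(preset) {
  stopifnot(inherits(preset, "scene_preset"))
  set.seed(preset$rng_seed)
  nz <- preset$stack_shape[1]; ny <- preset$stack_shape[2]
  nx <- preset$stack_shape[3]
  spec0 <- preset$cell_spec
  reach <- ceiling(spec0$soma_radius_px * sqrt(spec0$soma_axis_ratio) *
                     (1 + 2 * preset$spec_cv) + process_reach(spec0) +
                     spec0$process_thickness_px) + 4
  margin <- min(reach, floor(min(ny, nx) / 3))

  # place centers
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centers) < preset$n_cells) {
    cand <- c(stats::runif(1, margin + 1, ny - margin),
              stats::runif(1, margin + 1, nx - margin))
    ok <- nrow(centers) == 0 ||
      min(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)) >=
        preset$min_center_spacing_px
    if (ok) centers <- rbind(centers, cand)
    tries <- tries + 1L
    if (tries > 4000L * max(1L, preset$n_cells))
      stop("could not place n_cells at min_center_spacing_px")
  }

  labels <- matrix(0L, ny, nx)
  soma_labels <- matrix(0L, ny, nx)
  cell_px <- vector("list", preset$n_cells)   # linear indices per cell
  cell_in <- vector("list", preset$n_cells)   # intensities per pixel
  home_z <- integer(preset$n_cells)
  truth_rows <- vector("list", preset$n_cells)

  for (i in seq_len(preset$n_cells)) {
    jit <- exp(stats::rnorm(2, 0, preset$spec_cv))
    sp <- spec0
    sp$soma_radius_px <- sp$soma_radius_px * jit[1]
    if (sp$n_primary_processes > 0)
      sp$process_length_px <- sp$process_length_px * jit[2]
    cl <- generate_cell(sp, pixel_size_um = preset$pixel_size_um)
    off <- round(centers[i, ]) - cl$center
    co <- which(cl$cell_mask, arr.ind = TRUE)
    rr <- co[, 1] + off[1]; cc <- co[, 2] + off[2]
    keep <- rr >= 1 & rr <= ny & cc >= 1 & cc <= nx
    idx <- cbind(rr[keep], cc[keep])
    lin <- idx[, 1] + (idx[, 2] - 1L) * ny
    free <- labels[lin] == 0L             # earlier cells own contested pixels
    lin <- lin[free]
    labels[lin] <- i
    vals <- cl$intensity[cl$cell_mask][keep][free]
    soma_src <- cl$soma_mask[cl$cell_mask][keep][free]
    soma_labels[lin[soma_src]] <- i
    # placed mask may have been truncated by ownership: keep the component
    # holding the soma and re-measure truth from what was actually placed
    m <- idx_to_mask(lin, c(ny, nx))
    lab <- EBImage::bwlabel(m * 1L)
    soma_lin <- lin[soma_src]
    main_id <- lab[if (length(soma_lin)) soma_lin[1] else lin[1]]
    drop <- lin[lab[lin] != main_id]
    if (length(drop)) {
      labels[drop] <- 0L
      keep2 <- lab[lin] == main_id
      lin <- lin[keep2]; vals <- vals[keep2]; soma_src <- soma_src[keep2]
      m <- idx_to_mask(lin, c(ny, nx))
    }
    cell_px[[i]] <- lin
    cell_in[[i]] <- vals * spec0$intensity_scale
    home_z[i] <- sample.int(nz, 1)
    tr <- measure_cell(m, idx_to_mask(lin[soma_src], c(ny, nx)),
                       preset$pixel_size_um, cell_id = i)
    tr$center_y <- mean(idx_to_coords(lin, ny)[, 1])
    tr$center_x <- mean(idx_to_coords(lin, ny)[, 2])
    tr$soma_center_y <- mean(idx_to_coords(lin[soma_src], ny)[, 1])
    tr$soma_center_x <- mean(idx_to_coords(lin[soma_src], ny)[, 2])
    tr$home_z <- home_z[i]
    truth_rows[[i]] <- tr
  }

  # render signal: home section plus axial Gaussian falloff to the two
  # neighbouring sections, with mild per-section attenuation
  signal <- array(0, dim = c(ny, nx, nz))
  sigma_z <- 0.8
  atten <- 0.99^(seq_len(nz) - 1)
  for (i in seq_len(preset$n_cells)) {
    for (dz in -1:1) {
      z <- home_z[i] + dz
      if (z < 1 || z > nz) next
      w <- exp(-dz^2 / (2 * sigma_z^2)) * atten[z]
      plane_off <- (z - 1L) * ny * nx
      signal[cell_px[[i]] + plane_off] <-
        signal[cell_px[[i]] + plane_off] + cell_in[[i]] * w
    }
  }

  # noise: Poisson shot noise on signal, additive Gaussian background
  nvox <- length(signal)
  g <- preset$poisson_gain
  shot <- signal
  pos <- signal > 0
  shot[pos] <- stats::rpois(sum(pos), signal[pos] * g) / g
  bg_sd <- spec0$intensity_scale / preset$snr
  stack <- shot + stats::rnorm(nvox, preset$background_level, bg_sd)
  stack <- array(pmax(stack, 0), dim = c(ny, nx, nz))

  truth <- if (preset$n_cells == 0) {
    tb <- empty_morphometric_table()
    tb$center_y <- numeric(0); tb$center_x <- numeric(0)
    tb$soma_center_y <- numeric(0); tb$soma_center_x <- numeric(0)
    tb$home_z <- integer(0)
    tb
  } else dplyr::bind_rows(truth_rows)

  structure(list(stack = stack, truth_labels = labels,
                 truth_soma_labels = soma_labels, truth = truth,
                 preset = preset, seed = preset$rng_seed),
            class = "synthetic_scene")
}

idx_to_coords <- function(lin, ny) {
  cbind(((lin - 1L) %% ny) + 1L, ((lin - 1L) %/% ny) + 1L)
}
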