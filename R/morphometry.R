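#' Roundness of a shape
#'
#' Roundness is defined as \eqn{4\pi \cdot area / perimeter^2}: 1 for an ideal
#' circle, approaching 0 for filamentous shapes.  Digital perimeter estimates
#' can overshoot slightly for near-circular masks; values above 1 are clipped
#' and flagged via the \code{"clipped"} attribute.
#'
#' @param area shape area (any unit; roundness is dimensionless).
#' @param perimeter shape perimeter in the matching length unit; must be > 0.
#' @return roundness in (0, 1], with attribute \code{clipped} (logical).
#' @export
roundness <- function(area, perimeter) {
  stopifnot(length(area) == 1, length(perimeter) == 1)
  if (!is.finite(perimeter) || perimeter <= 0) stop("perimeter must be > 0")
  if (!is.finite(area) || area <= 0) stop("area must be > 0")
  val <- 4 * pi * area / perimeter^2
  clipped <- val > 1
  if (clipped) val <- 1
  structure(val, clipped = clipped)
}

# the eight extremal pixels of a mask, two per cardinal side, in the order
# topmost-left, topmost-right, rightmost-top, rightmost-bottom,
# bottommost-right, bottommost-left, leftmost-bottom, leftmost-top.
# coords is a 2-column (row, col) matrix of pixel centers.
extreme_points <- function(coords) {
  y <- coords[, 1]; x <- coords[, 2]
  ymin <- min(y); ymax <- max(y); xmin <- min(x); xmax <- max(x)
  rbind(
    c(ymin, min(x[y == ymin])), c(ymin, max(x[y == ymin])),
    c(min(y[x == xmax]), xmax), c(max(y[x == xmax]), xmax),
    c(ymax, max(x[y == ymax])), c(ymax, min(x[y == ymax])),
    c(max(y[x == xmin]), xmin), c(min(y[x == xmin]), xmin))
}

#' Cell spread
#'
#' Mean Euclidean distance from the mask's center of mass to its eight
#' extremal points (two per cardinal side), scaled by the pixel size.
#'
#' @param mask logical matrix, non-empty.
#' @param pixel_size_um physical pixel size (um/px); default 1 returns pixels.
#' @return spread in um (or px when \code{pixel_size_um = 1}).
#' @export
cell_spread <- function(mask, pixel_size_um = 1) {
  co <- which(mask, arr.ind = TRUE)
  if (nrow(co) == 0) stop("empty mask")
  ctr <- colMeans(co)
  ext <- extreme_points(co)
  mean(sqrt((ext[, 1] - ctr[1])^2 + (ext[, 2] - ctr[2])^2)) * pixel_size_um
}

# weights for the boundary-step contour length: maximum-likelihood step
# weights for straight digital segments (isothetic / diagonal moves), which
# keep the estimate near-unbiased for smooth outlines.
PERIM_W_AXIAL <- 0.948
PERIM_W_DIAG <- 1.340

# Moore-neighbour boundary trace of the filled mask; returns the closed tour
# of boundary pixel centers as a 2-column (row, col) matrix.
trace_boundary <- function(mask) {
  co <- which(mask, arr.ind = TRUE)
  n <- nrow(co)
  if (n == 0) stop("empty mask")
  if (n == 1) return(co)
  # clockwise Moore neighbourhood starting west
  dy <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dx <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  inside <- function(r, c) r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask)
  # start pixel: topmost row, then leftmost column; its west neighbour is
  # guaranteed outside the mask
  ymin <- min(co[, 1])
  x0 <- min(co[co[, 1] == ymin, 2])
  start <- c(ymin, x0)
  cur <- start
  back_dir <- 1L                      # direction index pointing at backtrack (west)
  tour <- matrix(0L, 0, 2)
  first_move <- NA_integer_
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- ((back_dir - 1L + k) %% 8L) + 1L
      r <- cur[1] + dy[d]; c <- cur[2] + dx[d]
      if (inside(r, c) && mask[r, c]) {
        if (nrow(tour) == 0) first_move <- d
        else if (cur[1] == start[1] && cur[2] == start[2] && d == first_move) {
          return(tour)                # Jacob's stopping criterion
        }
        tour <- rbind(tour, cur)
        # new backtrack: the neighbour scanned just before the hit, relative
        # to the new current pixel
        prev_d <- ((d - 2L) %% 8L) + 1L
        pr <- cur[1] + dy[prev_d]; pc <- cur[2] + dx[prev_d]
        cur <- c(r, c)
        # direction from new cur towards (pr, pc)
        back_dir <- which(dy == pr - cur[1] & dx == pc - cur[2])
        found <- TRUE
        break
      }
    }
    if (!found) {                     # isolated pixel among co (cannot happen
      return(rbind(tour, cur))        # for a connected mask)
    }
    if (nrow(tour) > 8L * n) stop("boundary trace failed to close")
  }
}

#' Mask perimeter
#'
#' Weighted boundary-step contour length: the closed Moore-neighbour tour of
#' the outer boundary, with axial steps weighted 0.948 and diagonal steps
#' 1.340 (near-unbiased for smooth digital outlines).  Interior holes are
#' filled before tracing, so only the outer contour contributes.
#'
#' @param mask logical matrix (single connected component).
#' @param pixel_size_um physical pixel size (um/px).
#' @return perimeter length in um (px when \code{pixel_size_um = 1}).
#' @export
mask_perimeter <- function(mask, pixel_size_um = 1) {
  co <- which(mask, arr.ind = TRUE)
  if (nrow(co) == 0) stop("empty mask")
  if (nrow(co) == 1) return(4 * PERIM_W_AXIAL * pixel_size_um)
  tour <- trace_boundary(fill_holes(mask))
  if (nrow(tour) == 1) return(4 * PERIM_W_AXIAL * pixel_size_um)
  nxt <- rbind(tour[-1, , drop = FALSE], tour[1, , drop = FALSE])
  step_diag <- (tour[, 1] != nxt[, 1]) & (tour[, 2] != nxt[, 2])
  (sum(!step_diag) * PERIM_W_AXIAL + sum(step_diag) * PERIM_W_DIAG) * pixel_size_um
}

#' Mask eccentricity
#'
#' Major/minor axis ratio of the moment-based best-fit ellipse (eigenvalues of
#' the second central moment matrix of pixel-center coordinates); 1 for a
#' disk, increasing with elongation.  Degenerate line masks (zero minor axis)
#' return \code{Inf}.
#'
#' @param mask logical matrix.
#' @return eccentricity >= 1 (possibly \code{Inf}).
#' @export
mask_eccentricity <- function(mask) {
  co <- which(mask, arr.ind = TRUE)
  if (nrow(co) == 0) stop("empty mask")
  dy <- co[, 1] - mean(co[, 1]); dx <- co[, 2] - mean(co[, 2])
  myy <- mean(dy^2); mxx <- mean(dx^2); mxy <- mean(dx * dy)
  ev <- eigen(matrix(c(myy, mxy, mxy, mxx), 2, 2), symmetric = TRUE)$values
  if (ev[2] <= 1e-12) return(Inf)
  sqrt(ev[1] / ev[2])
}

#' Measure one segmented cell
#'
#' Computes the six morphometric parameters of a cell mask and its soma mask:
#' cell area, soma area, perimeter, cell spread, eccentricity and roundness.
#' Areas and lengths are reported both in pixels and in physical units.
#'
#' @param cell_mask logical matrix, the cell mask (single component).
#' @param soma_mask logical matrix, the soma mask; must be a subset of
#'   \code{cell_mask}.
#' @param pixel_size_um physical pixel size in um/px (default 0.42).
#' @param cell_id,region,condition,animal identifier metadata carried into the
#'   record.
#' @return one-row tibble (a morphometric record).
#' @export
measure_cell <- function(cell_mask, soma_mask, pixel_size_um = 0.42,
                         cell_id = NA_integer_, region = NA_character_,
                         condition = NA_character_, animal = NA_character_) {
  stopifnot(identical(dim(cell_mask), dim(soma_mask)))
  if (!any(cell_mask)) stop("empty cell mask")
  if (!any(soma_mask)) stop("empty soma mask")
  if (any(soma_mask & !cell_mask)) stop("soma mask is not contained in the cell mask")
  a_cell <- sum(cell_mask)
  a_soma <- sum(soma_mask)
  per <- mask_perimeter(cell_mask)
  spr <- cell_spread(cell_mask)
  ecc <- mask_eccentricity(cell_mask)
  rnd <- roundness(a_cell, per)
  tibble::tibble(
    cell_id = cell_id, region = region, condition = condition, animal = animal,
    pixel_size_um = pixel_size_um,
    cell_area_px = a_cell, soma_area_px = a_soma,
    perimeter_px = per, spread_px = spr,
    eccentricity = ecc, roundness = as.numeric(rnd),
    roundness_clipped = isTRUE(attr(rnd, "clipped")),
    ecc_degenerate = !is.finite(ecc),
    cell_area_um2 = a_cell * pixel_size_um^2,
    soma_area_um2 = a_soma * pixel_size_um^2,
    perimeter_um = per * pixel_size_um,
    spread_um = spr * pixel_size_um)
}

empty_morphometric_table <- function() {
  measure_cell(matrix(TRUE, 1, 1), matrix(TRUE, 1, 1))[0, ]
}

#' Measure all accepted cells of a scene
#'
#' @param cells a \code{micromorph_cells} object (from the segmentation stage,
#'   after QC and soma extraction) or a plain list with elements
#'   \code{cell_mask}/\code{soma_mask} per cell.
#' @param pixel_size_um physical pixel size (um/px).
#' @param region,condition,animal metadata applied to every record.
#' @return tibble with one morphometric record per accepted cell (zero rows,
#'   full header, when no cell is accepted).
#' @export
measure_scene <- function(cells, pixel_size_um = 0.42,
                          region = NA_character_, condition = NA_character_,
                          animal = NA_character_) {
  lst <- if (inherits(cells, "micromorph_cells")) {
    acc <- Filter(function(cl) identical(cl$qc, "accepted") && length(cl$soma) > 0,
                  cells$cells)
    lapply(acc, function(cl) list(
      cell_id = cl$label,
      cell_mask = idx_to_mask(cl$mask, cells$dim),
      soma_mask = idx_to_mask(cl$soma, cells$dim)))
  } else cells
  if (length(lst) == 0) return(empty_morphometric_table())
  rows <- lapply(seq_along(lst), function(i) {
    cl <- lst[[i]]
    id <- if (!is.null(cl$cell_id)) cl$cell_id else i
    measure_cell(cl$cell_mask, cl$soma_mask, pixel_size_um,
                 cell_id = id, region = region, condition = condition,
                 animal = animal)
  })
  dplyr::bind_rows(rows)
}
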