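# internal mask helpers ------------------------------------------------------

# logical full-frame mask from linear pixel indices
idx_to_mask <- function(idx, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  m[idx] <- TRUE
  m
}

# fill interior holes of a binary mask (operates on the padded bounding box so
# background connected to the frame edge is never treated as a hole)
fill_holes <- function(mask) {
  co <- which(mask, arr.ind = TRUE)
  if (nrow(co) == 0) return(mask)
  r0 <- max(1L, min(co[, 1]) - 1L); r1 <- min(nrow(mask), max(co[, 1]) + 1L)
  c0 <- max(1L, min(co[, 2]) - 1L); c1 <- min(ncol(mask), max(co[, 2]) + 1L)
  sub <- mask[r0:r1, c0:c1, drop = FALSE]
  filled <- EBImage::fillHull(sub * 1L) > 0
  out <- mask
  out[r0:r1, c0:c1] <- filled
  out
}

n_components <- function(mask) {
  if (!any(mask)) return(0L)
  as.integer(max(EBImage::bwlabel(mask * 1L)))
}

# stamp a filled disk into a logical matrix, clipped to the frame
stamp_disk <- function(mask, r0, c0, rad) {
  rr <- max(1L, floor(r0 - rad)):min(nrow(mask), ceiling(r0 + rad))
  cc <- max(1L, floor(c0 - rad)):min(ncol(mask), ceiling(c0 + rad))
  if (length(rr) == 0 || length(cc) == 0) return(mask)
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  mask[rr, cc] <- mask[rr, cc] | (d2 <= rad^2)
  mask
}
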