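# Independent brute-force oracles: direct pixel loops, no code shared with
# the package implementation.

oracle_area <- function(mask) {
  n <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask)))
    if (mask[i, j]) n <- n + 1L
  n
}

oracle_centroid <- function(mask) {
  sy <- 0; sx <- 0; n <- 0
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask)))
    if (mask[i, j]) { sy <- sy + i; sx <- sx + j; n <- n + 1 }
  c(sy / n, sx / n)
}

# the eight extremal points by exhaustive scan (two per cardinal side)
oracle_extrema <- function(mask) {
  pts <- NULL
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask)))
    if (mask[i, j]) pts <- rbind(pts, c(i, j))
  y <- pts[, 1]; x <- pts[, 2]
  pick <- function(cond_val, cond_axis, f2, axis2) {
    sel <- pts[pts[, cond_axis] == cond_val, , drop = FALSE]
    sel[which(sel[, axis2] == f2(sel[, axis2]))[1], ]
  }
  rbind(pick(min(y), 1, min, 2), pick(min(y), 1, max, 2),
        pick(max(x), 2, min, 1), pick(max(x), 2, max, 1),
        pick(max(y), 1, max, 2), pick(max(y), 1, min, 2),
        pick(min(x), 2, max, 1), pick(min(x), 2, min, 1))
}

oracle_spread <- function(mask, pixel_size_um = 1) {
  ctr <- oracle_centroid(mask)
  ext <- oracle_extrema(mask)
  tot <- 0
  for (k in seq_len(nrow(ext)))
    tot <- tot + sqrt((ext[k, 1] - ctr[1])^2 + (ext[k, 2] - ctr[2])^2)
  tot / nrow(ext) * pixel_size_um
}

oracle_eccentricity <- function(mask) {
  ctr <- oracle_centroid(mask)
  syy <- 0; sxx <- 0; sxy <- 0; n <- 0
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask)))
    if (mask[i, j]) {
      dy <- i - ctr[1]; dx <- j - ctr[2]
      syy <- syy + dy * dy; sxx <- sxx + dx * dx; sxy <- sxy + dx * dy
      n <- n + 1
    }
  myy <- syy / n; mxx <- sxx / n; mxy <- sxy / n
  # eigenvalues of the 2x2 moment matrix in closed form
  tr2 <- (myy + mxx) / 2
  disc <- sqrt(((myy - mxx) / 2)^2 + mxy^2)
  l1 <- tr2 + disc; l2 <- tr2 - disc
  if (l2 <= 1e-12) return(Inf)
  sqrt(l1 / l2)
}

# hole filling by background flood fill from a padded border (queue-based)
oracle_fill_holes <- function(mask) {
  nr <- nrow(mask) + 2L; nc <- ncol(mask) + 2L
  pm <- matrix(FALSE, nr, nc)
  pm[2:(nr - 1), 2:(nc - 1)] <- mask
  outside <- matrix(FALSE, nr, nc)
  stack <- integer(nr * nc); top <- 1L
  stack[1] <- 1L                       # linear index of (1, 1)
  outside[1, 1] <- TRUE
  while (top > 0L) {
    p <- stack[top]; top <- top - 1L
    pr <- ((p - 1L) %% nr) + 1L; pc <- ((p - 1L) %/% nr) + 1L
    for (d in 1:4) {
      qr <- pr + c(-1L, 1L, 0L, 0L)[d]
      qc <- pc + c(0L, 0L, -1L, 1L)[d]
      if (qr < 1 || qr > nr || qc < 1 || qc > nc) next
      if (!pm[qr, qc] && !outside[qr, qc]) {
        outside[qr, qc] <- TRUE
        top <- top + 1L
        stack[top] <- qr + (qc - 1L) * nr
      }
    }
  }
  filled <- pm | !outside
  filled[2:(nr - 1), 2:(nc - 1)]
}

# independent Moore boundary walk on the hole-filled mask; weighted steps
oracle_perimeter <- function(mask, pixel_size_um = 1) {
  if (oracle_area(mask) == 1) return(4 * 0.948 * pixel_size_um)
  m <- oracle_fill_holes(mask)
  # pad so neighbour checks never leave the frame
  pm <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
  pm[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  # start at topmost-leftmost pixel; clockwise ring starting west
  ring <- list(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
               c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  start <- NULL
  for (i in seq_len(nrow(pm))) {
    for (j in seq_len(ncol(pm))) if (pm[i, j]) { start <- c(i, j); break }
    if (!is.null(start)) break
  }
  cur <- start; back <- 1L
  n_ax <- 0L; n_dg <- 0L
  first_exit <- NA_integer_; steps <- 0L
  repeat {
    hit <- NA_integer_
    for (k in 0:7) {
      d <- ((back - 1L + k) %% 8L) + 1L
      nb <- cur + unlist(ring[[d]])
      if (pm[nb[1], nb[2]]) { hit <- d; break }
    }
    if (is.na(hit)) break                        # isolated pixel
    if (steps > 0 && all(cur == start) && hit == first_exit) break
    if (steps == 0) first_exit <- hit
    if (ring[[hit]][1] != 0 && ring[[hit]][2] != 0) n_dg <- n_dg + 1L
    else n_ax <- n_ax + 1L
    prev <- ((hit - 2L) %% 8L) + 1L
    bpix <- cur + unlist(ring[[prev]])
    cur <- cur + unlist(ring[[hit]])
    for (k in 1:8) {
      if (all(cur + unlist(ring[[k]]) == bpix)) { back <- k; break }
    }
    steps <- steps + 1L
    if (steps > 10L * sum(pm)) stop("oracle trace did not close")
  }
  (n_ax * 0.948 + n_dg * 1.340) * pixel_size_um
}

oracle_roundness <- function(mask) {
  4 * pi * oracle_area(mask) / oracle_perimeter(mask)^2
}

# direct sum-of-squares one-way ANOVA
oracle_anova_F <- function(values, groups) {
  groups <- as.character(groups)
  gl <- unique(groups)
  grand <- mean(values)
  ssb <- 0; ssw <- 0; k <- length(gl); N <- length(values)
  for (g in gl) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  (ssb / (k - 1)) / (ssw / (N - k))
}

# greedy seed-to-truth matching; returns F1
match_f1 <- function(seeds, truth, radii) {
  matched <- rep(FALSE, nrow(truth)); tp <- 0L
  for (i in seq_len(nrow(seeds))) {
    d <- sqrt((truth$soma_center_y - seeds$y[i])^2 +
                (truth$soma_center_x - seeds$x[i])^2)
    j <- which.min(d)
    if (d[j] <= radii[j] && !matched[j]) { matched[j] <- TRUE; tp <- tp + 1L }
  }
  prec <- tp / nrow(seeds); rec <- tp / nrow(truth)
  2 * prec * rec / (prec + rec)
}

# a random connected blob mask (stamped random walk), for oracle comparisons
random_blob <- function(seed, side = 48) {
  set.seed(seed)
  m <- matrix(FALSE, side, side)
  pos <- c(side / 2, side / 2)
  for (s in 1:40) {
    r <- runif(1, 1, 3.5)
    m <- micromorph:::stamp_disk(m, pos[1], pos[2], r)
    pos <- pmax(4, pmin(side - 3, pos + rnorm(2, 0, 2.2)))
  }
  m
}
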