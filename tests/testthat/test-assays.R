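test_that("phagocytic index counts only particle signal inside cells", {
  cell <- micromorph:::stamp_disk(matrix(FALSE, 64, 64), 30, 30, 10)
  none <- matrix(FALSE, 64, 64)
  expect_identical(phagocytic_index(cell, none), 0)
  expect_identical(phagocytic_index(cell, cell), 1)

  part <- micromorph:::stamp_disk(matrix(FALSE, 64, 64), 30, 30, 3)
  expect_equal(phagocytic_index(cell, part), sum(part) / sum(cell))
  # particle signal outside the cell is ignored
  part_out <- part | micromorph:::stamp_disk(matrix(FALSE, 64, 64), 55, 55, 4)
  expect_identical(phagocytic_index(cell, part_out),
                   phagocytic_index(cell, part))
  expect_error(phagocytic_index(none, part), "zero cell area")
})

test_that("colocalization counts soma centroids inside the marker and grows under dilation", {
  labs <- matrix(0L, 80, 80)
  centers <- rbind(c(20, 20), c(20, 60), c(60, 20), c(60, 60))
  for (i in 1:4)
    labs[micromorph:::stamp_disk(matrix(FALSE, 80, 80),
                                 centers[i, 1], centers[i, 2], 4)] <- i
  expect_identical(count_colocalized(labs, matrix(FALSE, 80, 80)), 0L)
  expect_identical(count_colocalized(labs, matrix(TRUE, 80, 80)), 4L)

  set.seed(21)
  for (rep in 1:10) {
    marker <- matrix(runif(6400) < 0.3, 80, 80)
    n <- count_colocalized(labs, marker)
    # naive per-cell centroid-membership loop
    n_oracle <- 0L
    for (i in 1:4) {
      co <- which(labs == i, arr.ind = TRUE)
      if (marker[round(mean(co[, 1])), round(mean(co[, 2]))])
        n_oracle <- n_oracle + 1L
    }
    expect_identical(n, n_oracle)
    dil <- marker | rbind(marker[-1, ], FALSE) | cbind(marker[, -1], FALSE)
    expect_gte(count_colocalized(labs, dil), n)
  }
})

test_that("cell counting respects the region window", {
  labs <- matrix(0L, 80, 80)
  centers <- rbind(c(20, 20), c(20, 60), c(60, 20), c(60, 60))
  for (i in 1:4)
    labs[micromorph:::stamp_disk(matrix(FALSE, 80, 80),
                                 centers[i, 1], centers[i, 2], 4)] <- i
  expect_identical(count_cells(matrix(0L, 10, 10)), 0L)
  expect_identical(count_cells(labs), 4L)
  expect_identical(count_cells(labs, c(1, 40, 1, 80)), 2L)
  expect_identical(count_cells(labs, c(1, 40, 1, 40)), 1L)
  expect_error(count_cells(labs, c(0, 90, 1, 80)))
})

test_that("gate fractions are exact event ratios, invariant to joint monotone transforms", {
  ev <- tibble::tibble(CD11b = c(10, 10, 10, 10, 0.1),
                       CD45 = c(1, 2, 3, 4, 9))
  g <- gate_spec("CD11b", "CD45", parent_min = 1, child_min = 2.5)
  expect_identical(gate_fraction(ev, g), 0.5)
  # child threshold below every event passes everything
  expect_identical(gate_fraction(ev, gate_spec("CD11b", "CD45",
                                               parent_min = 1,
                                               child_min = 0)), 1)
  # monotone transform applied jointly to events and thresholds
  ev2 <- tibble::tibble(CD11b = asinh(ev$CD11b), CD45 = asinh(ev$CD45))
  g2 <- gate_spec("CD11b", "CD45", parent_min = asinh(1),
                  child_min = asinh(2.5))
  expect_identical(gate_fraction(ev2, g2), gate_fraction(ev, g))

  expect_error(gate_fraction(ev, gate_spec("CD11b", "CD45",
                                           parent_min = 100)), "empty parent")
  expect_error(gate_spec("CD45", "CD45"), "differ")
})

test_that("marking preference is the exact pixel ratio and decreases with outside marks", {
  geom <- mark_geometry()
  sh <- generate_mark_sheet(n_blobs = 12, target_bias = 1,
                            blob_radius_cm = 0.3, seed = 6)$sheet
  expect_equal(as.numeric(marking_preference(sh, geom)), 100)

  # half in, half out by construction
  side <- nrow(sh)
  half <- matrix(FALSE, side, side)
  in_px <- which(micromorph:::stamp_disk(matrix(FALSE, side, side),
                                         50, 50, 6))[1:50]
  half[in_px] <- TRUE
  # (115, 115) px = (23, 23) cm sits outside all four quadrant circles
  out_px <- which(micromorph:::stamp_disk(matrix(FALSE, side, side),
                                          115, 115, 6))[1:50]
  half[out_px] <- TRUE
  expect_equal(as.numeric(marking_preference(half, geom)), 50)

  # adding marks outside every circle strictly decreases the preference
  p0 <- as.numeric(marking_preference(sh, geom))
  sh2 <- sh; sh2[out_px] <- TRUE
  expect_lt(as.numeric(marking_preference(sh2, geom)), p0)

  und <- marking_preference(matrix(FALSE, side, side), geom)
  expect_true(is.na(und) && attr(und, "undefined"))
})

test_that("the SI quotient equals the per-frame membership ratio", {
  geom <- si_geometry()
  # hand-built track: 300 s at the social cylinder, 100 s at the object,
  # 100 s elsewhere, 1 s frames
  n_s <- 300; n_o <- 100; n_e <- 100
  track <- tibble::tibble(
    t = seq_len(n_s + n_o + n_e) - 1,
    y = c(rep(geom$centers["social", 1] + 6, n_s),
          rep(geom$centers["object", 1] - 6, n_o), rep(25, n_e)),
    x = c(rep(geom$centers["social", 2], n_s),
          rep(geom$centers["object", 2], n_o), rep(40, n_e)))
  q <- si_quotient(track, geom)
  expect_equal(as.numeric(q), 3)

  eq <- si_quotient(tibble::tibble(t = 0:3,
                                   y = rep(c(geom$centers["social", 1] + 6,
                                             geom$centers["object", 1] - 6), 2),
                                   x = rep(c(geom$centers["social", 2],
                                             geom$centers["object", 2]), 2)),
                    geom)
  expect_equal(as.numeric(eq), 1)

  none <- si_quotient(tibble::tibble(t = 0:9, y = rep(25, 10), x = rep(25, 10)),
                      geom)
  expect_true(is.na(none) && attr(none, "undefined"))
})
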