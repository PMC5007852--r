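test_that("maximum intensity projection is the per-pixel maximum over z", {
  st <- array(0, dim = c(5, 6, 3))
  st[2, 3, 2] <- 7
  m <- max_intensity_project(st)
  expect_identical(m[2, 3], 7)
  expect_identical(sum(m), 7)

  expect_identical(max_intensity_project(array(4, dim = c(3, 3, 4))),
                   matrix(4, 3, 3))
  expect_error(max_intensity_project(array(0, dim = c(3, 3, 0))), "stack")

  set.seed(5)
  for (i in 1:20) {
    st <- array(rnorm(4 * 5 * 3), dim = c(4, 5, 3))
    m <- max_intensity_project(st)
    for (z in 1:3) expect_true(all(m >= st[, , z]))
    # brute force per pixel
    for (y in 1:4) for (x in 1:5)
      expect_identical(m[y, x], max(st[y, x, ]))
  }
})

test_that("seed detection finds isolated blobs and nothing on flat images", {
  expect_identical(nrow(detect_seeds(matrix(3, 64, 64))), 0L)

  img <- matrix(0, 200, 200)
  centers <- rbind(c(60, 60), c(140, 150))
  for (k in 1:2) {
    g <- outer(seq_len(200) - centers[k, 1], seq_len(200) - centers[k, 2],
               function(a, b) exp(-(a^2 + b^2) / (2 * 16)))
    img <- img + g
  }
  seeds <- detect_seeds(img)
  expect_identical(nrow(seeds), 2L)
  for (k in 1:2) {
    d <- sqrt((seeds$y - centers[k, 1])^2 + (seeds$x - centers[k, 2])^2)
    expect_lte(min(d), 1)
  }
})

test_that("raising the h-maxima depth never increases the seed count", {
  sc <- render_scene(scene_preset("resting", n_cells = 6,
                                  stack_shape = c(6, 256, 256),
                                  min_center_spacing_px = 40, rng_seed = 31))
  mip <- max_intensity_project(sc$stack)
  counts <- vapply(c(0.05, 0.1, 0.2, 0.3, 0.5, 0.7), function(h) {
    nrow(detect_seeds(mip, segmentation_params(h_maxima_depth = h)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a single disk on clean background is recovered almost exactly", {
  img <- matrix(0, 128, 128)
  truth <- micromorph:::stamp_disk(matrix(FALSE, 128, 128), 64, 64, 12)
  img[truth] <- 100
  seeds <- detect_seeds(img)
  expect_identical(nrow(seeds), 1L)
  cells <- segment_cells(img, seeds)
  m <- cells$cells[[1]]$mask
  iou <- length(intersect(m, which(truth))) / length(union(m, which(truth)))
  expect_gte(iou, 0.9)
})

test_that("a seed planted on pure background is flagged with an empty mask", {
  sc <- std_scene()
  mip <- max_intensity_project(sc$stack)
  bgpix <- which(sc$truth_labels == 0)
  # a typical background pixel (at the background median) cannot start a mask
  lin <- bgpix[which.min(abs(mip[bgpix] - stats::median(mip)))]
  y <- ((lin - 1) %% nrow(mip)) + 1; x <- ((lin - 1) %/% nrow(mip)) + 1
  seeds <- tibble::tibble(y = as.integer(y), x = as.integer(x),
                          peak = mip[y, x], smoothed = mip[y, x])
  cells <- segment_cells(mip, seeds)
  expect_identical(cells$cells[[1]]$area, 0L)
  expect_identical(cells$cells[[1]]$reason, "background")
  qc <- qc_masks(cells, mip)
  expect_identical(qc$cells[[1]]$qc, "background")
})

test_that("masks from different seeds never share a pixel", {
  seg <- std_seg()
  idx <- unlist(lapply(seg$cells$cells, `[[`, "mask"))
  expect_identical(anyDuplicated(idx), 0L)
})

test_that("QC rejects border, undersized, oversized and multi-seed masks with reason codes", {
  mk <- function(mask, seed_y, seed_x, label = 1L) {
    list(label = label, seed_y = seed_y, seed_x = seed_x, seed_peak = 100,
         seed_smoothed = 100, mask = which(mask), area = sum(mask),
         reason = "grown", qc = NA_character_, soma = integer(0),
         soma_flag = NA_character_)
  }
  dims <- c(64L, 64L)
  border <- micromorph:::stamp_disk(matrix(FALSE, 64, 64), 6, 2, 5)
  big <- micromorph:::stamp_disk(matrix(FALSE, 64, 64), 32, 32, 30)
  small <- micromorph:::stamp_disk(matrix(FALSE, 64, 64), 20, 40, 2)
  good <- micromorph:::stamp_disk(matrix(FALSE, 64, 64), 30, 20, 8)

  cells <- micromorph:::new_cells(list(
    mk(border, 6L, 2L, 1L), mk(small, 20L, 40L, 2L),
    mk(good, 30L, 20L, 3L)), dims)
  qc <- qc_masks(cells, params = segmentation_params(
    area_bounds_px = c(50, 500)))
  expect_identical(qc$cells[[1]]$qc, "border")
  expect_identical(qc$cells[[2]]$qc, "area_small")
  expect_identical(qc$cells[[3]]$qc, "accepted")

  qc2 <- qc_masks(micromorph:::new_cells(list(mk(big, 32L, 32L)), dims),
                  params = segmentation_params(area_bounds_px = c(50, 500)))
  expect_identical(qc2$cells[[1]]$qc, "area_large")

  # one mask enclosing two seeds is a multi-soma rejection
  two <- micromorph:::new_cells(list(mk(big, 32L, 32L, 1L),
                                     mk(small, 30L, 30L, 2L)), dims)
  qc3 <- qc_masks(two, params = segmentation_params(
    area_bounds_px = c(50, 5000), border_margin_px = 1))
  expect_identical(qc3$cells[[1]]$qc, "multi_soma")
})

test_that("somas are contained in their cells and match generator truth at SNR 8", {
  sc <- std_scene(); seg <- std_seg()
  errs <- c()
  for (cl in seg$cells$cells) {
    if (!identical(cl$qc, "accepted")) next
    expect_true(all(cl$soma %in% cl$mask))
    labs <- sc$truth_labels[cl$mask]
    lid <- as.integer(names(which.max(table(labs[labs > 0]))))
    errs <- c(errs, abs(length(cl$soma) - sc$truth$soma_area_px[lid]) /
                sc$truth$soma_area_px[lid])
  }
  expect_gt(length(errs), 20)
  expect_lt(stats::median(errs), 0.2)
})

test_that("accepted-cell counts agree with a brute-force count of clearly placed cells", {
  sc <- render_scene(scene_preset("activated", n_cells = 8,
                                  stack_shape = c(6, 320, 320), rng_seed = 17))
  seg <- segment_scene(sc$stack)
  n_acc <- sum(vapply(seg$cells$cells, function(cl)
    identical(cl$qc, "accepted"), logical(1)))
  expect_identical(n_acc, 8L)
})
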