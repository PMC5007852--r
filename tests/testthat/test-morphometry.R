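test_that("roundness matches the analytic value for ideal shapes", {
  r <- 3.7
  expect_equal(as.numeric(roundness(pi * r^2, 2 * pi * r)), 1, tolerance = 1e-12)
  a <- 5
  expect_equal(as.numeric(roundness(a^2, 4 * a)), pi / 4, tolerance = 1e-12)
  expect_equal(as.numeric(roundness(10, 2 * (1 + 10))), 40 * pi / 484,
               tolerance = 1e-12)
  expect_error(roundness(10, 0), "perimeter")
  expect_error(roundness(10, -1), "perimeter")
})

test_that("roundness above 1 from discretization is clipped and flagged", {
  r <- roundness(100, sqrt(4 * pi * 100) * 0.99)
  expect_equal(as.numeric(r), 1)
  expect_true(attr(r, "clipped"))
  expect_false(attr(roundness(100, sqrt(4 * pi * 100) * 1.01), "clipped"))
})

test_that("cell spread is zero for a point, translation invariant, and matches the extrema oracle", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  expect_identical(cell_spread(m), 0)
  expect_error(cell_spread(matrix(FALSE, 3, 3)), "empty")

  # plus-shaped mask with independently located extrema
  plus <- matrix(FALSE, 15, 15)
  plus[7:9, 2:14] <- TRUE; plus[2:14, 7:9] <- TRUE
  expect_equal(cell_spread(plus), oracle_spread(plus), tolerance = 1e-12)

  for (s in 1:25) {
    m <- random_blob(s)
    big <- matrix(FALSE, 80, 80)
    set.seed(s + 1000)
    dy <- sample(0:25, 1); dx <- sample(0:25, 1)
    big[dy + seq_len(nrow(m)), dx + seq_len(ncol(m))] <- m
    expect_equal(cell_spread(big), cell_spread(m), tolerance = 1e-12)
  }
})

test_that("all six parameters agree with brute-force pixel-loop oracles on random masks", {
  for (s in 1:14) {
    cl <- generate_cell(cell_regime(if (s %% 2) "resting" else "activated"),
                        seed = s)
    rec <- cl$truth
    expect_equal(rec$cell_area_px, oracle_area(cl$cell_mask))
    expect_equal(rec$soma_area_px, oracle_area(cl$soma_mask))
    expect_equal(rec$perimeter_px, oracle_perimeter(cl$cell_mask),
                 tolerance = 1e-9)
    expect_equal(rec$spread_px, oracle_spread(cl$cell_mask), tolerance = 1e-9)
    expect_equal(rec$eccentricity, oracle_eccentricity(cl$cell_mask),
                 tolerance = 1e-9)
    expect_equal(rec$roundness,
                 min(1, oracle_roundness(cl$cell_mask)), tolerance = 1e-9)
  }
})

test_that("a digital disk measures like a circle", {
  m <- disk_mask(10)
  rec <- measure_cell(m, disk_mask(10, side = nrow(m)) & m, 0.42)
  expect_equal(rec$cell_area_um2, pi * (10 * 0.42)^2, tolerance = 0.05)
  expect_equal(rec$eccentricity, 1, tolerance = 0.05)
})

test_that("pixel size scales lengths linearly and areas quadratically, leaving shape ratios alone", {
  cl <- generate_cell(cell_regime("resting"), seed = 11)
  r1 <- measure_cell(cl$cell_mask, cl$soma_mask, 0.42)
  r2 <- measure_cell(cl$cell_mask, cl$soma_mask, 0.84)
  expect_equal(r2$perimeter_um, 2 * r1$perimeter_um, tolerance = 1e-12)
  expect_equal(r2$spread_um, 2 * r1$spread_um, tolerance = 1e-12)
  expect_equal(r2$cell_area_um2, 4 * r1$cell_area_um2, tolerance = 1e-12)
  expect_equal(r2$soma_area_um2, 4 * r1$soma_area_um2, tolerance = 1e-12)
  expect_identical(r2$roundness, r1$roundness)
  expect_identical(r2$eccentricity, r1$eccentricity)
})

test_that("degenerate line masks are flagged with infinite eccentricity", {
  m <- matrix(FALSE, 9, 9); m[5, 2:8] <- TRUE
  expect_identical(mask_eccentricity(m), Inf)
  rec <- measure_cell(m, m, 0.42)
  expect_true(rec$ecc_degenerate)
})

test_that("measure_scene yields one row per accepted cell and a full header when empty", {
  empty <- measure_scene(list())
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("cell_area_um2", "roundness", "eccentricity") %in%
                    names(empty)))
  cells <- lapply(1:12, function(i) {
    cl <- generate_cell(cell_regime("activated"), seed = i)
    list(cell_id = i, cell_mask = cl$cell_mask, soma_mask = cl$soma_mask)
  })
  tab <- measure_scene(cells, region = "PVN", condition = "HC", animal = "a1")
  expect_identical(nrow(tab), 12L)
  expect_identical(unique(tab$region), "PVN")
})

test_that("stored roundness is self-consistent with stored area and perimeter", {
  for (s in 1:10) {
    cl <- generate_cell(cell_regime("resting"), seed = s)
    rec <- cl$truth
    if (!rec$roundness_clipped)
      expect_equal(rec$roundness,
                   4 * pi * rec$cell_area_px / rec$perimeter_px^2,
                   tolerance = 1e-9)
    expect_lte(rec$soma_area_px, rec$cell_area_px)
  }
})
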