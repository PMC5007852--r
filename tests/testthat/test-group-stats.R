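make_table <- function(values, groups, region = "PFC", parameter = "roundness") {
  tibble::tibble(value = values, group = groups, region = region,
                 parameter = parameter)
}

test_that("normalization pins the control mean at exactly 100 percent", {
  tab <- make_table(c(80, 100, 120, 180, 220), c("HC", "HC", "HC", "SD", "SD"))
  out <- normalize_to_control(tab, "HC")
  expect_equal(out$value[1:3], c(80, 100, 120), tolerance = 1e-12)
  expect_equal(mean(out$value[out$group == "HC"]), 100, tolerance = 1e-12)
  # a treatment with twice the control mean lands at 200
  expect_equal(mean(out$value[out$group == "SD"]), 200, tolerance = 1e-12)

  allc <- normalize_to_control(make_table(rep(7, 4), rep("HC", 4)), "HC")
  expect_true(all(allc$value == 100))

  # idempotence
  again <- normalize_to_control(out, "HC")
  expect_equal(again$value, out$value, tolerance = 1e-12)
})

test_that("strata without a usable control are excluded and reported", {
  tab <- dplyr::bind_rows(
    make_table(c(1, 2, 3, 4), c("HC", "HC", "SD", "SD"), parameter = "roundness"),
    make_table(c(0, 0, 3, 4), c("HC", "HC", "SD", "SD"), parameter = "spread"))
  out <- normalize_to_control(tab, "HC")
  excl <- attr(out, "excluded")
  expect_identical(excl$parameter, "spread")
  expect_false("spread" %in% out$parameter)
})

test_that("one-way ANOVA matches the direct sum-of-squares oracle and the t-test identity", {
  set.seed(10)
  for (rep in 1:5) {
    d <- tibble::tibble(value = rnorm(24, rep(c(0, 0.5, 1), each = 8)),
                        group = rep(c("a", "b", "c"), each = 8))
    an <- one_way_anova(d)
    expect_equal(an$F, oracle_anova_F(d$value, d$group), tolerance = 1e-10)
    expect_identical(an$df_between, 2L)
    expect_identical(an$df_within, 21L)
  }

  d2 <- tibble::tibble(value = rnorm(20), group = rep(c("a", "b"), each = 10))
  an2 <- one_way_anova(d2)
  tt <- stats::t.test(value ~ group, data = d2, var.equal = TRUE)
  expect_equal(an2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an2$p, tt$p.value, tolerance = 1e-10)

  # identical data permuted across groups: F = 0
  v <- rep(c(1, 2, 3, 4), 3)
  d3 <- tibble::tibble(value = v, group = rep(c("a", "b", "c"), each = 4))
  expect_lt(one_way_anova(d3)$F, 1e-20)

  expect_error(one_way_anova(tibble::tibble(value = 1:4,
                                            group = rep("a", 4))), "2 groups")
  expect_error(one_way_anova(tibble::tibble(value = rep(1, 6),
                                            group = rep(c("a", "b"), 3))),
               "degenerate")
})

test_that("Bonferroni post hoc uses pooled-variance t tests with capped adjustment", {
  set.seed(11)
  d <- tibble::tibble(value = rnorm(18, rep(c(0, 1, 3), each = 6)),
                      group = rep(c("a", "b", "c"), each = 6))
  an <- one_way_anova(d)
  ph <- bonferroni_posthoc(d, an)
  expect_identical(nrow(ph), 3L)
  expect_identical(unique(ph$m), 3L)
  expect_equal(ph$p_adj, pmin(1, 3 * ph$p_raw), tolerance = 1e-12)

  # t values match the pooled-MSE formula oracle
  for (j in seq_len(nrow(ph))) {
    m1 <- mean(d$value[d$group == ph$group1[j]])
    m2 <- mean(d$value[d$group == ph$group2[j]])
    expect_equal(ph$t[j], (m1 - m2) / sqrt(an$mse * (1 / 6 + 1 / 6)),
                 tolerance = 1e-12)
  }

  # cross-check raw p values against stats::pairwise.t.test with pooled sd
  pw <- stats::pairwise.t.test(d$value, d$group, p.adjust.method = "none",
                               pool.sd = TRUE)
  expect_equal(ph$p_raw[ph$group1 == "a" & ph$group2 == "b"],
               pw$p.value["b", "a"], tolerance = 1e-10)
  expect_equal(ph$p_raw[ph$group1 == "b" & ph$group2 == "c"],
               pw$p.value["c", "b"], tolerance = 1e-10)
})

test_that("summary-statistics ANOVA reproduces the raw-data ANOVA on balanced designs", {
  set.seed(12)
  for (rep in 1:5) {
    v <- rnorm(30, rep(c(0, 1, 2), each = 10))
    g <- rep(c("a", "b", "c"), each = 10)
    raw <- one_way_anova(tibble::tibble(value = v, group = g))
    means <- tapply(v, g, mean)
    sems <- tapply(v, g, function(x) stats::sd(x) / sqrt(length(x)))
    rec <- anova_from_summary(means, sems, rep(10, 3))
    expect_equal(rec$F, raw$F, tolerance = 1e-9)
    expect_equal(rec$p, raw$p, tolerance = 1e-9)
    expect_equal(rec$mse, raw$mse, tolerance = 1e-9)
  }
  eq <- anova_from_summary(c(5, 5, 5), c(0.3, 0.4, 0.2), c(6, 6, 6))
  expect_equal(eq$F, 0, tolerance = 1e-12)
  expect_error(anova_from_summary(5, 0.3, 6), "2 groups")
})

test_that("Spearman correlation handles monotone pairs, ties and constants", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, -2 * x + 1)$rho, -1)

  set.seed(13)
  xt <- sample(rep(1:4, each = 3)); yt <- rnorm(12) + xt
  sp <- spearman_cor(xt, yt)
  # brute-force: Pearson on average ranks
  expect_equal(sp$rho, stats::cor(rank(xt), rank(yt)), tolerance = 1e-12)
  ct <- stats::cor.test(xt, yt, method = "spearman", exact = FALSE)
  expect_equal(sp$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(sp$p, ct$p.value, tolerance = 1e-9)

  const <- spearman_cor(rep(2, 5), 1:5)
  expect_true(is.na(const$rho))
  expect_identical(const$flag, "constant_input")
})
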