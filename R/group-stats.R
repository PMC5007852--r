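#' Normalize measurements to the control group
#'
#' Within each (region, parameter) stratum, every value is divided by the
#' control-group mean and multiplied by 100, so the control mean is exactly
#' 100 percent.  Strata whose control group is absent or has (near-)zero mean
#' are excluded and reported in the \code{"excluded"} attribute.
#'
#' @param table long-format data frame with columns \code{value},
#'   \code{group}, \code{region}, \code{parameter}.
#' @param control_label label of the control group (e.g. "HC").
#' @return the table with \code{value} on the percent scale; excluded strata
#'   (if any) in \code{attr(, "excluded")}.
#' @export
normalize_to_control <- function(table, control_label) {
  stopifnot(all(c("value", "group", "region", "parameter") %in% names(table)))
  tab <- tibble::as_tibble(table)
  key <- paste(tab$region, tab$parameter, sep = "\r")
  ctrl_means <- tapply(tab$value[tab$group == control_label],
                       key[tab$group == control_label], mean)
  tab$.ctrl <- as.numeric(ctrl_means[key])
  bad <- is.na(tab$.ctrl) | abs(tab$.ctrl) < .Machine$double.eps^0.5
  excluded <- unique(tab[bad, c("region", "parameter")])
  out <- tab[!bad, ]
  out$value <- out$value / out$.ctrl * 100
  out$.ctrl <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' One-way ANOVA
#'
#' Fixed-effects one-way analysis of variance (fitted via \code{stats::lm}),
#' returning the F statistic, degrees of freedom, p-value and pooled
#' mean-square error used by the Bonferroni post hoc tests.
#'
#' @param data data frame with a numeric \code{value} and a \code{group}
#'   column (>= 2 groups, >= 2 values each).
#' @return list of class \code{anova_result}: \code{F}, \code{df_between},
#'   \code{df_within}, \code{p}, \code{mse} and per-group summaries.
#' @export
one_way_anova <- function(data) {
  stopifnot(all(c("value", "group") %in% names(data)))
  g <- factor(data$group)
  v <- data$value
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 values")
  if (stats::var(v) == 0) stop("degenerate data: zero total variance")
  fit <- stats::lm(v ~ g)
  an <- stats::anova(fit)
  res <- list(F = an$`F value`[1], df_between = an$Df[1], df_within = an$Df[2],
              p = an$`Pr(>F)`[1], mse = an$`Mean Sq`[2],
              groups = tibble::tibble(group = levels(g),
                                      n = as.integer(table(g)),
                                      mean = unname(tapply(v, g, mean)[levels(g)])))
  class(res) <- "anova_result"
  res
}

#' Bonferroni post hoc pairwise comparisons
#'
#' Classical pooled-variance pairwise t tests using the ANOVA mean-square
#' error and within-group degrees of freedom; each raw p is multiplied by the
#' number of comparisons m = k(k-1)/2 and capped at 1.
#'
#' @param data the data frame passed to [one_way_anova()].
#' @param anova the corresponding \code{anova_result}.
#' @return tibble: group pair, t statistic, raw and Bonferroni-adjusted p.
#' @export
bonferroni_posthoc <- function(data, anova) {
  stopifnot(inherits(anova, "anova_result"))
  gs <- anova$groups
  k <- nrow(gs)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(anova$mse * (1 / gs$n[i1] + 1 / gs$n[i2]))
    tval <- unname((gs$mean[i1] - gs$mean[i2]) / se)
    p <- 2 * stats::pt(-abs(tval), anova$df_within)
    tibble::tibble(group1 = gs$group[i1], group2 = gs$group[i2],
                   diff = unname(gs$mean[i1] - gs$mean[i2]), t = tval,
                   p_raw = p, p_adj = min(1, m * p))
  })
  out <- dplyr::bind_rows(rows)
  out$m <- m
  out
}

#' Reconstruct a one-way ANOVA from printed summary statistics
#'
#' Recovers group variances from standard errors of the mean
#' (\eqn{s_i^2 = n_i \cdot sem_i^2}), pools them into the within-group sum of
#' squares, and computes the F statistic without raw data.  On summaries taken
#' from a raw dataset this reproduces [one_way_anova()] exactly.
#'
#' @param means,sems,ns numeric vectors of group means, SEMs and sizes
#'   (k >= 2, all n >= 2, sems > 0).
#' @return an \code{anova_result}.
#' @export
anova_from_summary <- function(means, sems, ns) {
  k <- length(means)
  if (k < 2) stop("need at least 2 groups")
  stopifnot(length(sems) == k, length(ns) == k, all(ns >= 2), all(sems > 0))
  vars <- ns * sems^2
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum((ns - 1) * vars)
  df_b <- k - 1
  df_w <- N - k
  mse <- ss_w / df_w
  Fv <- (ss_b / df_b) / mse
  res <- list(F = Fv, df_between = df_b, df_within = df_w,
              p = stats::pf(Fv, df_b, df_w, lower.tail = FALSE), mse = mse,
              groups = tibble::tibble(group = as.character(seq_len(k)),
                                      n = as.integer(ns), mean = means))
  class(res) <- "anova_result"
  res
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive their mean rank), with
#' a two-sided p-value from the t approximation on n - 2 degrees of freedom.
#' Constant input yields an undefined, flagged result.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list: \code{rho}, \code{p}, \code{n}, \code{flag} (NA or
#'   "constant_input").
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    return(list(rho = NA_real_, p = NA_real_, n = n, flag = "constant_input"))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), n - 2)
  }
  list(rho = rho, p = p, n = n, flag = NA_character_)
}

#' Per-stratum ANOVA table over morphometric records
#'
#' Converts a morphometric record table to long format (the six parameters,
#' um-scaled where dimensional), normalizes each (region, parameter) stratum
#' to the control group, and runs one-way ANOVA plus Bonferroni post hoc
#' tests per stratum.
#'
#' @param records tibble from [measure_scene()] with region/condition/animal
#'   metadata filled.
#' @param control_label control condition label.
#' @return list: \code{anova} (one row per region x parameter),
#'   \code{posthoc} (pairwise rows), \code{normalized} (long table).
#' @export
morphometry_group_stats <- function(records, control_label = "HC") {
  long <- records_to_group_table(records)
  if (nrow(long) == 0) {
    return(list(anova = tibble::tibble(), posthoc = tibble::tibble(),
                normalized = long, note = "nothing-to-test"))
  }
  norm <- normalize_to_control(long, control_label)
  strata <- unique(norm[, c("region", "parameter")])
  an_rows <- list(); ph_rows <- list()
  for (i in seq_len(nrow(strata))) {
    sub <- norm[norm$region == strata$region[i] &
                  norm$parameter == strata$parameter[i], ]
    if (length(unique(sub$group)) < 2 || any(table(sub$group) < 2)) next
    an <- one_way_anova(sub)
    ph <- bonferroni_posthoc(sub, an)
    an_rows[[length(an_rows) + 1L]] <- tibble::tibble(
      region = strata$region[i], parameter = strata$parameter[i],
      F = an$F, df_between = an$df_between, df_within = an$df_within,
      p = an$p, mse = an$mse)
    ph$region <- strata$region[i]; ph$parameter <- strata$parameter[i]
    ph_rows[[length(ph_rows) + 1L]] <- ph
  }
  list(anova = dplyr::bind_rows(an_rows), posthoc = dplyr::bind_rows(ph_rows),
       normalized = norm)
}

# the six reported parameters, um-scaled where dimensional
MORPH_PARAMS <- c("cell_area", "soma_area", "perimeter", "spread",
                  "eccentricity", "roundness")

#' Morphometric records to long group table
#'
#' Cells within one imaged field are pseudo-replicates (they share the field's
#' acquisition), so the default analysis unit is the per-animal/field mean —
#' the mean-per-animal design of the experiments this pipeline emulates.
#' Records with non-finite values (degenerate eccentricity) are dropped first.
#'
#' @param records tibble from [measure_scene()].
#' @param unit "animal" (default) aggregates to per-animal means; "cell"
#'   keeps one row per cell.
#' @return tibble with columns value, group, region, parameter, animal.
#' @export
records_to_group_table <- function(records, unit = c("animal", "cell")) {
  unit <- match.arg(unit)
  cols <- c(cell_area = "cell_area_um2", soma_area = "soma_area_um2",
            perimeter = "perimeter_um", spread = "spread_um",
            eccentricity = "eccentricity", roundness = "roundness")
  rows <- lapply(names(cols), function(p) {
    tibble::tibble(value = records[[cols[[p]]]],
                   group = records$condition, region = records$region,
                   parameter = p, animal = records$animal)
  })
  out <- dplyr::bind_rows(rows)
  out <- out[is.finite(out$value), ]
  if (unit == "animal" && nrow(out) > 0) {
    key <- paste(out$group, out$region, out$parameter, out$animal, sep = "\r")
    agg <- tapply(out$value, key, mean)
    parts <- strsplit(names(agg), "\r", fixed = TRUE)
    out <- tibble::tibble(value = as.numeric(agg),
                          group = vapply(parts, `[[`, "", 1),
                          region = vapply(parts, `[[`, "", 2),
                          parameter = vapply(parts, `[[`, "", 3),
                          animal = vapply(parts, `[[`, "", 4))
  }
  out
}
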