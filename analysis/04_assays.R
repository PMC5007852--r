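#!/usr/bin/env Rscript

# Scalar assay battery on synthetic inputs with known ground truth:
# phagocytic index, flow-gate fractions (CD45-hi within CD11b-hi, CD68-hi
# within microglia), urine-marking preference and social-interaction
# quotient.  Emulates a control vs chronic-stress contrast in the generator
# settings and writes a tidy summary under results/assays/.

suppressMessages(library(micromorph))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

out_dir <- "results/assays"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
rows <- list()
add <- function(kind, group, value, truth, n) {
  rows[[length(rows) + 1L]] <<- tibble::tibble(
    kind = kind, group = group, value = value, truth = truth, n = n)
}

# phagocytosis: chronic-stress microglia engulf more labelled material
ph_levels <- c(HC = 0.08, CSD = 0.2)
for (g in names(ph_levels)) {
  for (i in 1:8) {
    sc <- generate_phagocytosis_scene(5, ph_levels[[g]],
                                      seed = derive_seed(seed, paste0("ph", g), i))
    add("phagocytic_index", g,
        phagocytic_index(sc$cell_mask, sc$particle_mask),
        sc$truth_engulfed_fraction, sum(sc$cell_mask))
  }
}

# flow gating: CD68-hi fraction within CD11b-hi CD45-lo microglia
thr <- 2 + 4 * 0.15
for (g in c("HC", "CSD")) {
  f68 <- if (g == "HC") 0.12 else 0.3
  ev <- generate_flow_events(
    default_flow_populations(n_events = 10000, frac_cd68hi = f68),
    seed = derive_seed(seed, paste0("flow", g)))
  e <- ev$events
  e$l11b <- log10(e$CD11b); e$l45 <- log10(e$CD45); e$l68 <- log10(e$CD68)
  cd45hi <- gate_fraction(e, gate_spec("l11b", "l45", parent_min = thr,
                                       child_min = thr))
  mg <- e[e$l11b >= thr & e$l45 < thr, ]
  cd68hi <- gate_fraction(mg, gate_spec("l11b", "l68", parent_min = thr,
                                        child_min = thr))
  truth68 <- sum(e$truth_label == "microglia_cd68hi") /
    sum(e$truth_label %in% c("microglia_cd68hi", "microglia_cd68lo"))
  add("gate_cd45hi_fraction", g, cd45hi,
      sum(e$truth_label == "macrophage") / sum(e$truth_label != "debris"),
      nrow(e))
  add("gate_cd68hi_fraction", g, cd68hi, truth68, nrow(mg))
}

# behavior: chronic stress lowers marking preference and the SI quotient
for (g in c("HC", "CSD")) {
  bias <- if (g == "HC") 0.6 else 0.2
  soc <- if (g == "HC") 2 else 0.8
  for (i in 1:8) {
    sh <- generate_mark_sheet(n_blobs = 25, target_bias = bias,
                              seed = derive_seed(seed, paste0("usm", g), i))
    add("marking_preference", g, as.numeric(marking_preference(sh$sheet, sh$geometry)),
        as.numeric(sh$truth_preference), sum(sh$sheet))
    tr <- generate_track(track_spec(propensity_social = soc),
                         seed = derive_seed(seed, paste0("si", g), i))
    add("si_quotient", g, as.numeric(si_quotient(tr$track, tr$geometry)),
        as.numeric(tr$truth_quotient), nrow(tr$track))
  }
}

tab <- dplyr::bind_rows(rows)
write_table(tab, file.path(out_dir, "assay_results.csv"))
agg <- aggregate(value ~ kind + group, tab, mean)
for (i in seq_len(nrow(agg)))
  cat(sprintf("%-24s %-4s mean = %.3f\n", agg$kind[i], agg$group[i], agg$value[i]))
cat("max |assay - truth| =", max(abs(tab$value - tab$truth)), "\n")
cat("wrote", file.path(out_dir, "assay_results.csv"), "\n")
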