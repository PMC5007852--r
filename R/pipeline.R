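#' Pipeline configuration
#'
#' Describes a full simulated experiment: which regimes make up each
#' condition, the regions imaged, fields per region and condition, cells per
#' field, and the segmentation/statistics options.  One top-level seed is
#' split deterministically per field so every stage can be re-run
#' independently yet reproducibly.
#'
#' @param conditions named character vector mapping condition label to cell
#'   regime ("resting" or "activated"); the first entry is the control.
#' @param regions region labels.
#' @param fields_per_group number of imaged fields per region x condition.
#' @param n_cells cells per field.
#' @param stack_shape c(z, y, x) voxels per field.
#' @param min_center_spacing_px minimum soma spacing; smaller fields need a
#'   tighter packing than the full-frame default.
#' @param snr scene signal-to-noise ratio.
#' @param pixel_size_um pixel size (um/px).
#' @param params a [segmentation_params()].
#' @param seed top-level integer seed.
#' @param out_dir optional output directory; when set, stage outputs and a
#'   frozen config snapshot are written there.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(conditions = c(HC = "resting", ASD = "resting",
                                           CSD = "resting", LPS = "activated"),
                            regions = c("PFC", "HIPP", "PVN"),
                            fields_per_group = 6, n_cells = 30,
                            stack_shape = c(10, 512, 512),
                            min_center_spacing_px = 55, snr = 8,
                            pixel_size_um = 0.42,
                            params = segmentation_params(), seed = 1L,
                            out_dir = NULL) {
  stopifnot(length(conditions) >= 1, !is.null(names(conditions)),
            all(conditions %in% c("resting", "activated")))
  structure(list(conditions = conditions, regions = regions,
                 fields_per_group = fields_per_group, n_cells = n_cells,
                 stack_shape = stack_shape,
                 min_center_spacing_px = min_center_spacing_px, snr = snr,
                 pixel_size_um = pixel_size_um, params = params,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the simulate - segment - measure - test pipeline
#'
#' For every region x condition x field: renders a synthetic scene, projects
#' it, detects seeds, grows and QC's masks, extracts somas and measures the
#' six morphometric parameters; then normalizes to the control condition and
#' runs one-way ANOVA with Bonferroni post hoc tests per (region, parameter)
#' stratum.  Deterministic given the config seed.  With \code{out_dir} set,
#' records, QC log, statistics and a frozen config + seed snapshot are
#' written with stable filenames.
#'
#' @param config a [pipeline_config()].
#' @param keep_scenes keep rendered stacks in the result (memory-heavy).
#' @return list: \code{records}, \code{qc_log}, \code{stats} (see
#'   [morphometry_group_stats()]), \code{truth}, \code{config}.
#' @export
run_pipeline <- function(config = pipeline_config(), keep_scenes = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  control <- names(config$conditions)[1]
  records <- list(); qc_logs <- list(); truths <- list(); scenes <- list()
  for (region in config$regions) {
    for (ci in seq_along(config$conditions)) {
      cond <- names(config$conditions)[ci]
      regime <- config$conditions[[ci]]
      for (f in seq_len(config$fields_per_group)) {
        fid <- paste(region, cond, f, sep = "_")
        sd_f <- derive_seed(config$seed, paste("simulate", fid))
        scene <- render_scene(scene_preset(
          regime, n_cells = config$n_cells, stack_shape = config$stack_shape,
          min_center_spacing_px = config$min_center_spacing_px,
          snr = config$snr, pixel_size_um = config$pixel_size_um,
          rng_seed = sd_f))
        seg <- tryCatch(segment_scene(scene$stack, config$params),
                        error = function(e)
                          stop("stage segment failed for field ", fid, ": ",
                               conditionMessage(e)))
        rec <- measure_scene(seg$cells, config$pixel_size_um,
                             region = region, condition = cond, animal = fid)
        rec$field <- fid
        records[[fid]] <- rec
        lg <- seg$cells$log
        if (!is.null(lg)) { lg$field <- fid; qc_logs[[fid]] <- lg }
        tr <- scene$truth
        if (nrow(tr) > 0) { tr$field <- fid; tr$region <- region; tr$condition <- cond }
        truths[[fid]] <- tr
        if (keep_scenes) scenes[[fid]] <- scene
      }
    }
  }
  records <- dplyr::bind_rows(records)
  if (nrow(records) == 0) records <- {
    r <- empty_morphometric_table(); r$field <- character(0); r
  }
  stats <- morphometry_group_stats(records, control_label = control)
  out <- list(records = records, qc_log = dplyr::bind_rows(qc_logs),
              stats = stats, truth = dplyr::bind_rows(truths),
              config = config)
  if (keep_scenes) out$scenes <- scenes
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(records, file.path(config$out_dir, "morphometric_records.csv"))
    if (nrow(out$qc_log) > 0)
      write_table(out$qc_log, file.path(config$out_dir, "qc_log.csv"))
    if (nrow(stats$anova) > 0) {
      write_table(stats$anova, file.path(config$out_dir, "anova_table.csv"))
      write_table(stats$posthoc, file.path(config$out_dir, "posthoc_table.csv"))
    }
    snap <- config
    snap$params <- unclass(snap$params)
    snap$conditions <- as.list(snap$conditions)
    write_run_config(unclass(snap), file.path(config$out_dir, "run_config.json"))
  }
  out
}
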