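# End-to-end pipeline orchestration: simulate -> segment -> quantify ->
# classify -> summarize -> RPS -> rank/select -> QC, reproducible from
# (config, seed), with per-stage count logging.

RUN_CONFIG_KEYS <- list(
  top = c("seed", "outdir", "synthdata", "segmentation", "foci_quant",
          "cell_classify", "screen_stats"),
  synthdata = c("n_compounds", "n_replicates", "n_control", "n_dox",
                "dox_dose", "effects", "mode", "n_fields", "cells_per_well",
                "image_size", "cells_per_field", "p_nonsignal"),
  segmentation = c("window", "offset", "smooth_sigma", "watershed_tolerance",
                   "min_area", "max_area", "crop_size", "include_border"),
  foci_quant = c("d_min", "d_max", "detection_k", "min_separation"),
  cell_classify = c("backend", "n_train", "positivity_threshold"),
  screen_stats = c("readout", "n_select"))

#' Validated pipeline run configuration
#'
#' Nested configuration with one section per stage; unknown keys are
#' rejected before any computation. The MD5 hash of the validated
#' configuration is embedded in every output file.
#'
#' @param seed master seed for the run.
#' @param outdir output directory for result CSVs.
#' @param synthdata,segmentation,foci_quant,cell_classify,screen_stats
#'   named lists of per-stage overrides (see `fociscreen:::RUN_CONFIG_KEYS`
#'   for accepted keys).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, outdir = tempfile("fociscreen_run_"),
                       synthdata = list(), segmentation = list(),
                       foci_quant = list(), cell_classify = list(),
                       screen_stats = list()) {
  cfg <- list(seed = as.integer(seed), outdir = outdir,
              synthdata = synthdata, segmentation = segmentation,
              foci_quant = foci_quant, cell_classify = cell_classify,
              screen_stats = screen_stats)
  for (sec in c("synthdata", "segmentation", "foci_quant", "cell_classify",
                "screen_stats")) {
    unknown <- setdiff(names(cfg[[sec]]), RUN_CONFIG_KEYS[[sec]])
    if (length(unknown))
      stop_fs("unknown key(s) in config section '%s': %s", sec,
              paste(unknown, collapse = ", "))
  }
  class(cfg) <- "run_config"
  cfg
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[fociscreen] ", fmt), ...))
}

#' Run the full screening pipeline
#'
#' In `mode = "images"` every well is rendered, segmented, quantified by the
#' threshold backend, and classified; in `mode = "fast"` per-well true cell
#' records are summarized directly (no pixels). Both modes end in RPS
#' normalization, ranking/selection, and QC. Outputs (well summaries,
#' compound results, QC tables, and in images mode per-cell records) are
#' written as CSV under `config$outdir`, each carrying the config hash; the
#' full bundle is returned invisibly.
#'
#' @param config a [run_config()].
#' @param verbose log per-stage counts?
#' @return list of class `pipeline_result`: `wells`, `screen`
#'   (a `screen_result`), `cells` (images mode), `classifier` (images mode),
#'   `config`, `hash`, `mode`, `files`.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  if (!inherits(config, "run_config")) stop_fs("config must be a run_config()")
  hash <- config_hash(config)
  sd_ <- config$synthdata
  seg_ <- config$segmentation
  fq_ <- config$foci_quant
  cc_ <- config$cell_classify
  ss_ <- config$screen_stats

  sim_args <- list()
  if (!is.null(sd_$image_size)) sim_args$image_size <- sd_$image_size
  if (!is.null(sd_$cells_per_field)) sim_args$cells_per_field <- sd_$cells_per_field
  if (!is.null(sd_$p_nonsignal)) sim_args$p_nonsignal <- sd_$p_nonsignal
  scfg <- do.call(sim_config, sim_args)

  design <- screen_design(
    n_compounds = sd_$n_compounds %||% 315L,
    n_replicates = sd_$n_replicates %||% 3L,
    n_control = sd_$n_control %||% 4L,
    n_dox = sd_$n_dox %||% 4L,
    dox_dose = sd_$dox_dose %||% 0.5,
    effects = sd_$effects %||% numeric(0))
  mode <- sd_$mode %||% "fast"
  pos_thr <- cc_$positivity_threshold %||% 5L
  stage_log(verbose, "design: %d compounds x %d replicates, %d wells, mode=%s",
            design$n_compounds, design$n_replicates, nrow(design$layout), mode)

  sim <- simulate_screen(design, scfg, seed = config$seed, mode = mode,
                         cells_per_well = sd_$cells_per_well %||% 600,
                         n_fields = sd_$n_fields %||% 1L,
                         positivity_threshold = pos_thr)

  cells_df <- NULL; model <- NULL
  if (mode == "images") {
    sp_args <- seg_[intersect(names(seg_),
                              c("window", "offset", "smooth_sigma",
                                "watershed_tolerance", "min_area", "max_area"))]
    sp <- do.call(segment_params, c(list(config = scfg), sp_args))
    fp <- foci_params(d_min = fq_$d_min %||% 3L, d_max = fq_$d_max %||% 9L,
                      detection_k = fq_$detection_k %||% 4,
                      min_separation = fq_$min_separation %||% 3)
    crop_size <- seg_$crop_size %||% scfg$crop_size

    n_train <- cc_$n_train %||% 1200L
    stage_log(verbose, "training classifier (backend=%s, n=%d)",
              cc_$backend %||% "feature_baseline", n_train)
    tset <- make_training_set(n_train, scfg,
                              trt = treatment(dose = design$dox_dose),
                              seed = derive_seed(config$seed, 900001L),
                              positivity_threshold = pos_thr)
    model <- train_classifier(tset, backend = cc_$backend %||% "feature_baseline",
                              seed = derive_seed(config$seed, 900002L),
                              fparams = fp)

    lay <- design$layout
    wells <- list(); cells <- list()
    n_seg <- 0L; n_class <- 0L
    for (i in seq_len(nrow(lay))) {
      wellset <- sim$images[[i]]
      recs <- list(); fcounts <- list()
      for (fs in wellset) {
        seg <- segment_nuclei(fs$field, sp)
        crops <- extract_crops(fs$field, seg$label_map, seg$instances,
                               crop_size = crop_size,
                               include_border = isTRUE(seg_$include_border))
        n_seg <- n_seg + nrow(seg$instances)
        if (!length(crops)) next
        crops <- lapply(crops, normalize_crop)
        dets <- lapply(crops, detect_foci, params = fp)
        recs[[length(recs) + 1L]] <- classify(model, crops)
        fcounts[[length(fcounts) + 1L]] <- data.frame(
          foci_count = vapply(dets, `[[`, 1L, "foci_count"),
          not_evaluable = vapply(dets, `[[`, TRUE, "not_evaluable"))
      }
      rec <- if (length(recs)) do.call(rbind, recs) else
        classify(model, list())
      fc <- if (length(fcounts)) do.call(rbind, fcounts) else
        data.frame(foci_count = integer(0), not_evaluable = logical(0))
      n_class <- n_class + nrow(rec)
      wells[[i]] <- summarize_well(rec, lay[i, ],
                                   foci = if (nrow(fc)) fc else NULL)
      if (nrow(rec)) cells[[length(cells) + 1L]] <-
        cbind(rec, replicate = lay$replicate[i])
    }
    well_table <- do.call(rbind, wells)
    cells_df <- if (length(cells)) do.call(rbind, cells) else NULL
    stage_log(verbose, "segmented %d nuclei; classified %d cells across %d wells",
              n_seg, n_class, nrow(well_table))
  } else {
    well_table <- sim$wells
    well_table$mean_foci_per_cell <- well_table$foci_per_cell
    stage_log(verbose, "fast mode: %d wells summarized from true cell records",
              nrow(well_table))
  }

  readout <- ss_$readout %||% "pct_foci_positive"
  if (readout == "foci_per_cell") readout <- "mean_foci_per_cell"
  screen <- rank_screen(well_table, readout = readout,
                        n_select = ss_$n_select %||% 12L)
  stage_log(verbose, "ranked %d compounds; %d selected (readout=%s)",
            nrow(screen$compounds), sum(screen$compounds$selected), readout)

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    wells = write_result_csv(well_table,
                             file.path(config$outdir, "well_summaries.csv"), hash),
    compounds = write_result_csv(screen$compounds,
                                 file.path(config$outdir, "compound_results.csv"), hash),
    qc_ecdf = write_result_csv(screen$qc$ecdf,
                               file.path(config$outdir, "qc_ecdf.csv"), hash),
    qc_hist = write_result_csv(screen$qc$histogram,
                               file.path(config$outdir, "qc_histogram.csv"), hash))
  if (!is.null(cells_df))
    files["cells"] <- write_result_csv(cells_df,
                                       file.path(config$outdir, "cells.csv"), hash)
  jsonlite::write_json(
    list(version = fs_version(), config_hash = hash, mode = mode,
         seed = config$seed, readout = readout,
         positivity_threshold = pos_thr,
         qc_p_value = screen$qc$comparison$p_value),
    file.path(config$outdir, "provenance.json"), auto_unbox = TRUE, digits = NA)

  invisible(structure(list(wells = well_table, screen = screen,
                           cells = cells_df, classifier = model,
                           config = config, hash = hash, mode = mode,
                           files = files),
                      class = "pipeline_result"))
}
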