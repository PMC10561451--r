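# Screen layout and whole-screen simulation.

well_names_96 <- function() {
  as.vector(t(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0)))
}

#' Design a plate-based compound screen
#'
#' Builds the replicate/plate/well layout for an n-compound screen on
#' 96-well plates. Every plate carries its own normal-control wells (no
#' damage, no compound) and model wells (damaging dose alone), with the
#' remaining wells assigned to compounds; compounds are co-incubated with
#' the damaging dose. The default geometry — 4 control + 4 model wells per
#' plate, 88 compound wells — places 315 compounds on 4 plates per
#' replicate, 3 replicates.
#'
#' @param n_compounds number of library compounds (default 315).
#' @param n_replicates independent replicate screens (default 3).
#' @param n_control,n_dox control and damage-model wells per plate.
#' @param dox_dose damaging dose in uM applied to model and compound wells.
#' @param compound_dose compound dose in uM (metadata; default 50).
#' @param duration_h exposure duration in hours (metadata; default 1).
#' @param effects named numeric vector: compound_id -> true fractional
#'   suppression e in \[0,1\]. Unnamed compounds default to 0 (inactive).
#'   Names not present in the library are an error.
#' @return object of class `screen_design`: the layout data frame
#'   (`replicate, plate, well, role, compound_id, dose_uM, duration_h,
#'   effect_e`) plus the true-active table.
#' @export
screen_design <- function(n_compounds = 315L, n_replicates = 3L,
                          n_control = 4L, n_dox = 4L,
                          dox_dose = 0.5, compound_dose = 50,
                          duration_h = 1, effects = numeric(0)) {
  if (n_control < 1L || n_dox < 1L)
    stop_fs("every plate needs at least one control and one DOX well")
  compounds <- sprintf("CPD%03d", seq_len(n_compounds))
  if (length(effects)) {
    if (is.null(names(effects)) || any(!nzchar(names(effects))))
      stop_fs("effects must be a named vector of compound ids")
    unknown <- setdiff(names(effects), compounds)
    if (length(unknown))
      stop_fs("unknown compound in true-active table: %s",
              paste(unknown, collapse = ", "))
    if (any(effects < 0 | effects > 1)) stop_fs("effects must lie in [0, 1]")
  }
  eff <- stats::setNames(numeric(n_compounds), compounds)
  eff[names(effects)] <- effects

  wells <- well_names_96()
  n_cpd_per_plate <- length(wells) - n_control - n_dox
  n_plates <- ceiling(n_compounds / n_cpd_per_plate)
  rows <- list()
  for (rep_i in seq_len(n_replicates)) {
    remaining <- compounds
    for (p in seq_len(n_plates)) {
      plate <- sprintf("R%d-P%d", rep_i, p)
      take <- utils::head(remaining, n_cpd_per_plate)
      remaining <- utils::tail(remaining, -length(take))
      role <- c(rep("control", n_control), rep("dox", n_dox),
                rep("compound", length(take)))
      cpd <- c(rep(NA_character_, n_control + n_dox), take)
      w <- wells[seq_along(role)]
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = rep_i, plate = plate, well = w, role = role,
        compound_id = cpd,
        dose_uM = ifelse(role == "control", 0, dox_dose),
        compound_dose_uM = ifelse(role == "compound", compound_dose, 0),
        duration_h = duration_h,
        effect_e = ifelse(role == "compound", unname(eff[cpd]), 0))
    }
  }
  layout <- do.call(rbind, rows)
  layout$effect_e[is.na(layout$effect_e)] <- 0
  structure(list(layout = layout, effects = eff,
                 n_compounds = n_compounds, n_replicates = n_replicates,
                 dox_dose = dox_dose, compound_dose = compound_dose,
                 duration_h = duration_h),
            class = "screen_design")
}

well_treatment <- function(layout_row, design) {
  switch(layout_row$role,
         control = treatment(dose = 0, effect = 0),
         dox = treatment(dose = layout_row$dose_uM, effect = 0),
         compound = treatment(dose = layout_row$dose_uM,
                              effect = layout_row$effect_e,
                              compound_id = layout_row$compound_id),
         stop_fs("unknown well role '%s'", layout_row$role))
}

#' Simulate a whole screen
#'
#' Two fidelity levels. `mode = "fast"` draws per-well true cell records
#' directly from the generator's statistical law (expression point-mass,
#' Poisson foci) and summarizes them — no pixels are rendered, so a full
#' 315-compound, 3-replicate screen takes seconds; per-well readouts carry
#' exactly the sampling noise of a finite cell count. `mode = "images"`
#' renders every field through [generate_well()] and returns the image set
#' for the full pipeline. The mode is recorded in the result's provenance.
#'
#' @param design a [screen_design()].
#' @param config a [sim_config()].
#' @param seed integer master seed; per-well seeds are derived by the
#'   deterministic counter scheme.
#' @param mode `"fast"` or `"images"`.
#' @param cells_per_well expected cells measured per well in fast mode
#'   (Poisson mean).
#' @param n_fields fields per well in images mode.
#' @param positivity_threshold truth-labeling foci threshold.
#' @return class `screen_sim`: for fast mode, `wells` (one row per well with
#'   class counts, `pct_foci_positive`, `foci_per_cell`), the design, mode
#'   and seed; for images mode, additionally `images`, a list of per-well
#'   field sets keyed by `replicate/plate/well`.
#' @export
simulate_screen <- function(design, config = sim_config(), seed,
                            mode = c("fast", "images"),
                            cells_per_well = 600, n_fields = 4L,
                            positivity_threshold = 5L) {
  mode <- match.arg(mode)
  layout <- design$layout
  wells <- vector("list", nrow(layout))
  images <- if (mode == "images") vector("list", nrow(layout)) else NULL
  for (i in seq_len(nrow(layout))) {
    row <- layout[i, ]
    trt <- well_treatment(row, design)
    wseed <- derive_seed(seed, i)
    if (mode == "fast") {
      set.seed(wseed)
      n <- stats::rpois(1, cells_per_well)
      egain <- draw_expression(n, config)
      mu <- mean_foci(config$dose_model, trt$dose, trt$effect,
                      trt$duration_factor)
      k <- stats::rpois(n, mu)
      cls <- label_truth(egain, k, positivity_threshold)
      n_pos <- sum(cls == "foci_positive")
      n_neg <- sum(cls == "foci_negative")
      n_nonsig <- sum(cls == "non_signaling")
      sig <- egain > 0
      wells[[i]] <- data.frame(
        replicate = row$replicate, plate = row$plate, well = row$well,
        role = row$role, compound_id = row$compound_id,
        n_cells = n, n_pos = n_pos, n_neg = n_neg, n_nonsig = n_nonsig,
        pct_foci_positive = if (n_pos + n_neg > 0)
          100 * n_pos / (n_pos + n_neg) else NA_real_,
        foci_per_cell = if (any(sig)) mean(k[sig]) else NA_real_,
        n_evaluable = sum(sig))
    } else {
      images[[i]] <- generate_well(config, trt, n_fields = n_fields,
                                   seed = wseed, plate = row$plate,
                                   well = row$well,
                                   positivity_threshold = positivity_threshold)
      names(images)[i] <- sprintf("%d/%s/%s", row$replicate, row$plate, row$well)
    }
  }
  out <- list(design = design, mode = mode, seed = seed)
  if (mode == "fast") out$wells <- do.call(rbind, wells)
  else out$images <- images
  structure(out, class = "screen_sim")
}
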