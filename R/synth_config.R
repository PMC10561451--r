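#' Simulation configuration for synthetic two-channel fields
#'
#' Parameters of the synthetic microscope: field geometry, nucleus placement
#' and brightness, per-cell reporter expression (including a point mass of
#' zero-expression "non-signaling" cells), focus rendering, and the camera
#' noise model. Defaults emulate a 40x-objective two-channel acquisition of
#' EGFP-53BP1 reporter cardiomyocytes: nuclei of ~12 um diameter, strong
#' cell-to-cell variation in both nuclear-stain and green brightness, and a
#' fraction of cells with no detectable green signal.
#'
#' @param image_size integer vector (rows, cols) of the field in pixels.
#' @param pixel_scale micrometres per pixel; metadata only.
#' @param cells_per_field expected nucleus count (Poisson mean).
#' @param nucleus_radius_mean,nucleus_radius_sd nucleus radius in pixels.
#' @param nucleus_brightness_range multiplicative per-nucleus gain interval
#'   for the nuclear channel (models variable nuclear staining).
#' @param nucleus_level nuclear-channel intensity (counts) at gain 1.
#' @param expression_meanlog,expression_sdlog log-normal parameters of the
#'   per-cell green expression gain among signaling cells.
#' @param p_nonsignal probability a cell has zero expression (non-signaling).
#' @param diffuse_green_level diffuse intranuclear green intensity (counts)
#'   at expression gain 1.
#' @param focus_amplitude focus peak intensity relative to the cell's own
#'   diffuse green level.
#' @param focus_sigma Gaussian focus width in pixels.
#' @param focus_min_separation minimum pairwise distance between planted
#'   foci (px); 0 (default) allows overlap as in real damage patterns,
#'   positive values build well-separated benchmark crops (foci that cannot
#'   be placed are dropped and the truth count adjusted).
#' @param background_level camera offset/background (counts), both channels.
#' @param background_gradient logical; add a low-order polynomial background
#'   gradient to stress thresholding (off by default).
#' @param read_noise_sd Gaussian read noise standard deviation (counts).
#' @param photon_noise logical; apply signal-dependent (Poisson) noise.
#' @param bit_depth camera bit depth; intensities are clipped to
#'   \[0, 2^bit_depth - 1\] and stored as integers.
#' @param touching logical stress flag; when set, nuclei are planted in
#'   touching pairs to exercise watershed splitting.
#' @param crop_size side of the square single-cell crop in pixels.
#' @param dose_model a [foci_dose_model()] linking treatment to mean foci.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(image_size = c(1024L, 1024L),
                       pixel_scale = 0.325,
                       cells_per_field = 150,
                       nucleus_radius_mean = 18,
                       nucleus_radius_sd = 3,
                       nucleus_brightness_range = c(0.3, 1.0),
                       nucleus_level = 12000,
                       expression_meanlog = 0,
                       expression_sdlog = 0.5,
                       p_nonsignal = 0.1,
                       diffuse_green_level = 3000,
                       focus_amplitude = 3,
                       focus_sigma = 2,
                       focus_min_separation = 0,
                       background_level = 200,
                       background_gradient = FALSE,
                       read_noise_sd = 10,
                       photon_noise = TRUE,
                       bit_depth = 16L,
                       touching = FALSE,
                       crop_size = 64L,
                       dose_model = foci_dose_model()) {
  cfg <- list(
    image_size = as.integer(image_size),
    pixel_scale = pixel_scale,
    cells_per_field = cells_per_field,
    nucleus_radius_mean = nucleus_radius_mean,
    nucleus_radius_sd = nucleus_radius_sd,
    nucleus_brightness_range = as.numeric(nucleus_brightness_range),
    nucleus_level = nucleus_level,
    expression_meanlog = expression_meanlog,
    expression_sdlog = expression_sdlog,
    p_nonsignal = p_nonsignal,
    diffuse_green_level = diffuse_green_level,
    focus_amplitude = focus_amplitude,
    focus_sigma = focus_sigma,
    focus_min_separation = focus_min_separation,
    background_level = background_level,
    background_gradient = isTRUE(background_gradient),
    read_noise_sd = read_noise_sd,
    photon_noise = isTRUE(photon_noise),
    bit_depth = as.integer(bit_depth),
    touching = isTRUE(touching),
    crop_size = as.integer(crop_size),
    dose_model = dose_model
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (length(cfg$image_size) != 2L || any(cfg$image_size < 16L))
    stop_fs("image_size must be two integers >= 16")
  assert_scalar_num(cfg$p_nonsignal, "p_nonsignal", 0, 1)
  assert_scalar_num(cfg$focus_sigma, "focus_sigma", lower = 1e-9)
  assert_scalar_num(cfg$cells_per_field, "cells_per_field", lower = 0)
  if (any(cfg$nucleus_brightness_range <= 0) ||
      diff(cfg$nucleus_brightness_range) < 0)
    stop_fs("nucleus_brightness_range must be an increasing interval of positive gains")
  for (nm in c("nucleus_level", "diffuse_green_level", "focus_amplitude"))
    assert_scalar_num(cfg[[nm]], nm, lower = 1e-12)
  assert_scalar_num(cfg$background_level, "background_level", lower = 0)
  assert_scalar_num(cfg$read_noise_sd, "read_noise_sd", lower = 0)
  if (cfg$bit_depth < 8L || cfg$bit_depth > 16L)
    stop_fs("bit_depth must be in [8, 16]")
  invisible(cfg)
}

#' Dose/effect model for mean foci per cell
#'
#' A saturating hyperbolic law linking the DNA-damaging dose (doxorubicin,
#' uM) to the Poisson mean of the per-cell focus count:
#' \deqn{\mu(d, e) = \lambda_0 + (1 - e)\,\Delta(d), \qquad
#'       \Delta(d) = (\lambda_{max} - \lambda_0)\frac{d}{d + EC_{50}}}
#' where `e` in \[0,1\] is a compound's fractional suppression of the
#' dose-induced increment. Longer exposure regimes scale the increment by
#' `duration_factor`, capped so the mean never exceeds `lambda_max`. The law
#' is monotone: nondecreasing in dose and nonincreasing in `e`.
#'
#' @param lambda0 baseline mean foci per signaling cell (untreated).
#' @param lambda_max saturating mean foci under high dose.
#' @param ec50_dose dose (uM) at half the saturating increment.
#' @param duration_factor multiplier on the increment for longer regimes
#'   (1 for the 1 h screening regime).
#' @return An object of class `foci_dose_model`.
#' @export
foci_dose_model <- function(lambda0 = 1, lambda_max = 10,
                            ec50_dose = 0.25, duration_factor = 1) {
  assert_scalar_num(lambda0, "lambda0", lower = 0)
  assert_scalar_num(lambda_max, "lambda_max", lower = lambda0)
  assert_scalar_num(ec50_dose, "ec50_dose", lower = 1e-12)
  assert_scalar_num(duration_factor, "duration_factor", lower = 0)
  structure(list(lambda0 = lambda0, lambda_max = lambda_max,
                 ec50_dose = ec50_dose, duration_factor = duration_factor),
            class = "foci_dose_model")
}

#' Mean foci per signaling cell under a treatment
#'
#' @param model a [foci_dose_model()].
#' @param dose dose in uM (vectorised).
#' @param effect per-compound fractional suppression e in \[0,1\].
#' @param duration_factor overrides the model's duration multiplier.
#' @return numeric vector of Poisson means.
#' @export
mean_foci <- function(model, dose, effect = 0,
                      duration_factor = model$duration_factor) {
  if (any(effect < 0 | effect > 1)) stop_fs("effect must lie in [0, 1]")
  if (any(dose < 0)) stop_fs("dose must be nonnegative")
  delta <- (model$lambda_max - model$lambda0) * dose / (dose + model$ec50_dose)
  delta <- pmin(delta * duration_factor, model$lambda_max - model$lambda0)
  model$lambda0 + (1 - effect) * delta
}

#' Treatment descriptor for a well or field
#'
#' @param dose DNA-damaging dose in uM (0.5 uM is the screening model
#'   condition).
#' @param effect compound fractional suppression e in \[0,1\] (0 = inactive).
#' @param duration_factor exposure-regime multiplier (1 = 1 h regime).
#' @param compound_id optional compound identifier carried into truth records.
#' @return list of class `fs_treatment`.
#' @export
treatment <- function(dose = 0, effect = 0, duration_factor = 1,
                      compound_id = NA_character_) {
  assert_scalar_num(dose, "dose", lower = 0)
  assert_scalar_num(effect, "effect", 0, 1)
  structure(list(dose = dose, effect = effect,
                 duration_factor = duration_factor,
                 compound_id = compound_id),
            class = "fs_treatment")
}
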