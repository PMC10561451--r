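# Synthetic two-channel field generation with exact ground truth.
#
# The generator is the package's stand-in for the microscope: channel 1 is
# the nuclear stain ("DAPI channel"), channel 2 the green reporter ("FITC
# channel"). Every rendered cell carries a truth record (expression gain,
# planted foci, true class), so segmentation, counting and classification
# can be scored against exact ground truth.

# additive soft-edged disk: peak / (1 + exp((d - radius)/edge))
render_disk <- function(mat, r0, c0, radius, peak, edge = 1.5) {
  nr <- nrow(mat); nc <- ncol(mat)
  ext <- ceiling(radius + 6 * edge)
  if (r0 + ext < 1 || r0 - ext > nr || c0 + ext < 1 || c0 - ext > nc)
    return(mat)
  rr <- max(1L, floor(r0 - ext)):min(nr, ceiling(r0 + ext))
  cc <- max(1L, floor(c0 - ext)):min(nc, ceiling(c0 + ext))
  d <- sqrt(outer((rr - r0)^2, (cc - c0)^2, "+"))
  mat[rr, cc] <- mat[rr, cc] + peak / (1 + exp((d - radius) / edge))
  mat
}

render_gaussian_spot <- function(mat, r0, c0, amp, sigma) {
  nr <- nrow(mat); nc <- ncol(mat)
  ext <- ceiling(4 * sigma)
  if (r0 + ext < 1 || r0 - ext > nr || c0 + ext < 1 || c0 - ext > nc)
    return(mat)
  rr <- max(1L, floor(r0 - ext)):min(nr, ceiling(r0 + ext))
  cc <- max(1L, floor(c0 - ext)):min(nc, ceiling(c0 + ext))
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  mat[rr, cc] <- mat[rr, cc] + amp * exp(-d2 / (2 * sigma^2))
  mat
}

# camera model: optional Poisson (photon) noise, Gaussian read noise,
# clipping to the bit depth, integer storage
apply_camera <- function(clean, cfg) {
  x <- clean
  if (cfg$photon_noise) {
    x[] <- stats::rpois(length(x), lambda = pmax(x, 0))
  }
  if (cfg$read_noise_sd > 0) {
    x <- x + stats::rnorm(length(x), 0, cfg$read_noise_sd)
  }
  x <- round(clip_intensity(x, cfg$bit_depth))
  storage.mode(x) <- "integer"
  x
}

background_canvas <- function(cfg) {
  nr <- cfg$image_size[1]; nc <- cfg$image_size[2]
  bg <- matrix(cfg$background_level, nr, nc)
  if (cfg$background_gradient) {
    # low-order polynomial gradient, up to +30% of the background level
    u <- (seq_len(nr) - 1) / (nr - 1); v <- (seq_len(nc) - 1) / (nc - 1)
    bg <- bg * (1 + 0.3 * outer(u, v, function(a, b) 0.5 * a + 0.3 * b + 0.2 * a * b))
  }
  bg
}

# Rejection-sampled non-overlapping placement. With the touching stress
# flag, cells are planted as pairs at ~95% of the sum of radii.
place_nuclei <- function(n, radii, nr, nc, touching, max_tries = 4000L) {
  rows <- numeric(0); cols <- numeric(0); rads <- numeric(0)
  sep_ok <- function(r0, c0, rad, gap = 2) {
    !length(rows) || all(sqrt((rows - r0)^2 + (cols - c0)^2) >= rads + rad + gap)
  }
  i <- 1L
  while (i <= n) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      r0 <- stats::runif(1, 1, nr); c0 <- stats::runif(1, 1, nc)
      if (touching && i < n) {
        th <- stats::runif(1, 0, 2 * pi)
        d <- 0.95 * (radii[i] + radii[i + 1])
        r1 <- r0 + d * sin(th); c1 <- c0 + d * cos(th)
        if (r1 < 1 || r1 > nr || c1 < 1 || c1 > nc) next
        if (sep_ok(r0, c0, radii[i]) && sep_ok(r1, c1, radii[i + 1])) {
          rows <- c(rows, r0, r1); cols <- c(cols, c0, c1)
          rads <- c(rads, radii[i], radii[i + 1])
          i <- i + 2L; placed <- TRUE; break
        }
      } else {
        if (sep_ok(r0, c0, radii[i])) {
          rows <- c(rows, r0); cols <- c(cols, c0); rads <- c(rads, radii[i])
          i <- i + 1L; placed <- TRUE; break
        }
      }
    }
    if (!placed)
      stop_fs(paste0("nucleus placement failed after %d retries: ",
                     "cells_per_field exceeds the non-overlap density limit ",
                     "for a %dx%d field"), max_tries, nr, nc)
  }
  data.frame(row = rows, col = cols, radius = rads)
}

draw_expression <- function(n, cfg) {
  gain <- stats::rlnorm(n, cfg$expression_meanlog, cfg$expression_sdlog)
  gain[stats::runif(n) < cfg$p_nonsignal] <- 0
  gain
}

# draw the per-cell truth (radius, gains, foci) shared by field and crop
# generators; foci are planted uniformly inside 0.75 * radius
draw_cell_truth <- function(n, cfg, trt, positivity_threshold) {
  radius <- pmax(4, stats::rnorm(n, cfg$nucleus_radius_mean, cfg$nucleus_radius_sd))
  ngain <- stats::runif(n, cfg$nucleus_brightness_range[1],
                        cfg$nucleus_brightness_range[2])
  egain <- draw_expression(n, cfg)
  mu <- mean_foci(cfg$dose_model, trt$dose, trt$effect, trt$duration_factor)
  nfoci <- stats::rpois(n, mu)
  cls <- label_truth(egain, nfoci, positivity_threshold)
  list(radius = radius, nucleus_gain = ngain, expression_gain = egain,
       n_foci = nfoci, true_class = cls)
}

# Plant up to n_foci positions uniformly in the inner 0.75-radius disk.
# With a positive minimum separation, positions are rejection-sampled and
# unplaceable foci are dropped, so the returned row count is the true count.
draw_foci_positions <- function(n_foci, radius, cfg) {
  empty <- data.frame(dr = numeric(0), dc = numeric(0),
                      amplitude = numeric(0), sigma = numeric(0))
  if (n_foci == 0) return(empty)
  min_sep <- cfg$focus_min_separation %||% 0
  dr <- numeric(0); dc <- numeric(0)
  for (j in seq_len(n_foci)) {
    for (t in 1:200) {
      u <- sqrt(stats::runif(1)) * 0.75 * radius
      th <- stats::runif(1, 0, 2 * pi)
      a <- u * sin(th); b <- u * cos(th)
      if (min_sep <= 0 || !length(dr) ||
          all((dr - a)^2 + (dc - b)^2 >= min_sep^2)) {
        dr <- c(dr, a); dc <- c(dc, b); break
      }
    }
  }
  n <- length(dr)
  if (n == 0) return(empty)
  amp <- cfg$focus_amplitude * stats::rlnorm(n, 0, 0.15)
  data.frame(dr = dr, dc = dc, amplitude = amp,
             sigma = rep(cfg$focus_sigma, n))
}

#' Generate one synthetic two-channel field with ground truth
#'
#' Renders nuclei as soft-edged disks in the nuclear channel with per-nucleus
#' brightness gain, and — for signaling cells — diffuse intranuclear green
#' plus Gaussian foci in the green channel. Non-signaling cells render no
#' green signal at all, so their green channel is statistically
#' indistinguishable from background. Output is a pure function of
#' `(config, trt, seed)`.
#'
#' @param config a [sim_config()].
#' @param trt a [treatment()].
#' @param seed integer seed.
#' @param plate,well,field identity strings carried into outputs.
#' @param positivity_threshold foci count at or above which a signaling cell
#'   is truth-labeled foci-positive (see [label_truth()]).
#' @return list with elements `field` (class `field_image`: integer matrices
#'   `nuclear` and `green` plus identity) and `truth` (class
#'   `ground_truth_field`: per-cell records, planted foci table, seed).
#' @export
generate_field <- function(config, trt = treatment(), seed,
                           plate = "P1", well = "A01", field = "F1",
                           positivity_threshold = 5L) {
  validate_sim_config(config)
  if (missing(seed)) stop_fs("a seed is required")
  set.seed(seed)
  nr <- config$image_size[1]; nc <- config$image_size[2]
  n <- stats::rpois(1, config$cells_per_field)

  nuclear <- background_canvas(config)
  green <- background_canvas(config)
  cells <- data.frame(cell_id = integer(0), row = numeric(0), col = numeric(0),
                      radius = numeric(0), nucleus_gain = numeric(0),
                      expression_gain = numeric(0), n_foci = integer(0),
                      true_class = character(0))
  foci_tab <- data.frame(cell_id = integer(0), row = numeric(0),
                         col = numeric(0), amplitude = numeric(0),
                         sigma = numeric(0))

  if (n > 0) {
    tr <- draw_cell_truth(n, config, trt, positivity_threshold)
    pos <- place_nuclei(n, tr$radius, nr, nc, config$touching)
    for (i in seq_len(n)) {
      nuclear <- render_disk(nuclear, pos$row[i], pos$col[i], pos$radius[i],
                             tr$nucleus_gain[i] * config$nucleus_level)
      if (tr$expression_gain[i] > 0) {
        diffuse <- tr$expression_gain[i] * config$diffuse_green_level
        green <- render_disk(green, pos$row[i], pos$col[i], pos$radius[i], diffuse)
        fp <- draw_foci_positions(tr$n_foci[i], pos$radius[i], config)
        tr$n_foci[i] <- nrow(fp)   # planted count is the truth
        for (j in seq_len(nrow(fp))) {
          green <- render_gaussian_spot(green, pos$row[i] + fp$dr[j],
                                        pos$col[i] + fp$dc[j],
                                        fp$amplitude[j] * diffuse, fp$sigma[j])
        }
        if (nrow(fp))
          foci_tab <- rbind(foci_tab, data.frame(
            cell_id = i, row = pos$row[i] + fp$dr, col = pos$col[i] + fp$dc,
            amplitude = fp$amplitude, sigma = fp$sigma))
      } else {
        # non-signaling: foci positions are still drawn for bookkeeping so
        # the draw sequence (and thus field layout) does not depend on gain
        draw_foci_positions(tr$n_foci[i], pos$radius[i], config)
      }
    }
    cells <- data.frame(cell_id = seq_len(n), row = pos$row, col = pos$col,
                        radius = pos$radius, nucleus_gain = tr$nucleus_gain,
                        expression_gain = tr$expression_gain,
                        n_foci = tr$n_foci,
                        true_class = as.character(
                          label_truth(tr$expression_gain, tr$n_foci,
                                      positivity_threshold)))
  }

  fi <- structure(list(nuclear = apply_camera(nuclear, config),
                       green = apply_camera(green, config),
                       plate = plate, well = well, field = field,
                       bit_depth = config$bit_depth),
                  class = "field_image")
  gt <- structure(list(cells = cells, foci = foci_tab, seed = seed,
                       treatment = trt, plate = plate, well = well,
                       field = field,
                       positivity_threshold = positivity_threshold),
                  class = "ground_truth_field")
  list(field = fi, truth = gt)
}

#' Rasterize a truth nucleus mask
#'
#' @param truth a `ground_truth_field`.
#' @param cell_id cell identifier within the truth record.
#' @param image_size field size (rows, cols).
#' @return logical matrix, TRUE inside the cell's nucleus disk.
#' @export
truth_nucleus_mask <- function(truth, cell_id, image_size) {
  ci <- truth$cells[truth$cells$cell_id == cell_id, ]
  if (nrow(ci) != 1L) stop_fs("unknown cell_id %s", cell_id)
  d <- sqrt(outer((seq_len(image_size[1]) - ci$row)^2,
                  (seq_len(image_size[2]) - ci$col)^2, "+"))
  d <= ci$radius
}

#' Generate all fields of one well
#'
#' Field seeds are derived deterministically from the well seed by the
#' package's counter scheme, so the well is reproducible from its own seed.
#'
#' @inheritParams generate_field
#' @param n_fields number of fields imaged in the well (>= 1).
#' @return list of `list(field, truth)` pairs sharing well identity.
#' @export
generate_well <- function(config, trt = treatment(), n_fields = 4L, seed,
                          plate = "P1", well = "A01",
                          positivity_threshold = 5L) {
  if (n_fields < 1L) stop_fs("n_fields must be >= 1")
  lapply(seq_len(n_fields), function(k) {
    generate_field(config, trt, seed = derive_seed(seed, k),
                   plate = plate, well = well, field = sprintf("F%d", k),
                   positivity_threshold = positivity_threshold)
  })
}

#' Simulate a labeled set of single-cell crops
#'
#' Renders cells directly into crop-sized patches (nucleus centred up to a
#' small jitter) under the same intensity and noise model as full fields.
#' This is the fast route to large labeled corpora for classifier training
#' and foci-counting benchmarks.
#'
#' @inheritParams generate_field
#' @param n number of cells.
#' @param jitter max centring jitter in pixels.
#' @return list with `crops` (list of `cell_crop` objects, raw, not yet
#'   normalized) and `truth` (per-cell data frame including per-crop planted
#'   focus offsets in the attribute `foci`).
#' @export
simulate_cell_crops <- function(n, config, trt = treatment(), seed,
                                positivity_threshold = 5L, jitter = 2) {
  validate_sim_config(config)
  set.seed(seed)
  cs <- config$crop_size
  tr <- draw_cell_truth(n, config, trt, positivity_threshold)
  # keep the nucleus inside the crop
  tr$radius <- pmin(tr$radius, cs / 2 - 3)
  ctr <- (cs + 1) / 2
  crops <- vector("list", n)
  foci_list <- vector("list", n)
  pos_thr <- positivity_threshold
  for (i in seq_len(n)) {
    r0 <- ctr + stats::runif(1, -jitter, jitter)
    c0 <- ctr + stats::runif(1, -jitter, jitter)
    nuc <- matrix(config$background_level, cs, cs)
    grn <- matrix(config$background_level, cs, cs)
    nuc <- render_disk(nuc, r0, c0, tr$radius[i],
                       tr$nucleus_gain[i] * config$nucleus_level)
    fp <- draw_foci_positions(tr$n_foci[i], tr$radius[i], config)
    if (tr$expression_gain[i] > 0) {
      diffuse <- tr$expression_gain[i] * config$diffuse_green_level
      grn <- render_disk(grn, r0, c0, tr$radius[i], diffuse)
      for (j in seq_len(nrow(fp)))
        grn <- render_gaussian_spot(grn, r0 + fp$dr[j], c0 + fp$dc[j],
                                    fp$amplitude[j] * diffuse, fp$sigma[j])
    }
    d <- sqrt(outer((seq_len(cs) - r0)^2, (seq_len(cs) - c0)^2, "+"))
    crops[[i]] <- new_cell_crop(nuclear = apply_camera(nuc, config),
                                green = apply_camera(grn, config),
                                mask = d <= tr$radius[i],
                                cell_id = i, center = c(r0, c0))
    # with a separation constraint, the planted (not the drawn) count is the
    # truth; non-signaling cells keep the drawn bookkeeping count
    if (tr$expression_gain[i] > 0) tr$n_foci[i] <- nrow(fp)
    foci_list[[i]] <- if (nrow(fp))
      data.frame(cell_id = i, row = r0 + fp$dr, col = c0 + fp$dc,
                 amplitude = fp$amplitude, sigma = fp$sigma)
    else NULL
  }
  truth <- data.frame(cell_id = seq_len(n), radius = tr$radius,
                      nucleus_gain = tr$nucleus_gain,
                      expression_gain = tr$expression_gain,
                      n_foci = tr$n_foci,
                      true_class = as.character(
                        label_truth(tr$expression_gain, tr$n_foci, pos_thr)))
  attr(truth, "foci") <- do.call(rbind, foci_list)
  list(crops = crops, truth = truth)
}
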