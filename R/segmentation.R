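# Nucleus instance segmentation and single-cell crop extraction.
#
# The detector is a deterministic classical pipeline — smoothing, adaptive
# (locally normalized) thresholding, hole filling, distance-transform
# watershed, area filtering — chosen so that per-nucleus staining gain
# differences across the generator's whole brightness range do not prevent
# detection. Coordinates are 1-based (row, col) throughout, the R matrix
# convention.

#' Segmentation parameters
#'
#' Defaults are derived from a [sim_config()]: the adaptive-threshold window
#' scales with the nucleus radius and the area filter covers the radius
#' range mean +/- 3 sd.
#'
#' @param config optional [sim_config()] from which to derive defaults.
#' @param smooth_sigma Gaussian pre-smoothing sigma (px).
#' @param window half-width of the adaptive-threshold moving window (px);
#'   must exceed the nucleus radius so the local mean samples background.
#' @param offset adaptive-threshold offset above the local mean, as a
#'   fraction of full scale.
#' @param open_size diameter of the opening brush removing specks (px, odd).
#' @param watershed_tolerance minimum distance-map depth separating two
#'   objects before they are split (px).
#' @param min_area,max_area retained instance area range (px^2).
#' @return list of class `segment_params`.
#' @export
segment_params <- function(config = NULL,
                           smooth_sigma = 2,
                           window = NULL,
                           offset = 0.01,
                           open_size = 5L,
                           watershed_tolerance = 2,
                           min_area = NULL, max_area = NULL) {
  r_mean <- if (is.null(config)) 18 else config$nucleus_radius_mean
  r_sd <- if (is.null(config)) 3 else config$nucleus_radius_sd
  window <- window %||% ceiling(1.5 * r_mean)
  min_area <- min_area %||% floor(pi * max(3, r_mean - 3 * r_sd)^2)
  max_area <- max_area %||% ceiling(pi * (r_mean + 3 * r_sd)^2)
  structure(list(smooth_sigma = smooth_sigma, window = window,
                 offset = offset, open_size = as.integer(open_size),
                 watershed_tolerance = watershed_tolerance,
                 min_area = min_area, max_area = max_area),
            class = "segment_params")
}

#' Segment nucleus instances from the nuclear channel
#'
#' @param field a `field_image` (two co-registered integer channels).
#' @param params a [segment_params()].
#' @return list with `label_map` (integer matrix, 0 = background, labels
#'   contiguous 1..K) and `instances` (data frame: `label, centroid_row,
#'   centroid_col, area, mean_nuclear_intensity, border_touching`, sorted by
#'   label).
#' @export
segment_nuclei <- function(field, params = segment_params()) {
  if (!inherits(field, "field_image") ||
      is.null(field$nuclear) || is.null(field$green))
    stop_fs("input must be a two-channel field_image (nuclear + green)")
  maxv <- 2^field$bit_depth - 1
  img <- field$nuclear / maxv
  if (all(field$nuclear >= maxv))
    stop_fs("nuclear channel is fully saturated; cannot segment")

  sm <- EBImage::gblur(img, sigma = params$smooth_sigma)
  bw <- EBImage::thresh(sm, w = params$window, h = params$window,
                        offset = params$offset)
  bw <- EBImage::fillHull(bw)
  bw <- EBImage::opening(bw, EBImage::makeBrush(params$open_size, "disc"))
  dm <- EBImage::distmap(bw)
  lab <- EBImage::watershed(dm, tolerance = params$watershed_tolerance, ext = 1)
  lab <- EBImage::imageData(lab)

  # area filter, then relabel contiguously preserving label order
  if (max(lab) > 0) {
    areas <- tabulate(lab, nbins = max(lab))
    keep <- which(areas >= params$min_area & areas <= params$max_area)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    nz <- lab > 0
    lab[nz] <- remap[lab[nz]]
  }
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))

  k <- max(lab)
  if (k == 0) {
    inst <- data.frame(label = integer(0), centroid_row = numeric(0),
                       centroid_col = numeric(0), area = integer(0),
                       mean_nuclear_intensity = numeric(0),
                       border_touching = logical(0))
    return(list(label_map = lab, instances = inst))
  }
  idx <- which(lab > 0)
  li <- lab[idx]
  ri <- (idx - 1) %% nrow(lab) + 1
  ci <- (idx - 1) %/% nrow(lab) + 1
  area <- tabulate(li, k)
  cr <- rowsum(ri, li)[, 1] / area
  cc <- rowsum(ci, li)[, 1] / area
  mi <- rowsum(as.numeric(field$nuclear[idx]), li)[, 1] / area
  border <- ri == 1 | ri == nrow(lab) | ci == 1 | ci == ncol(lab)
  bt <- as.logical(rowsum(as.integer(border), li)[, 1] > 0)
  inst <- data.frame(label = seq_len(k), centroid_row = cr, centroid_col = cc,
                     area = as.integer(area), mean_nuclear_intensity = mi,
                     border_touching = bt)
  list(label_map = lab, instances = inst)
}

new_cell_crop <- function(nuclear, green, mask, cell_id, center,
                          plate = NA_character_, well = NA_character_,
                          field = NA_character_) {
  if (!any(mask)) stop_fs("cell crop mask is empty")
  structure(list(nuclear = nuclear, green = green, mask = mask,
                 cell_id = cell_id, center = center,
                 plate = plate, well = well, field = field,
                 raw_green_mean = mean(green[mask]),
                 normalized = NULL, p_low_value = NA_real_,
                 p_high_value = NA_real_, low_dynamic_range = NA),
            class = "cell_crop")
}

#' Extract fixed-size single-cell crops
#'
#' One square two-channel crop per retained instance, centred on the nucleus
#' centroid. Windows reaching past the field edge are padded with the
#' background level (median of unlabeled pixels). Border-touching instances
#' are excluded by default since their class and count would be biased.
#'
#' @param field a `field_image`.
#' @param label_map,instances output of [segment_nuclei()].
#' @param crop_size crop side in pixels (even; should be at least twice the
#'   median nucleus diameter).
#' @param include_border keep border-touching instances?
#' @return list of `cell_crop` objects.
#' @export
extract_crops <- function(field, label_map, instances, crop_size = 64L,
                          include_border = FALSE) {
  crop_size <- as.integer(crop_size)
  if (crop_size %% 2L != 0L) stop_fs("crop_size must be even")
  if (!nrow(instances)) return(list())
  keep <- if (include_border) instances else
    instances[!instances$border_touching, ]
  fill <- if (any(label_map == 0)) stats::median(field$nuclear[label_map == 0])
          else 0
  fill_g <- if (any(label_map == 0)) stats::median(field$green[label_map == 0])
            else 0
  half <- crop_size %/% 2L
  nr <- nrow(label_map); nc <- ncol(label_map)
  out <- list()
  for (i in seq_len(nrow(keep))) {
    lb <- keep$label[i]
    px <- which(label_map == lb)
    rr <- range((px - 1) %% nr + 1); cr <- range((px - 1) %/% nr + 1)
    if (diff(rr) + 1 > crop_size || diff(cr) + 1 > crop_size) {
      warning(sprintf("instance %d bounding box exceeds crop_size %d; skipped",
                      lb, crop_size))
      next
    }
    r0 <- round(keep$centroid_row[i]); c0 <- round(keep$centroid_col[i])
    rows <- (r0 - half + 1L):(r0 + half)
    cols <- (c0 - half + 1L):(c0 + half)
    nucp <- matrix(as.integer(round(fill)), crop_size, crop_size)
    grnp <- matrix(as.integer(round(fill_g)), crop_size, crop_size)
    mskp <- matrix(FALSE, crop_size, crop_size)
    vr <- rows >= 1 & rows <= nr; vc <- cols >= 1 & cols <= nc
    nucp[vr, vc] <- field$nuclear[rows[vr], cols[vc]]
    grnp[vr, vc] <- field$green[rows[vr], cols[vc]]
    mskp[vr, vc] <- label_map[rows[vr], cols[vc]] == lb
    out[[length(out) + 1L]] <- new_cell_crop(
      nucp, grnp, mskp, cell_id = lb, center = c(r0, c0),
      plate = field$plate, well = field$well, field = field$field)
  }
  out
}

#' Percentile-anchor normalization of a crop's green channel
#'
#' Maps the green channel to \[0,1\] by its own within-crop percentiles,
#' \eqn{g' = \mathrm{clip}((g - v_{low})/(v_{high} - v_{low}), 0, 1)}, which
#' makes the normalized appearance exactly invariant to affine intensity
#' transforms (gain and offset) of the input — the property that lets cells
#' of very different reporter brightness be classified alike. A crop whose
#' percentile spread is below `eps` (flat, e.g. truly blank) is set to all
#' zeros and flagged `low_dynamic_range`. The raw green mean and the
#' percentile anchors are preserved so downstream stages can still judge
#' absolute signal presence.
#'
#' @param crop a `cell_crop`.
#' @param p_low,p_high anchor percentiles in \[0,100\], `p_low < p_high`.
#' @param eps minimal anchor spread (raw counts) below which the crop is
#'   flagged flat; must be positive.
#' @return the crop with `normalized`, `p_low_value`, `p_high_value` and
#'   `low_dynamic_range` filled in.
#' @export
normalize_crop <- function(crop, p_low = 1, p_high = 99.5, eps = 1e-6) {
  if (eps <= 0) stop_fs("eps must be positive")
  if (!(p_low >= 0 && p_low < p_high && p_high <= 100))
    stop_fs("need 0 <= p_low < p_high <= 100")
  g <- as.numeric(crop$green)
  v <- stats::quantile(g, c(p_low, p_high) / 100, names = FALSE, type = 7)
  crop$p_low_value <- v[1]; crop$p_high_value <- v[2]
  if (v[2] - v[1] < eps) {
    crop$normalized <- matrix(0, nrow(crop$green), ncol(crop$green))
    crop$low_dynamic_range <- TRUE
  } else {
    nrm <- (crop$green - v[1]) / (v[2] - v[1])
    crop$normalized <- matrix(pmin(pmax(nrm, 0), 1),
                              nrow(crop$green), ncol(crop$green))
    crop$low_dynamic_range <- FALSE
  }
  crop
}

#' Object-level segmentation score against generator truth
#'
#' Greedy nearest-centroid matching within `radius` pixels (closest pair
#' first; ties resolved toward the lower instance label). Precision, recall
#' and F1 are over all truth cells, including border-clipped ones.
#'
#' @param truth a `ground_truth_field` (or its `cells` data frame).
#' @param instances instance table from [segment_nuclei()].
#' @param radius match radius in pixels (default 5).
#' @return list: `tp, fp, fn, precision, recall, f1`.
#' @export
segmentation_score <- function(truth, instances, radius = 5) {
  tr <- if (inherits(truth, "ground_truth_field")) truth$cells else truth
  nt <- nrow(tr); np <- nrow(instances)
  if (nt == 0 || np == 0) {
    tp <- 0L
  } else {
    d <- sqrt(outer(tr$row, instances$centroid_row, "-")^2 +
              outer(tr$col, instances$centroid_col, "-")^2)
    matched <- rep(FALSE, nt); used <- rep(FALSE, np)
    tp <- 0L
    repeat {
      dm <- d
      dm[matched, ] <- Inf; dm[, used] <- Inf
      if (!any(is.finite(dm)) || min(dm) > radius) break
      ij <- which(dm == min(dm), arr.ind = TRUE)
      ij <- ij[order(ij[, 2]), , drop = FALSE][1, ]   # tie: lower label
      matched[ij[1]] <- TRUE; used[ij[2]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- np - tp; fn <- nt - tp
  prec <- if (np > 0) tp / np else NA_real_
  rec <- if (nt > 0) tp / nt else NA_real_
  list(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec,
       f1 = if (tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_)
}
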