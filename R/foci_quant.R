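# Threshold-based foci recognition and per-cell counting — the classical
# granularity-style readout. A white top-hat isolates bright structures
# smaller than the structuring element; robust statistics (median/MAD) of
# the top-hat response inside the nucleus set the detection threshold, so
# bright foci do not inflate their own cutoff.

#' Foci detection parameters
#'
#' @param d_min,d_max expected focus diameter range in pixels.
#' @param tophat_radius radius of the top-hat disk (default `ceiling(d_max/2)`).
#' @param detection_k detection threshold in robust-SD units
#'   (1.4826 x MAD) above the median top-hat response within the nucleus.
#' @param min_separation minimum distance between accepted maxima (px).
#' @param min_prominence absolute floor on the top-hat prominence of an
#'   accepted focus (normalized-intensity units); keeps the MAD-based
#'   threshold from collapsing to zero on (nearly) noise-free crops.
#' @param plateau_tolerance intensity difference below which tied maxima
#'   count as one plateau (normalized units); intensity-clipped foci form
#'   flat tops whose pixels differ only by quantization ripple.
#' @return list of class `foci_params`.
#' @export
foci_params <- function(d_min = 3L, d_max = 9L, tophat_radius = NULL,
                        detection_k = 4, min_separation = 3,
                        min_prominence = 0.1, plateau_tolerance = 1e-3) {
  if (d_min < 1 || d_min > d_max) stop_fs("need 1 <= d_min <= d_max")
  if (detection_k <= 0) stop_fs("detection_k must be positive")
  structure(list(d_min = as.integer(d_min), d_max = as.integer(d_max),
                 tophat_radius = as.integer(tophat_radius %||% ceiling(d_max / 2)),
                 detection_k = detection_k, min_separation = min_separation,
                 min_prominence = min_prominence,
                 plateau_tolerance = plateau_tolerance),
            class = "foci_params")
}

# greedy non-maximum suppression: strongest first, row-major tie-break
suppress_maxima <- function(rows, cols, strength, min_sep) {
  ord <- order(-strength, rows, cols)
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) ||
        all((rows[keep] - rows[i])^2 + (cols[keep] - cols[i])^2 >= min_sep^2))
      keep <- c(keep, i)
  }
  sort(keep)
}

#' Detect foci in a normalized single-cell crop
#'
#' Pipeline: white top-hat (disk of `tophat_radius`) of the normalized green
#' channel -> median/MAD of the response within the nucleus mask -> candidate
#' pixels above `median + detection_k * 1.4826 * MAD` -> local maxima with
#' greedy `min_separation` suppression. Only maxima inside the nucleus mask
#' are counted. Deterministic for fixed input and parameters.
#'
#' A crop flagged `low_dynamic_range` is returned with zero count and
#' `not_evaluable = TRUE`: deciding whether a cell is non-signaling is the
#' classifier's job, not the counter's.
#'
#' @param crop a normalized `cell_crop` (see [normalize_crop()]).
#' @param params a [foci_params()].
#' @return list of class `foci_detection`: `foci_count`, `not_evaluable`,
#'   and `foci` (data frame: `row, col, prominence, equiv_diameter`).
#' @export
detect_foci <- function(crop, params = foci_params()) {
  if (is.null(crop$normalized))
    stop_fs("crop must be normalized first (see normalize_crop)")
  if (is.null(crop$mask) || !any(crop$mask))
    stop_fs("crop has no nucleus mask")
  empty <- data.frame(row = integer(0), col = integer(0),
                      prominence = numeric(0), equiv_diameter = numeric(0))
  if (isTRUE(crop$low_dynamic_range))
    return(structure(list(foci_count = 0L, not_evaluable = TRUE, foci = empty),
                     class = "foci_detection"))

  brush <- EBImage::makeBrush(2L * params$tophat_radius + 1L, "disc")
  th <- EBImage::imageData(EBImage::whiteTopHat(crop$normalized, brush))
  vals <- th[crop$mask]
  cut <- max(stats::median(vals) + params$detection_k * 1.4826 * raw_mad(vals),
             params$min_prominence)
  cand <- which(th > cut & crop$mask)
  if (!length(cand))
    return(structure(list(foci_count = 0L, not_evaluable = FALSE, foci = empty),
                     class = "foci_detection"))

  nr <- nrow(th)
  rows <- (cand - 1) %% nr + 1
  cols <- (cand - 1) %/% nr + 1
  # local maximum within the suppression radius (max filter via grayscale
  # dilation), then greedy suppression with row-major tie-break
  box <- matrix(1, 2 * ceiling(params$min_separation) + 1,
                2 * ceiling(params$min_separation) + 1)
  mx <- EBImage::imageData(EBImage::dilate(th, box))
  is_max <- th[cand] >= mx[cand] - params$plateau_tolerance
  rows <- rows[is_max]; cols <- cols[is_max]; cand <- cand[is_max]
  if (!length(cand))
    return(structure(list(foci_count = 0L, not_evaluable = FALSE, foci = empty),
                     class = "foci_detection"))
  # a clipped or flat-topped focus is a plateau of tied maxima: collapse
  # each connected plateau to its first pixel in row-major order
  mm <- matrix(FALSE, nrow(th), ncol(th)); mm[cand] <- TRUE
  plab <- EBImage::imageData(EBImage::bwlabel(mm))
  first_px <- vapply(split(cand, plab[cand]), min, 0)
  ord <- order((first_px - 1) %/% nr, (first_px - 1) %% nr)  # row-major
  cand <- as.integer(first_px[ord])
  rows <- (cand - 1) %% nr + 1
  cols <- (cand - 1) %/% nr + 1
  keep <- suppress_maxima(rows, cols, th[cand], params$min_separation)

  # equivalent diameter from the connected above-threshold region
  comp <- EBImage::imageData(EBImage::bwlabel(th > cut & crop$mask))
  careas <- tabulate(comp[comp > 0], nbins = max(comp))
  cid <- comp[cand[keep]]
  eqd <- 2 * sqrt(ifelse(cid > 0, careas[pmax(cid, 1)], 1) / pi)
  foci <- data.frame(row = rows[keep], col = cols[keep],
                     prominence = th[cand[keep]], equiv_diameter = eqd)
  structure(list(foci_count = nrow(foci), not_evaluable = FALSE, foci = foci),
            class = "foci_detection")
}

#' Per-cell foci counts and per-well mean
#'
#' The well mean is taken over evaluable cells only; `n_evaluable` is
#' reported alongside. A well with zero evaluable cells gets a missing mean
#' and an explicit flag — never a zero.
#'
#' @param detections list of `foci_detection` objects (one per cell), or a
#'   data frame with columns `foci_count` and `not_evaluable`.
#' @return list: `cells` (data frame `cell_index, foci_count, not_evaluable`),
#'   `well_mean` (numeric or NA), `n_evaluable`, `all_not_evaluable` flag.
#' @export
foci_per_cell <- function(detections) {
  if (is.data.frame(detections)) {
    cells <- data.frame(cell_index = seq_len(nrow(detections)),
                        foci_count = detections$foci_count,
                        not_evaluable = detections$not_evaluable)
  } else {
    if (!length(detections)) stop_fs("need at least one cell record")
    cells <- data.frame(
      cell_index = seq_along(detections),
      foci_count = vapply(detections, function(d) as.integer(d$foci_count), 1L),
      not_evaluable = vapply(detections, function(d) isTRUE(d$not_evaluable),
                             TRUE))
  }
  ev <- !cells$not_evaluable
  list(cells = cells,
       well_mean = if (any(ev)) mean(cells$foci_count[ev]) else NA_real_,
       n_evaluable = sum(ev),
       all_not_evaluable = !any(ev))
}
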