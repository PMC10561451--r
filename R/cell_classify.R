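# Three-class single-cell phenotype classification:
# non_signaling < foci_negative < foci_positive (the fixed class order,
# also the tie-break order on equal probabilities).

FOCI_CLASSES <- c("non_signaling", "foci_negative", "foci_positive")

#' Truth-label a cell from generator ground truth
#'
#' A cell with zero expression gain is `non_signaling` regardless of its
#' bookkeeping focus count; otherwise a cell with at least
#' `positivity_threshold` true foci is `foci_positive`, else
#' `foci_negative`. The threshold is a configuration value and is recorded
#' in provenance wherever labels are produced.
#'
#' @param expression_gain per-cell green expression gain (0 = non-signaling).
#' @param n_foci true focus count.
#' @param positivity_threshold nonnegative integer, default 5.
#' @return factor with levels `non_signaling, foci_negative, foci_positive`.
#' @export
label_truth <- function(expression_gain, n_foci, positivity_threshold = 5L) {
  if (positivity_threshold < 0) stop_fs("positivity_threshold must be >= 0")
  if (length(expression_gain) != length(n_foci))
    stop_fs("expression_gain and n_foci lengths differ")
  out <- ifelse(expression_gain == 0, "non_signaling",
                ifelse(n_foci >= positivity_threshold,
                       "foci_positive", "foci_negative"))
  factor(out, levels = FOCI_CLASSES)
}

#' Fixed-order feature vector for a normalized crop
#'
#' Features, in order: raw green mean within the mask and the percentile
#' anchor spread (absolute signal presence, on the raw intensity scale — a
#' gain g scales both by g); log-compressed signal-to-background contrasts
#' referenced to the robust noise level outside the mask (nearly
#' gain-invariant signal presence); variance and excess kurtosis of the
#' normalized channel within the mask (texture); top-hat energy within the
#' mask; threshold-backend focus count and summed prominence; a three-scale
#' granularity spectrum (fraction of masked energy removed by openings of
#' radius 2, 4, 8); and mask area. Deterministic.
#'
#' @param crop a normalized `cell_crop`.
#' @param fparams [foci_params()] for the embedded threshold detector.
#' @return named numeric vector (fixed names and order).
#' @export
featurize <- function(crop, fparams = foci_params()) {
  if (is.null(crop$mask)) stop_fs("crop has no nucleus mask")
  if (is.null(crop$normalized))
    stop_fs("crop must be normalized first (see normalize_crop)")
  m <- crop$mask
  out_px <- as.numeric(crop$green[!m])
  noise <- 1.4826 * raw_mad(out_px) + 1
  snr_log <- log1p(max(0, crop$raw_green_mean - stats::median(out_px)) / noise)
  spread_log <- log1p((crop$p_high_value - crop$p_low_value) / noise)
  nv <- crop$normalized[m]
  mu <- mean(nv); s2 <- stats::var(nv)
  kurt <- if (s2 > 1e-12) mean((nv - mu)^4) / s2^2 - 3 else 0

  brush <- EBImage::makeBrush(2L * fparams$tophat_radius + 1L, "disc")
  th <- EBImage::imageData(EBImage::whiteTopHat(crop$normalized, brush))
  tophat_energy <- sum(th[m])

  det <- detect_foci(crop, fparams)
  prom <- if (nrow(det$foci)) sum(det$foci$prominence) else 0

  # granularity spectrum: energy removed by successively larger openings
  total <- sum(crop$normalized[m])
  gran <- numeric(3); prev <- crop$normalized
  for (i in seq_along(c(2L, 4L, 8L))) {
    r <- c(2L, 4L, 8L)[i]
    op <- EBImage::imageData(EBImage::opening(crop$normalized,
                                              EBImage::makeBrush(2L * r + 1L, "disc")))
    gran[i] <- if (total > 1e-12) sum(pmax(prev[m] - op[m], 0)) / total else 0
    prev <- op
  }

  c(raw_green_mean = crop$raw_green_mean,
    anchor_spread = crop$p_high_value - crop$p_low_value,
    signal_snr_log = snr_log,
    spread_snr_log = spread_log,
    norm_var = s2,
    norm_kurtosis = kurt,
    tophat_energy = tophat_energy,
    foci_count = as.numeric(det$foci_count),
    foci_prominence_sum = prom,
    gran_r2 = gran[1], gran_r4 = gran[2], gran_r8 = gran[3],
    mask_area = sum(m))
}

# mean-pool a crop channel down to a coarse grid for the pixel backend
pool_to_grid <- function(x, g = 16L) {
  n <- nrow(x)
  f <- n %/% g
  idx <- rep(seq_len(g), each = f)[seq_len(f * g)]
  rowsum(t(rowsum(x[seq_len(f * g), seq_len(f * g)], idx)), idx) / f^2
}

#' Build a labeled training set from simulated crops
#'
#' Generates `n` crops via [simulate_cell_crops()], normalizes them, and
#' attaches truth labels with disjoint train/val/test split tags
#' (70/15/15, assigned deterministically from the seed).
#'
#' @inheritParams simulate_cell_crops
#' @param trt treatment under which cells are simulated; the default
#'   screening model dose produces all three classes in realistic balance.
#' @return list of class `training_set`: `crops` (normalized), `labels`,
#'   `split`, `positivity_threshold`.
#' @export
make_training_set <- function(n, config, trt = treatment(dose = 0.5),
                              seed, positivity_threshold = 5L) {
  sim <- simulate_cell_crops(n, config, trt, seed = seed,
                             positivity_threshold = positivity_threshold)
  crops <- lapply(sim$crops, normalize_crop)
  labels <- factor(sim$truth$true_class, levels = FOCI_CLASSES)
  set.seed(derive_seed(seed, 999L))
  split <- sample(c("train", "val", "test"), n, replace = TRUE,
                  prob = c(0.7, 0.15, 0.15))
  structure(list(crops = crops, labels = labels, split = split,
                 truth = sim$truth,
                 positivity_threshold = positivity_threshold),
            class = "training_set")
}

#' Train the three-class cell classifier
#'
#' Two desk-scale backends with the same contract. `feature_baseline`
#' (default): weighted multinomial logistic regression on [featurize()]
#' outputs — deterministic, trains in seconds. `nnet_pixels`: a
#' single-hidden-layer neural network on the mean-pooled normalized green
#' channel plus the absolute-signal features — stochastic init, still
#' minutes at most. Class imbalance is handled by per-observation weights
#' inversely proportional to class support.
#'
#' @param tset a `training_set` (or any list with `crops`, `labels`,
#'   `split`).
#' @param backend `"feature_baseline"` or `"nnet_pixels"`.
#' @param seed integer seed (stored; controls `nnet_pixels` init).
#' @param fparams [foci_params()] used by [featurize()].
#' @param hidden hidden-layer size for `nnet_pixels`.
#' @return object of class `foci_classifier` with validation metrics (when a
#'   val split is present) recorded in `$val_metrics`.
#' @export
train_classifier <- function(tset, backend = c("feature_baseline", "nnet_pixels"),
                             seed = 1L, fparams = foci_params(), hidden = 8L) {
  backend <- match.arg(backend)
  tr <- tset$split == "train"
  counts <- table(factor(tset$labels[tr], levels = FOCI_CLASSES))
  if (any(counts == 0))
    stop_fs("every class must be present in the train split; counts: %s",
            paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  w <- as.numeric(sum(counts) / (length(counts) * counts[tset$labels[tr]]))

  if (backend == "feature_baseline") {
    X <- t(vapply(tset$crops, featurize, numeric(13), fparams = fparams))
    X <- compress_raw_features(X)
    ctr <- colMeans(X[tr, , drop = FALSE])
    scl <- pmax(apply(X[tr, , drop = FALSE], 2, stats::sd), 1e-9)
    Xs <- scale(X, ctr, scl)
    df <- data.frame(Xs[tr, , drop = FALSE],
                     .label = factor(tset$labels[tr], levels = FOCI_CLASSES))
    fit <- nnet::multinom(.label ~ ., data = df, weights = w,
                          trace = FALSE, maxit = 500, decay = 1e-4)
    model <- list(backend = backend, fit = fit, center = ctr, scale = scl,
                  feature_names = colnames(X))
  } else {
    set.seed(seed)
    X <- t(vapply(tset$crops, backend_pixel_features, numeric(258)))
    ctr <- colMeans(X[tr, , drop = FALSE])
    scl <- pmax(apply(X[tr, , drop = FALSE], 2, stats::sd), 1e-9)
    Xs <- scale(X, ctr, scl)
    y <- nnet::class.ind(factor(tset$labels[tr], levels = FOCI_CLASSES))
    fit <- nnet::nnet(Xs[tr, , drop = FALSE], y, size = hidden, weights = w,
                      softmax = TRUE, decay = 1e-3, maxit = 300,
                      MaxNWts = 10000, trace = FALSE)
    model <- list(backend = backend, fit = fit, center = ctr, scale = scl,
                  feature_names = colnames(X))
  }
  model$fparams <- fparams
  model$seed <- seed
  model$positivity_threshold <- tset$positivity_threshold %||% NA_integer_
  class(model) <- "foci_classifier"

  va <- tset$split == "val"
  if (any(va)) {
    pred <- classify(model, tset$crops[va])
    model$val_metrics <- evaluate_records(pred, tset$labels[va])[
      c("macro_accuracy", "overall_accuracy")]
  }
  model
}

backend_pixel_features <- function(crop) {
  g <- pool_to_grid(crop$normalized, 16L)
  c(as.numeric(g), log1p(crop$raw_green_mean),
    log1p(crop$p_high_value - crop$p_low_value))
}

# The raw-scale columns vary multiplicatively with reporter gain; the
# baseline backend drops them from its design matrix and judges signal
# presence by the noise-referenced (scale-invariant) SNR features, which is
# what keeps classification stable across cell-to-cell brightness.
compress_raw_features <- function(X) {
  X[, !colnames(X) %in% c("raw_green_mean", "anchor_spread"), drop = FALSE]
}

classifier_matrix <- function(model, crops) {
  X <- if (model$backend == "feature_baseline")
    compress_raw_features(
      t(vapply(crops, featurize, numeric(13), fparams = model$fparams)))
  else
    t(vapply(crops, backend_pixel_features, numeric(258)))
  scale(X, model$center, model$scale)
}

#' Classify crops into the three phenotypes
#'
#' @param model a `foci_classifier`.
#' @param crops list of normalized `cell_crop` objects (same normalization
#'   procedure as training).
#' @return data frame of cell records, one row per crop in input order:
#'   `cell_id, plate, well, field, class, p_nonsig, p_neg, p_pos,
#'   raw_green_mean, foci_count`. Probabilities sum to 1; the class is the
#'   argmax with ties broken in fixed class order.
#' @export
classify <- function(model, crops) {
  if (!length(crops))
    return(data.frame(cell_id = integer(0), plate = character(0),
                      well = character(0), field = character(0),
                      class = character(0), p_nonsig = numeric(0),
                      p_neg = numeric(0), p_pos = numeric(0),
                      raw_green_mean = numeric(0), foci_count = integer(0)))
  bad <- !vapply(crops, function(cr) !is.null(cr$normalized), TRUE)
  if (any(bad)) stop_fs("all crops must be normalized before classification")
  Xs <- classifier_matrix(model, crops)
  if (model$backend == "feature_baseline") {
    pr <- stats::predict(model$fit, newdata = as.data.frame(Xs), type = "probs")
  } else {
    pr <- stats::predict(model$fit, Xs)
  }
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1,
                                     dimnames = list(NULL, FOCI_CLASSES))
  pr <- pr[, FOCI_CLASSES, drop = FALSE]
  pr <- pr / rowSums(pr)
  # argmax with fixed-order tie-break: the first maximal class wins
  cls <- FOCI_CLASSES[apply(pr, 1, which.max)]
  data.frame(
    cell_id = vapply(crops, function(cr) as.integer(cr$cell_id), 1L),
    plate = vapply(crops, function(cr) cr$plate %||% NA_character_, ""),
    well = vapply(crops, function(cr) cr$well %||% NA_character_, ""),
    field = vapply(crops, function(cr) cr$field %||% NA_character_, ""),
    class = factor(cls, levels = FOCI_CLASSES),
    p_nonsig = pr[, "non_signaling"],
    p_neg = pr[, "foci_negative"],
    p_pos = pr[, "foci_positive"],
    raw_green_mean = vapply(crops, function(cr) cr$raw_green_mean, 1.0),
    foci_count = vapply(crops, function(cr)
      as.integer(detect_foci_count_cached(cr, model$fparams)), 1L),
    row.names = NULL)
}

detect_foci_count_cached <- function(crop, fparams) {
  detect_foci(crop, fparams)$foci_count
}

evaluate_records <- function(records, labels) {
  pred <- factor(records$class, levels = FOCI_CLASSES)
  truth <- factor(labels, levels = FOCI_CLASSES)
  cm <- table(truth = truth, predicted = pred)
  recall <- diag(cm) / pmax(rowSums(cm), 1)
  precision <- diag(cm) / pmax(colSums(cm), 1)
  present <- rowSums(cm) > 0
  list(confusion = cm,
       precision = precision, recall = recall,
       macro_accuracy = mean(recall[present]),
       overall_accuracy = sum(diag(cm)) / sum(cm))
}

#' Evaluate a classifier on a labeled crop set
#'
#' Macro accuracy is the mean per-class recall over classes present in the
#' labels (balanced accuracy); all metrics derive from the confusion matrix
#' only.
#'
#' @param model a `foci_classifier`.
#' @param crops list of normalized crops.
#' @param labels true class factor (same length).
#' @return list: `confusion` (rows = truth), `precision`, `recall`,
#'   `macro_accuracy`, `overall_accuracy`.
#' @export
evaluate <- function(model, crops, labels) {
  if (length(crops) != length(labels)) stop_fs("crops/labels length mismatch")
  evaluate_records(classify(model, crops), labels)
}
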