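test_that("truth labeling follows the expression/threshold rule", {
  expect_equal(as.character(label_truth(0, 12)), "non_signaling")
  expect_equal(as.character(label_truth(1.0, 0)), "foci_negative")
  expect_equal(as.character(label_truth(0.4, 9)), "foci_positive")
  expect_equal(as.character(label_truth(0.4, 4, positivity_threshold = 5)),
               "foci_negative")
  expect_equal(as.character(label_truth(0.4, 4, positivity_threshold = 4)),
               "foci_positive")
  expect_error(label_truth(1, 1, positivity_threshold = -1), ">= 0")
})

test_that("featurize is deterministic with documented gain behaviour", {
  cfg <- sim_config(p_nonsignal = 0)
  sim <- simulate_cell_crops(3, cfg, treatment(dose = 0.5), seed = 12)
  cr <- normalize_crop(sim$crops[[1]])
  f1 <- featurize(cr)
  expect_identical(f1, featurize(cr))
  expect_named(f1, c("raw_green_mean", "anchor_spread", "signal_snr_log",
                     "spread_snr_log", "norm_var", "norm_kurtosis",
                     "tophat_energy", "foci_count", "foci_prominence_sum",
                     "gran_r2", "gran_r4", "gran_r8", "mask_area"))
  # gain x2 pre-clipping: raw-scale features double, shape features equal
  f2 <- featurize(gain_crop(sim$crops[[2]], 1))
  f2x <- featurize(gain_crop(sim$crops[[2]], 2))
  expect_equal(f2x[["raw_green_mean"]], 2 * f2[["raw_green_mean"]])
  expect_equal(f2x[["anchor_spread"]], 2 * f2[["anchor_spread"]])
  shape <- c("norm_var", "norm_kurtosis", "tophat_energy", "foci_count",
             "gran_r2", "gran_r4", "gran_r8", "mask_area")
  expect_equal(f2x[shape], f2[shape], tolerance = 1e-10)
  bad <- cr; bad$mask <- NULL
  expect_error(featurize(bad), "mask")
})

test_that("flat zero-expression crops have background-level features", {
  cfg <- sim_config(photon_noise = FALSE, read_noise_sd = 0, p_nonsignal = 1)
  sim <- simulate_cell_crops(2, cfg, treatment(dose = 0.5), seed = 3)
  f <- featurize(normalize_crop(sim$crops[[1]]))
  expect_equal(f[["tophat_energy"]], 0)
  expect_equal(f[["signal_snr_log"]], 0)
  expect_equal(f[["foci_count"]], 0)
})

test_that("training validates class presence and is reproducible", {
  full <- trained_model()
  tset <- full$tset
  broken <- tset
  broken$split[broken$labels == "non_signaling"] <- "test"
  expect_error(train_classifier(broken), "non_signaling=0")

  m1 <- train_classifier(tset, seed = 2)
  m2 <- train_classifier(tset, seed = 2)
  expect_identical(coef(m1$fit), coef(m2$fit))
})

test_that("a linearly separable toy set is fit perfectly", {
  cfg <- sim_config(photon_noise = FALSE, read_noise_sd = 0)
  # extremes only: blank cells, clean negatives, heavily damaged positives
  s0 <- simulate_cell_crops(30, sim_config(photon_noise = FALSE,
                                           read_noise_sd = 0, p_nonsignal = 1),
                            treatment(dose = 0), seed = 1)
  s1 <- simulate_cell_crops(30, sim_config(photon_noise = FALSE,
                                           read_noise_sd = 0, p_nonsignal = 0),
                            treatment(dose = 0, effect = 0), seed = 2)
  s2 <- simulate_cell_crops(30, sim_config(photon_noise = FALSE,
                                           read_noise_sd = 0, p_nonsignal = 0),
                            treatment(dose = 50), seed = 3)
  crops <- lapply(c(s0$crops, s1$crops, s2$crops), normalize_crop)
  nf <- c(s0$truth$n_foci, s1$truth$n_foci, s2$truth$n_foci)
  labels <- label_truth(c(s0$truth$expression_gain, s1$truth$expression_gain,
                          s2$truth$expression_gain), nf)
  # keep only unambiguous exemplars: clean negatives, heavily damaged positives
  keep <- (labels == "non_signaling") |
    (labels == "foci_negative" & nf == 0) |
    (labels == "foci_positive" & nf >= 8)
  tset <- list(crops = crops[keep], labels = droplevels(labels[keep]),
               split = rep("train", sum(keep)))
  tset$labels <- factor(tset$labels,
                        levels = c("non_signaling", "foci_negative",
                                   "foci_positive"))
  m <- train_classifier(tset)
  ev <- evaluate(m, tset$crops, tset$labels)
  expect_equal(ev$overall_accuracy, 1.0)
})

test_that("classification yields valid records on the probability simplex", {
  full <- trained_model()
  te <- full$tset$split == "test"
  rec <- classify(full$model, full$tset$crops[te])
  expect_equal(nrow(rec), sum(te))
  p <- as.matrix(rec[, c("p_nonsig", "p_neg", "p_pos")])
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  expect_true(all(p >= 0 & p <= 1))
  amax <- c("non_signaling", "foci_negative", "foci_positive")[
    apply(p, 1, which.max)]
  expect_equal(as.character(rec$class), amax)
  expect_equal(nrow(classify(full$model, list())), 0)
})

test_that("zero-expression crops are recalled as non-signaling", {
  full <- trained_model()
  zs <- simulate_cell_crops(200, sim_config(p_nonsignal = 1),
                            treatment(dose = 0.5), seed = 9)
  rec <- classify(full$model, lapply(zs$crops, normalize_crop))
  expect_gte(mean(rec$class == "non_signaling"), 0.99)
})

test_that("evaluation equals a brute-force pairwise tally", {
  full <- trained_model()
  idx <- which(full$tset$split == "test")[1:30]
  rec <- classify(full$model, full$tset$crops[idx])
  labels <- full$tset$labels[idx]
  ev <- evaluate(full$model, full$tset$crops[idx], labels)
  classes <- levels(labels)
  brute <- matrix(0L, 3, 3, dimnames = list(classes, classes))
  for (i in seq_along(idx))
    brute[as.character(labels[i]), as.character(rec$class[i])] <-
      brute[as.character(labels[i]), as.character(rec$class[i])] + 1L
  expect_equal(unclass(ev$confusion), unclass(brute), ignore_attr = TRUE)
  expect_equal(sum(ev$confusion), 30)
})

test_that("degenerate predictors give the expected macro accuracy", {
  # all-one-class predictions on a balanced 3-class set: macro accuracy 1/3
  labels <- factor(rep(c("non_signaling", "foci_negative", "foci_positive"),
                       each = 10),
                   levels = c("non_signaling", "foci_negative", "foci_positive"))
  rec <- data.frame(class = factor(rep("foci_negative", 30),
                                   levels = levels(labels)))
  ev <- fociscreen:::evaluate_records(rec, labels)
  expect_equal(ev$macro_accuracy, 1 / 3)
  perfect <- data.frame(class = labels)
  evp <- fociscreen:::evaluate_records(perfect, labels)
  expect_equal(evp$macro_accuracy, 1.0)
  expect_true(all(diag(evp$confusion) == 10))
})

test_that("the pixel-grid neural backend trains and emits valid records", {
  tset <- make_training_set(400, sim_config(), seed = 5)
  m <- train_classifier(tset, backend = "nnet_pixels", seed = 3, hidden = 6)
  te <- tset$split == "test"
  rec <- classify(m, tset$crops[te])
  p <- as.matrix(rec[, c("p_nonsig", "p_neg", "p_pos")])
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  ev <- evaluate(m, tset$crops[te], tset$labels[te])
  expect_gt(ev$overall_accuracy, 0.5)
})
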