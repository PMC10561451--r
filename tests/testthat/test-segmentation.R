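test_that("a blank field yields zero instances and an empty crop list", {
  cfg <- small_config(cells_per_field = 0)
  g <- generate_field(cfg, treatment(), seed = 1)
  seg <- segment_nuclei(g$field, segment_params(cfg))
  expect_equal(nrow(seg$instances), 0)
  expect_equal(max(seg$label_map), 0)
  expect_length(extract_crops(g$field, seg$label_map, seg$instances), 0)
})

test_that("nuclei across the whole brightness range are found within 2 px", {
  cfg <- small_config(cells_per_field = 5)
  g <- generate_field(cfg, treatment(dose = 0.5), seed = 23)
  seg <- segment_nuclei(g$field, segment_params(cfg))
  tr <- g$truth$cells
  interior <- tr[tr$row > tr$radius & tr$row < 256 - tr$radius &
                 tr$col > tr$radius & tr$col < 256 - tr$radius, ]
  for (i in seq_len(nrow(interior))) {
    d <- sqrt((seg$instances$centroid_row - interior$row[i])^2 +
              (seg$instances$centroid_col - interior$col[i])^2)
    expect_lt(min(d), 2)
  }
})

test_that("touching pairs are split by the watershed", {
  cfg <- sim_config(image_size = c(256L, 256L), cells_per_field = 4,
                    touching = TRUE)
  g <- generate_field(cfg, treatment(dose = 0.5), seed = 21)
  seg <- segment_nuclei(g$field, segment_params(cfg))
  expect_equal(nrow(seg$instances), nrow(g$truth$cells))
})

test_that("label maps are contiguous and disjoint; input is validated", {
  cfg <- small_config()
  g <- generate_field(cfg, treatment(dose = 0.5), seed = 4)
  seg <- segment_nuclei(g$field, segment_params(cfg))
  labs <- sort(unique(as.vector(seg$label_map)))
  expect_identical(labs, c(0:max(seg$label_map)))
  expect_identical(seg$instances$label, seq_len(max(seg$label_map)))
  expect_error(segment_nuclei(list(nuclear = matrix(0, 4, 4))),
               "two-channel")
  sat <- g$field; sat$nuclear[] <- 65535L
  expect_error(segment_nuclei(sat, segment_params(cfg)), "saturated")
})

test_that("crops are centred, border policy applies, and padding works", {
  cfg <- small_config(cells_per_field = 8)
  g <- generate_field(cfg, treatment(dose = 0.5), seed = 15)
  seg <- segment_nuclei(g$field, segment_params(cfg))
  crops <- extract_crops(g$field, seg$label_map, seg$instances, crop_size = 64)
  inst <- seg$instances
  expect_length(crops, sum(!inst$border_touching))
  crops_all <- extract_crops(g$field, seg$label_map, seg$instances,
                             crop_size = 64, include_border = TRUE)
  expect_length(crops_all, nrow(inst))
  for (cr in crops) {
    expect_equal(dim(cr$green), c(64L, 64L))
    k <- which(inst$label == cr$cell_id)
    expect_lte(abs(cr$center[1] - inst$centroid_row[k]), 1)
    expect_lte(abs(cr$center[2] - inst$centroid_col[k]), 1)
    expect_true(any(cr$mask))
  }
  expect_error(extract_crops(g$field, seg$label_map, seg$instances,
                             crop_size = 63), "even")
})

test_that("normalization is affine-invariant and flags flat crops", {
  cfg <- small_config(cells_per_field = 4)
  sim <- simulate_cell_crops(6, cfg, treatment(dose = 0.5), seed = 8)
  cr <- normalize_crop(sim$crops[[1]])
  expect_true(all(cr$normalized >= 0 & cr$normalized <= 1))
  expect_lte(cr$p_low_value, cr$p_high_value)
  # exact affine invariance, pre-clipping
  aff <- sim$crops[[1]]
  aff$green <- aff$green * 3.7 + 123
  aff <- normalize_crop(aff)
  expect_equal(aff$normalized, cr$normalized, tolerance = 1e-12)

  flat <- sim$crops[[2]]
  flat$green[] <- 500L
  flat <- normalize_crop(flat)
  expect_true(flat$low_dynamic_range)
  expect_true(all(flat$normalized == 0))
  expect_error(normalize_crop(sim$crops[[3]], eps = 0), "positive")
  expect_error(normalize_crop(sim$crops[[3]], p_low = 50, p_high = 40))
})

test_that("the normalized maximum falls on a planted focus", {
  cfg <- sim_config(photon_noise = FALSE, read_noise_sd = 0,
                    p_nonsignal = 0, focus_min_separation = 18)
  sim <- simulate_cell_crops(20, cfg, treatment(dose = 0.5), seed = 13)
  foci <- attr(sim$truth, "foci")
  for (i in which(sim$truth$n_foci > 0)) {
    cr <- normalize_crop(sim$crops[[i]])
    am <- which(cr$normalized == max(cr$normalized), arr.ind = TRUE)[1, ]
    fi <- foci[foci$cell_id == i, ]
    expect_lt(min(sqrt((fi$row - am[1])^2 + (fi$col - am[2])^2)), 2.5)
  }
})

test_that("object-level detection scores are computed by greedy matching", {
  tr <- data.frame(row = c(10, 50), col = c(10, 50), radius = 5)
  inst <- data.frame(label = 1:2, centroid_row = c(11, 90),
                     centroid_col = c(10, 90))
  sc <- segmentation_score(tr, inst, radius = 5)
  expect_equal(sc$tp, 1); expect_equal(sc$fp, 1); expect_equal(sc$fn, 1)
  expect_equal(sc$f1, 0.5)
})
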