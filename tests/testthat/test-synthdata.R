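test_that("empty and deterministic field generation behave as contracted", {
  cfg <- small_config(cells_per_field = 0)
  g <- generate_field(cfg, treatment(), seed = 1)
  expect_equal(nrow(g$truth$cells), 0)
  expect_equal(dim(g$field$nuclear), c(256L, 256L))
  # background + noise only: everything near the background level
  expect_lt(max(g$field$nuclear), cfg$background_level + 10 * sqrt(cfg$background_level))

  cfg2 <- small_config()
  a <- generate_field(cfg2, treatment(dose = 0.5), seed = 7)
  b <- generate_field(cfg2, treatment(dose = 0.5), seed = 7)
  expect_identical(a$field$nuclear, b$field$nuclear)
  expect_identical(a$field$green, b$field$green)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("intensities respect the bit depth and are integer grids", {
  g <- generate_field(small_config(), treatment(dose = 5), seed = 3)
  expect_true(is.integer(g$field$green))
  expect_gte(min(g$field$nuclear), 0)
  expect_lte(max(g$field$green), 2^16 - 1)
})

test_that("per-cell mean true foci matches the configured dose law", {
  cfg <- sim_config(image_size = c(2048L, 2048L), cells_per_field = 200)
  g <- generate_field(cfg, treatment(dose = 0.5), seed = 11)
  sig <- g$truth$cells$expression_gain > 0
  mu <- mean_foci(cfg$dose_model, 0.5)
  k <- g$truth$cells$n_foci[sig]
  se <- sqrt(mu / length(k))
  expect_lt(abs(mean(k) - mu), 3 * se)
})

test_that("non-signaling fraction sits inside the exact binomial interval", {
  cfg <- sim_config()
  sim <- simulate_cell_crops(1000, cfg, treatment(dose = 0.5), seed = 19)
  n0 <- sum(sim$truth$expression_gain == 0)
  ci <- binom.test(n0, 1000, p = cfg$p_nonsignal, conf.level = 0.99)$conf.int
  expect_true(cfg$p_nonsignal >= ci[1] && cfg$p_nonsignal <= ci[2])
})

test_that("mean foci is monotone in dose and antitone in compound effect", {
  cfg <- sim_config()
  doses <- c(0, 0.05, 0.5, 5)
  means <- vapply(seq_along(doses), function(i) {
    s <- simulate_cell_crops(500, cfg, treatment(dose = doses[i]),
                             seed = 100 + i)
    mean(s$truth$n_foci[s$truth$expression_gain > 0])
  }, 1.0)
  mus <- mean_foci(cfg$dose_model, doses)
  ses <- sqrt(mus / 450)   # ~90% of cells signal
  expect_true(all(diff(means) > -3 * (ses[-1] + ses[-4])))
  # analytic law: nonincreasing in e at fixed dose
  expect_true(all(diff(mean_foci(cfg$dose_model, 0.5, seq(0, 1, 0.25))) <= 0))
})

test_that("wells produce distinct fields from derived seeds, reproducibly", {
  cfg <- small_config()
  w <- generate_well(cfg, treatment(dose = 0.5), n_fields = 4, seed = 5)
  expect_length(w, 4)
  expect_true(all(vapply(w, function(f) f$field$well, "") == "A01"))
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(identical(w[[i]]$field$green, w[[j]]$field$green))
  w2 <- generate_well(cfg, treatment(dose = 0.5), n_fields = 4, seed = 5)
  expect_identical(w[[3]]$field$nuclear, w2[[3]]$field$nuclear)
  expect_length(generate_well(cfg, treatment(), n_fields = 1, seed = 1), 1)
})

test_that("overcrowded fields fail with a density-limit error", {
  cfg <- sim_config(image_size = c(64L, 64L), cells_per_field = 60)
  expect_error(generate_field(cfg, treatment(), seed = 2), "density limit")
})

test_that("fast screen simulation honours effects and is deterministic", {
  des <- screen_design(n_compounds = 3L, n_replicates = 2L,
                       effects = c(CPD002 = 1))
  cfg <- sim_config()
  scr <- simulate_screen(des, cfg, seed = 31, cells_per_well = 2000)
  w <- scr$wells
  # e = 1 compound wells match control-well foci means; e = 0 match DOX
  ctl <- mean(w$foci_per_cell[w$role == "control"])
  dox <- mean(w$foci_per_cell[w$role == "dox"])
  full <- mean(w$foci_per_cell[!is.na(w$compound_id) & w$compound_id == "CPD002"])
  inert <- mean(w$foci_per_cell[!is.na(w$compound_id) & w$compound_id != "CPD002"])
  se <- sqrt(mean_foci(cfg$dose_model, 0.5) / 1800)
  expect_lt(abs(full - ctl), 6 * se)
  expect_lt(abs(inert - dox), 6 * se)
  scr2 <- simulate_screen(des, cfg, seed = 31, cells_per_well = 2000)
  expect_identical(scr$wells, scr2$wells)
  expect_identical(scr$mode, "fast")
})

test_that("screen design validates its true-active table and geometry", {
  expect_error(screen_design(effects = c(NOPE = 0.5)), "unknown compound")
  expect_error(screen_design(n_control = 0L), "control")
  des <- screen_design(n_compounds = 10L, n_replicates = 1L)
  expect_true(all(c("control", "dox") %in% des$layout$role))
})
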