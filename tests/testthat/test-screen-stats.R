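test_that("well summaries implement the percent-foci-positive formula", {
  rec <- data.frame(
    well = "B02",
    class = factor(rep(c("foci_positive", "foci_negative", "non_signaling"),
                       c(30, 10, 5)),
                   levels = c("non_signaling", "foci_negative", "foci_positive")))
  lay <- data.frame(plate = "P1", well = "B02", role = "compound",
                    compound_id = "CPD001")
  s <- summarize_well(rec, lay)
  expect_equal(s$pct_foci_positive, 75.0)
  expect_equal(s$n_pos + s$n_neg + s$n_nonsig, nrow(rec))

  rec0 <- rec; rec0$class[rec0$class == "foci_positive"] <- "foci_negative"
  expect_equal(summarize_well(rec0, lay)$pct_foci_positive, 0.0)

  recn <- data.frame(well = "B02",
                     class = factor(rep("non_signaling", 12),
                                    levels = levels(rec$class)))
  sn <- summarize_well(recn, lay)
  expect_true(is.na(sn$pct_foci_positive))
  expect_true(sn$no_signaling_cells)

  bad <- rbind(rec, transform(rec, well = "B03"))
  expect_error(summarize_well(bad, lay), "multiple wells")
})

test_that("RPS normalization matches its defining formula", {
  tb <- compute_rps(data.frame(compound_id = c("a", "b", "c"),
                               value = c(2, 4, 8)))
  expect_equal(tb$rps, c(50, 100, 200))
  # a compound at the plate median scores exactly 100
  expect_equal(tb$rps[tb$value == median(c(2, 4, 8))], 100)
  same <- compute_rps(data.frame(compound_id = letters[1:4], value = rep(3, 4)))
  expect_true(all(same$rps == 100))
  expect_error(compute_rps(data.frame(compound_id = "a", value = 0)),
               "median is 0")
  # missing values are excluded from the median and stay missing
  nm <- compute_rps(data.frame(compound_id = c("a", "b", "c"),
                               value = c(NA, 4, 8)))
  expect_true(is.na(nm$rps[1]))
  expect_equal(nm$rps[2], 100 * 4 / 6)
})

test_that("replicate aggregation ranks, tie-breaks, and selects", {
  r1 <- data.frame(compound_id = c("X", "Y", "Z"), rps = c(50, 100, 100))
  r2 <- data.frame(compound_id = c("X", "Y", "Z"), rps = c(70, 100, 100))
  res <- aggregate_and_rank(list(r1, r2), n_select = 2)
  expect_equal(res$compound_id, c("X", "Y", "Z"))   # tie Y/Z -> id order
  expect_equal(res$rank, 1:3)
  expect_equal(sum(res$selected), 2)
  expect_true(res$selected[res$compound_id == "Y"])

  expect_warning(res2 <- aggregate_and_rank(list(r1[1:2, ]), n_select = 12),
                 "all selected")
  expect_true(all(res2$selected))

  dup <- data.frame(compound_id = c("X", "X"), rps = c(1, 2))
  expect_error(aggregate_and_rank(list(dup)), "duplicate")

  # missing replicate: mean over available, count recorded
  r3 <- data.frame(compound_id = "X", rps = 90)
  res3 <- aggregate_and_rank(list(r1, r3), n_select = 1)
  expect_equal(res3$n_replicates[res3$compound_id == "X"], 2)
  expect_equal(res3$n_replicates[res3$compound_id == "Y"], 1)
  expect_equal(res3$mean_rps[res3$compound_id == "X"], 70)
})

test_that("per-plate RPS median over compound wells is 100 by construction", {
  des <- screen_design(n_compounds = 40L, n_replicates = 2L)
  scr <- simulate_screen(des, sim_config(), seed = 3, cells_per_well = 300)
  for (k in 1:2) for (pl in unique(scr$wells$plate[scr$wells$replicate == k])) {
    cw <- scr$wells[scr$wells$replicate == k & scr$wells$plate == pl &
                      scr$wells$role == "compound", ]
    tb <- compute_rps(data.frame(compound_id = cw$compound_id,
                                 value = cw$pct_foci_positive))
    expect_equal(median(tb$rps), 100)
  }
})

test_that("4PL fitting recovers parameters and is honest about failure", {
  d <- c(1, 3, 10, 30, 60, 100, 200, 400)
  y <- 10 + (90 - 10) / (1 + (d / 40)^1.2)
  f <- fit_dose_response(d, y)
  expect_true(f$converged)
  expect_lt(abs(f$ic50 - 40) / 40, 0.01)
  expect_equal(f$hill, 1.2, tolerance = 0.01)
  expect_lte(f$bottom, f$top)

  expect_false(fit_dose_response(d, rep(7, 8))$converged)
  expect_error(fit_dose_response(d[1:3], y[1:3]), "4 distinct")
  expect_error(fit_dose_response(d, c(y[-1], NaN)), "non-finite")
  # zero dose is mapped to a pseudo-dose, not an error
  f0 <- fit_dose_response(c(0, d[-1]), c(92, y[-1]))
  expect_true(f0$converged)
})

test_that("seeded Monte-Carlo IC50 recovery stays within 10% median error", {
  set.seed(2024)
  d <- c(1, 3, 10, 30, 60, 100, 200, 400)
  errs <- replicate(200, {
    ic50 <- exp(runif(1, log(5), log(80)))
    y <- 5 + 80 / (1 + (d / ic50)^runif(1, 0.8, 2))
    f <- fit_dose_response(d, y * (1 + rnorm(length(d), 0, 0.05)))
    if (f$converged) abs(f$ic50 - ic50) / ic50 else NA
  })
  expect_lte(median(errs, na.rm = TRUE), 0.10)
})

test_that("Mann-Whitney U agrees with the exhaustive pair-counting oracle", {
  set.seed(7)
  for (rep in 1:25) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    x <- sample(8, n1, replace = TRUE); y <- sample(8, n2, replace = TRUE)
    u <- mann_whitney_u(x, y)
    brute <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(u$U, brute)
    expect_gte(u$U, 0); expect_lte(u$U, n1 * n2)
  }
  expect_equal(mann_whitney_u(1:5, 1:5)$U, 12.5)      # n1*n2/2
  expect_equal(mann_whitney_u(1:4, 11:15)$U, 0)       # all x below all y
  expect_equal(mann_whitney_u(11:15, 1:4)$U, 20)
  expect_error(mann_whitney_u(numeric(0), 1), "nonempty")
})

test_that("tie-free exact p-values match the reference distribution", {
  set.seed(9)
  x <- rnorm(6); y <- rnorm(7) + 1
  u <- mann_whitney_u(x, y)
  w <- wilcox.test(x, y, exact = TRUE)
  expect_equal(u$p_value, w$p.value, tolerance = 1e-12)
  expect_equal(u$method, "exact")
})

test_that("QC tables are normalized and conserve well counts", {
  res <- data.frame(compound_id = letters[1:6],
                    mean_rps = c(95, 99, 100, 101, 105, 40),
                    selected = c(rep(FALSE, 5), TRUE))
  ctl <- c(90, 95, 100, 102, 99)
  sel <- c(35, 42, 38)
  qc <- screen_qc(res, ctl, sel)
  expect_equal(tail(qc$ecdf$cum_fraction, 1), 1.0)
  expect_equal(sum(qc$histogram$count[qc$histogram$group == "control"]),
               length(ctl))
  expect_equal(sum(qc$histogram$count[qc$histogram$group == "selected"]),
               length(sel))
  expect_s3_class(qc$comparison, "group_comparison")
})

test_that("a screen with strong true actives shows a significant QC split", {
  eff <- setNames(rep(0.8, 12), sprintf("CPD%03d", c(3, 21, 47, 88, 102, 133,
                                                     160, 199, 230, 262, 291, 310)))
  des <- screen_design(effects = eff)
  scr <- simulate_screen(des, sim_config(), seed = 17, cells_per_well = 600)
  res <- rank_screen(scr$wells)
  expect_lt(res$qc$comparison$p_value, 0.01)
})
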