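# Screening statistics: % foci-positive well summaries, robust percent of
# samples (RPS) plate normalization, replicate aggregation and hit ranking,
# 4PL dose-response fitting, Mann-Whitney QC.

#' Summarize one well from classified cell records
#'
#' Implements the per-well readouts: the percentage of foci-positive cells,
#' `100 * n_pos / (n_pos + n_neg)` — non-signaling cells are excluded from
#' the denominator — and optionally the mean foci per evaluable cell. A well
#' with no signaling cells gets a missing percentage and an explicit flag.
#'
#' @param records cell-record data frame from [classify()]; must belong to a
#'   single well.
#' @param layout_row one-row data frame with at least `plate, well, role`
#'   (and optionally `compound_id, replicate`).
#' @param foci data frame or list from [foci_per_cell()] for the same cells
#'   (optional).
#' @return one-row data frame of class counts, `pct_foci_positive`,
#'   `mean_foci_per_cell`, `n_cells`, and `no_signaling_cells` flag.
#' @export
summarize_well <- function(records, layout_row, foci = NULL) {
  wells <- unique(stats::na.omit(records$well))
  if (length(wells) > 1)
    stop_fs("records span multiple wells: %s", paste(wells, collapse = ", "))
  n_pos <- sum(records$class == "foci_positive")
  n_neg <- sum(records$class == "foci_negative")
  n_nonsig <- sum(records$class == "non_signaling")
  denom <- n_pos + n_neg
  fm <- NA_real_
  if (!is.null(foci)) fm <- if (is.list(foci) && !is.data.frame(foci))
    foci$well_mean else mean(foci$foci_count[!foci$not_evaluable])
  data.frame(
    plate = layout_row$plate, well = layout_row$well, role = layout_row$role,
    compound_id = layout_row$compound_id %||% NA_character_,
    replicate = layout_row$replicate %||% NA_integer_,
    n_pos = n_pos, n_neg = n_neg, n_nonsig = n_nonsig,
    n_cells = nrow(records),
    pct_foci_positive = if (denom > 0) 100 * n_pos / denom else NA_real_,
    mean_foci_per_cell = fm,
    no_signaling_cells = denom == 0)
}

#' Robust percent of samples (RPS) plate normalization
#'
#' `RPS_i = 100 * S_i / median(S)` where the median is taken over the
#' compound wells of the same plate only (control and model wells are not
#' compounds and are excluded from the median). Missing readouts stay
#' missing and do not enter the median.
#'
#' @param plate_table data frame with columns `compound_id` and `value`
#'   (one replicate, one plate; compound wells only).
#' @return the table with an `rps` column appended.
#' @export
compute_rps <- function(plate_table) {
  if (!all(c("compound_id", "value") %in% names(plate_table)))
    stop_fs("plate_table needs columns compound_id and value")
  v <- plate_table$value
  if (all(is.na(v))) stop_fs("no non-missing compound readouts on this plate")
  med <- stats::median(v, na.rm = TRUE)
  if (med == 0) stop_fs("plate median is 0; RPS normalization undefined")
  plate_table$rps <- 100 * v / med
  plate_table
}

#' Aggregate replicate RPS values and select hits
#'
#' Per-compound mean RPS over available replicates (count recorded),
#' ascending rank with ties broken by compound id (lexicographic, stable),
#' and the `n_select` lowest-mean-RPS compounds flagged selected.
#'
#' @param rps_tables list of data frames (one per replicate) with
#'   `compound_id` and `rps`; a compound may be missing from a replicate.
#' @param n_select number of compounds carried forward (default 12).
#' @return data frame of class results: `compound_id, mean_rps, n_replicates,
#'   rps_rep<k> columns, rank, selected`, sorted by rank.
#' @export
aggregate_and_rank <- function(rps_tables, n_select = 12L) {
  if (n_select < 0) stop_fs("n_select must be >= 0")
  for (k in seq_along(rps_tables)) {
    tb <- rps_tables[[k]]
    if (anyDuplicated(tb$compound_id))
      stop_fs("duplicate compound_id within replicate %d", k)
  }
  ids <- sort(unique(unlist(lapply(rps_tables, `[[`, "compound_id"))))
  mat <- matrix(NA_real_, length(ids), length(rps_tables),
                dimnames = list(ids, sprintf("rps_rep%d", seq_along(rps_tables))))
  for (k in seq_along(rps_tables)) {
    tb <- rps_tables[[k]]
    mat[tb$compound_id, k] <- tb$rps
  }
  mean_rps <- rowMeans(mat, na.rm = TRUE)
  n_rep <- rowSums(!is.na(mat))
  if (any(n_rep == 0)) stop_fs("compound present in no replicate")
  ord <- order(mean_rps, ids)                  # tie-break: compound_id order
  res <- data.frame(compound_id = ids, mean_rps = mean_rps,
                    n_replicates = n_rep, mat, row.names = NULL,
                    check.names = FALSE)[ord, ]
  res$rank <- seq_len(nrow(res))
  if (n_select > nrow(res)) {
    warning(sprintf("n_select (%d) exceeds number of compounds (%d); all selected",
                    n_select, nrow(res)))
    n_select <- nrow(res)
  }
  res$selected <- res$rank <= n_select
  rownames(res) <- NULL
  res
}

fourPL <- function(d, bottom, span, lic50, hill) {
  bottom + span / (1 + (d / exp(lic50))^hill)
}

#' Four-parameter logistic dose-response fit
#'
#' Fits \eqn{y = bottom + (top - bottom) / (1 + (d/IC_{50})^{hill})} by
#' least squares on log-dose with multi-start initialization from data
#' quantiles. `top >= bottom` is enforced by fitting the span on
#' \eqn{[0, \infty)}. A zero dose is mapped to a pseudo-dose (a configurable
#' fraction of the smallest positive dose) for log-scale handling. Flat or
#' unfittable data yield `converged = FALSE` and no IC50.
#'
#' @param doses numeric vector (>= 4 distinct values after pseudo-dose
#'   mapping).
#' @param responses numeric vector, finite, same length.
#' @param zero_dose_frac pseudo-dose for d = 0, as a fraction of the
#'   smallest positive dose (default 0.01).
#' @return list of class `dose_response_fit`: `bottom, top, ic50, hill`,
#'   `residual_sd`, `converged`, `note`.
#' @export
fit_dose_response <- function(doses, responses, zero_dose_frac = 0.01) {
  if (length(doses) != length(responses)) stop_fs("length mismatch")
  if (any(!is.finite(responses))) stop_fs("non-finite responses")
  if (any(doses < 0)) stop_fs("doses must be nonnegative")
  d <- doses
  if (any(d == 0)) {
    dp <- min(d[d > 0])
    d[d == 0] <- zero_dose_frac * dp
  }
  if (length(unique(d)) < 4L)
    stop_fs("need at least 4 distinct doses for a 4-parameter fit")
  fail <- function(note) structure(
    list(bottom = NA_real_, top = NA_real_, ic50 = NA_real_, hill = NA_real_,
         residual_sd = NA_real_, converged = FALSE, note = note),
    class = "dose_response_fit")
  if (stats::sd(responses) < 1e-10 * (abs(mean(responses)) + 1))
    return(fail("flat responses; dose-response model degenerate"))

  rng <- range(responses)
  starts <- expand.grid(
    lic50 = log(stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)),
    hill = c(0.5, 1, 2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        responses ~ fourPL(d, bottom, span, lic50, hill),
        start = list(bottom = rng[1], span = diff(rng),
                     lic50 = starts$lic50[i], hill = starts$hill[i]),
        lower = c(bottom = -Inf, span = 0, lic50 = -Inf, hill = 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      ss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
    }
  }
  if (is.null(best)) return(fail("no start converged"))
  cf <- stats::coef(best$fit)
  if (cf[["span"]] < 1e-10 * (diff(rng) + 1))
    return(fail("fitted span ~ 0; no dose effect resolvable"))
  structure(list(
    bottom = unname(cf[["bottom"]]),
    top = unname(cf[["bottom"]] + cf[["span"]]),
    ic50 = exp(unname(cf[["lic50"]])),
    hill = unname(cf[["hill"]]),
    residual_sd = sqrt(best$ss / max(1, length(d) - 4)),
    converged = TRUE, note = "ok"), class = "dose_response_fit")
}

#' Mann-Whitney U comparison of two groups
#'
#' U for the first sample counts pairs with \eqn{x_i > y_j}, ties counted as
#' half, computed from midranks. Two-sided p-value: exact via the null U
#' distribution when there are no ties and \eqn{n_1 n_2 \le 400}; full
#' enumeration over group assignments when ties are present and the
#' assignment count is feasible; otherwise the normal approximation with
#' tie correction and continuity correction.
#'
#' @param x,y numeric vectors, both nonempty.
#' @return list of class `group_comparison`: `U, p_value, n1, n2, direction`
#'   (sign of `U - n1 n2 / 2`) and `method`.
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop_fs("both groups must be nonempty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2     # counts x_i > y_j (+ half-ties)
  mu <- n1 * n2 / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && n1 * n2 <= 400) {
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 1 - stats::pwilcox(U - 1, n1, n2))
    method <- "exact"
  } else if (ties && choose(n1 + n2, n1) <= 2e5) {
    pool <- c(x, y)
    combs <- utils::combn(n1 + n2, n1)
    rall <- rank(pool)
    Us <- apply(combs, 2, function(ix) sum(rall[ix])) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "enumeration"
  } else {
    N <- n1 + n2
    tt <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(max(sigma2, 1e-12))
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  structure(list(U = U, p_value = min(p, 1), n1 = n1, n2 = n2,
                 direction = sign(U - mu), method = method),
            class = "group_comparison")
}

#' Screen quality-control tables
#'
#' Produces (i) the empirical cumulative distribution of per-compound mean
#' RPS, (ii) fixed-bin histograms (width 10 RPS units from 0) of per-well
#' RPS for control wells versus wells of selected compounds, and (iii) the
#' Mann-Whitney comparison between those two groups of wells.
#'
#' @param results output of [aggregate_and_rank()].
#' @param control_rps per-well RPS-scale values for control wells (each well
#'   normalized by its own plate's compound median).
#' @param selected_rps per-well RPS values for wells of selected compounds.
#' @return list of class `screen_qc`: `ecdf` (data frame `mean_rps,
#'   cum_fraction`), `histogram` (data frame `bin_low, bin_high, group,
#'   count`), `comparison` (a `group_comparison`).
#' @export
screen_qc <- function(results, control_rps, selected_rps) {
  v <- sort(results$mean_rps)
  ecdf_tab <- data.frame(mean_rps = v,
                         cum_fraction = seq_along(v) / length(v))
  binw <- 10
  hi <- max(c(control_rps, selected_rps, binw))
  breaks <- seq(0, ceiling(hi / binw) * binw, by = binw)
  htab <- do.call(rbind, lapply(
    list(control = control_rps, selected = selected_rps),
    function(vv) {
      ct <- hist(vv, breaks = breaks, plot = FALSE, right = FALSE)$counts
      data.frame(bin_low = utils::head(breaks, -1),
                 bin_high = utils::tail(breaks, -1), count = ct)
    }))
  htab$group <- rep(c("control", "selected"),
                    each = length(breaks) - 1)
  rownames(htab) <- NULL
  structure(list(ecdf = ecdf_tab,
                 histogram = htab[, c("bin_low", "bin_high", "group", "count")],
                 comparison = mann_whitney_u(control_rps, selected_rps)),
            class = "screen_qc")
}

#' Run RPS normalization and ranking over a simulated or measured screen
#'
#' Convenience layer: takes a per-well table (columns `replicate, plate,
#' well, role, compound_id` and the chosen readout), computes per-plate RPS
#' for compound wells replicate by replicate, aggregates, ranks, selects,
#' and builds QC tables using control wells normalized by their plate's
#' compound median.
#'
#' @param well_table per-well data frame (e.g. `simulate_screen()$wells` or
#'   bound [summarize_well()] rows).
#' @param readout column name used as well readout: `"pct_foci_positive"`
#'   or `"mean_foci_per_cell"` / `"foci_per_cell"`.
#' @param n_select compounds carried forward (default 12).
#' @return list of class `screen_result`: `compounds`
#'   ([aggregate_and_rank()] output), `qc` ([screen_qc()] output),
#'   `readout`, `well_rps` (per-well RPS for compound and control wells).
#' @export
rank_screen <- function(well_table, readout = "pct_foci_positive",
                        n_select = 12L) {
  if (!readout %in% names(well_table))
    stop_fs("readout column '%s' not in well table", readout)
  reps <- sort(unique(well_table$replicate))
  rps_tables <- list(); well_rps <- list()
  for (k in reps) {
    wt <- well_table[well_table$replicate == k, ]
    per_rep <- list()
    for (pl in unique(wt$plate)) {
      wp <- wt[wt$plate == pl, ]
      cw <- wp[wp$role == "compound", ]
      tb <- compute_rps(data.frame(compound_id = cw$compound_id,
                                   value = cw[[readout]]))
      per_rep[[pl]] <- tb[, c("compound_id", "rps")]
      med <- stats::median(cw[[readout]], na.rm = TRUE)
      ctl <- wp[wp$role == "control", ]
      well_rps[[length(well_rps) + 1L]] <- rbind(
        data.frame(replicate = k, plate = pl, well = cw$well,
                   role = "compound", compound_id = cw$compound_id,
                   rps = tb$rps),
        data.frame(replicate = k, plate = pl, well = ctl$well,
                   role = "control", compound_id = NA_character_,
                   rps = 100 * ctl[[readout]] / med))
    }
    rps_tables[[k]] <- do.call(rbind, per_rep)
  }
  compounds <- aggregate_and_rank(rps_tables, n_select = n_select)
  well_rps <- do.call(rbind, well_rps)
  sel_ids <- compounds$compound_id[compounds$selected]
  ctl <- well_rps$rps[well_rps$role == "control"]
  sel <- well_rps$rps[well_rps$role == "compound" &
                        well_rps$compound_id %in% sel_ids]
  qc <- screen_qc(compounds, ctl, sel)
  structure(list(compounds = compounds, qc = qc, readout = readout,
                 well_rps = well_rps, n_select = n_select),
            class = "screen_result")
}
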