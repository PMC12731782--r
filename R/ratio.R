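#' Per-batch normalization of variant currents to a wild-type reference
#'
#' The central statistic of the analysis: for every batch and voltage, the
#' mean current of the variant group is divided by the mean current of the
#' matched reference group recorded in the same batch, cancelling the strong
#' batch-to-batch expression variability. Voltages where the reference current
#' is too small for a meaningful ratio (below `gate_mult` times the estimated
#' noise SD of a steady-state value, or below `min_abs` in magnitude) are
#' masked. A flat ratio of 1 indicates wild-type-like behaviour; a flat ratio
#' below 1 a uniform amplitude reduction; a positive slope a depolarizing
#' shift of voltage-dependent activation; a negative slope a gain of function
#' at less positive voltages.
#'
#' @param variant_iv [iv_curve] of the variant group (cells carry batch ids).
#' @param reference_iv [iv_curve] of the reference group, same voltage grid,
#'   batches matched by identifier (never by order).
#' @param gate_mult reference-magnitude gate in units of the steady-state
#'   noise SD.
#' @param min_abs absolute floor of the magnitude gate (guards noise-free
#'   data, where the estimated noise SD is 0).
#' @param per_cell_ratio if `TRUE`, average per-cell ratios within a batch
#'   instead of dividing batch means (alternative convention; default divides
#'   batch means).
#' @return an object of class `ratio_curve`: voltages, per-batch ratio matrix,
#'   pooled mean/SD, n_batches, mask, reference label.
#' @export
normalize_to_reference <- function(variant_iv, reference_iv, gate_mult = 5,
                                   min_abs = 1e-9, per_cell_ratio = FALSE) {
  stopifnot(inherits(variant_iv, "iv_curve"), inherits(reference_iv, "iv_curve"))
  if (!isTRUE(all.equal(variant_iv$voltages, reference_iv$voltages))) {
    stopf("variant and reference voltage grids differ")
  }
  batches <- intersect(unique(variant_iv$cells$batch),
                       unique(reference_iv$cells$batch))
  if (length(batches) == 0) stopf("no common batches between groups")

  se_ref <- reference_iv$se_ss
  if (!is.finite(se_ref)) se_ref <- 0
  gate <- max(gate_mult * se_ref, min_abs)

  ratio <- matrix(NA_real_, length(variant_iv$voltages), length(batches))
  masked <- rep(FALSE, length(variant_iv$voltages))
  for (j in seq_along(batches)) {
    b <- batches[j]
    v_m <- rowMeans(variant_iv$values[, variant_iv$cells$batch == b, drop = FALSE])
    r_cells <- reference_iv$values[, reference_iv$cells$batch == b, drop = FALSE]
    r_m <- rowMeans(r_cells)
    masked <- masked | abs(r_m) < gate
    if (per_cell_ratio) {
      v_cells <- variant_iv$values[, variant_iv$cells$batch == b, drop = FALSE]
      ratio[, j] <- rowMeans(sweep(v_cells, 1, r_m, "/"))
    } else {
      ratio[, j] <- v_m / r_m
    }
  }
  if (all(masked)) stopf("all voltages masked by the reference magnitude gate")

  ratio[masked, ] <- NA_real_

  # delta-method SE of the pooled ratio from within-batch cell scatter; a
  # stabler estimate of the same sampling variance than the SD across the
  # (few) batches
  se_delta <- rep(NA_real_, length(variant_iv$voltages))
  for (i in which(!masked)) {
    var_i <- 0
    for (j in seq_along(batches)) {
      b <- batches[j]
      vv <- variant_iv$values[i, variant_iv$cells$batch == b]
      rv <- reference_iv$values[i, reference_iv$cells$batch == b]
      var_i <- var_i + ratio[i, j]^2 *
        (stats::var(vv) / (mean(vv)^2 * length(vv)) +
         stats::var(rv) / (mean(rv)^2 * length(rv)))
    }
    se_delta[i] <- sqrt(var_i) / length(batches)
  }

  structure(
    list(
      voltages = variant_iv$voltages,
      ratio = ratio,
      mean = rowMeans(ratio),
      sd = apply(ratio, 1, stats::sd),
      se = se_delta,
      n_batches = length(batches),
      masked = masked,
      construct = variant_iv$construct,
      reference = reference_iv$construct
    ),
    class = "ratio_curve"
  )
}

#' @export
print.ratio_curve <- function(x, ...) {
  cat(sprintf(
    "Ratio curve: %s / %s, %d batches, %d voltages (%d masked)\n",
    x$construct, x$reference, x$n_batches, length(x$voltages), sum(x$masked)
  ))
  invisible(x)
}

#' Slope-based functional classification of a ratio curve
#'
#' Fits a weighted least-squares line to the pooled ratio over the unmasked
#' voltage range (weights: inverse variance across batches per voltage). The
#' slope is tested against two error models whenever at least two batches
#' with variation are available: a t interval on per-batch slope replicates
#' (robust to the strong correlation of ratio errors across voltages within a
#' batch — a cell's expression level multiplies its whole curve) and the
#' pooled weighted-regression interval (robust to the sparse batch
#' replication). A slope is flagged only when both intervals exclude zero;
#' the reported CI is their union. The ordered rule set is then:
#' 1. `below_reference_control` if the pooled ratio averaged over the
#'    `top_n` most positive unmasked voltages falls below `floor_ratio`
#'    (currents suppressed below the partner-alone control band);
#' 2. `positive_shift` / `negative_slope_gof` if the two-sided `level`
#'    confidence interval of the slope excludes zero, by slope sign;
#' 3. `uniform_reduction` if the mean ratio is below `flat_max` with a slope
#'    CI containing zero;
#' 4. `wt_like` otherwise.
#'
#' @param rc a `ratio_curve` with at least 4 unmasked voltages.
#' @param floor_ratio threshold of rule 1.
#' @param flat_max mean-ratio threshold of rule 3.
#' @param top_n number of most positive voltages used by rule 1.
#' @param level confidence level of the slope interval.
#' @return an object of class `phenotype_call`: `label`, `slope`, `slope_ci`,
#'   `mean_ratio`, and a `trace` of the rules evaluated.
#' @export
classify_ratio <- function(rc, floor_ratio = 0.3, flat_max = 0.8, top_n = 3,
                           level = 0.95) {
  stopifnot(inherits(rc, "ratio_curve"))
  keep <- !rc$masked
  if (sum(keep) < 4) stopf("fewer than 4 unmasked voltages; cannot classify")
  v <- rc$voltages[keep]
  y <- rc$mean[keep]
  var_b <- (rc$sd[keep]^2) / rc$n_batches
  w <- if (all(var_b > 0)) 1 / var_b else rep(1, length(v))
  fit <- stats::lm(y ~ v, weights = w)
  slope <- unname(stats::coef(fit)[2])
  batch_slopes <- if (rc$n_batches >= 2) {
    vapply(seq_len(rc$n_batches), function(j) {
      unname(stats::coef(stats::lm(rc$ratio[keep, j] ~ v, weights = w))[2])
    }, numeric(1))
  } else {
    numeric(0)
  }
  se_lm <- suppressWarnings(summary(fit))$coefficients[2, 2]
  tq_lm <- stats::qt(1 - (1 - level) / 2, stats::df.residual(fit))
  ci_lm <- slope + c(-1, 1) * tq_lm * se_lm
  ci <- if (length(batch_slopes) >= 2 && stats::sd(batch_slopes) > 0) {
    se_b <- stats::sd(batch_slopes) / sqrt(rc$n_batches)
    tq_b <- stats::qt(1 - (1 - level) / 2, rc$n_batches - 1)
    ci_b <- slope + c(-1, 1) * tq_b * se_b
    range(ci_lm, ci_b)
  } else {
    ci_lm
  }
  mean_ratio <- mean(y)
  # numerically-zero slopes from exact data must not count as CI exclusions
  tol <- 1e-10
  excludes0 <- ci[1] > tol || ci[2] < -tol

  top <- order(v, decreasing = TRUE)[seq_len(min(top_n, length(v)))]
  top_mean <- mean(y[top])

  trace <- character()
  label <- NULL
  trace <- c(trace, sprintf("rule1: mean ratio at top %d voltages = %.3f vs floor %.3f",
                            length(top), top_mean, floor_ratio))
  if (top_mean < floor_ratio) {
    label <- "below_reference_control"
  } else {
    trace <- c(trace, sprintf("rule2: slope = %.2e /mV, %d%% CI [%.2e, %.2e]",
                              slope, round(level * 100), ci[1], ci[2]))
    if (excludes0) {
      label <- if (slope > 0) "positive_shift" else "negative_slope_gof"
    } else {
      trace <- c(trace, sprintf("rule3: mean ratio = %.3f vs flat_max %.3f",
                                mean_ratio, flat_max))
      label <- if (mean_ratio < flat_max) "uniform_reduction" else "wt_like"
    }
  }
  structure(
    list(label = label, slope = slope, slope_ci = ci, mean_ratio = mean_ratio,
         construct = rc$construct, trace = trace),
    class = "phenotype_call"
  )
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat(sprintf("Phenotype: %s -> %s (slope %.2e /mV, CI [%.2e, %.2e], mean ratio %.3f)\n",
              x$construct %||% "?", x$label, x$slope, x$slope_ci[1],
              x$slope_ci[2], x$mean_ratio))
  invisible(x)
}

#' Silent-subunit (E281A) co-expression assay
#'
#' In oocytes co-expressing the partner subunit with a transport-dead E281A
#' variant, all current is carried by the partner; a dominant effect of the
#' variant on the shared gate reduces the current. Each cell's current at the
#' test voltage (+170 mV) is normalized to the mean of the reference
#' (E281A-WT) cells of the same batch.
#'
#' @param values per-cell currents at the test voltage.
#' @param construct per-cell construct labels.
#' @param batch per-cell batch identifiers.
#' @param reference construct label of the within-batch reference group.
#' @return list with `cells` (data frame: construct, batch, value, normalized)
#'   and `summary` (data frame: construct, mean, sd, n).
#' @export
e281a_assay <- function(values, construct, batch, reference) {
  stopifnot(length(values) == length(construct), length(values) == length(batch))
  if (!reference %in% construct) stopf("reference construct '%s' absent", reference)
  ref_mean <- tapply(values[construct == reference], batch[construct == reference], mean)
  need <- unique(as.character(batch))
  missing <- setdiff(need, names(ref_mean))
  if (length(missing)) {
    stopf("batch(es) without reference cells: %s", paste(missing, collapse = ", "))
  }
  norm <- values / ref_mean[as.character(batch)]
  cells <- data.frame(construct = construct, batch = batch, value = values,
                      normalized = as.numeric(norm), stringsAsFactors = FALSE)
  keep <- cells$construct != reference
  agg <- cells[keep, ]
  summary <- do.call(rbind, lapply(split(agg, agg$construct), function(d) {
    data.frame(construct = d$construct[1], mean = mean(d$normalized),
               sd = stats::sd(d$normalized), n = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(cells = cells, summary = summary)
}
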