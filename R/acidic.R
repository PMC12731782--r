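#' Fit the per-cell leak line at neutral pH
#'
#' At pH 7.3, currents at voltages at or below 0 mV are assumed to be pure
#' ohmic leak. For each cell, the current-voltage relationship is fitted with
#' an ordinary least-squares line over `range` (default -120..0 mV); the line
#' is later extrapolated to all voltages and subtracted.
#'
#' @param voltages voltage grid, mV.
#' @param currents per-cell currents at pH 7.3 on that grid.
#' @param range fit range, mV (must lie within [-120, 0]).
#' @return an object of class `leak_line`: `slope` (uS), `intercept` (uA),
#'   `range`, `rms` (residual root-mean-square).
#' @export
fit_leak_line <- function(voltages, currents, range = c(-120, 0)) {
  if (range[1] < -120 || range[2] > 0) stopf("fit range must lie within [-120, 0] mV")
  keep <- voltages >= range[1] & voltages <= range[2]
  if (sum(keep) < 3) stopf("fewer than 3 voltages in the leak fit range")
  fit <- stats::lm(currents[keep] ~ voltages[keep])
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      range = range,
      rms = sqrt(mean(stats::residuals(fit)^2))
    ),
    class = "leak_line"
  )
}

leak_at <- function(leak, v) leak$slope * v + leak$intercept

#' Leak-subtracted, normalized current-voltage relationship
#'
#' Extrapolates a cell's neutral-pH leak line to all voltages, subtracts it
#' from the condition IV, and normalizes to that cell's current at pH 7.3 and
#' +160 mV: `value(V) = (I_cond(V) - L(V)) / (I_73(160) - L(160))`. Because
#' both numerator and denominator scale with expression level, the result is
#' invariant to per-cell global scaling. By default the denominator is the
#' leak-subtracted +160 mV value; `subtract_denominator = FALSE` uses the raw
#' current instead.
#'
#' @param voltages voltage grid, mV (must contain +160).
#' @param i_cond condition currents (e.g. pH 5.3) on that grid.
#' @param leak the cell's [fit_leak_line()] result.
#' @param i_73 the same cell's pH 7.3 currents (source of the denominator).
#' @param subtract_denominator subtract the leak from the denominator too.
#' @return numeric vector of normalized currents (class-free), with the
#'   denominator attached as attribute `denom`.
#' @export
subtract_and_normalize <- function(voltages, i_cond, leak, i_73,
                                   subtract_denominator = TRUE) {
  stopifnot(inherits(leak, "leak_line"), length(i_cond) == length(voltages),
            length(i_73) == length(voltages))
  i160 <- i_73[match(160, voltages)]
  if (is.na(i160)) stopf("voltage grid must contain +160 mV")
  denom <- if (subtract_denominator) i160 - leak_at(leak, 160) else i160
  if (!is.finite(denom) || denom <= 0) {
    stopf("normalization denominator is not positive (%.3g)", denom)
  }
  out <- (i_cond - leak_at(leak, voltages)) / denom
  attr(out, "denom") <- denom
  out
}

#' Full acidic-pH normalization for a group of cells
#'
#' Applies [fit_leak_line()] and [subtract_and_normalize()] per cell and
#' aggregates.
#'
#' @param iv_73 [iv_curve] at pH 7.3 (raw, leak-containing currents).
#' @param iv_cond [iv_curve] of the same cells under the test condition.
#' @param subtract_denominator see [subtract_and_normalize()].
#' @return object of class `normalized_iv`: voltages, per-cell value matrix,
#'   group mean/SD/n, condition label.
#' @export
normalize_acidic_group <- function(iv_73, iv_cond, subtract_denominator = TRUE) {
  stopifnot(inherits(iv_73, "iv_curve"), inherits(iv_cond, "iv_curve"))
  if (!isTRUE(all.equal(iv_73$voltages, iv_cond$voltages))) {
    stopf("mismatched voltage grids between conditions")
  }
  if (!identical(iv_73$cells$cell_id, iv_cond$cells$cell_id)) {
    stopf("conditions must come from the same cells, in the same order")
  }
  v <- iv_73$voltages
  vals <- vapply(seq_len(iv_73$n), function(i) {
    leak <- fit_leak_line(v, iv_73$values[, i])
    as.numeric(subtract_and_normalize(v, iv_cond$values[, i], leak,
                                      iv_73$values[, i],
                                      subtract_denominator = subtract_denominator))
  }, numeric(length(v)))
  structure(
    list(
      voltages = v, values = vals, mean = rowMeans(vals),
      sd = apply(vals, 1, stats::sd), n = ncol(vals),
      construct = iv_cond$construct, condition = iv_cond$ph
    ),
    class = "normalized_iv"
  )
}

#' @export
print.normalized_iv <- function(x, ...) {
  cat(sprintf("Normalized IV: %s (%s), %d cells, %d voltages\n",
              x$construct, x$condition, x$n, length(x$voltages)))
  invisible(x)
}

#' Per-voltage comparison of inward currents
#'
#' Welch's t-test of the normalized currents between two groups at every
#' voltage at or below `v_max` (default +20 mV), with significance stars per
#' voltage. No multiplicity correction is applied, mirroring common
#' per-voltage annotation practice (a deliberately liberal convention).
#'
#' @param group_a,group_b `normalized_iv` objects on the same voltage grid,
#'   each with at least 3 cells.
#' @param v_max most positive voltage entering the comparison, mV.
#' @return data frame: voltage_mV, mean_a, mean_b, diff, t, p, stars.
#' @export
compare_inward <- function(group_a, group_b, v_max = 20) {
  stopifnot(inherits(group_a, "normalized_iv"), inherits(group_b, "normalized_iv"))
  if (!isTRUE(all.equal(group_a$voltages, group_b$voltages))) {
    stopf("mismatched voltage grids")
  }
  if (group_a$n < 3 || group_b$n < 3) stopf("each group needs n >= 3")
  keep <- which(group_a$voltages <= v_max)
  rows <- lapply(keep, function(i) {
    tt <- stats::t.test(group_a$values[i, ], group_b$values[i, ])
    data.frame(
      voltage_mV = group_a$voltages[i],
      mean_a = mean(group_a$values[i, ]), mean_b = mean(group_b$values[i, ]),
      diff = mean(group_b$values[i, ]) - mean(group_a$values[i, ]),
      t = unname(tt$statistic), p = tt$p.value, stars = stars(tt$p.value),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
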