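#' Significance stars
#'
#' Maps p-values to the printed annotation convention with strict
#' inequalities: no asterisk for p >= 0.05, `*` for p < 0.05, `**` for
#' p < 0.01, `***` for p < 0.001.
#'
#' @param p p-value(s) in [0, 1].
#' @return character vector of star strings.
#' @export
#' @examples
#' stars(c(0.05, 0.049, 0.009, 0.0009))
stars <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

new_stat_result <- function(test, groups, statistic, p, n) {
  stopifnot(p >= 0, p <= 1)
  structure(
    list(test = test, groups = groups, statistic = statistic, p = p,
         stars = stars(p), n = n),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: %s; statistic = %.3f, p = %.4g %s (n = %s)\n",
              x$test, paste(x$groups, collapse = " vs "), x$statistic, x$p,
              x$stars, paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Unpaired ratio t-test
#'
#' Two-sample t-test for positive ratio-scaled data (normalized currents):
#' by default the test is performed on natural-log-transformed values — the
#' standard meaning of a ratio t-test, in its unpaired form since variant and
#' control groups come from different batches. Welch's unequal-variance form
#' is the default; `var_equal = TRUE` gives the classic pooled test, and
#' `log_transform = FALSE` the plain t-test on raw ratios for sensitivity
#' analysis.
#'
#' @param variant_values,reference_values per-cell normalized values, both
#'   n >= 3 and (if log-transformed) strictly positive.
#' @param log_transform test log-values (default) or raw values.
#' @param var_equal pooled-variance Student form instead of Welch.
#' @return a `stat_result`.
#' @export
ratio_t_test <- function(variant_values, reference_values,
                         log_transform = TRUE, var_equal = FALSE) {
  if (length(variant_values) < 3 || length(reference_values) < 3) {
    stopf("both groups need n >= 3")
  }
  if (log_transform && (any(variant_values <= 0) || any(reference_values <= 0))) {
    stopf("ratio values must be positive for the log-scale test")
  }
  x <- if (log_transform) log(variant_values) else variant_values
  y <- if (log_transform) log(reference_values) else reference_values
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stopf("both groups have zero variance; test undefined")
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  new_stat_result(
    test = if (log_transform) "unpaired ratio t-test (log scale)" else
      "unpaired t-test",
    groups = c("variant", "reference"),
    statistic = unname(tt$statistic), p = tt$p.value,
    n = c(length(variant_values), length(reference_values))
  )
}

#' One-way ANOVA with Tukey post hoc comparisons
#'
#' Omnibus one-way ANOVA across named groups followed by Tukey's HSD; if a
#' reference group is designated, only its pairwise comparisons are reported.
#'
#' @param groups named list of per-cell value vectors (>= 2 groups, each
#'   n >= 3).
#' @param reference optional name of the reference group for pairwise
#'   reporting.
#' @return list with `omnibus` (a `stat_result`) and `pairwise` (list of
#'   `stat_result`s from Tukey's HSD).
#' @export
anova_tukey <- function(groups, reference = NULL) {
  if (length(groups) < 2) stopf("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 3)) stopf("each group needs n >= 3")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stopf("groups must be named")
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  omnibus <- new_stat_result(
    "one-way ANOVA", names(groups), statistic = an[1, "F value"],
    p = an[1, "Pr(>F)"], n = lengths(groups)
  )
  tk <- stats::TukeyHSD(fit)$group
  pairs <- rownames(tk)
  keep <- if (is.null(reference)) {
    seq_along(pairs)
  } else {
    grep(paste0("(^", reference, "-|-", reference, "$)"), pairs)
  }
  pairwise <- lapply(keep, function(i) {
    gs <- strsplit(pairs[i], "-")[[1]]
    new_stat_result("Tukey HSD", gs, statistic = tk[i, "diff"],
                    p = tk[i, "p adj"], n = lengths(groups)[gs])
  })
  names(pairwise) <- pairs[keep]
  list(omnibus = omnibus, pairwise = pairwise)
}

#' Per-voltage ANOVA/Tukey comparison of IV curves
#'
#' Applies [anova_tukey()] at every voltage at or above `v_min` (comparisons
#' at lower voltages are omitted because currents there are too small to
#' compare meaningfully), reporting Tukey p-values of each group against the
#' reference.
#'
#' @param ivs named list of [iv_curve]s on a common voltage grid.
#' @param reference name of the reference curve.
#' @param v_min smallest voltage entering the comparison, mV.
#' @return data frame: voltage_mV, group, diff, p, stars.
#' @export
anova_tukey_iv <- function(ivs, reference, v_min = 30) {
  stopifnot(length(ivs) >= 2, reference %in% names(ivs))
  volts <- ivs[[1]]$voltages
  rows <- list()
  for (i in which(volts >= v_min)) {
    groups <- lapply(ivs, function(iv) iv$values[i, ])
    res <- anova_tukey(groups, reference = reference)
    for (nm in names(res$pairwise)) {
      pr <- res$pairwise[[nm]]
      rows[[length(rows) + 1]] <- data.frame(
        voltage_mV = volts[i], group = setdiff(pr$groups, reference)[1],
        diff = pr$statistic, p = pr$p, stars = pr$stars,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Assemble a self-describing analysis report
#'
#' Collects ratio curves, phenotype calls and statistical results into one
#' JSON-serializable report with provenance (seed and a config fingerprint),
#' plus a short markdown summary.
#'
#' @param ratio_curves named list of `ratio_curve`s (may be empty).
#' @param phenotype_calls named list of `phenotype_call`s.
#' @param stat_results list of `stat_result`s or per-voltage tables (may be
#'   empty).
#' @param seed the seed the study was generated from.
#' @param config any list describing the configuration (hashed into the
#'   provenance fingerprint).
#' @param file optional path; writes `<file>.json` and `<file>.md`.
#' @return list with `report` (the JSON-able structure) and `markdown`.
#' @export
build_report <- function(ratio_curves = list(), phenotype_calls = list(),
                         stat_results = list(), seed = NA, config = list(),
                         file = NULL) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  report <- list(
    provenance = list(seed = seed, config_hash = fnv1a(as.character(cfg_json))),
    phenotypes = lapply(phenotype_calls, function(pc) {
      list(construct = pc$construct, label = pc$label, slope = pc$slope,
           slope_ci = pc$slope_ci, mean_ratio = pc$mean_ratio,
           trace = pc$trace)
    }),
    ratios = lapply(ratio_curves, function(rc) {
      list(construct = rc$construct, reference = rc$reference,
           voltage_mV = rc$voltages, ratio_mean = rc$mean, ratio_sd = rc$sd,
           n_batches = rc$n_batches, masked = rc$masked)
    }),
    stats = lapply(stat_results, function(s) {
      if (inherits(s, "stat_result")) {
        list(test = s$test, groups = s$groups, statistic = s$statistic,
             p = s$p, stars = s$stars, n = s$n)
      } else {
        s
      }
    })
  )
  md <- c(
    "# Analysis report",
    sprintf("- seed: %s; config: %s", seed, report$provenance$config_hash),
    "",
    "## Phenotype calls",
    if (length(phenotype_calls)) {
      vapply(report$phenotypes, function(p) {
        sprintf("- %s: **%s** (slope %.2e /mV, mean ratio %.3f)",
                p$construct, p$label, p$slope, p$mean_ratio)
      }, character(1))
    } else {
      "- (none)"
    }
  )
  if (!is.null(file)) {
    jsonlite::write_json(report, paste0(file, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    writeLines(md, paste0(file, ".md"))
  }
  list(report = report, markdown = md)
}

#' Export a ratio curve as a CSV table
#'
#' Columns: voltage_mV, ratio_mean, ratio_sd, n_batches, masked.
#' @param rc a `ratio_curve`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ratio_csv <- function(rc, path) {
  stopifnot(inherits(rc, "ratio_curve"))
  utils::write.csv(
    data.frame(voltage_mV = rc$voltages, ratio_mean = rc$mean,
               ratio_sd = rc$sd, n_batches = rc$n_batches,
               masked = rc$masked),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
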