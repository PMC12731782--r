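#' @title Current-voltage relationship container
#' @description An `iv_curve` holds per-cell steady-state currents on a common
#' voltage grid together with group summaries. Created by [build_iv()] or by
#' the IV-level simulator.
#' @name iv_curve
NULL

new_iv_curve <- function(voltages, values, cells, units = "uA",
                         construct = NA_character_, ph = "ph7.3",
                         se_ss = NA_real_, corrected = TRUE) {
  values <- as.matrix(values)
  stopifnot(length(voltages) == nrow(values), nrow(cells) == ncol(values))
  structure(
    list(
      voltages = voltages, values = values, cells = cells,
      mean = rowMeans(values),
      sd = if (ncol(values) == 1) rep(0, nrow(values)) else
        apply(values, 1, stats::sd),
      n = ncol(values),
      units = units, construct = construct, ph = ph,
      se_ss = se_ss, corrected = corrected
    ),
    class = "iv_curve"
  )
}

#' @export
print.iv_curve <- function(x, ...) {
  cat(sprintf(
    "IV curve: %s (%s), %d cells, %d voltages [%g..%g mV], units %s\n",
    x$construct, x$ph, x$n, length(x$voltages), min(x$voltages),
    max(x$voltages), x$units
  ))
  invisible(x)
}

# -- sweep CSV I/O ------------------------------------------------------------

#' Write / read a sweep family CSV
#'
#' Columnar sweep format: leading `# key=value` metadata lines, then a header
#' `time_s,V_200,V_190,...` with one column per sweep named by its step
#' voltage in mV. P/N companions share the file stem with suffix `_pn`.
#'
#' @param ss a `sweep_set`.
#' @param path output file path.
#' @param ph pH condition label stored in the header.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(ss, path, ph = ss$meta$ph %||% "ph7.3") {
  stopifnot(inherits(ss, "sweep_set"))
  meta <- c(
    cell_id = ss$meta$cell_id, construct = ss$meta$construct,
    batch = ss$meta$batch, mode = ss$meta$mode, ph = ph,
    units = ss$meta$units, sampling_hz = ss$protocol$sampling_hz,
    pn_scale = ss$protocol$pn_scale, is_pn = tolower(ss$is_pn),
    corrected = tolower(ss$corrected),
    holding_mV = ss$protocol$holding_mV,
    step_duration_ms = ss$protocol$step_duration_ms,
    pre_ms = ss$protocol$pre_ms, post_ms = ss$protocol$post_ms
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s=%s", names(meta), meta), con)
  df <- data.frame(time_s = ss$time, ss$current)
  names(df) <- c("time_s", sprintf("V_%g", protocol_voltages(ss$protocol)))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @return for `read_sweep_csv`, the reconstructed `sweep_set`.
#' @export
read_sweep_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- stats::setNames(as.list(vals), keys)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)], check.names = FALSE)
  volts <- as.numeric(sub("^V_", "", names(df)[-1]))
  num <- function(x) as.numeric(meta[[x]])
  protocol <- voltage_protocol(
    holding_mV = num("holding_mV"), step_start_mV = volts[1],
    step_delta_mV = if (length(volts) > 1) volts[2] - volts[1] else -10,
    step_end_mV = volts[length(volts)],
    step_duration_ms = num("step_duration_ms"), pre_ms = num("pre_ms"),
    post_ms = num("post_ms"), sampling_hz = num("sampling_hz"),
    pn_scale = num("pn_scale")
  )
  new_sweep_set(
    time = df$time_s, current = as.matrix(df[-1]), protocol = protocol,
    meta = list(
      cell_id = meta$cell_id, construct = meta$construct,
      batch = as.integer(meta$batch), mode = meta$mode, ph = meta$ph,
      units = meta$units, pn_scale = num("pn_scale"),
      sampling_hz = num("sampling_hz")
    ),
    corrected = identical(meta$corrected, "true"),
    is_pn = identical(meta$is_pn, "true")
  )
}

# -- trace processing ---------------------------------------------------------

#' P/N leak and capacitance subtraction
#'
#' Subtracts the scaled P/N companion from a raw sweep family:
#' `corrected = raw - pn / pn_scale`, per sample and sweep. Any component that
#' is linear in the command voltage (ohmic leak, linear capacitive transients)
#' is removed exactly; the transport current, absent from the P/N sweeps, is
#' untouched.
#'
#' @param raw raw `sweep_set`.
#' @param pn companion P/N `sweep_set` acquired at `pn_scale`.
#' @return corrected `sweep_set` (`corrected` flag set).
#' @export
pn_subtract <- function(raw, pn) {
  stopifnot(inherits(raw, "sweep_set"), inherits(pn, "sweep_set"))
  if (!identical(dim(raw$current), dim(pn$current))) {
    stopf("raw and P/N sweep families have mismatched dimensions")
  }
  if (raw$protocol$sampling_hz != pn$protocol$sampling_hz) {
    stopf("raw and P/N sampling rates differ")
  }
  scale <- pn$protocol$pn_scale
  out <- raw
  out$current <- raw$current - pn$current / scale
  out$corrected <- TRUE
  out
}

#' Steady-state current per sweep
#'
#' For each sweep, the mean over the last third of the test-step segment
#' (0-based indices `[floor(2L/3), L)` of the segment, i.e. the final
#' `L - floor(2L/3)` samples). An estimate of the noise SD of each value is
#' attached as attribute `se`, derived from lag-1 sample differences within
#' the averaged window.
#'
#' @param ss a `sweep_set`; by default it must be P/N-corrected.
#' @param allow_raw permit extraction from uncorrected sweeps (diagnostics).
#' @return named numeric vector of steady-state currents per step voltage.
#' @export
steady_state <- function(ss, allow_raw = FALSE) {
  stopifnot(inherits(ss, "sweep_set"))
  if (!ss$corrected && !allow_raw) {
    stopf("sweeps are not P/N-corrected; use allow_raw = TRUE for diagnostics")
  }
  seg <- protocol_segments(ss$protocol)
  L <- seg$n_step
  if (L < 3) stopf("step segment has fewer than 3 samples")
  idx <- seg$step_idx[(floor(2 * L / 3) + 1):L]
  win <- ss$current[idx, , drop = FALSE]
  vals <- colMeans(win)
  names(vals) <- sprintf("V_%g", protocol_voltages(ss$protocol))
  noise_sd <- if (nrow(win) >= 2) {
    mean(apply(win, 2, function(x) stats::sd(diff(x)) / sqrt(2)))
  } else {
    NA_real_
  }
  attr(vals, "se") <- noise_sd / sqrt(length(idx))
  vals
}

#' Build a group current-voltage relationship
#'
#' Stacks per-cell steady-state vectors and computes mean, SD and n per
#' voltage.
#'
#' @param cells list of `sweep_set`s sharing protocol, construct and pH.
#' @param allow_mixed permit mixing constructs (otherwise an error).
#' @param allow_raw passed to [steady_state()].
#' @return an [iv_curve].
#' @export
build_iv <- function(cells, allow_mixed = FALSE, allow_raw = FALSE) {
  stopifnot(length(cells) >= 1)
  constructs <- unique(vapply(cells, function(s) s$meta$construct %||% NA_character_,
                              character(1)))
  if (length(constructs) > 1 && !allow_mixed) {
    stopf("cells mix constructs (%s); pass allow_mixed = TRUE to override",
          paste(constructs, collapse = ", "))
  }
  phs <- unique(vapply(cells, function(s) s$meta$ph %||% "ph7.3", character(1)))
  if (length(phs) > 1) stopf("cells mix pH conditions")
  volts <- protocol_voltages(cells[[1]]$protocol)
  ss <- lapply(cells, steady_state, allow_raw = allow_raw)
  vals <- do.call(cbind, lapply(ss, as.numeric))
  meta <- data.frame(
    cell_id = vapply(cells, function(s) s$meta$cell_id %||% NA_character_, character(1)),
    batch = vapply(cells, function(s) as.integer(s$meta$batch %||% NA), integer(1)),
    stringsAsFactors = FALSE
  )
  colnames(vals) <- meta$cell_id
  se <- mean(vapply(ss, function(x) attr(x, "se"), numeric(1)), na.rm = TRUE)
  new_iv_curve(volts, vals, meta,
               units = cells[[1]]$meta$units %||% "uA",
               construct = constructs[1], ph = phs,
               se_ss = se, corrected = all(vapply(cells, `[[`, logical(1), "corrected")))
}

#' Convert an IV curve to current density
#'
#' Divides each cell's currents by its membrane capacitance (whole-cell
#' recordings only), yielding pA/pF.
#'
#' @param iv an [iv_curve] in pA (`cell_patch` mode).
#' @param capacitance_pF numeric vector of per-cell capacitances, pF, in cell
#'   order (or named by cell_id).
#' @return an [iv_curve] in pA/pF.
#' @export
current_density <- function(iv, capacitance_pF) {
  stopifnot(inherits(iv, "iv_curve"))
  if (!identical(iv$units, "pA")) {
    stopf("current density requires whole-cell currents in pA (got %s)", iv$units)
  }
  if (!is.null(names(capacitance_pF))) {
    capacitance_pF <- capacitance_pF[iv$cells$cell_id]
  }
  if (length(capacitance_pF) != iv$n || anyNA(capacitance_pF)) {
    stopf("one capacitance per cell is required")
  }
  if (any(capacitance_pF <= 0)) stopf("capacitances must be positive")
  vals <- sweep(iv$values, 2, capacitance_pF, "/")
  out <- new_iv_curve(iv$voltages, vals, iv$cells, units = "pA/pF",
                      construct = iv$construct, ph = iv$ph,
                      se_ss = iv$se_ss / mean(capacitance_pF),
                      corrected = iv$corrected)
  out
}

#' Write / read an IV table CSV
#'
#' Columns: voltage_mV, mean, sd, n, then one column per cell; metadata in
#' `# key=value` header lines.
#' @param iv an [iv_curve].
#' @param path file path.
#' @return `path` (write) or the [iv_curve] (read), invisibly for write.
#' @export
write_iv_csv <- function(iv, path) {
  stopifnot(inherits(iv, "iv_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(construct = iv$construct, ph = iv$ph, units = iv$units,
            corrected = tolower(iv$corrected), se_ss = iv$se_ss,
            batches = paste(iv$cells$batch, collapse = ";"))
  writeLines(sprintf("# %s=%s", names(meta), meta), con)
  df <- data.frame(voltage_mV = iv$voltages, mean = iv$mean, sd = iv$sd,
                   n = iv$n, iv$values, check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_iv_csv
#' @export
read_iv_csv <- function(path) {
  lines <- readLines(path)
  hdr <- sub("^#\\s*", "", grep("^#", lines, value = TRUE))
  meta <- stats::setNames(as.list(sub("^[^=]*=", "", hdr)), sub("=.*$", "", hdr))
  df <- utils::read.csv(text = lines[!grepl("^#", lines)], check.names = FALSE)
  vals <- as.matrix(df[, -(1:4), drop = FALSE])
  cells <- data.frame(
    cell_id = colnames(vals),
    batch = as.integer(strsplit(meta$batches, ";")[[1]]),
    stringsAsFactors = FALSE
  )
  new_iv_curve(df$voltage_mV, vals, cells, units = meta$units,
               construct = meta$construct, ph = meta$ph,
               se_ss = as.numeric(meta$se_ss),
               corrected = identical(meta$corrected, "true"))
}

#' Process a simulated session into IV curves
#'
#' Reads a session manifest, P/N-corrects every cell and builds one
#' [iv_curve] per construct (and pH condition).
#'
#' @param manifest_path path to `manifest.json` written by [simulate_session()].
#' @param use_pn apply P/N subtraction (the `--no-pn` diagnostic path skips it).
#' @return named list of [iv_curve]s, one per construct x pH.
#' @export
process_session <- function(manifest_path, use_pn = TRUE) {
  dir <- dirname(manifest_path)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  keys <- unique(paste(manifest$construct, manifest$ph, sep = "|"))
  out <- list()
  for (key in keys) {
    rows <- manifest[paste(manifest$construct, manifest$ph, sep = "|") == key, ]
    cells <- lapply(rows$file, function(f) {
      raw <- read_sweep_csv(file.path(dir, f))
      if (!use_pn) return(raw)
      pn_path <- file.path(dir, sub("\\.csv$", "_pn.csv", f))
      if (!file.exists(pn_path)) stopf("missing P/N companion for '%s'", f)
      pn_subtract(raw, read_sweep_csv(pn_path))
    })
    nm <- if (length(unique(manifest$ph)) > 1) gsub("\\|", "_", key) else
      sub("\\|.*$", "", key)
    out[[nm]] <- build_iv(cells, allow_raw = !use_pn)
  }
  out
}
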