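#' Specification of a synthetic voltage-clamp session
#'
#' Describes the group structure and noise model of a simulated recording
#' session: TEVC in Xenopus oocytes (`oocyte_tevc`, currents in uA) or
#' whole-cell patch clamp (`cell_patch`, currents in pA). Expression varies
#' lognormally per cell and per batch; every cell carries an ohmic leak and a
#' capacitive transient at each step edge, plus additive Gaussian noise.
#'
#' @param constructs list of construct descriptions, see [construct_spec()],
#'   or a character vector of variant labels (each co-expressed 1:1 with the
#'   wild-type partner).
#' @param mode `"oocyte_tevc"` or `"cell_patch"`.
#' @param n_batches number of batches (>= 1).
#' @param cells_per_batch cells per construct per batch; a length-2 vector
#'   gives an inclusive range sampled per batch (minimum 3).
#' @param expression_cv lognormal sigma of per-cell expression.
#' @param batch_cv lognormal sigma of the per-batch expression factor.
#' @param leak_g list with `mean` and `cv` of the lognormal ohmic leak
#'   conductance distribution (uS for oocytes, nS for cells).
#' @param cap_amp capacitive transient amplitude per mV of voltage jump
#'   (current units / mV); decay time constant is 0.2 ms.
#' @param noise_sd additive Gaussian current noise SD per sample.
#' @param seed integer RNG seed; all randomness derives from it.
#' @param ph_condition `"ph7.3"`, `"ph5.3"`, or `"paired"` (both conditions
#'   recorded in each cell).
#' @return an object of class `session_spec`.
#' @export
session_spec <- function(constructs = list(construct_spec("C3_C4.WT", "WT")),
                         mode = c("oocyte_tevc", "cell_patch"),
                         n_batches = 3, cells_per_batch = c(6, 8),
                         expression_cv = 0.3, batch_cv = 0.2,
                         leak_g = list(mean = 0.2, cv = 0.3),
                         cap_amp = 0.005, noise_sd = 0.05, seed = 1,
                         ph_condition = c("ph7.3", "ph5.3", "paired")) {
  mode <- match.arg(mode)
  ph_condition <- match.arg(ph_condition)
  if (is.character(constructs)) {
    constructs <- lapply(constructs, function(v) {
      construct_spec(paste0("C3_C4.", v), v)
    })
  }
  if (n_batches < 1) stopf("n_batches must be >= 1")
  if (min(cells_per_batch) < 3) {
    stopf("cells_per_batch must be >= 3 for any group entering statistics")
  }
  structure(
    list(
      constructs = constructs, mode = mode, n_batches = n_batches,
      cells_per_batch = cells_per_batch, expression_cv = expression_cv,
      batch_cv = batch_cv, leak_g = leak_g, cap_amp = cap_amp,
      noise_sd = noise_sd, seed = as.integer(seed),
      ph_condition = ph_condition
    ),
    class = "session_spec"
  )
}

#' Construct (expression condition) description
#'
#' @param label construct label used in metadata and reports.
#' @param variant variant label of protomer B (must exist in the variant
#'   library supplied to the simulator).
#' @param expr_ratio expression ratio partner:variant; `Inf` expresses the
#'   partner alone, `0` the variant alone.
#' @param silent_b if `TRUE` the variant protomer is in the transport-dead
#'   E281A background.
#' @return a list describing the construct.
#' @export
construct_spec <- function(label, variant = "WT", expr_ratio = 1,
                           silent_b = FALSE) {
  list(label = label, variant = variant, expr_ratio = expr_ratio,
       silent_b = silent_b)
}

# Dimer population implied by a construct description.
population_for <- function(cs) {
  if (identical(cs$expr_ratio, 0)) {
    homodimer_b(silent_b = cs$silent_b)
  } else {
    assemble_dimers(cs$expr_ratio, silent_b = cs$silent_b)
  }
}

# -- trace-level simulation ---------------------------------------------------

# One sweep family (samples x steps). transport_uA: steady-state transport
# current per step (0 during holding since the driving force vanishes at 0 mV).
# scale < 1 yields the P/N companion: command voltages (hence leak and
# capacitive components) are scaled, transport is absent.
sweep_family_matrix <- function(protocol, transport, leak_g, cap_amp,
                                noise_sd, scale = 1, with_transport = TRUE) {
  seg <- protocol_segments(protocol)
  hz <- protocol$sampling_hz
  steps <- protocol_voltages(protocol) * scale
  hold <- protocol$holding_mV * scale
  tau_s <- 0.2e-3 # capacitive transient time constant
  n <- seg$n_total
  t <- (seq_len(n) - 1) / hz
  t_on <- seg$n_pre / hz
  t_off <- (seg$n_pre + seg$n_step) / hz

  cur <- matrix(0, n, length(steps))
  in_step <- seq_len(n) > seg$n_pre & seq_len(n) <= seg$n_pre + seg$n_step
  in_post <- seq_len(n) > seg$n_pre + seg$n_step
  for (j in seq_along(steps)) {
    v <- ifelse(in_step, steps[j], hold)
    y <- leak_g * v
    y <- y + cap_amp * (steps[j] - hold) * ifelse(t >= t_on, exp(-(t - t_on) / tau_s), 0) *
      (seq_len(n) > seg$n_pre)
    y <- y + cap_amp * (hold - steps[j]) * ifelse(t >= t_off, exp(-(t - t_off) / tau_s), 0) *
      in_post
    if (with_transport) y <- y + transport[j] * in_step
    cur[, j] <- y
  }
  if (noise_sd > 0) cur <- cur + matrix(stats::rnorm(length(cur), 0, noise_sd), n)
  cur
}

new_sweep_set <- function(time, current, protocol, meta, corrected = FALSE,
                          is_pn = FALSE) {
  structure(
    list(time = time, current = current, protocol = protocol, meta = meta,
         corrected = corrected, is_pn = is_pn),
    class = "sweep_set"
  )
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf(
    "Sweep set: %d samples x %d sweeps (%s, %s%s%s)\n",
    nrow(x$current), ncol(x$current), x$meta$cell_id %||% "?",
    x$meta$units %||% "?", if (x$corrected) ", corrected" else "",
    if (x$is_pn) ", P/N" else ""
  ))
  invisible(x)
}

# Simulate raw + P/N sweep families for one cell.
simulate_cell_sweeps <- function(protocol, gate, pop, variant, expr_factor,
                                 leak_g, cap_amp, noise_sd, meta,
                                 ph = "ph7.3", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  volts <- protocol_voltages(protocol)
  transport <- model_iv(gate, pop, variant, volts, ph = ph) * expr_factor
  seg <- protocol_segments(protocol)
  t <- (seq_len(seg$n_total) - 1) / protocol$sampling_hz

  raw <- sweep_family_matrix(protocol, transport, leak_g, cap_amp, noise_sd)
  pn <- sweep_family_matrix(protocol, transport, leak_g, cap_amp, noise_sd,
                            scale = protocol$pn_scale, with_transport = FALSE)
  meta$ph <- ph
  list(
    raw = new_sweep_set(t, raw, protocol, meta),
    pn = new_sweep_set(t, pn, protocol, meta, is_pn = TRUE)
  )
}

#' Simulate a full voltage-clamp session
#'
#' Generates, for every construct x batch x cell, a raw sweep family (steady
#' transport x lognormal cell and batch expression factors + ohmic leak +
#' capacitive step transients + Gaussian noise) and the companion P/N family
#' acquired with the scaled-down protocol (leak and capacitive components
#' only, scaled by `pn_scale`, with its own noise). Fully determined by
#' `spec$seed`: the same spec yields byte-identical files.
#'
#' @param spec a [session_spec()].
#' @param gate a [gate_model()].
#' @param variants named list of [variant_params()], e.g. [variant_library()].
#' @param protocol a [voltage_protocol()].
#' @param out_dir if non-`NULL`, sweep CSVs and a JSON manifest are written
#'   there (created if needed).
#' @return invisibly, a list with `cells` (per-cell lists with elements `raw`,
#'   `pn`, and for paired sessions `raw_ph5.3`, `pn_ph5.3`) and `manifest`
#'   (data frame: file, construct, batch, ph, mode).
#' @export
simulate_session <- function(spec, gate = gate_model(),
                             variants = variant_library(),
                             protocol = voltage_protocol(), out_dir = NULL) {
  stopifnot(inherits(spec, "session_spec"))
  units <- if (spec$mode == "oocyte_tevc") "uA" else "pA"
  batch_f <- vapply(seq_len(spec$n_batches), function(b) {
    with_seed(child_seed(spec$seed, 7001L, b),
              stats::rlnorm(1, -spec$batch_cv^2 / 2, spec$batch_cv))
  }, numeric(1))

  cells <- list()
  man <- list()
  phs <- if (spec$ph_condition == "paired") c("ph7.3", "ph5.3") else spec$ph_condition

  for (ci in seq_along(spec$constructs)) {
    cs <- spec$constructs[[ci]]
    variant <- variants[[cs$variant]]
    if (is.null(variant)) stopf("unknown variant '%s'", cs$variant)
    pop <- population_for(cs)
    for (b in seq_len(spec$n_batches)) {
      n_cells <- if (length(spec$cells_per_batch) > 1) {
        with_seed(child_seed(spec$seed, 7107L, ci, b),
                  sample(seq(min(spec$cells_per_batch), max(spec$cells_per_batch)), 1))
      } else {
        spec$cells_per_batch
      }
      for (k in seq_len(n_cells)) {
        cell_id <- sprintf("%s_b%d_c%02d", cs$label, b, k)
        draws <- with_seed(child_seed(spec$seed, 7211L, ci, b, k), list(
          e = stats::rlnorm(1, -spec$expression_cv^2 / 2, spec$expression_cv),
          g = stats::rlnorm(1, log(spec$leak_g$mean) - spec$leak_g$cv^2 / 2,
                            spec$leak_g$cv)
        ))
        meta <- list(cell_id = cell_id, construct = cs$label, batch = b,
                     mode = spec$mode, units = units,
                     pn_scale = protocol$pn_scale,
                     sampling_hz = protocol$sampling_hz)
        rec <- list()
        for (pi in seq_along(phs)) {
          fam <- simulate_cell_sweeps(
            protocol, gate, pop, variant, draws$e * batch_f[b], draws$g,
            spec$cap_amp, spec$noise_sd, meta, ph = phs[pi],
            seed = child_seed(spec$seed, 7309L, ci, b, k, pi)
          )
          nm <- if (pi == 1) c("raw", "pn") else paste0(c("raw", "pn"), "_", phs[pi])
          rec[nm] <- fam
        }
        rec$expr_factor <- draws$e * batch_f[b]
        rec$leak_g <- draws$g
        cells[[cell_id]] <- rec

        for (pi in seq_along(phs)) {
          fname <- if (length(phs) > 1) {
            sprintf("%s_%s.csv", cell_id, gsub("\\.", "", phs[pi]))
          } else {
            sprintf("%s.csv", cell_id)
          }
          man[[length(man) + 1]] <- data.frame(
            file = fname, construct = cs$label, batch = b, ph = phs[pi],
            mode = spec$mode, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  manifest <- do.call(rbind, man)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stopf("cannot create output directory '%s'", out_dir)
    for (i in seq_len(nrow(manifest))) {
      cell <- cells[[sub("(_ph[0-9]+)?\\.csv$", "", manifest$file[i])]]
      raw_nm <- if (length(phs) == 1 || manifest$ph[i] == phs[1]) "raw" else
        paste0("raw_", manifest$ph[i])
      pn_nm <- sub("^raw", "pn", raw_nm)
      stem <- sub("\\.csv$", "", manifest$file[i])
      write_sweep_csv(cell[[raw_nm]], file.path(out_dir, manifest$file[i]),
                      ph = manifest$ph[i])
      write_sweep_csv(cell[[pn_nm]], file.path(out_dir, paste0(stem, "_pn.csv")),
                      ph = manifest$ph[i])
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(list(cells = cells, manifest = manifest))
}

# -- IV-level simulation ------------------------------------------------------

#' Steady-state noise SD implied by the trace pipeline
#'
#' The SD of a steady-state estimate obtained by averaging the last third of
#' the step segment, for raw traces (`corrected = FALSE`) or after P/N
#' subtraction (which adds the P/N sweep noise scaled by `1/pn_scale`).
#'
#' @param noise_sd per-sample current noise SD.
#' @param protocol a [voltage_protocol()].
#' @param corrected whether the estimate follows P/N subtraction.
#' @return scalar SD in current units.
#' @export
ss_noise_sd <- function(noise_sd, protocol = voltage_protocol(),
                        corrected = TRUE) {
  seg <- protocol_segments(protocol)
  n_avg <- seg$n_step - floor(2 * seg$n_step / 3)
  amp <- if (corrected) sqrt(1 + 1 / protocol$pn_scale^2) else 1
  amp * noise_sd / sqrt(n_avg)
}

#' Simulate a study at the steady-state (IV) level
#'
#' Draws per-cell steady-state current-voltage relationships directly from the
#' biophysical model with the same statistical structure as the trace-level
#' pipeline: current = model x lognormal cell expression x lognormal batch
#' factor (+ ohmic leak for `pipeline = "raw"`) + Gaussian noise with the
#' SD the trace pipeline would produce ([ss_noise_sd()]). Used for
#' replicate-heavy power and calibration studies where re-simulating full
#' sweep families adds runtime but no information; the equivalence of the two
#' routes is established by round-trip tests of the trace pipeline.
#'
#' @inheritParams simulate_session
#' @param voltages voltage grid, mV (default: the protocol ladder).
#' @param pipeline `"pn_corrected"` (leak-free corrected currents) or `"raw"`
#'   (ohmic leak retained, no P/N noise amplification).
#' @return named list (by construct label) of [iv_curve] objects; for paired
#'   sessions each element is a list with `ph7.3` and `ph5.3` curves.
#' @export
simulate_iv_study <- function(spec, gate = gate_model(),
                              variants = variant_library(),
                              protocol = voltage_protocol(),
                              voltages = protocol_voltages(protocol),
                              pipeline = c("pn_corrected", "raw")) {
  stopifnot(inherits(spec, "session_spec"))
  pipeline <- match.arg(pipeline)
  units <- if (spec$mode == "oocyte_tevc") "uA" else "pA"
  sd_ss <- ss_noise_sd(spec$noise_sd, protocol,
                       corrected = pipeline == "pn_corrected")
  batch_f <- vapply(seq_len(spec$n_batches), function(b) {
    with_seed(child_seed(spec$seed, 7001L, b),
              stats::rlnorm(1, -spec$batch_cv^2 / 2, spec$batch_cv))
  }, numeric(1))
  phs <- if (spec$ph_condition == "paired") c("ph7.3", "ph5.3") else spec$ph_condition

  out <- list()
  for (ci in seq_along(spec$constructs)) {
    cs <- spec$constructs[[ci]]
    variant <- variants[[cs$variant]]
    if (is.null(variant)) stopf("unknown variant '%s'", cs$variant)
    pop <- population_for(cs)
    model <- lapply(phs, function(p) model_iv(gate, pop, variant, voltages, ph = p))
    vals <- stats::setNames(lapply(phs, function(p) NULL), phs)
    meta <- NULL
    for (b in seq_len(spec$n_batches)) {
      n_cells <- if (length(spec$cells_per_batch) > 1) {
        with_seed(child_seed(spec$seed, 7107L, ci, b),
                  sample(seq(min(spec$cells_per_batch), max(spec$cells_per_batch)), 1))
      } else {
        spec$cells_per_batch
      }
      for (k in seq_len(n_cells)) {
        draws <- with_seed(child_seed(spec$seed, 7211L, ci, b, k), list(
          e = stats::rlnorm(1, -spec$expression_cv^2 / 2, spec$expression_cv),
          g = stats::rlnorm(1, log(spec$leak_g$mean) - spec$leak_g$cv^2 / 2,
                            spec$leak_g$cv)
        ))
        for (pi in seq_along(phs)) {
          y <- model[[pi]] * draws$e * batch_f[b]
          if (pipeline == "raw") y <- y + draws$g * voltages
          y <- y + with_seed(child_seed(spec$seed, 7409L, ci, b, k, pi),
                             stats::rnorm(length(voltages), 0, sd_ss))
          vals[[pi]] <- cbind(vals[[pi]], y)
        }
        meta <- rbind(meta, data.frame(
          cell_id = sprintf("%s_b%d_c%02d", cs$label, b, k), batch = b,
          stringsAsFactors = FALSE
        ))
      }
    }
    curves <- lapply(seq_along(phs), function(pi) {
      m <- vals[[pi]]
      colnames(m) <- meta$cell_id
      new_iv_curve(voltages, m, meta, units = units, construct = cs$label,
                   ph = phs[pi], se_ss = sd_ss,
                   corrected = pipeline == "pn_corrected")
    })
    out[[cs$label]] <- if (length(phs) == 1) curves[[1]] else
      stats::setNames(curves, phs)
  }
  out
}
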