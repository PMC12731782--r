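# Shared fixtures. Trace-level tests use a reduced sampling rate so sweep
# matrices stay small; the segment structure (5 ms steps, last-third
# averaging) is unchanged.

quick_protocol <- function(...) {
  voltage_protocol(sampling_hz = 20000, ...)
}

test_gate <- function(...) gate_model(...)

wt_pop <- function() assemble_dimers(1)

# noise-free single-cell session spec
clean_spec <- function(constructs = list(construct_spec("C3_C4.WT", "WT")),
                       leak_mean = 0.2, ...) {
  session_spec(
    constructs = constructs, n_batches = 1, cells_per_batch = 3,
    expression_cv = 0, batch_cv = 0, leak_g = list(mean = leak_mean, cv = 0),
    noise_sd = 0, seed = 7, ...
  )
}

# IV curve built directly from a per-cell value matrix
manual_iv <- function(voltages, values, batch = rep(1, ncol(values)),
                      construct = "X", se_ss = 0, units = "uA", ph = "ph7.3") {
  values <- as.matrix(values)
  cells <- data.frame(
    cell_id = sprintf("%s_c%02d", construct, seq_len(ncol(values))),
    batch = batch, stringsAsFactors = FALSE
  )
  colnames(values) <- cells$cell_id
  clchet:::new_iv_curve(voltages, values, cells, units = units,
                        construct = construct, ph = ph, se_ss = se_ss)
}

# analytic phasor coordinates of a monoexponential decay
phasor_closed_form <- function(tau_ns, rep_rate_mhz = 80) {
  w <- 2 * pi * rep_rate_mhz * 1e-3
  c(G = 1 / (1 + (w * tau_ns)^2), S = w * tau_ns / (1 + (w * tau_ns)^2))
}

# in-memory noise-free decay stack of one pixel
mono_stack <- function(tau_ns, n_bins = 4096, rep_rate_mhz = 80,
                       photons = 1) {
  p <- decay_profile(tau_ns, rep_rate_mhz, n_bins)
  clchet:::new_decay_stack(array(photons * p, c(1, 1, n_bins)), rep_rate_mhz)
}
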