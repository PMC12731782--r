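#' Step voltage-clamp protocol description
#'
#' The standard stimulus used throughout: from a holding potential of 0 mV,
#' 5 ms steps are applied from +200 mV down to -40 mV in -10 mV increments,
#' sampled at 100 kHz. Leak/capacitance correction sweeps use the same shape
#' scaled by `pn_scale` (P/N protocol).
#'
#' @param holding_mV holding potential, mV.
#' @param step_start_mV first (most positive) step voltage, mV.
#' @param step_delta_mV step increment, mV (negative for a descending ladder).
#' @param step_end_mV last step voltage, mV.
#' @param step_duration_ms duration of the test step segment, ms.
#' @param pre_ms,post_ms durations of the holding segments before and after the
#'   step, ms.
#' @param sampling_hz sampling rate, Hz.
#' @param pn_scale scale factor of the P/N correction protocol, in (0, 1).
#' @return an object of class `voltage_protocol`.
#' @export
#' @examples
#' p <- voltage_protocol()
#' protocol_voltages(p)[1:3]
voltage_protocol <- function(holding_mV = 0, step_start_mV = 200,
                             step_delta_mV = -10, step_end_mV = -40,
                             step_duration_ms = 5, pre_ms = 2, post_ms = 2,
                             sampling_hz = 100000, pn_scale = 0.2) {
  if (step_delta_mV == 0) stopf("step_delta_mV must be nonzero")
  span <- step_start_mV - step_end_mV
  if (abs(span %% abs(step_delta_mV)) > 1e-9) {
    stopf("(step_start - step_end) must be divisible by |step_delta|")
  }
  if (pn_scale <= 0 || pn_scale >= 1) stopf("pn_scale must lie in (0, 1)")
  if (sampling_hz <= 0) stopf("sampling_hz must be positive")
  structure(
    list(
      holding_mV = holding_mV, step_start_mV = step_start_mV,
      step_delta_mV = step_delta_mV, step_end_mV = step_end_mV,
      step_duration_ms = step_duration_ms, pre_ms = pre_ms, post_ms = post_ms,
      sampling_hz = sampling_hz, pn_scale = pn_scale
    ),
    class = "voltage_protocol"
  )
}

#' Step voltages of a protocol
#' @param protocol a [voltage_protocol()].
#' @return numeric vector of step voltages, mV, in acquisition order.
#' @export
protocol_voltages <- function(protocol) {
  seq(protocol$step_start_mV, protocol$step_end_mV, by = protocol$step_delta_mV)
}

# Sample counts and index ranges of the pre/step/post segments.
protocol_segments <- function(protocol) {
  hz <- protocol$sampling_hz
  n_pre <- round(protocol$pre_ms * 1e-3 * hz)
  n_step <- round(protocol$step_duration_ms * 1e-3 * hz)
  n_post <- round(protocol$post_ms * 1e-3 * hz)
  list(
    n_pre = n_pre, n_step = n_step, n_post = n_post,
    n_total = n_pre + n_step + n_post,
    step_idx = n_pre + seq_len(n_step)
  )
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf(
    "Voltage protocol: hold %g mV; steps %g..%g mV by %g mV (%d sweeps);\n  %g ms steps, %g kHz sampling, P/N scale %g\n",
    x$holding_mV, x$step_start_mV, x$step_end_mV, x$step_delta_mV,
    length(protocol_voltages(x)), x$step_duration_ms, x$sampling_hz / 1000,
    x$pn_scale
  ))
  invisible(x)
}
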