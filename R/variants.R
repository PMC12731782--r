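#' Boltzmann activation function
#'
#' Open probability of the common gate, `1 / (1 + exp(-(V - v_half) / k))`.
#' The common gate of CLC exchangers activates with depolarization and
#' saturates at large positive voltages; a Boltzmann is the minimal form with
#' that behaviour.
#'
#' @param v voltage(s), mV.
#' @param v_half half-activation voltage, mV.
#' @param k slope factor, mV (> 0).
#' @return open probability in (0, 1).
#' @export
boltzmann_p <- function(v, v_half, k) {
  if (k <= 0) stopf("slope factor k must be positive")
  1 / (1 + exp(-(v - v_half) / k))
}

#' Common-gate model of a CLC transporter dimer
#'
#' @param v_half half-activation voltage of the common gate, mV.
#' @param slope_k Boltzmann slope factor, mV (> 0).
#' @param i_unit transport current per protomer per unit expression at the
#'   reference driving force of 100 mV with the gate fully open (recording
#'   units: microamps for oocyte TEVC, picoamps for whole-cell patch).
#' @param v_rev reversal potential of the transport component, mV.
#' @return an object of class `gate_model`.
#' @export
gate_model <- function(v_half = 120, slope_k = 15, i_unit = 1.5, v_rev = 0) {
  if (slope_k <= 0) stopf("slope_k must be positive")
  structure(
    list(v_half = v_half, slope_k = slope_k, i_unit = i_unit, v_rev = v_rev),
    class = "gate_model"
  )
}

#' Biophysical parameterization of a CLCN4 variant
#'
#' @param label short variant name.
#' @param dv_half shift of the common-gate half-activation voltage, mV.
#' @param amp_factor per-protomer transport amplitude scale (0 = transport-dead).
#' @param gof_inward_g inward conductance appearing at acidic pH in
#'   gain-of-function heteromers, uS per unit expression (0 for non-GoF).
#' @param dominant whether `dv_half` applies to heterodimers carrying a single
#'   variant protomer (dominant action on the shared gate).
#' @return an object of class `variant_params`.
#' @export
variant_params <- function(label, dv_half = 0, amp_factor = 1,
                           gof_inward_g = 0, dominant = FALSE) {
  if (amp_factor < 0) stopf("amp_factor must be >= 0")
  if (gof_inward_g < 0) stopf("gof_inward_g must be >= 0")
  structure(
    list(
      label = label, dv_half = dv_half, amp_factor = amp_factor,
      gof_inward_g = gof_inward_g, dominant = dominant
    ),
    class = "variant_params"
  )
}

#' Library of the studied CLCN4 variants
#'
#' Qualitative signs follow the experimental phenotypes: the wild type is the
#' reference; R360S is transport-dead as a homodimer but carries a small
#' dominant gating shift and an acidic-pH inward (gain-of-function)
#' conductance in heteromers; V536M, G545S and K560E shift activation to more
#' positive voltages with graded strength (K560E > G545S > V536M). The shift
#' magnitudes are configurable model defaults, not measured values.
#'
#' @return named list of [variant_params()] for WT, R360S, V536M, G545S, K560E.
#' @export
#' @examples
#' variant_library()$K560E$dv_half
variant_library <- function() {
  list(
    WT    = variant_params("WT", dv_half = 0, amp_factor = 1),
    R360S = variant_params("R360S", dv_half = 5, amp_factor = 0,
                           gof_inward_g = 0.02, dominant = TRUE),
    V536M = variant_params("V536M", dv_half = 30, dominant = TRUE),
    G545S = variant_params("G545S", dv_half = 45, dominant = TRUE),
    K560E = variant_params("K560E", dv_half = 75, dominant = TRUE)
  )
}

#' Dimer population from independent co-expression
#'
#' Under independent (binomial) pairing of protomers A and B expressed at
#' ratio `expr_ratio_ab`, the fractions of A-homodimers, A/B heterodimers and
#' B-homodimers are a^2, 2ab, b^2 with a = r/(1+r), b = 1/(1+r).
#'
#' @param expr_ratio_ab expression ratio A:B (> 0; `Inf` gives pure A).
#' @param silent_b if `TRUE`, protomer B is transport-dead (E281A background);
#'   this changes transport-competence flags only, never the fractions.
#' @return an object of class `dimer_population` with fields `frac_aa`,
#'   `frac_ab`, `frac_bb`, `transport_a`, `transport_b`.
#' @export
#' @examples
#' assemble_dimers(1)  # 1:2:1
assemble_dimers <- function(expr_ratio_ab = 1, silent_b = FALSE) {
  if (!is.numeric(expr_ratio_ab) || is.na(expr_ratio_ab) || expr_ratio_ab <= 0) {
    stopf("expr_ratio_ab must be a positive number")
  }
  if (is.infinite(expr_ratio_ab)) {
    a <- 1
    b <- 0
  } else {
    a <- expr_ratio_ab / (1 + expr_ratio_ab)
    b <- 1 / (1 + expr_ratio_ab)
  }
  pop <- structure(
    list(
      frac_aa = a^2, frac_ab = 2 * a * b, frac_bb = b^2,
      transport_a = TRUE, transport_b = !silent_b
    ),
    class = "dimer_population"
  )
  stopifnot(abs(pop$frac_aa + pop$frac_ab + pop$frac_bb - 1) < 1e-12)
  pop
}

#' Homodimer-only population of protomer B
#'
#' Convenience for assays of a variant expressed alone.
#' @param silent_b see [assemble_dimers()].
#' @return a `dimer_population` with `frac_bb = 1`.
#' @export
homodimer_b <- function(silent_b = FALSE) {
  pop <- assemble_dimers(1, silent_b = silent_b)
  pop$frac_aa <- 0
  pop$frac_ab <- 0
  pop$frac_bb <- 1
  pop
}

#' Noise-free steady-state current of a dimer mixture
#'
#' The quasi-steady-state transport current per unit expression:
#' `I(V) = sum_dimer frac * amp * i_unit * p(V; v_half_dimer, k) * d(V)` with
#' `p` the Boltzmann activation of the shared common gate, driving force
#' `d(V) = (V - v_rev) / 100` (so `i_unit` is the open-gate per-protomer
#' current at +100 mV relative to reversal), and `amp` the summed amplitude of
#' the transport-competent protomers in the dimer. Dimers containing a
#' dominant variant protomer have their common-gate `v_half` shifted by the
#' full `dv_half`; variant homodimers are always shifted. At acidic pH
#' (`ph = "ph5.3"`), gain-of-function heteromers additionally carry an inward
#' conductance `-gof_inward_g * max(0, -(V - gof_v_rev))`.
#'
#' @param gate a [gate_model()].
#' @param pop a [dimer_population()] (protomer A = partner, B = variant).
#' @param variant a [variant_params()] for protomer B.
#' @param voltages voltages, mV (|V| <= 250).
#' @param ph condition label, `"ph7.3"` (default) or `"ph5.3"`.
#' @param variant_a optional [variant_params()] for protomer A (defaults to a
#'   wild-type-like reference protomer).
#' @param gof_v_rev reversal potential of the acidic-pH inward component, mV.
#' @return numeric vector of currents per unit expression (leak- and
#'   noise-free), same units as `i_unit`.
#' @export
model_iv <- function(gate, pop, variant, voltages, ph = "ph7.3",
                     variant_a = variant_params("REF"), gof_v_rev = -20) {
  stopifnot(inherits(gate, "gate_model"), inherits(pop, "dimer_population"),
            inherits(variant, "variant_params"))
  if (any(abs(voltages) > 250)) stopf("voltages must be within +/-250 mV")
  ph <- match.arg(ph, c("ph7.3", "ph5.3"))

  amp_a <- variant_a$amp_factor * pop$transport_a
  amp_b <- variant$amp_factor * pop$transport_b
  d <- (voltages - gate$v_rev) / 100

  vh_aa <- gate$v_half + if (isTRUE(variant_a$dominant)) variant_a$dv_half else 0
  vh_bb <- gate$v_half + variant$dv_half
  vh_ab <- gate$v_half +
    (if (isTRUE(variant$dominant)) variant$dv_half else 0) +
    (if (isTRUE(variant_a$dominant)) variant_a$dv_half else 0)

  i <- gate$i_unit * d * (
    pop$frac_aa * 2 * amp_a * boltzmann_p(voltages, vh_aa, gate$slope_k) +
    pop$frac_ab * (amp_a + amp_b) * boltzmann_p(voltages, vh_ab, gate$slope_k) +
    pop$frac_bb * 2 * amp_b * boltzmann_p(voltages, vh_bb, gate$slope_k)
  )

  if (ph == "ph5.3" && variant$gof_inward_g > 0) {
    i <- i - pop$frac_ab * variant$gof_inward_g * pmax(0, -(voltages - gof_v_rev))
  }
  i
}
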