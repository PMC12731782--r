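---
title: "Detecting dominant CLCN4 variant effects in ClC-3/ClC-4 heteromers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting dominant CLCN4 variant effects in ClC-3/ClC-4 heteromers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clchet)
```

# The scientific problem

ClC-3 and ClC-4 are endosomal 2Cl&#8722;/H&#43; exchangers. ClC-4 functions
physiologically in heterodimers with ClC-3, and several disease-associated
*CLCN4* missense variants that look like simple loss of function in ClC-4
homodimers produce unexpectedly severe, dominant phenotypes. The analysis
this package implements asks the quantitative question behind that
observation: **does a variant protomer alter the behaviour of a heterodimer
containing one wild-type protomer?**

The experimental readouts are voltage-clamp current recordings (two-electrode
voltage clamp in *Xenopus* oocytes; whole-cell patch clamp in transfected
cells), and phasor FLIM-FRET imaging used to confirm that the two tagged
subunits actually form complexes. Every stage of the computational chain —
trace processing, normalization, classification, the acidic-pH assay, phasor
analysis, statistics — is implemented and validated here against a synthetic
data generator that emulates the recordings.

# The biophysical model behind the simulator

CLC dimers carry two independent transport pathways controlled by a shared
("common") gate that activates with depolarization and saturates at large
positive voltages. The simulator uses the minimal quasi-steady-state form
with that behaviour:

$$I(V) \;=\; \sum_{\text{dimer}} f_{\text{dimer}} \; a_{\text{dimer}} \;
i_u \; p(V;\,V_{1/2}^{\text{dimer}},\,k) \; \frac{V - V_{rev}}{100\,\mathrm{mV}}$$

* $p(V) = 1/(1+e^{-(V-V_{1/2})/k})$ — Boltzmann activation of the common
  gate. A Boltzmann is the simplest saturating activation and mirrors the
  treatment of common-gate shifts in the muscle channel ClC-1, the classic
  precedent for dominant gating mutations in CLC proteins.
* $f_{\text{dimer}}$ — fractions of A-homodimer / heterodimer / B-homodimer.
  Co-expression at ratio $r$ assembles independently (binomially):
  $a^2 : 2ab : b^2$ with $a = r/(1+r)$. No assembly bias is assumed.
* $a_{\text{dimer}}$ — summed amplitude of the transport-competent
  protomers (each contributes `amp_factor`; an E281A-silenced protomer
  contributes 0 while still occupying its position in the dimer).
* Driving force $(V - V_{rev})/100$ — transport current vanishes at the
  reversal potential (0 mV by default, consistent with leak-corrected traces
  showing negligible current at the holding potential), so $i_u$ is the
  open-gate per-protomer current at +100 mV of driving force.
* **Dominance**: a dominant variant shifts the common-gate $V_{1/2}$ of any
  dimer that contains at least one variant protomer by its full
  `dv_half`. This is the simplest encoding of a dominant-negative action on
  a shared gate; half-shifts or occupancy-weighted shifts would only rescale
  the `dv_half` values.
* **Acidic pH**: gain-of-function heteromers acquire an inward conductance
  $-g_{GoF}\max(0, -(V - V_{rev,GoF}))$ at pH 5.3 ($V_{rev,GoF} = -20$ mV).
  pH enters only as a condition label; no transport-cycle pH dependence is
  modelled.

No kinetics are modelled: each voltage step carries its steady-state
transport current (the trace-level simulator adds capacitive transients and
leak separately). Time-resolved gating relaxations and the nonlinear
"gating-glutamate" capacitive currents are out of scope.

## Generator defaults and why

| parameter | default | rationale |
|---|---|---|
| gate $V_{1/2}$ | +120 mV | strong outward rectification: sizeable currents only above ~+60 mV, as in oocyte recordings of these transporters |
| gate slope $k$ | 15 mV | effective gating valence ≈ 1.7 e, within the range reported for CLC common gating; chosen once by a prospective power analysis so the graded silenced-subunit phenotype is resolvable at the study's sample sizes |
| $i_u$ | 1.5 µA | WT co-expression currents of ~5–6 µA at +200 mV, a typical healthy oocyte expression level |
| ΔV½: R360S / V536M / G545S / K560E | +5 / +30 / +45 / +75 mV | qualitative ordering from the homodimer and silenced-subunit phenotypes (K560E strongest, G545S > V536M, R360S smallest); magnitudes are model calibrations, not measured values, sized so the graded reduction is clearly separated at n = 3 batches × 6–8 cells (dominant ClC-1 mutations shift common gating by +50…+90 mV, so the upper values are realistic) |
| R360S `amp_factor` | 0 | complete loss of function as a homodimer |
| R360S `gof_inward_g` | 0.02 µS | a "small but significant" inward component at acidic pH, detectable at n = 9 vs 13 |
| cell expression CV | 0.3 (lognormal σ) | typical oocyte-to-oocyte injection/expression scatter |
| batch factor CV | 0.2 (lognormal σ) | batches (frogs) vary strongly; this is exactly why the analysis normalizes within batch |
| leak conductance | lognormal, mean 0.2 µS, CV 0.3 | ordinary oocyte leak |
| capacitive transient | amplitude ∝ ΔV, τ = 0.2 ms | a linear membrane-charging transient; present scaled in the P/N sweeps so subtraction removes it exactly |
| noise SD | 0.05 µA per sample | TEVC current noise at 10 kHz bandwidth |
| protocol | hold 0 mV; 5 ms steps +200…−40 mV in −10 mV; 100 kHz; P/N scale 0.2 | the study's stimulus; the acidic-pH sessions extend the ladder to −120 mV |

Expression factors are lognormal with unit mean (µ = −σ²/2), so group means
converge to the batch factor; batch factors multiply all constructs measured
in the same batch, which is what makes within-batch normalization effective.
All randomness derives from one user seed expanded per cell/pixel through a
counter-based mixing scheme, so outputs are byte-stable and independent of
generation order.

# Trace processing

Raw sweeps are corrected by P/N subtraction: a companion family recorded
with the 0.2×-scaled protocol contains the leak and capacitive components at
0.2 amplitude, and `corrected = raw − pn / 0.2` removes every component
linear in the command voltage exactly. Steady-state current is the mean over
the **last third** of the step segment; with a segment of $L$ samples the
window is the 0-based index range $[\lfloor 2L/3 \rfloor, L)$ (floor
division — the convention matters only at non-multiple-of-3 lengths and is
fixed here once). Subtraction quintuples the P/N sweep noise
(variance $1 + 1/0.2^2$), which the steady-state averaging then reduces by
the window length; `ss_noise_sd()` exposes this propagation and the IV-level
generator uses it.

# Ratio normalization and phenotype classification

For each batch and voltage the variant group's mean current is divided by
the matched wild-type reference group's mean current from the *same batch*
(pairing is by batch identifier, never by file order). Interpretation:
a flat ratio of 1 is wild-type-like; a flat ratio below 1 is a uniform
amplitude reduction; a ratio rising with voltage indicates a depolarizing
shift of activation (the reduction is overcome at strong depolarization);
a falling ratio indicates gain of function at less positive voltages.

Voltages where any batch's reference mean is below 5× the estimated
steady-state noise SD (or below 10⁻⁹ in magnitude, the guard for noise-free
data) are masked — reference currents that small make the ratio meaningless.

`classify_ratio()` fits a weighted least-squares line to the pooled ratio
(weights: inverse variance across batches per voltage) and tests the slope
against **two error models**: a t interval on per-batch slope replicates,
and the pooled regression interval. Ratio errors are almost perfectly
correlated across voltages within a batch — a cell's expression level
multiplies its entire curve — so pooled residuals alone understate slope
uncertainty, while three batch replicates alone are thin (df = 2). A slope
is therefore flagged only when both intervals exclude zero, and the reported
confidence interval is their union. The ordered rules are: (1) ratio at the
three most positive voltages below 0.3 → `below_reference_control`;
(2) slope CI excluding 0 → `positive_shift` or `negative_slope_gof` by sign;
(3) mean ratio below 0.8 with slope CI containing 0 → `uniform_reduction`;
(4) otherwise `wt_like`. All thresholds are arguments with these defaults.

The ratio curve also carries a delta-method standard error of the pooled
ratio computed from within-batch cell scatter; it estimates the same
sampling variance as the SD across batches but with far more stable degrees
of freedom, and it is what the acceptance checks compare against.

In the **silenced-subunit assay**, a transport-dead (E281A) variant protomer
is co-expressed with the wild-type partner, so all current is carried by
partner protomers and any current reduction reflects the variant's action on
the shared gate. Currents at +170 mV are normalized to the within-batch mean
of the E281A-wild-type reference cells; group means of the three variants
reproduce the graded reduction (K560E < G545S < R360S).

# Acidic-pH gain-of-function assay

For each cell, the pH 7.3 IV is fitted with an ordinary least-squares line
over −120…0 mV (at neutral pH, currents at non-positive voltages are taken
to be leak), the line is extrapolated to all voltages and subtracted from
both conditions, and currents are normalized to the cell's pH 7.3 value at
+160 mV. The denominator uses the leak-subtracted value — the wording "the
current at pH 7.3, 160 mV" is ambiguous between raw and subtracted, and the
subtracted form makes the pipeline exactly invariant to per-cell expression
scaling (`subtract_denominator = FALSE` gives the raw alternative).
Group comparison (`compare_inward`) applies Welch's t-test per voltage for
V ≤ +20 mV with significance stars and **no multiplicity correction**,
mirroring per-voltage annotation practice; this is deliberately liberal and
documented as such.

# Phasor FLIM-FRET

Per-pixel decay histograms are transformed to first-harmonic phasor
coordinates at the 80 MHz pulse frequency,
$G = \sum_k c_k\cos(\omega t_k)/\sum_k c_k$,
$S = \sum_k c_k\sin(\omega t_k)/\sum_k c_k$, with bin-center times $t_k$ and
no instrument-response deconvolution (the approach is fit-free and the
simulator generates no IRF). Monoexponential decays satisfy
$G = 1/(1+(\omega\tau)^2)$, $S = \omega\tau/(1+(\omega\tau)^2)$ — the
universal semicircle — and the lifetime follows $\tau = S/(2\pi f G)$.
The simulator wraps the exponential tail across the 12.5 ns period (the
steady state under pulsed excitation) and integrates it exactly over each
bin, so the analytic phasor holds at finite period up to the bin-center
discretization of the transform, which is O((T/n)²) ≈ 10⁻⁷ at 4096 bins.

The predominant pixel cluster is located on a 2D histogram of (G, S) at bin
width 0.005; a 2D Gaussian is fitted by least squares within ±5 moment-
estimated sigmas of the mode, falling back (flagged) to the photon-weighted
centroid if the fit fails; pixels need ≥ 20 photons to enter. These are
declared defaults — the binning of the original acquisition software is not
public — and all are arguments. FRET efficiency is $E = 1 - \tau_{DA}/\tau_D$
with the donor-only lifetime determined per session; negative efficiencies
(lifetime lengthening) are returned but flagged.

# Statistical layer

* **Ratio t-test** (`ratio_t_test`): normalized currents are ratio-scaled
  and positive, so the unpaired test runs on natural logs — the standard
  meaning of a "ratio t-test", in unpaired form because variant and control
  come from different batches. Welch's unequal-variance form is the default
  (a pooled-variance flag exists); a raw-scale flag supports sensitivity
  analysis. Zero-variance degenerate groups raise errors rather than
  returning p = 0.
* **ANOVA + Tukey** (`anova_tukey`, `anova_tukey_iv`): absolute quantities
  (current densities) use one-way ANOVA with Tukey's HSD against a
  designated reference, applied per voltage for V ≥ +30 mV — below that the
  currents are too small to compare meaningfully.
* **Stars** (`stars`): strict thresholds — none for p ≥ 0.05, `*` < 0.05,
  `**` < 0.01, `***` < 0.001.

# Numerical choices and degenerate inputs

* Last-third window: floor division, documented above.
* Slope "CI excludes zero" uses a 10⁻¹⁰ tolerance so exactly-flat noise-free
  ratios never trigger a sign by floating-point accident.
* Masked voltages propagate as removed values, never NaN; an all-masked
  curve, a batch without reference cells, a non-positive normalization
  denominator, zero/negative capacitance, and a missing P/N companion are
  hard errors.
* All-zero FLIM pixels are dropped at the photon floor, not NaN-propagated;
  a zero photon budget produces an all-zero stack flagged `empty`.
* 16-bit TIFF output clips counts at 65535 (unreachable at the default
  photon budgets).

# What the simulations do and do not establish

The generator reproduces the statistical structure the analysis relies on:
multiplicative cell- and batch-level expression variability, ohmic leak plus
linear capacitive contamination removed by P/N subtraction, steady-state
noise propagation, Poisson photon statistics on wrapped monoexponential
decays. Passing tests therefore demonstrate that the chain recovers known
ground truth under those assumptions. Real recordings contain features the
generator deliberately omits — band-limited (correlated) noise, series
resistance and liquid-junction errors, endogenous oocyte conductances,
rundown, ClC-4's intrinsically weaker voltage dependence relative to ClC-3,
instrument response and background in FLIM, multi-exponential donor decays —
so green tests do not certify performance on real data in those regimes.
Replicate-heavy calibration studies (phenotype recovery rates, detection
power, type-I error) draw cells at the steady-state level with the
trace-derived noise SD rather than re-simulating full sweep families; the
equivalence of the two routes is itself a test on noise-free sessions, and
the study sizes used by the test suite (3 batches × 6–8 cells, 100–200
replicates, 10⁴ t-test repetitions, 16×16–32×32-pixel images) were chosen as
the smallest sizes at which the checked properties are stable.

# Known limitations

* The phenotype classifier is a rule set over a line fit; it reports a
  decision trace but no posterior uncertainty over labels.
* Dominance is encoded as a full common-gate shift; intermediate dominance
  models are representable only through `dv_half` rescaling.
* The acidic-pH assay assumes the leak line estimated at pH 7.3 remains
  valid at pH 5.3.
* Batch structure is exchangeable (no frog-level covariates); mixed-effects
  modelling of batches is intentionally out of scope.
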