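#!/usr/bin/env Rscript
# Step 1: generate the synthetic raw data.
#
# Writes a demonstration TEVC session (sweep CSVs + P/N companions + JSON
# manifest) for wild-type co-expression and the two clearest variant
# phenotypes, plus a two-region FLIM decay stack (TIFF + sidecar). The
# replicate-heavy studies of steps 3-4 draw their cells at the steady-state
# level directly inside those scripts; this session exercises the full
# trace-level path that step 2 processes.

library(clchet)

STUDY_SEED <- 20251
out <- "results/session_demo"
dir.create("results", showWarnings = FALSE)

spec <- session_spec(
  constructs = list(
    construct_spec("C3_C4.WT", "WT"),
    construct_spec("C3_C4.R360S", "R360S"),
    construct_spec("C3_C4.K560E", "K560E")
  ),
  n_batches = 3, cells_per_batch = c(6, 8), seed = STUDY_SEED
)
ses <- simulate_session(spec, gate_model(), variant_library(),
                        voltage_protocol(), out_dir = out)
cat(sprintf("wrote %d sweep files (+ P/N companions) under %s\n",
            nrow(ses$manifest), out))

fspec <- flim_spec(
  image_shape = c(32, 32), n_bins = 256,
  tau_map = c(donor_only = 2.22, donor_acceptor = 1.89),
  photons_per_pixel = 1e4, seed = STUDY_SEED
)
simulate_flim(fspec, out_base = "results/flim_demo")
cat("wrote results/flim_demo.tif + results/flim_demo.json\n")
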