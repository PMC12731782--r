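#!/usr/bin/env Rscript
# Step 2: raw sweeps -> leak-corrected current-voltage relationships.
#
# Reads the manifest written by step 1, applies P/N subtraction to every
# cell, extracts steady-state currents (mean over the last third of each
# voltage step) and writes one IV table per construct.

library(clchet)

ivs <- process_session("results/session_demo/manifest.json")
dir.create("results/ivs", showWarnings = FALSE)
for (nm in names(ivs)) {
  path <- file.path("results/ivs", paste0(gsub("[^A-Za-z0-9._-]", "_", nm),
                                          ".csv"))
  write_iv_csv(ivs[[nm]], path)
  iv <- ivs[[nm]]
  cat(sprintf("%-14s n=%2d cells, I(+200 mV) = %6.2f +/- %.2f %s -> %s\n",
              nm, iv$n, iv$mean[1], iv$sd[1], iv$units, path))
}
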