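#!/usr/bin/env Rscript
# Step 6: collect the study outputs into one self-describing summary.

library(clchet)

phen <- jsonlite::read_json("results/phenotype_report.json")
fret <- jsonlite::read_json("results/fret_report.json")
acid <- utils::read.csv("results/acidic_comparison.csv")

md <- c(
  "# Synthetic heteromer study - summary",
  "",
  sprintf("provenance: seed %s, config %s", phen$provenance$seed,
          phen$provenance$config_hash),
  "",
  "## Variant phenotypes (ratio to wild-type co-expression)",
  vapply(phen$phenotypes, function(p) {
    sprintf("- %s: **%s** (mean ratio %.2f)", p$construct, p$label,
            p$mean_ratio)
  }, character(1)),
  "",
  "## FLIM-FRET",
  sprintf("- tau_D = %.2f ns, tau_DA = %.2f ns, E = %.3f", fret$tau_d_ns,
          fret$tau_da_ns, fret$efficiency),
  "",
  "## Acidic-pH inward currents (ClC-3 vs ClC-3/R360S, pH 5.3)",
  sprintf("- %d of %d voltages at or below +20 mV significant at alpha = 0.05",
          sum(acid$p < 0.05), nrow(acid)),
  sprintf("- most negative voltage: diff = %.4f, p = %.3g %s",
          acid$diff[which.min(acid$voltage_mV)],
          acid$p[which.min(acid$voltage_mV)],
          acid$stars[which.min(acid$voltage_mV)])
)
writeLines(md, "results/study_summary.md")
cat(md, sep = "\n")
cat("\nwrote results/study_summary.md\n")
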