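#!/usr/bin/env Rscript
# Generate the synthetic paired BS/oxBS study with known ground truth.
# Writes the probe manifest, two-channel intensities, negative controls,
# truth table and annotation BED tracks under results/sim_data/.
source("analysis/00_config.R")

cfg <- analysis_config()
run_pipeline(cfg, "simulate")

truth <- data.table::fread(file.path(cfg$data_dir, "truth.tsv"))
cat("\nSimulated", nrow(truth), "probes;",
    sum(truth$true_5hmc > 0), "carry 5hmC\n")
cat("mean true 5hmC among carriers:",
    round(mean(truth$true_5hmc[truth$true_5hmc > 0]), 3), "\n")
cat("\nProbes per gene-feature category:\n")
print(table(truth$region_label))
cat("\nProbes per island context:\n")
print(table(truth$island_context))
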