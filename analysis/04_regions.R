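#!/usr/bin/env Rscript
# Regional structure of 5mC and 5hmC: gene-feature categories (1 kb
# upstream/downstream flanks), CpG island / shore (0-2 kb) / shelf (2-4 kb)
# context, and the profile around transcription start sites.
source("analysis/00_config.R")

cfg <- analysis_config()
run_pipeline(cfg, "regions")

gene <- data.table::fread(file.path(cfg$out_dir, "region_summary_genes.tsv"))
isl <- data.table::fread(file.path(cfg$out_dir, "region_summary_islands.tsv"))
cat("\nBy gene feature (proportion of probes with significant positive 5hmC):\n")
print(gene[, .(category, n, prop_sig_pos = round(prop_sig_pos, 3),
               mc_median = round(mc_median, 3),
               hmc_median = round(hmc_median, 3))])
cat("\nBy island context:\n")
print(isl[, .(category, n, prop_sig_pos = round(prop_sig_pos, 3),
              mc_median = round(mc_median, 3))])
tss <- data.table::fread(file.path(cfg$out_dir, "tss_profile.tsv"))
at_tss <- tss[abs(bin_mid) <= 500]
away <- tss[abs(bin_mid) >= 3000]
cat(sprintf("\n5mC median within 500 bp of TSS: %.3f vs %.3f beyond 3 kb\n",
            median(at_tss$mc_median), median(away$mc_median)))
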