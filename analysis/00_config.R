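# Shared configuration for the analysis scripts (source from the repo root).
# One synthetic study at array scale: 100k probes, 4 BS + 4 oxBS replicate
# arrays of one sample, 70% of probes with no 5hmC, heteroskedastic
# per-probe beta noise (SD uniform on [0.005, 0.05]).
library(oxbsarray)

analysis_config <- function() {
  pipeline_config(
    data_dir = "results/sim_data",
    out_dir = "results/pipeline",
    sim = list(n_probes = 100000L, n_reps_per_arm = 4L, seed = 20240L,
               pi0 = 0.7, hmc_truth_dist = c(0.005, 0.45),
               noise_sd_dist = c(0.005, 0.05))
  )
}
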