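# Shared fixtures built in code.

# A beta matrix from explicit per-arm replicate columns.
make_betas <- function(bs_cols, ox_cols) {
  v <- cbind(do.call(cbind, bs_cols), do.call(cbind, ox_cols))
  beta_matrix(v, rep(c("BS", "oxBS"), c(length(bs_cols), length(ox_cols))),
              c(seq_along(bs_cols), seq_along(ox_cols)))
}

# Calibrated small simulation reused by several files: noise SD mean 0.02,
# 4 + 4 replicates.
calibrated_sim <- function(n_probes = 10000, seed = 11,
                           noise = c(0.005, 0.035), ...) {
  simulate_dataset(sim_config(n_probes = n_probes, seed = seed,
                              noise_sd_dist = noise, ...))
}

# Raw measurement-model betas (no offset, no normalization): M / (M + U).
raw_betas <- function(ds) {
  b <- compute_beta(ds$M, ds$U, alpha = 0)
  beta_matrix(b, ds$arm, ds$replicate)
}

# Truth rows aligned with an analysis over probe ids.
truth_for <- function(ds, probe_ids) ds$truth[match(probe_ids, probe_id)]

# Hand-built two-gene model (one per strand) as a BED6-style data.table,
# 0-based half-open.  Gene gp: + strand, TSS 10000, body [10000, 12000) with
# 5'UTR [10000, 10200), exon [10200, 10800), intron [10800, 11600),
# 3'UTR [11600, 12000).  Gene gm: - strand, body [50000, 52000), TSS at
# 52000 side, exon covering [50400, 51000), intron [51000, 51600); the
# uncovered stretches of gm exercise the "other" category.
tiny_gene_model <- function() {
  data.table::data.table(
    chrom = "chrT",
    start = c(10000L, 10000L, 10200L, 10800L, 11600L,
              50000L, 50400L, 51000L),
    end   = c(12000L, 10200L, 10800L, 11600L, 12000L,
              52000L, 51000L, 51600L),
    name  = c("gp:tx", "gp:5utr", "gp:exon", "gp:intron", "gp:3utr",
              "gm:tx", "gm:exon", "gm:intron"),
    score = 0L,
    strand = c(rep("+", 5L), rep("-", 3L))
  )
}

probes_at <- function(pos, chrom = "chrT") {
  data.table::data.table(chrom = chrom, pos = as.integer(pos))
}
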