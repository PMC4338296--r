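#' Configuration for the Infinium-style BS/oxBS simulator
#'
#' Bundles every knob of the synthetic data generator.  Defaults emulate the
#' study design the package targets: one DNA sample split over 4 BS and
#' 4 oxBS replicate arrays, ~70% of probes carrying no 5hmC, nonzero 5hmC
#' uniform on \[0.005, 0.45\], and heteroskedastic per-probe beta noise with
#' SD uniform on \[0.005, 0.05\] -- a regime under which between-replicate
#' beta correlations land near the high-0.9x values typical of good arrays.
#'
#' @param n_probes number of non-control probes to simulate.
#' @param n_reps_per_arm replicate arrays per arm (BS and oxBS each).
#' @param seed integer seed; fully determines the simulated dataset.
#' @param pi0 fraction of probes with exactly zero true 5hmC.
#' @param hmc_truth_dist length-2 numeric, uniform range for nonzero true
#'   5hmC levels.
#' @param noise_sd_dist length-2 numeric, uniform range for the per-probe
#'   beta-scale replicate noise SD.  Use `c(s, s)` for homoskedastic noise
#'   and `c(0, 0)` for the noise-free limit.
#' @param intensity_scale mean total (M + U) fluorescence per Type II probe.
#' @param type1_intensity_factor multiplicative intensity offset of Type I
#'   probes relative to Type II, giving SWAN something to correct.
#' @param background_mean,background_sd per-channel negative-control
#'   intensity parameters.
#' @param frac_type2 fraction of probes on the Type II design.
#' @param n_negative_controls number of negative-control probes.
#' @param fail_rate fraction of probe-by-array cells whose total intensity is
#'   replaced by a background draw (a failed measurement).
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_probes = 10000,
                       n_reps_per_arm = 4,
                       seed = 1L,
                       pi0 = 0.7,
                       hmc_truth_dist = c(0.005, 0.45),
                       noise_sd_dist = c(0.005, 0.05),
                       intensity_scale = 5000,
                       type1_intensity_factor = 1.25,
                       background_mean = 150,
                       background_sd = 40,
                       frac_type2 = 0.72,
                       n_negative_controls = 600,
                       fail_rate = 0.002) {
  chk_range <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) ||
        x[1] > x[2] || x[1] < 0 || x[2] > 1)
      stop("invalid distribution spec for '", nm,
           "': need numeric c(lo, hi) with 0 <= lo <= hi <= 1", call. = FALSE)
  }
  if (!is.numeric(pi0) || length(pi0) != 1L || pi0 < 0 || pi0 > 1)
    stop("invalid value for 'pi0': must be a fraction in [0, 1]", call. = FALSE)
  chk_range(hmc_truth_dist, "hmc_truth_dist")
  if (!is.numeric(noise_sd_dist) || length(noise_sd_dist) != 2L ||
      any(noise_sd_dist < 0) || noise_sd_dist[1] > noise_sd_dist[2])
    stop("invalid distribution spec for 'noise_sd_dist'", call. = FALSE)
  if (n_probes < 1) stop("n_probes must be >= 1", call. = FALSE)
  if (n_reps_per_arm < 1) stop("n_reps_per_arm must be >= 1", call. = FALSE)
  if (fail_rate < 0 || fail_rate >= 1)
    stop("fail_rate must be in [0, 1)", call. = FALSE)
  structure(list(
    n_probes = as.integer(n_probes),
    n_reps_per_arm = as.integer(n_reps_per_arm),
    seed = as.integer(seed),
    pi0 = pi0,
    hmc_truth_dist = hmc_truth_dist,
    noise_sd_dist = noise_sd_dist,
    intensity_scale = intensity_scale,
    type1_intensity_factor = type1_intensity_factor,
    background_mean = background_mean,
    background_sd = background_sd,
    frac_type2 = frac_type2,
    n_negative_controls = as.integer(n_negative_controls),
    fail_rate = fail_rate
  ), class = "sim_config")
}

# ---------------------------------------------------------------------------
# Synthetic genome layout.
#
# The genome is a single chromosome tiled with identical 30 kb "gene units".
# Local coordinates within a + strand unit (0-based, half-open):
#   [    0,  8000)  intergenic
#   [ 8000,  9000)  upstream flank (TSS at 9000)
#   [ 9000,  9500)  5'UTR
#   [ 9500, 10500)  exon 1
#   [10500, 13500)  intron 1
#   [13500, 14500)  exon 2
#   [14500, 17500)  intron 2
#   [17500, 18500)  exon 3
#   [18500, 19000)  3'UTR   (TTS at 19000)
#   [19000, 20000)  downstream flank
#   [20000, 30000)  intergenic
# A 1 kb CpG island [8500, 9500) straddles the TSS of ~60% of genes; ~25% of
# units additionally carry an intergenic island [24000, 24600).  Minus-strand
# units are the mirror image.  All islands sit > 4 kb from unit boundaries,
# so a probe's island/shore/shelf context is decided within its own unit.
# ---------------------------------------------------------------------------

.unit_width <- 30000L
.unit_features <- list(            # + strand frame, 0-based half-open
  `5utr`      = rbind(c(9000L, 9500L)),
  exon        = rbind(c(9500L, 10500L), c(13500L, 14500L), c(17500L, 18500L)),
  intron      = rbind(c(10500L, 13500L), c(14500L, 17500L)),
  `3utr`      = rbind(c(18500L, 19000L)),
  upstream    = rbind(c(8000L, 9000L)),
  downstream  = rbind(c(19000L, 20000L)),
  intergenic  = rbind(c(0L, 8000L), c(20000L, 30000L))
)
.tx_body <- c(9000L, 19000L)
.tss_island <- c(8500L, 9500L)
.ig_island  <- c(24000L, 24600L)

# Region categories sampled for probes, loosely matching the density of a
# 450K manifest (island/promoter heavy, many intronic and intergenic probes).
.region_probs <- c(upstream = 0.08, `5utr` = 0.10, exon = 0.18,
                   intron = 0.28, `3utr` = 0.04, downstream = 0.06,
                   intergenic = 0.26)

# Distance (bp) from a position to the nearest edge of an interval set;
# 0 when inside.  Intervals are 0-based half-open rows of a 2-col matrix.
.dist_to_intervals <- function(pos, ivs) {
  d <- rep(Inf, length(pos))
  for (i in seq_len(nrow(ivs))) {
    s <- ivs[i, 1]; e <- ivs[i, 2]
    di <- ifelse(pos >= s & pos < e, 0,
                 ifelse(pos < s, s - pos, pos - e + 1))
    d <- pmin(d, di)
  }
  d
}

#' Simulate per-probe ground truth for a BS/oxBS array experiment
#'
#' Generates the `TruthLandscape`: probe coordinates on a synthetic genome of
#' repeated gene units, gene-feature and CpG-island context, Infinium design
#' type, and true per-probe fractions of unmodified C, 5mC and 5hmC that sum
#' to 1 exactly.  The truth is region-structured: CpG-island and
#' TSS-proximal probes carry low 5mC and are least likely to carry 5hmC,
#' gene-body probes carry high 5mC and are most likely to carry 5hmC, while
#' nonzero 5hmC *levels* are drawn from the same distribution everywhere --
#' so per-region median 5hmC among modified probes is roughly flat even
#' though the proportion of modified probes varies by region.
#'
#' @param config a [sim_config()].
#' @return A `data.table` with one row per probe: `probe_id`, `chrom`,
#'   `pos` (0-based), `design_type`, `n_cpgs`, `region_label`,
#'   `island_context`, `true_c`, `true_5mc`, `true_5hmc`, `noise_sd`;
#'   gene-model and island tracks attached as attributes `genes` and
#'   `islands` (0-based half-open intervals).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_probes
    n_units <- max(20L, ceiling(n / 400))
    unit_start <- (seq_len(n_units) - 1L) * .unit_width
    unit_strand <- rep_len(c("+", "-"), n_units)
    has_tss_island <- runif(n_units) < 0.6
    has_ig_island  <- runif(n_units) < 0.25

    # -- probe placement -----------------------------------------------------
    unit <- sample.int(n_units, n, replace = TRUE)
    region <- sample(names(.region_probs), n, replace = TRUE,
                     prob = .region_probs)
    local <- integer(n)
    for (r in names(.region_probs)) {
      idx <- which(region == r)
      if (!length(idx)) next
      ivs <- .unit_features[[r]]
      w <- ivs[, 2] - ivs[, 1]
      pick <- sample.int(nrow(ivs), length(idx), replace = TRUE,
                         prob = w / sum(w))
      local[idx] <- ivs[pick, 1] +
        floor(runif(length(idx)) * w[pick])
    }

    # island context from the + frame layout (mirroring preserves distances)
    d_isl <- rep(Inf, n)
    ti <- has_tss_island[unit]
    d_isl[ti] <- .dist_to_intervals(local[ti], rbind(.tss_island))
    ii <- has_ig_island[unit]
    d_isl[ii] <- pmin(d_isl[ii], .dist_to_intervals(local[ii], rbind(.ig_island)))
    island_context <- ifelse(d_isl == 0, "island",
                      ifelse(d_isl <= 2000, "shore",
                      ifelse(d_isl <= 4000, "shelf", "open_sea")))

    mirror <- unit_strand[unit] == "-"
    local[mirror] <- .unit_width - 1L - local[mirror]
    pos <- unit_start[unit] + local

    # -- modification truth --------------------------------------------------
    low_ctx <- island_context == "island" | region %in% c("upstream", "5utr")
    body_ctx <- region %in% c("exon", "intron", "3utr", "downstream")
    mc_lo <- ifelse(island_context == "island", 0.02,
             ifelse(low_ctx, 0.05,
             ifelse(island_context == "shore", 0.20,
             ifelse(region == "exon", 0.55,
             ifelse(body_ctx, 0.45, 0.30)))))
    mc_hi <- ifelse(island_context == "island", 0.12,
             ifelse(low_ctx, 0.25,
             ifelse(island_context == "shore", 0.50,
             ifelse(region == "exon", 0.90,
             ifelse(body_ctx, 0.85, 0.75)))))
    true_5mc <- mc_lo + runif(n) * (mc_hi - mc_lo)

    # region-weighted probability of carrying any 5hmC; weights renormalized
    # so the marginal fraction of modified probes is exactly 1 - pi0
    w_hmc <- ifelse(low_ctx, 0.6, ifelse(body_ctx, 1.25, 1.0))
    p_hmc <- pmin((1 - config$pi0) * w_hmc / mean(w_hmc), 1)
    has_hmc <- runif(n) < p_hmc
    hd <- config$hmc_truth_dist
    true_5hmc <- ifelse(has_hmc, hd[1] + runif(n) * (hd[2] - hd[1]), 0)
    # keep headroom for unmodified C without distorting the 5hmC marginal
    over <- true_5mc + true_5hmc > 0.98
    true_5mc[over] <- 0.98 - true_5hmc[over]
    true_c <- 1 - true_5mc - true_5hmc

    nd <- config$noise_sd_dist
    noise_sd <- nd[1] + runif(n) * (nd[2] - nd[1])

    design_type <- ifelse(runif(n) < config$frac_type2, "II", "I")
    n_cpgs <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))

    truth <- data.table(
      probe_id = sprintf("cg%07d", seq_len(n)),
      chrom = "chrS1",
      pos = as.integer(pos),
      design_type = design_type,
      n_cpgs = as.integer(n_cpgs),
      region_label = region,
      island_context = island_context,
      true_c = true_c,
      true_5mc = true_5mc,
      true_5hmc = true_5hmc,
      noise_sd = noise_sd
    )

    # -- annotation tracks ---------------------------------------------------
    mirror_iv <- function(iv) cbind(.unit_width - iv[, 2], .unit_width - iv[, 1])
    genes <- vector("list", n_units)
    isl <- vector("list", n_units)
    for (u in seq_len(n_units)) {
      plus <- unit_strand[u] == "+"
      feat <- function(nm) {
        iv <- .unit_features[[nm]]
        if (!plus) iv <- mirror_iv(iv)
        data.table(chrom = "chrS1", start = unit_start[u] + iv[, 1],
                   end = unit_start[u] + iv[, 2],
                   name = paste0("g", u, ":", nm), score = 0L,
                   strand = unit_strand[u])
      }
      body <- if (plus) rbind(.tx_body) else mirror_iv(rbind(.tx_body))
      genes[[u]] <- rbind(
        data.table(chrom = "chrS1", start = unit_start[u] + body[, 1],
                   end = unit_start[u] + body[, 2],
                   name = paste0("g", u, ":tx"), score = 0L,
                   strand = unit_strand[u]),
        feat("5utr"), feat("exon"), feat("intron"), feat("3utr"))
      iu <- NULL
      if (has_tss_island[u]) iu <- rbind(iu, rbind(.tss_island))
      if (has_ig_island[u]) iu <- rbind(iu, rbind(.ig_island))
      if (!is.null(iu)) {
        if (!plus) iu <- mirror_iv(iu)
        isl[[u]] <- data.table(chrom = "chrS1",
                               start = unit_start[u] + iu[, 1],
                               end = unit_start[u] + iu[, 2])
      }
    }
    setattr(truth, "genes", rbindlist(genes))
    setattr(truth, "islands", setorder(rbindlist(isl), start))
    truth[]
  })
}

# Beta-distributed replicate noise with exact mean p and SD s (capped at
# 0.9 * sqrt(p (1 - p)) where the target SD is infeasible for a Beta law).
.rbeta_noise <- function(p, s) {
  out <- p
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  act <- s > 1e-12
  if (any(act)) {
    smax <- 0.9 * sqrt(p * (1 - p))
    s2 <- pmin(s, smax)[act]
    pa <- p[act]
    nu <- pa * (1 - pa) / s2^2 - 1
    out[act] <- rbeta(sum(act), pa * nu, (1 - pa) * nu)
  }
  out
}

#' Simulate two-channel probe intensities from a truth landscape
#'
#' Applies the oxBS-array measurement model: BS arrays read 5mC + 5hmC
#' (bisulfite leaves both unconverted), oxBS arrays read 5mC alone.  The
#' expected beta of each probe/array cell equals the arm's true level; the
#' between-replicate beta SD equals the probe's `noise_sd` (Beta-distributed
#' perturbation, exact in mean).  Noisy betas are converted to channel
#' intensities M = T*beta, U = T*(1-beta) with a lognormal per-cell total T,
#' Type I probes running brighter than Type II; a `fail_rate` fraction of
#' cells is replaced by background-level signal, and negative-control probes
#' are drawn from the background distribution throughout.
#'
#' @param truth a [simulate_truth()] result.
#' @param config the same [sim_config()] used to build `truth`.
#' @return A list of class `sim_dataset`: `manifest` (probe metadata
#'   including control rows), `M`/`U` (probes x arrays intensity matrices),
#'   `negative_controls` (list of control `M`/`U` matrices), `arm` and
#'   `replicate` per array, `truth`, and annotation tables `genes`/`islands`.
#' @export
simulate_intensities <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(truth) != config$n_probes)
    stop("truth and config disagree on the number of probes", call. = FALSE)
  with_seed(config$seed + 1L, {
    n <- nrow(truth)
    nr <- config$n_reps_per_arm
    arrays <- c(paste0("BS", seq_len(nr)), paste0("oxBS", seq_len(nr)))
    arm <- rep(c("BS", "oxBS"), each = nr)
    replicate <- rep(seq_len(nr), 2L)
    na <- length(arrays)

    beta_true <- cbind(
      matrix(truth$true_5mc + truth$true_5hmc, n, nr),  # BS arm
      matrix(truth$true_5mc, n, nr)                     # oxBS arm
    )
    beta_noisy <- matrix(
      .rbeta_noise(as.vector(beta_true),
                   rep(truth$noise_sd, na)), n, na)

    scale <- config$intensity_scale *
      ifelse(truth$design_type == "I", config$type1_intensity_factor, 1)
    sdlog <- 0.3
    tot <- matrix(rlnorm(n * na,
                         meanlog = log(rep(scale, na)) - sdlog^2 / 2,
                         sdlog = sdlog), n, na)

    failed <- matrix(runif(n * na) < config$fail_rate, n, na)
    rbg <- function(k) pmax(rnorm(k, config$background_mean,
                                  config$background_sd), 1)
    M <- tot * beta_noisy
    U <- tot * (1 - beta_noisy)
    nf <- sum(failed)
    if (nf) { M[failed] <- rbg(nf); U[failed] <- rbg(nf) }
    dimnames(M) <- dimnames(U) <- list(truth$probe_id, arrays)

    nc <- config$n_negative_controls
    neg_M <- matrix(rbg(nc * na), nc, na,
                    dimnames = list(sprintf("neg%04d", seq_len(nc)), arrays))
    neg_U <- matrix(rbg(nc * na), nc, na, dimnames = dimnames(neg_M))

    manifest <- rbind(
      truth[, .(probe_id, chrom, pos, design_type, n_cpgs)][, is_control := FALSE],
      data.table(probe_id = rownames(neg_M), chrom = "*", pos = -1L,
                 design_type = "II", n_cpgs = 0L, is_control = TRUE)
    )

    structure(list(
      manifest = manifest, M = M, U = U,
      negative_controls = list(M = neg_M, U = neg_U),
      arm = arm, replicate = replicate,
      truth = truth,
      genes = attr(truth, "genes"), islands = attr(truth, "islands")
    ), class = "sim_dataset")
  })
}

#' Simulate a complete paired BS/oxBS dataset
#'
#' Convenience wrapper: [simulate_truth()] followed by
#' [simulate_intensities()].
#'
#' @param config a [sim_config()].
#' @return A `sim_dataset`; see [simulate_intensities()].
#' @export
simulate_dataset <- function(config) {
  simulate_intensities(simulate_truth(config), config)
}

.intensity_dt <- function(M, U) {
  dt <- data.table(probe_id = rownames(M))
  for (a in colnames(M)) {
    dt[[paste0("M_", a)]] <- M[, a]
    dt[[paste0("U_", a)]] <- U[, a]
  }
  dt
}

.dt_intensity <- function(dt) {
  cols <- setdiff(names(dt), "probe_id")
  arrays <- unique(sub("^[MU]_", "", cols))
  M <- as.matrix(dt[, paste0("M_", arrays), with = FALSE])
  U <- as.matrix(dt[, paste0("U_", arrays), with = FALSE])
  dimnames(M) <- dimnames(U) <- list(dt$probe_id, arrays)
  list(M = M, U = U)
}

#' Write a simulated dataset to plain-text fixture files
#'
#' Emits `manifest.tsv`, `intensities.tsv`, `negative_controls.tsv`,
#' `truth.tsv`, `genes.bed` (BED6, name = `<gene>:<feature>`, one `tx` row
#' per gene plus UTR/exon/intron rows) and `islands.bed` (BED3).  All BED
#' intervals are 0-based half-open.  The files round-trip losslessly through
#' [read_fixture()].
#'
#' @param dataset a `sim_dataset`.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_fixture <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- c(
    manifest = file.path(out_dir, "manifest.tsv"),
    intensities = file.path(out_dir, "intensities.tsv"),
    negative_controls = file.path(out_dir, "negative_controls.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    genes = file.path(out_dir, "genes.bed"),
    islands = file.path(out_dir, "islands.bed")
  )
  fwrite(dataset$manifest, paths["manifest"], sep = "\t")
  fwrite(.intensity_dt(dataset$M, dataset$U), paths["intensities"], sep = "\t")
  fwrite(.intensity_dt(dataset$negative_controls$M,
                       dataset$negative_controls$U),
         paths["negative_controls"], sep = "\t")
  fwrite(dataset$truth, paths["truth"], sep = "\t")
  fwrite(dataset$genes, paths["genes"], sep = "\t", col.names = FALSE)
  fwrite(dataset$islands, paths["islands"], sep = "\t", col.names = FALSE)
  invisible(paths)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir directory containing the fixture TSV/BED files.
#' @return A `sim_dataset` equal field-for-field to the one written.
#' @export
read_fixture <- function(dir) {
  need <- c("manifest.tsv", "intensities.tsv", "negative_controls.tsv",
            "truth.tsv", "genes.bed", "islands.bed")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("fixture directory ", dir, " is missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  manifest <- fread(file.path(dir, "manifest.tsv"))
  iv <- .dt_intensity(fread(file.path(dir, "intensities.tsv")))
  nc <- .dt_intensity(fread(file.path(dir, "negative_controls.tsv")))
  truth <- fread(file.path(dir, "truth.tsv"))
  genes <- fread(file.path(dir, "genes.bed"),
                 col.names = c("chrom", "start", "end", "name", "score",
                               "strand"))
  islands <- fread(file.path(dir, "islands.bed"),
                   col.names = c("chrom", "start", "end"))
  arrays <- colnames(iv$M)
  arm <- sub("[0-9]+$", "", arrays)
  structure(list(
    manifest = manifest, M = iv$M, U = iv$U,
    negative_controls = nc,
    arm = arm, replicate = as.integer(sub("^[A-Za-z]+", "", arrays)),
    truth = truth, genes = genes, islands = islands
  ), class = "sim_dataset")
}
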