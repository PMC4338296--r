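#' Build or load a pipeline configuration
#'
#' One configuration object drives every stage of [run_pipeline()]: the
#' simulation block, preprocessing thresholds, the FDR threshold, replicate
#' subsets, the qPCR validation design, and the data/output directories.
#' Serializes losslessly to YAML or JSON.
#'
#' @param path optional YAML (`.yaml`/`.yml`) or JSON (`.json`) file to
#'   load; fields present in the file override the defaults, and `...`
#'   overrides both.
#' @param ... named overrides of individual fields.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    data_dir = "pipeline_data",
    out_dir = "pipeline_out",
    alpha = 100,
    det_threshold = 0.01,
    max_failed_arrays = 1,
    fdr = 0.01,
    swan_seed = 1L,
    subsets = list(c(1L, 3L), c(2L, 4L)),
    n_validation_sites = 27L,
    sim = list(n_probes = 10000L, n_reps_per_arm = 4L, seed = 1L,
               pi0 = 0.7, hmc_truth_dist = c(0.005, 0.45),
               noise_sd_dist = c(0.005, 0.05))
  )
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    loaded <- if (grepl("\\.json$", path)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (!is.null(loaded$subsets)) {
      s <- loaded$subsets
      # JSON simplification can return a matrix (one row per subset)
      if (is.matrix(s)) s <- lapply(seq_len(nrow(s)), function(i) s[i, ])
      loaded$subsets <- lapply(s, as.integer)
    }
    cfg[names(loaded)] <- loaded
  }
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), c(names(cfg), "sim"))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(dots)] <- dots
  }
  for (f in c("det_threshold", "fdr"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop("config field '", f, "' must lie in (0, 1)", call. = FALSE)
  if (cfg$alpha < 0) stop("config field 'alpha' must be >= 0", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Serialize a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @param path output file; format chosen from the extension (`.json` or
#'   YAML otherwise).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  plain <- unclass(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(plain, path)
  }
  invisible(path)
}

.stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

.write_summary <- function(out_dir, stage, summary) {
  jsonlite::write_json(summary,
                       file.path(out_dir, paste0(stage, "_summary.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.require_artifact <- function(path, produced_by) {
  if (!file.exists(path))
    stop("missing artifact ", basename(path), "; run the '", produced_by,
         "' stage first", call. = FALSE)
  path
}

#' Run pipeline stages over a configured dataset
#'
#' Stages (`command`): `simulate` writes a ground-truth fixture into
#' `data_dir`; `preprocess` converts intensities to filtered, normalized
#' betas; `detect` runs the moderated F-test; `quantify` writes per-probe
#' modification estimates and their summary; `regions` writes region and
#' TSS-profile summaries; `replicates` writes the subset-comparison table;
#' `validate` simulates the qPCR assay at truth-selected sites and writes
#' the concordance table; `all` chains everything.  Every stage writes its
#' TSV artifacts plus a JSON run summary (probe accounting, thresholds,
#' seeds) into `out_dir` and logs timings to stderr.  TSV artifacts are
#' byte-identical across reruns of the same configuration.
#'
#' @param config a [pipeline_config()].
#' @param command one of `simulate`, `preprocess`, `detect`, `quantify`,
#'   `regions`, `replicates`, `validate`, `all`.
#' @return Invisibly, the list of artifact paths written by the stage(s).
#' @export
run_pipeline <- function(config,
                         command = c("all", "simulate", "preprocess",
                                     "detect", "quantify", "regions",
                                     "replicates", "validate")) {
  stopifnot(inherits(config, "pipeline_config"))
  command <- match.arg(command)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (command == "all")
    c("simulate", "preprocess", "detect", "quantify", "regions",
      "replicates", "validate") else command
  paths <- list()
  for (st in stages) {
    t0 <- Sys.time()
    .stage_log(st, "started")
    paths[[st]] <- switch(st,
      simulate = .stage_simulate(config),
      preprocess = .stage_preprocess(config),
      detect = .stage_detect(config),
      quantify = .stage_quantify(config),
      regions = .stage_regions(config),
      replicates = .stage_replicates(config),
      validate = .stage_validate(config)
    )
    .stage_log(st, sprintf("done in %.2fs",
                           as.numeric(Sys.time() - t0, units = "secs")))
  }
  invisible(paths)
}

.stage_simulate <- function(config) {
  sim <- do.call(sim_config, config$sim)
  ds <- simulate_dataset(sim)
  p <- write_fixture(ds, config$data_dir)
  .write_summary(config$out_dir, "simulate", list(
    n_probes = sim$n_probes, n_arrays = 2L * sim$n_reps_per_arm,
    pi0 = sim$pi0, seed = sim$seed,
    n_true_positive = sum(ds$truth$true_5hmc > 0)
  ))
  p
}

.load_fixture <- function(config) {
  .require_artifact(file.path(config$data_dir, "manifest.tsv"), "simulate")
  read_fixture(config$data_dir)
}

.stage_preprocess <- function(config) {
  ds <- .load_fixture(config)
  pp <- preprocess_dataset(ds, alpha = config$alpha,
                           det_threshold = config$det_threshold,
                           max_failed_arrays = config$max_failed_arrays,
                           seed = config$swan_seed)
  arrays <- paste0(pp$betas$arm, pp$betas$replicate)
  bdt <- data.table(probe_id = pp$probe_id)
  for (j in seq_along(arrays)) bdt[[arrays[j]]] <- pp$betas$values[, j]
  ddt <- data.table(probe_id = ds$manifest[is_control == FALSE, probe_id])
  for (j in seq_along(arrays)) ddt[[arrays[j]]] <- pp$mask$detp[, j]
  out <- c(betas = file.path(config$out_dir, "betas.tsv"),
           detp = file.path(config$out_dir, "detection_p.tsv"),
           kept = file.path(config$out_dir, "kept_probes.txt"))
  fwrite(bdt, out["betas"], sep = "\t")
  fwrite(ddt, out["detp"], sep = "\t")
  writeLines(pp$probe_id, out["kept"])
  cors <- pairwise_correlation(pp$betas)
  .write_summary(config$out_dir, "preprocess", list(
    n_input = pp$n_input, n_kept = pp$n_kept,
    n_filtered = pp$n_input - pp$n_kept,
    det_threshold = config$det_threshold,
    max_failed_arrays = config$max_failed_arrays,
    alpha = config$alpha, swan_seed = config$swan_seed,
    mean_correlation = as.list(attr(cors, "mean_within_arm"))
  ))
  out
}

.read_betas <- function(config) {
  path <- .require_artifact(file.path(config$out_dir, "betas.tsv"),
                            "preprocess")
  dt <- fread(path)
  arrays <- setdiff(names(dt), "probe_id")
  v <- as.matrix(dt[, arrays, with = FALSE])
  rownames(v) <- dt$probe_id
  beta_matrix(v, sub("[0-9]+$", "", arrays),
              as.integer(sub("^[A-Za-z]+", "", arrays)))
}

.stage_detect <- function(config) {
  bm <- .read_betas(config)
  res <- diff_test(bm, fdr = config$fdr)
  out <- file.path(config$out_dir, "probe_tests.tsv")
  fwrite(res, out, sep = "\t")
  fit <- attr(res, "fit")
  .write_summary(config$out_dir, "detect", list(
    n_tested = nrow(res), fdr = config$fdr,
    d0 = if (is.infinite(fit$d0)) "Inf" else fit$d0, s0_sq = fit$s0_sq,
    n_significant = sum(res$significant),
    n_significant_positive = sum(res$significant & res$delta > 0),
    n_significant_negative = sum(res$significant & res$delta < 0)
  ))
  out
}

.read_tests <- function(config) {
  fread(.require_artifact(file.path(config$out_dir, "probe_tests.tsv"),
                          "detect"))
}

.stage_quantify <- function(config) {
  bm <- .read_betas(config)
  res <- .read_tests(config)
  est <- estimate_levels(bm, res)
  out <- file.path(config$out_dir, "estimates.tsv")
  fwrite(est, out, sep = "\t")
  s <- summarize_positive_calls(est)
  .write_summary(config$out_dir, "quantify", list(
    n_probes = nrow(est),
    n_significant_positive = s$n_positive,
    n_significant_negative = s$n_negative,
    hmc_pct = list(min = s$min * 100, q25 = s$q25 * 100,
                   median = s$median * 100, q75 = s$q75 * 100,
                   max = s$max * 100),
    median_effect_size_pct = effect_size_summary(res)
  ))
  out
}

.read_estimates <- function(config) {
  fread(.require_artifact(file.path(config$out_dir, "estimates.tsv"),
                          "quantify"))
}

.stage_regions <- function(config) {
  est <- .read_estimates(config)
  ds <- .load_fixture(config)
  man <- ds$manifest[match(est$probe_id, probe_id)]
  genes <- file.path(config$data_dir, "genes.bed")
  islands <- file.path(config$data_dir, "islands.bed")
  gene_cat <- annotate_gene_regions(man, genes)
  isl_ctx <- annotate_island_context(man, islands)
  out <- c(gene = file.path(config$out_dir, "region_summary_genes.tsv"),
           island = file.path(config$out_dir, "region_summary_islands.tsv"),
           tss = file.path(config$out_dir, "tss_profile.tsv"))
  fwrite(summarize_by_region(est, gene_cat), out["gene"], sep = "\t")
  fwrite(summarize_by_region(est, isl_ctx), out["island"], sep = "\t")
  fwrite(tss_profile(man, genes, est), out["tss"], sep = "\t")
  .write_summary(config$out_dir, "regions", list(
    n_probes = nrow(est),
    gene_categories = as.list(table(gene_cat)),
    island_contexts = as.list(table(isl_ctx))
  ))
  out
}

.stage_replicates <- function(config) {
  bm <- .read_betas(config)
  cmp <- subset_analysis(bm, subsets = config$subsets, fdr = config$fdr)
  tab <- data.table(
    analysis = names(cmp$n_sig_any),
    n_sig_any = cmp$n_sig_any,
    n_sig_positive = cmp$n_sig_positive,
    n_new_vs_full = c(cmp$n_new_vs_full, 0L),
    min_positive_level = cmp$min_positive_level
  )
  out <- file.path(config$out_dir, "replicate_comparison.tsv")
  fwrite(tab, out, sep = "\t")
  .write_summary(config$out_dir, "replicates", list(
    subsets = vapply(config$subsets, paste, "", collapse = ","),
    n_sig_any = as.list(cmp$n_sig_any),
    n_overlap = cmp$n_overlap,
    n_new_vs_full = cmp$n_new_vs_full
  ))
  out
}

.stage_validate <- function(config) {
  est <- .read_estimates(config)
  ds <- .load_fixture(config)
  truth <- ds$truth[match(est$probe_id, probe_id)]
  idx <- select_validation_sites(est, n = config$n_validation_sites)
  cq <- simulate_qpcr(truth$true_5hmc[idx],
                      seed = config$sim$seed + 1000L)
  wide <- dcast(cq, site_id ~ condition, value.var = "cq",
                fun.aggregate = mean)
  wide[, qpcr_5hmc := mapply(qpcr_5hmc_fraction, glu, mock, undig)]
  conc <- concordance(est$level_5hmc[idx], wide$qpcr_5hmc)
  tab <- data.table(site_id = wide$site_id,
                    probe_id = est$probe_id[idx],
                    array_5hmc = est$level_5hmc[idx],
                    qpcr_5hmc = wide$qpcr_5hmc,
                    true_5hmc = truth$true_5hmc[idx])
  out <- file.path(config$out_dir, "qpcr_concordance.tsv")
  fwrite(tab, out, sep = "\t")
  .write_summary(config$out_dir, "validate", list(
    n_sites = conc$n, r = conc$r
  ))
  out
}
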