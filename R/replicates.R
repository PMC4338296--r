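#' Restrict a beta matrix to selected replicate indices (both arms)
#'
#' @param betas a [beta_matrix()].
#' @param reps integer replicate indices to keep in each arm.
#' @return A [beta_matrix()] over the selected arrays.
#' @export
subset_beta <- function(betas, reps) {
  sel <- betas$replicate %in% reps
  if (sum(sel & betas$arm == "BS") < 2 || sum(sel & betas$arm == "oxBS") < 2)
    stop("each subset needs >= 2 replicates per arm", call. = FALSE)
  beta_matrix(betas$values[, sel, drop = FALSE], betas$arm[sel],
              betas$replicate[sel])
}

#' Compare replicate-subset analyses against the full analysis
#'
#' Re-runs the complete differential test (shrinkage refitted within each
#' subset, mirroring truly separate analyses) on each replicate subset and
#' on the full replicate set, then counts significant probes, the overlap
#' between subsets, and probes significant in a subset but not in the full
#' analysis.  Counts are reported both for all significant probes
#' (positive or negative difference) and for positives only.
#'
#' @param betas a [beta_matrix()] over the full replicate set.
#' @param subsets list of integer replicate-index vectors, default
#'   `list(c(1, 3), c(2, 4))`.
#' @param fdr FDR threshold passed to [diff_test()].
#' @return List of class `subset_comparison`: per-analysis significant
#'   counts (`any` and `positive` accounting), `n_overlap` between the
#'   first two subsets, `n_new_vs_full` per subset, minimum positive
#'   significant 5hmC per analysis, and the per-analysis result tables in
#'   `$results` (subsets first, full analysis last as `"full"`).
#' @export
subset_analysis <- function(betas, subsets = list(c(1, 3), c(2, 4)),
                            fdr = 0.01) {
  analyses <- c(lapply(subsets, function(r) subset_beta(betas, r)),
                list(betas))
  names(analyses) <- c(vapply(subsets, paste, "", collapse = "+"), "full")
  results <- lapply(analyses, diff_test, fdr = fdr)
  sig_any <- lapply(results, function(r) which(r$significant))
  sig_pos <- lapply(results, function(r) which(r$significant & r$delta > 0))
  min_pos <- vapply(results, function(r) {
    lev <- r[significant == TRUE & delta > 0, delta]
    if (length(lev)) min(lev) else NA_real_
  }, 0)
  full <- length(results)
  structure(list(
    subsets = subsets,
    n_sig_any = vapply(sig_any, length, 0L),
    n_sig_positive = vapply(sig_pos, length, 0L),
    n_sig_full = length(sig_any[[full]]),
    n_overlap = if (length(subsets) >= 2)
      length(intersect(sig_any[[1]], sig_any[[2]])) else NA_integer_,
    n_overlap_positive = if (length(subsets) >= 2)
      length(intersect(sig_pos[[1]], sig_pos[[2]])) else NA_integer_,
    n_new_vs_full = vapply(seq_along(subsets), function(i)
      length(setdiff(sig_any[[i]], sig_any[[full]])), 0L),
    min_positive_level = min_pos,
    results = results
  ), class = "subset_comparison")
}

#' @export
print.subset_comparison <- function(x, ...) {
  cat("Replicate-subset comparison (FDR-significant probe counts)\n")
  for (i in seq_along(x$n_sig_any))
    cat(sprintf("  %-8s any: %6d  positive: %6d  min positive level: %s\n",
                names(x$n_sig_any)[i], x$n_sig_any[i], x$n_sig_positive[i],
                format(x$min_positive_level[i], digits = 3)))
  if (!is.na(x$n_overlap))
    cat("  overlap between first two subsets:", x$n_overlap, "\n")
  cat("  subset-only calls vs full:", paste(x$n_new_vs_full, collapse = ", "),
      "\n")
  invisible(x)
}

#' Detection floor and power curve of the 5hmC subtraction assay
#'
#' The detection floor is the smallest estimated 5hmC among probes called
#' significant positive -- restricted, when simulator truth is available, to
#' probes whose true 5hmC is genuinely positive (validated calls).  The
#' power curve reports the fraction of probes detected per 1% bin of true
#' 5hmC level; its value at true level 0 is the realized per-null
#' significant-call rate.
#'
#' @param estimates an [estimate_levels()] table with significance calls.
#' @param truth optional truth table (with `true_5hmc`) aligned row-for-row
#'   with `estimates` (match on `probe_id` before calling if the analysis
#'   dropped probes).
#' @param bin_width power-curve bin width on the fraction scale, default
#'   0.01.
#' @return List: `floor` (fraction scale; `NA` when no qualifying call
#'   exists) and, with truth, `power_curve` (`bin_start`, `n`,
#'   `detection_rate`).
#' @export
detection_floor <- function(estimates, truth = NULL, bin_width = 0.01) {
  sig_pos <- estimates$significant == TRUE & estimates$level_5hmc > 0
  if (is.null(truth)) {
    lev <- estimates$level_5hmc[sig_pos]
    return(list(floor = if (length(lev)) min(lev) else NA_real_,
                power_curve = NULL))
  }
  stopifnot(nrow(truth) == nrow(estimates))
  qual <- sig_pos & truth$true_5hmc > 0
  lev <- estimates$level_5hmc[qual]
  dt <- data.table(true = truth$true_5hmc, detected = sig_pos)
  dt[, bin_start := floor(true / bin_width) * bin_width]
  pc <- dt[, .(n = .N, detection_rate = mean(detected)), by = bin_start]
  setorder(pc, bin_start)
  list(floor = if (length(lev)) min(lev) else NA_real_,
       power_curve = pc[])
}
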