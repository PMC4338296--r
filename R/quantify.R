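#' Per-probe 5mC / 5hmC / unmodified-C estimates by subtraction
#'
#' The BS arm measures 5mC + 5hmC, the oxBS arm 5mC alone, so with arm
#' means taken as simple averages over replicates:
#' `level_5mc = mean(oxBS)`, `level_5hmc = mean(BS) - mean(oxBS)`,
#' `level_c = 1 - mean(BS)`.  The three sum to 1 by construction.  Negative
#' 5hmC estimates are reported as-is -- they are the expected noise artifact
#' at probes with little or no 5hmC, and clamping them would hide that
#' diagnostic.
#'
#' @param betas a [beta_matrix()] with both arms present.
#' @param results optional [diff_test()] table; if supplied, `significant`
#'   and `sign` are merged onto the estimates by row order.
#' @return `data.table`: `probe_id`, `level_5mc`, `level_5hmc`, `level_c`
#'   (+ `significant`, `sign` when `results` given).
#' @export
estimate_levels <- function(betas, results = NULL) {
  v <- betas$values
  bs <- betas$arm == "BS"
  ox <- betas$arm == "oxBS"
  if (!any(bs) || !any(ox))
    stop("both BS and oxBS arrays are required", call. = FALSE)
  mean_bs <- rowMeans(v[, bs, drop = FALSE])
  mean_ox <- rowMeans(v[, ox, drop = FALSE])
  est <- data.table(
    probe_id = if (!is.null(rownames(v))) rownames(v)
               else sprintf("p%d", seq_len(nrow(v))),
    level_5mc = mean_ox,
    level_5hmc = mean_bs - mean_ox,
    level_c = 1 - mean_bs
  )
  if (!is.null(results)) {
    stopifnot(nrow(results) == nrow(est))
    est[, significant := results$significant]
    est[, sign := results$sign]
  }
  est[]
}

#' Distribution of 5hmC among significant positive probes
#'
#' Summarizes estimated 5hmC over probes called significant with a positive
#' BS - oxBS difference: range, quartiles and median (the headline numbers
#' of the assay), counts of positive and negative significant calls, and
#' histogram bins for the usual level-distribution plot.
#'
#' @param estimates an [estimate_levels()] table carrying `significant` and
#'   `sign`.
#' @param bin_width histogram bin width on the fraction scale.
#' @return List: `n_positive`, `n_negative`, `min`, `q25`, `median`, `q75`,
#'   `max` (all on the fraction scale; `NA` and a warning when no positive
#'   calls exist) and a `histogram` data.table (`mid`, `count`).
#' @export
summarize_positive_calls <- function(estimates, bin_width = 0.01) {
  stopifnot(!is.null(estimates$significant))
  pos <- estimates[significant == TRUE & level_5hmc > 0, level_5hmc]
  neg <- estimates[significant == TRUE & level_5hmc < 0, level_5hmc]
  if (!length(pos)) {
    warning("no significant positive probes; summary is empty")
    return(list(n_positive = 0L, n_negative = length(neg),
                min = NA_real_, q25 = NA_real_, median = NA_real_,
                q75 = NA_real_, max = NA_real_,
                histogram = data.table(mid = numeric(), count = integer())))
  }
  qs <- quantile(pos, c(0.25, 0.5, 0.75), names = FALSE)
  breaks <- seq(floor(min(pos) / bin_width) * bin_width,
                ceiling(max(pos) / bin_width) * bin_width, by = bin_width)
  if (length(breaks) < 2) breaks <- c(breaks, breaks + bin_width)
  h <- hist(pos, breaks = breaks, plot = FALSE)
  list(n_positive = length(pos), n_negative = length(neg),
       min = min(pos), q25 = qs[1], median = qs[2], q75 = qs[3],
       max = max(pos),
       histogram = data.table(mid = h$mids, count = h$counts))
}

#' Median effect size among significant probes, in percent
#'
#' The median BS - oxBS difference over probes passing the FDR threshold,
#' reported x100 (percentage points of methylation).
#'
#' @param results a [diff_test()] table.
#' @return Scalar; `NA` when nothing is significant.
#' @export
effect_size_summary <- function(results) {
  d <- results[significant == TRUE, delta]
  if (!length(d)) return(NA_real_)
  median(d) * 100
}
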