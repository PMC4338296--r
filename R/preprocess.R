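#' Beta value from two-channel intensities
#'
#' The platform convention beta = M / (M + U + alpha), where M is the
#' methylated-channel and U the unmethylated-channel intensity and alpha a
#' small stabilizing offset.  When the full denominator is zero the beta is
#' defined as 0 (no evidence of signal).
#'
#' @param M,U non-negative intensities (vectors or matrices, recycled).
#' @param alpha non-negative offset, default 100 intensity units.
#' @return Beta values in `[0, 1)` for `alpha > 0` (in `[0, 1]` at
#'   `alpha = 0`), same shape as `M`.
#' @export
compute_beta <- function(M, U, alpha = 100) {
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE) || alpha < 0)
    stop("intensities and alpha must be non-negative", call. = FALSE)
  den <- M + U + alpha
  b <- M / den
  b[den == 0] <- 0
  b
}

#' Fit a per-array background model from negative-control probes
#'
#' Background total-intensity location and spread per array:
#' `mu_bg = mean(M_neg) + mean(U_neg)` and
#' `sigma_bg = sd(M_neg) + sd(U_neg)`, the conservative convention used for
#' array detection calls (summing channel SDs rather than adding variances).
#'
#' @param neg_M,neg_U control-probe intensity matrices (controls x arrays).
#' @return A `data.table` with columns `array`, `mu_bg`, `sigma_bg`.
#' @export
fit_background <- function(neg_M, neg_U) {
  if (is.null(neg_M) || is.null(neg_U) || nrow(neg_M) < 2)
    stop("no negative-control intensities supplied; a background model ",
         "requires at least two control probes per array", call. = FALSE)
  data.table(
    array = colnames(neg_M),
    mu_bg = colMeans(neg_M) + colMeans(neg_U),
    sigma_bg = apply(neg_M, 2, sd) + apply(neg_U, 2, sd)
  )
}

#' Detection p-values against a negative-control background
#'
#' For each probe/array cell, the upper-tail probability that total signal
#' M + U arises from a Gaussian background with that array's `mu_bg` and
#' `sigma_bg`.  Small p means the probe is confidently detected above
#' background; p is monotone decreasing in M + U.
#'
#' @param M,U probe intensity matrices (probes x arrays).
#' @param background a [fit_background()] table covering every array.
#' @return Matrix of p-values in `[0, 1]`, same shape as `M`.
#' @export
detection_pvalue <- function(M, U, background) {
  arrays <- colnames(M)
  if (is.null(arrays)) arrays <- as.character(seq_len(ncol(as.matrix(M))))
  bg <- background[match(arrays, background$array)]
  if (anyNA(bg$mu_bg))
    stop("background model missing for arrays: ",
         paste(arrays[is.na(bg$mu_bg)], collapse = ", "), call. = FALSE)
  tot <- as.matrix(M) + as.matrix(U)
  p <- tot
  for (j in seq_along(arrays))
    p[, j] <- pnorm(tot[, j], mean = bg$mu_bg[j], sd = bg$sigma_bg[j],
                    lower.tail = FALSE)
  dimnames(p) <- dimnames(tot)
  p
}

#' Flag probes failing detection in too many arrays
#'
#' A probe/array cell fails when its detection p-value is >= `threshold`
#' (p >= 0.01 means the signal is not distinguishable from background).
#' A probe is kept iff it fails in at most `max_failed_arrays` arrays --
#' i.e. probes undetected "in more than one array" are excluded.  The
#' opposite reading (fail when p < threshold) is available via
#' `fail_when = "lt"` for strict comparability with texts that state the
#' filter in that direction.
#'
#' @param detp detection p-value matrix (probes x arrays).
#' @param threshold detection threshold, default 0.01.
#' @param max_failed_arrays maximum tolerated failing arrays, default 1.
#' @param fail_when `"ge"` (default) or `"lt"`; direction of the per-cell
#'   failure comparison.
#' @return A list of class `detection_mask`: `detp`, `failed` (logical
#'   matrix), `n_failed` per probe, and the per-probe `keep` flag.
#' @export
filter_failed_probes <- function(detp, threshold = 0.01,
                                 max_failed_arrays = 1,
                                 fail_when = c("ge", "lt")) {
  fail_when <- match.arg(fail_when)
  failed <- if (fail_when == "ge") detp >= threshold else detp < threshold
  n_failed <- rowSums(failed)
  structure(list(detp = detp, failed = failed, n_failed = n_failed,
                 keep = n_failed <= max_failed_arrays,
                 threshold = threshold,
                 max_failed_arrays = max_failed_arrays),
            class = "detection_mask")
}

# Map intensities x onto a reference distribution defined by the sorted
# subset values `sub_sorted` -> `ref` (equal lengths): subset members map by
# rank; everything else by linear interpolation between flanking subset
# quantiles, with a constant offset beyond the extremes.
.quantile_map <- function(x, sub_sorted, ref) {
  out <- approx(sub_sorted, ref, xout = x, ties = list("ordered", mean),
                rule = 1)$y
  lo <- x < sub_sorted[1]
  hi <- x > sub_sorted[length(sub_sorted)]
  out[lo] <- ref[1] - (sub_sorted[1] - x[lo])
  out[hi] <- ref[length(ref)] + (x[hi] - sub_sorted[length(sub_sorted)])
  pmax(out, 0)
}

#' Subset-quantile within-array normalization (SWAN)
#'
#' Infinium Type I and Type II probes have systematically different
#' intensity distributions.  SWAN matches them within each array and
#' channel: a random subset of Type I and Type II probes with the same
#' CpG-content composition (strata of 1, 2, and 3+ CpGs in the probe body,
#' equal counts per stratum per type) defines a reference distribution as
#' the pointwise mean of the two subsets' sorted intensities; subset probes
#' are mapped onto the reference by rank, remaining probes by interpolation
#' between flanking subset quantiles (constant offset beyond the extremes).
#'
#' @param M,U intensity matrices (probes x arrays), rows aligned with
#'   `manifest`.
#' @param manifest probe manifest with `design_type` and `n_cpgs` for every
#'   row of `M` (control rows excluded).
#' @param seed integer seed for the subset draw; the same subset is used for
#'   every array and channel of one call.
#' @return List with normalized `M` and `U` matrices, dimensions unchanged.
#' @export
swan_normalize <- function(M, U, manifest, seed = 1L) {
  stopifnot(nrow(M) == nrow(manifest), nrow(U) == nrow(manifest))
  strat <- pmin(manifest$n_cpgs, 3L)
  with_seed(seed, {
    take <- list()
    counts <- table(factor(manifest$design_type, c("I", "II")),
                    factor(strat, 1:3))
    if (any(counts == 0)) {
      bad <- which(counts == 0, arr.ind = TRUE)
      stop("SWAN: no Type ", rownames(counts)[bad[1, 1]],
           " probes in CpG stratum ", colnames(counts)[bad[1, 2]],
           call. = FALSE)
    }
    m <- min(counts)
    for (ty in c("I", "II")) for (s in 1:3) {
      idx <- which(manifest$design_type == ty & strat == s)
      take[[paste(ty, s)]] <- sample(idx, m)
    }
    sub1 <- sort(unlist(take[paste("I", 1:3)], use.names = FALSE))
    sub2 <- sort(unlist(take[paste("II", 1:3)], use.names = FALSE))

    norm_channel <- function(x) {
      out <- x
      for (j in seq_len(ncol(x))) {
        s1 <- sort(x[sub1, j]); s2 <- sort(x[sub2, j])
        ref <- (s1 + s2) / 2
        col <- x[, j]
        # subset probes: exact rank mapping within their own type subset
        r1 <- sub1[order(col[sub1])]; r2 <- sub2[order(col[sub2])]
        newcol <- col
        newcol[r1] <- ref; newcol[r2] <- ref
        rest1 <- setdiff(which(manifest$design_type == "I"), sub1)
        rest2 <- setdiff(which(manifest$design_type == "II"), sub2)
        newcol[rest1] <- .quantile_map(col[rest1], s1, ref)
        newcol[rest2] <- .quantile_map(col[rest2], s2, ref)
        out[, j] <- newcol
      }
      out
    }
    list(M = norm_channel(M), U = norm_channel(U))
  })
}

#' Construct a beta matrix with arm and replicate labels
#'
#' @param values probes x arrays matrix of betas in `[0, 1]`.
#' @param arm character vector, `"BS"`/`"oxBS"` per array.
#' @param replicate integer replicate index per array.
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, arm, replicate) {
  stopifnot(ncol(values) == length(arm), length(arm) == length(replicate))
  if (any(values < 0 | values > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]", call. = FALSE)
  if (!all(arm %in% c("BS", "oxBS")))
    stop("arm labels must be 'BS' or 'oxBS'", call. = FALSE)
  if (anyDuplicated(paste(arm, replicate)))
    stop("duplicated (arm, replicate) pair", call. = FALSE)
  structure(list(values = values, arm = arm, replicate = replicate),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("beta_matrix:", nrow(x$values), "probes x", ncol(x$values),
      "arrays (", sum(x$arm == "BS"), "BS /", sum(x$arm == "oxBS"),
      "oxBS )\n")
  invisible(x)
}

#' Pairwise Pearson correlations between arrays, on the x100 scale
#'
#' The replicate-agreement diagnostic: Pearson correlation of beta columns
#' for every pair of arrays (probes with a missing value dropped pairwise),
#' reported x100 so that perfect agreement prints as 100.
#'
#' @param betas a [beta_matrix()].
#' @return Symmetric arrays x arrays matrix, diagonal 100, with a
#'   `mean_within_arm` attribute giving the average off-diagonal correlation
#'   within the BS arm, within the oxBS arm, and between arms.
#' @export
pairwise_correlation <- function(betas) {
  v <- betas$values
  if (ncol(v) < 2) stop("need at least two arrays", call. = FALSE)
  r <- cor(v, use = "pairwise.complete.obs") * 100
  arm <- betas$arm
  off <- function(sel1, sel2) {
    sub <- r[sel1, sel2, drop = FALSE]
    if (identical(sel1, sel2)) mean(sub[upper.tri(sub)]) else mean(sub)
  }
  attr(r, "mean_within_arm") <- c(
    BS = off(arm == "BS", arm == "BS"),
    oxBS = off(arm == "oxBS", arm == "oxBS"),
    between = off(arm == "BS", arm == "oxBS")
  )
  r
}

#' Run the full preprocessing chain on a simulated or loaded dataset
#'
#' SWAN-normalizes intensities, computes raw-intensity detection p-values
#' against the negative-control background, filters probes undetected in
#' more than `max_failed_arrays` arrays, and converts the surviving
#' normalized intensities to betas.  Detection is assessed on raw
#' intensities because the background model is fitted from raw controls.
#'
#' @param dataset a `sim_dataset` (from [simulate_dataset()] or
#'   [read_fixture()]).
#' @param alpha beta offset, see [compute_beta()].
#' @param det_threshold,max_failed_arrays see [filter_failed_probes()].
#' @param swan logical; apply SWAN normalization.
#' @param seed seed for the SWAN subset draw.
#' @return List: `betas` (a [beta_matrix()] over kept probes), `mask`
#'   (the `detection_mask`), `background`, `probe_id` of kept probes, and
#'   `n_input`/`n_kept`.
#' @export
preprocess_dataset <- function(dataset, alpha = 100, det_threshold = 0.01,
                               max_failed_arrays = 1, swan = TRUE,
                               seed = 1L) {
  stopifnot(inherits(dataset, "sim_dataset"))
  man <- dataset$manifest[is_control == FALSE]
  bg <- fit_background(dataset$negative_controls$M,
                       dataset$negative_controls$U)
  detp <- detection_pvalue(dataset$M, dataset$U, bg)
  mask <- filter_failed_probes(detp, det_threshold, max_failed_arrays)
  if (swan) {
    nrm <- swan_normalize(dataset$M, dataset$U, man, seed = seed)
  } else {
    nrm <- list(M = dataset$M, U = dataset$U)
  }
  b <- compute_beta(nrm$M, nrm$U, alpha)
  keep <- mask$keep
  list(
    betas = beta_matrix(b[keep, , drop = FALSE], dataset$arm,
                        dataset$replicate),
    mask = mask,
    background = bg,
    probe_id = man$probe_id[keep],
    n_input = nrow(man),
    n_kept = sum(keep)
  )
}
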