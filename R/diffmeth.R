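#' Per-probe group means and pooled variance for the BS vs oxBS contrast
#'
#' @param betas a [beta_matrix()] with >= 2 replicates in each arm.
#' @return `data.table` with per-probe `mean_bs`, `mean_oxbs`,
#'   `delta = mean_bs - mean_oxbs`, pooled within-arm sample variance `s_sq`
#'   and its residual degrees of freedom `d = n_bs + n_oxbs - 2`.
#' @export
groupwise_stats <- function(betas) {
  v <- betas$values
  bs <- betas$arm == "BS"
  ox <- betas$arm == "oxBS"
  n1 <- sum(bs); n2 <- sum(ox)
  if (n1 < 2 || n2 < 2)
    stop("need >= 2 replicates per arm to estimate within-group variance ",
         "(have ", n1, " BS, ", n2, " oxBS)", call. = FALSE)
  m1 <- rowMeans(v[, bs, drop = FALSE])
  m2 <- rowMeans(v[, ox, drop = FALSE])
  ss1 <- rowSums((v[, bs, drop = FALSE] - m1)^2)
  ss2 <- rowSums((v[, ox, drop = FALSE] - m2)^2)
  d <- n1 + n2 - 2L
  data.table(
    probe_id = if (!is.null(rownames(v))) rownames(v)
               else sprintf("p%d", seq_len(nrow(v))),
    mean_bs = m1, mean_oxbs = m2, delta = m1 - m2,
    s_sq = (ss1 + ss2) / d, d = d, n_bs = n1, n_oxbs = n2
  )
}

#' Invert the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by Newton iteration on the
#' asymptotically-motivated update, starting from `x0 = 0.5 + 1/y`.
#' Used to moment-match the prior degrees of freedom of the variance
#' hierarchy.
#'
#' @param y positive values; `y <= 0` maps to `Inf` (the trigamma of
#'   infinity is 0).
#' @param tol convergence tolerance on the relative step.
#' @return `x` with `trigamma(x) = y` elementwise.
#' @export
trigamma_inverse <- function(y, tol = 1e-10) {
  x <- rep(NA_real_, length(y))
  x[y <= 0] <- Inf
  big <- is.finite(y) & y > 1e7
  x[big] <- 1 / sqrt(y[big])
  sml <- is.finite(y) & y < 1e-6 & y > 0
  x[sml] <- 1 / y[sml]
  todo <- which(is.na(x))
  if (length(todo)) {
    yy <- y[todo]
    xx <- 0.5 + 1 / yy
    for (i in 1:50) {
      tri <- trigamma(xx)
      dif <- tri * (1 - tri / yy) / psigamma(xx, deriv = 2L)
      xx <- xx + dif
      if (max(abs(dif / xx)) < tol) break
    }
    x[todo] <- xx
  }
  x
}

#' Fit the empirical-Bayes variance hierarchy
#'
#' Assumes per-probe sample variances follow `s_sq ~ s0_sq * chisq_d / d`
#' with a scaled-inverse-chi-square prior of `d0` degrees of freedom on the
#' true variances.  Moment matching on the log scale: with
#' `e = log(s_sq) - digamma(d/2) + log(d/2)`, the excess of `var(e)` over
#' `trigamma(d/2)` estimates `trigamma(d0/2)`, and
#' `s0_sq = exp(mean(e) + digamma(d0/2) - log(d0/2))`.  When the observed
#' dispersion does not exceed what sampling alone explains, `d0 = Inf` and
#' `s0_sq = exp(mean(e))` (complete pooling).
#'
#' @param s_sq per-probe sample variances.
#' @param d residual degrees of freedom (scalar; the paired-arm design gives
#'   every probe the same d).
#' @param var_floor variances below this are floored before taking logs;
#'   far below any realistic beta-scale variance.
#' @return List of class `shrinkage_fit`: `d0`, `s0_sq`, `d`.
#' @export
fit_shrinkage <- function(s_sq, d, var_floor = 1e-8) {
  if (length(d) != 1L) {
    if (length(unique(d)) != 1L)
      stop("per-probe degrees of freedom must be constant", call. = FALSE)
    d <- d[1]
  }
  if (all(s_sq <= 0))
    stop("all sample variances are zero; supply a variance floor or more ",
         "replicates", call. = FALSE)
  z <- log(pmax(s_sq, var_floor))
  e <- z - digamma(d / 2) + log(d / 2)
  ve <- var(e)
  excess <- ve - trigamma(d / 2)
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else if (ve > 1e-15) {
    # under-dispersed but non-degenerate: boundary estimate, all true
    # variances equal; bias-corrected geometric mean under chi-square
    # sampling of s_sq
    d0 <- Inf
    s0_sq <- exp(mean(e))
  } else {
    # all sample variances identical: no sampling scatter to correct for
    d0 <- Inf
    s0_sq <- exp(mean(z))
  }
  structure(list(d0 = d0, s0_sq = s0_sq, d = d), class = "shrinkage_fit")
}

#' Squeeze per-probe variances toward the fitted prior
#'
#' Posterior-mean shrinkage `(d0 * s0_sq + d * s_sq) / (d0 + d)`: equal to
#' `s_sq` when `d0 = 0` (no shrinkage) and to `s0_sq` when `d0 = Inf`
#' (complete pooling).
#'
#' @param s_sq per-probe sample variances.
#' @param fit a [fit_shrinkage()] result (or any list with `d0`, `s0_sq`,
#'   `d`).
#' @return Squeezed variances `s_tilde_sq`.
#' @export
squeeze_variance <- function(s_sq, fit) {
  if (is.infinite(fit$d0)) return(rep(fit$s0_sq, length(s_sq)))
  (fit$d0 * fit$s0_sq + fit$d * s_sq) / (fit$d0 + fit$d)
}

#' Moderated F statistic and p-value for the two-arm contrast
#'
#' `F = delta^2 / (s_tilde_sq * (1/n1 + 1/n2))`, referred to an
#' F distribution on `(1, d + d0)` degrees of freedom -- the empirical-Bayes
#' prior adds `d0` degrees of freedom to the residual `d`.  At `d0 = Inf`
#' the reference distribution is the chi-square on 1 df.  At `d0 = 0` the
#' test is exactly the classical two-sample pooled-variance t-test squared.
#'
#' @param delta per-probe mean difference (BS - oxBS).
#' @param s_tilde_sq squeezed variances, `> 0`.
#' @param n1,n2 replicates per arm.
#' @param fit a `shrinkage_fit` providing `d0` and `d`.
#' @return List with vectors `F` and `p`.
#' @export
moderated_f <- function(delta, s_tilde_sq, n1, n2, fit) {
  stopifnot(all(s_tilde_sq > 0))
  Fstat <- delta^2 / (s_tilde_sq * (1 / n1 + 1 / n2))
  p <- if (is.infinite(fit$d0)) {
    pchisq(Fstat, df = 1, lower.tail = FALSE)
  } else {
    pf(Fstat, df1 = 1, df2 = fit$d + fit$d0, lower.tail = FALSE)
  }
  list(F = Fstat, p = p)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and mapped back to the
#' input order.  Monotone (order-preserving) in p.
#'
#' @param p p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

#' Attach significance calls to per-probe test results
#'
#' @param results `data.table` with at least `q` and `delta`.
#' @param threshold FDR threshold; significant iff `q < threshold`.
#' @return The table with `significant` and `sign`
#'   (`"positive"`/`"negative"`, `NA` at `delta == 0`) columns added, and
#'   counts of significant positive/negative probes in attribute `counts`.
#' @export
call_probes <- function(results, threshold = 0.01) {
  res <- copy(results)
  res[, significant := q < threshold]
  res[, sign := fifelse(delta > 0, "positive",
                        fifelse(delta < 0, "negative", NA_character_))]
  setattr(res, "counts", c(
    positive = res[significant == TRUE & delta > 0, .N],
    negative = res[significant == TRUE & delta < 0, .N]
  ))
  res[]
}

#' Full BS vs oxBS differential test on a beta matrix
#'
#' Chains [groupwise_stats()], [fit_shrinkage()], [squeeze_variance()],
#' [moderated_f()], [bh_fdr()] and [call_probes()].
#'
#' @param betas a [beta_matrix()].
#' @param fdr significance threshold on the BH q-value, default 0.01.
#' @param var_floor see [fit_shrinkage()].
#' @return A `data.table` of per-probe results (`probe_id`, `mean_bs`,
#'   `mean_oxbs`, `delta`, `s_sq`, `s_tilde_sq`, `F`, `p`, `q`,
#'   `significant`, `sign`) with the `shrinkage_fit` in attribute `fit`.
#' @export
diff_test <- function(betas, fdr = 0.01, var_floor = 1e-8) {
  gs <- groupwise_stats(betas)
  fit <- fit_shrinkage(gs$s_sq, gs$d[1], var_floor = var_floor)
  gs[, s_tilde_sq := squeeze_variance(s_sq, fit)]
  ft <- moderated_f(gs$delta, gs$s_tilde_sq, gs$n_bs[1], gs$n_oxbs[1], fit)
  gs[, F := ft$F]
  gs[, p := ft$p]
  gs[, q := bh_fdr(p)]
  out <- call_probes(gs, threshold = fdr)
  setattr(out, "fit", fit)
  setattr(out, "fdr_threshold", fdr)
  out
}
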