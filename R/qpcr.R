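#' 5hmC fraction from a glucosyl-MspI qPCR triplet
#'
#' In the validation assay, beta-glucosyltransferase glucosylates 5hmC at a
#' CCGG site, which blocks MspI cleavage; qPCR across the site then
#' amplifies only uncut (protected) template.  Relative to the undigested
#' control, the protected fraction is `efficiency^-(Cq - Cq_undig)`.  The
#' glucosylated reaction protects 5hmC plus any background resistance; the
#' mock reaction measures background alone; their difference is the 5hmC
#' fraction.  Replicate Cq values are averaged on the Cq scale first.
#' Only Cq differences matter: adding a constant to all three Cqs leaves
#' the result unchanged.
#'
#' @param cq_glu,cq_mock,cq_undig quantification cycles (scalars or
#'   replicate vectors, averaged) for the glucosylated + digested, mock +
#'   digested, and undigested reactions.
#' @param efficiency amplification base per cycle, in `(1, 2]`; 2 = perfect
#'   doubling.
#' @return Signed 5hmC fraction, clamped to `[-1, 1]` (x100 at the
#'   reporting layer).
#' @export
qpcr_5hmc_fraction <- function(cq_glu, cq_mock, cq_undig, efficiency = 2) {
  if (any(efficiency <= 1 | efficiency > 2))
    stop("amplification efficiency must lie in (1, 2]", call. = FALSE)
  g <- mean(cq_glu); m <- mean(cq_mock); u <- mean(cq_undig)
  if (any(c(g, m, u) <= 0)) stop("Cq values must be positive", call. = FALSE)
  r_glu <- efficiency^-(g - u)
  r_mock <- efficiency^-(m - u)
  min(1, max(-1, r_glu - r_mock))
}

#' Read a long-format Cq table and compute per-site 5hmC fractions
#'
#' @param path TSV with columns `site_id`, `condition`
#'   (`glu`/`mock`/`undig`) and `cq`, one row per technical replicate.
#' @param efficiency see [qpcr_5hmc_fraction()].
#' @return `data.table`: `site_id`, mean `cq_glu`/`cq_mock`/`cq_undig`,
#'   `qpcr_5hmc` fraction.
#' @export
read_cq_table <- function(path, efficiency = 2) {
  dt <- fread(path)
  need <- c("site_id", "condition", "cq")
  if (!all(need %in% names(dt)))
    stop("Cq table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(dt$condition), c("glu", "mock", "undig"))
  if (length(bad))
    stop("unknown qPCR condition(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  wide <- dcast(dt, site_id ~ condition, value.var = "cq", fun.aggregate = mean)
  if (!all(c("glu", "mock", "undig") %in% names(wide)) || anyNA(wide))
    stop("every site needs all three conditions (glu, mock, undig)",
         call. = FALSE)
  wide[, qpcr_5hmc := mapply(qpcr_5hmc_fraction, glu, mock, undig,
                             MoreArgs = list(efficiency = efficiency))]
  setnames(wide, c("glu", "mock", "undig"),
           c("cq_glu", "cq_mock", "cq_undig"))[]
}

#' Locate CCGG (MspI) sites near a probe position
#'
#' CCGG is its own reverse complement, so a single forward scan covers both
#' strands.  Sites are returned sorted by distance to the probe's
#' interrogated position (0 when the position falls inside the 4-bp motif),
#' ties broken by start coordinate.
#'
#' @param sequence uppercase ACGTN nucleotide string.
#' @param probe_pos 0-based position of the interrogated C within
#'   `sequence`.
#' @return `data.table`: 0-based motif `start` and `distance` in bp; empty
#'   when the sequence has no CCGG.
#' @export
find_ccgg_sites <- function(sequence, probe_pos) {
  if (grepl("[^ACGTN]", sequence))
    stop("sequence may contain only A, C, G, T, N", call. = FALSE)
  if (probe_pos < 0 || probe_pos >= nchar(sequence))
    stop("probe_pos outside the sequence", call. = FALSE)
  hits <- gregexpr("(?=CCGG)", sequence, perl = TRUE)[[1]]
  if (hits[1] == -1) return(data.table(start = integer(), distance = integer()))
  start <- as.integer(hits) - 1L
  end <- start + 3L
  distance <- ifelse(probe_pos >= start & probe_pos <= end, 0L,
                     pmin(abs(start - probe_pos), abs(probe_pos - end)))
  setorder(data.table(start = start, distance = as.integer(distance)),
           distance, start)[]
}

#' Concordance between array and qPCR 5hmC estimates
#'
#' @param array_levels,qpcr_levels paired per-site 5hmC fractions (same
#'   order; pair by `site_id` upstream).
#' @return List of class `concordance_result`: Pearson `r` (unit scale;
#'   `NA` with fewer than 3 pairs), `n`, and a table of per-site percent
#'   differences relative to qPCR (`(array - qpcr) / qpcr * 100`), with
#'   sites at qPCR exactly 0 excluded from that panel and listed separately
#'   in `zero_qpcr`.
#' @export
concordance <- function(array_levels, qpcr_levels) {
  stopifnot(length(array_levels) == length(qpcr_levels))
  n <- length(array_levels)
  r <- if (n >= 3) cor(array_levels, qpcr_levels) else NA_real_
  nz <- qpcr_levels != 0
  structure(list(
    r = r, n = n,
    percent_difference = data.table(
      array = array_levels[nz], qpcr = qpcr_levels[nz],
      pct_diff = (array_levels[nz] - qpcr_levels[nz]) / qpcr_levels[nz] * 100),
    zero_qpcr = data.table(array = array_levels[!nz])
  ), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("Array vs qPCR concordance over", x$n, "sites: r =",
      format(x$r, digits = 3), "\n")
  invisible(x)
}

#' Pick validation sites spanning the assay's dynamic range
#'
#' Emulates the selection of qPCR validation sites: given per-probe array
#' estimates, picks `n` probes whose estimated 5hmC comes closest to `n`
#' evenly spaced target levels across `range` -- including negative
#' estimates, which are exactly the calls the orthogonal assay should show
#' to cluster around zero.
#'
#' @param estimates an [estimate_levels()] table.
#' @param n number of sites, default 27.
#' @param range target level range (fractions), default `c(-0.05, 0.40)`.
#' @return Row indices into `estimates`.
#' @export
select_validation_sites <- function(estimates, n = 27,
                                    range = c(-0.05, 0.40)) {
  lev <- estimates$level_5hmc
  targets <- seq(range[1], range[2], length.out = n)
  picked <- integer(0)
  for (t in targets) {
    o <- order(abs(lev - t))
    picked <- c(picked, setdiff(o, picked)[1])
  }
  picked
}

#' Simulate qPCR Cq triplets for sites with known 5hmC fractions
#'
#' Inverts the protection model: the glucosylated reaction protects
#' `true_frac + mock_protection` of the template, the mock reaction
#' `mock_protection`, and each reaction's Cq is derived from its protected
#' fraction relative to an undigested baseline, plus Gaussian technical
#' noise on the Cq scale.
#'
#' @param true_frac true 5hmC fractions per site (negatives are treated as
#'   zero template protection above background).
#' @param efficiency amplification base.
#' @param cq_undig baseline undigested Cq.
#' @param mock_protection background fraction resisting digestion.
#' @param cq_sd technical Cq noise SD.
#' @param n_reps technical replicates per condition.
#' @param seed RNG seed.
#' @return Long-format `data.table` (`site_id`, `condition`, `cq`) suitable
#'   for [read_cq_table()]'s arithmetic via [qpcr_5hmc_fraction()].
#' @export
simulate_qpcr <- function(true_frac, efficiency = 2, cq_undig = 20,
                          mock_protection = 0.02, cq_sd = 0.05, n_reps = 3,
                          seed = 1L) {
  with_seed(seed, {
    n <- length(true_frac)
    prot_glu <- pmin(pmax(true_frac, 0) + mock_protection, 0.999)
    prot_mock <- rep(mock_protection, n)
    cq_of <- function(prot) cq_undig - log(prot) / log(efficiency)
    rows <- list()
    for (i in seq_len(n)) {
      site <- sprintf("site%02d", i)
      rows[[length(rows) + 1L]] <- data.table(
        site_id = site,
        condition = rep(c("glu", "mock", "undig"), each = n_reps),
        cq = c(cq_of(prot_glu[i]) + rnorm(n_reps, 0, cq_sd),
               cq_of(prot_mock[i]) + rnorm(n_reps, 0, cq_sd),
               cq_undig + rnorm(n_reps, 0, cq_sd))
      )
    }
    rbindlist(rows)
  })
}
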