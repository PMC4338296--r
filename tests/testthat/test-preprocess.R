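test_that("compute_beta follows the platform convention", {
  expect_equal(compute_beta(600, 300, 100), 0.600)
  expect_equal(compute_beta(0, 0, 100), 0)
  expect_equal(compute_beta(450, 450, 0), 0.5)
  expect_equal(compute_beta(0, 0, 0), 0)       # zero-denominator convention
  expect_equal(compute_beta(3, 1, 0), 3 / 4)   # exact rationals
  x <- compute_beta(runif(1000, 0, 1e4), runif(1000, 0, 1e4), 100)
  expect_true(all(x >= 0 & x < 1))
  expect_error(compute_beta(-1, 5, 100), "non-negative")
})

test_that("detection p-values are calibrated against the background model", {
  bg <- data.table::data.table(array = "a1", mu_bg = 500, sigma_bg = 50)
  p_at <- function(tot) detection_pvalue(matrix(tot, 1, 1, dimnames = list("p", "a1")),
                                         matrix(0, 1, 1, dimnames = list("p", "a1")),
                                         bg)[1, 1]
  expect_equal(p_at(500), 0.5)
  expect_lt(p_at(500 + 10 * 50), 1e-15)
  expect_gt(p_at(0), 1 - 1e-15)
  # monotone decreasing in total intensity
  tots <- seq(0, 2000, by = 50)
  expect_true(all(diff(vapply(tots, p_at, 0)) <= 0))
  expect_error(fit_background(NULL, NULL), "negative-control")
})

test_that("failed-probe filter excludes probes undetected in more than one array", {
  detp <- matrix(0, 3, 8)
  detp[1, c(2, 5)] <- 0.5   # fails twice -> excluded
  detp[2, 4] <- 0.02        # fails once -> kept
  mask <- filter_failed_probes(detp, threshold = 0.01, max_failed_arrays = 1)
  expect_identical(mask$keep, c(FALSE, TRUE, TRUE))

  all_pass <- filter_failed_probes(matrix(1e-6, 5, 4))
  expect_true(all(all_pass$keep))
})

test_that("failed-probe filter agrees with a brute-force count", {
  set.seed(42)
  for (i in 1:20) {
    detp <- matrix(runif(80, 0, 0.03), 10, 8)
    thr <- runif(1, 0.005, 0.02)
    mx <- sample(0:3, 1)
    mask <- filter_failed_probes(detp, thr, mx)
    brute <- logical(10)
    for (pr in 1:10) {
      nf <- 0
      for (a in 1:8) if (detp[pr, a] >= thr) nf <- nf + 1
      brute[pr] <- nf <= mx
    }
    expect_identical(mask$keep, brute)
  }
})

swan_fixture <- function(n = 240, seed = 21, balanced = TRUE) {
  set.seed(seed)
  # balanced: every (type, stratum) cell has n/6 probes, so the SWAN subset
  # covers every probe and the rank-mapping path alone is exercised
  n_cpgs_half <- if (balanced) rep(1:3, each = n / 6)
                 else sample(1:3, n / 2, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  manifest <- data.table::data.table(
    probe_id = sprintf("p%03d", 1:n),
    design_type = rep(c("I", "II"), each = n / 2),
    n_cpgs = rep(n_cpgs_half, 2))
  list(manifest = manifest,
       M = matrix(rlnorm(n * 2, log(3000), 0.4), n, 2,
                  dimnames = list(manifest$probe_id, c("a1", "a2"))),
       U = matrix(rlnorm(n * 2, log(3000), 0.4), n, 2,
                  dimnames = list(manifest$probe_id, c("a1", "a2"))))
}

test_that("SWAN is a fixed point when type distributions already agree", {
  fx <- swan_fixture()
  # give Type I and Type II probes identical intensity multisets per stratum
  man <- fx$manifest
  for (s in 1:3) for (ch in c("M", "U")) for (j in 1:2) {
    i1 <- which(man$design_type == "I" & man$n_cpgs == s)
    i2 <- which(man$design_type == "II" & man$n_cpgs == s)
    fx[[ch]][i2, j] <- sample(fx[[ch]][i1, j])
  }
  out <- swan_normalize(fx$M, fx$U, man, seed = 1)
  expect_equal(out$M, fx$M, tolerance = 1e-12)
  expect_equal(out$U, fx$U, tolerance = 1e-12)
})

test_that("SWAN matches type subsets exactly at subset ranks and preserves order", {
  fx <- swan_fixture(seed = 22)
  out <- swan_normalize(fx$M, fx$U, fx$manifest, seed = 5)
  man <- fx$manifest
  # with balanced strata every probe is in the subset: sorted Type I and
  # Type II intensities must agree exactly per array and channel
  for (ch in c("M", "U")) for (j in 1:2) {
    v <- out[[ch]][, j]
    expect_equal(unname(sort(v[man$design_type == "I"])),
                 unname(sort(v[man$design_type == "II"])), tolerance = 1e-12)
    # rank order within each type preserved
    for (ty in c("I", "II")) {
      idx <- man$design_type == ty
      expect_identical(order(fx[[ch]][idx, j]), order(out[[ch]][idx, j]))
    }
  }
  expect_true(all(out$M >= 0) && all(out$U >= 0))
  # determinism in the subset draw
  out2 <- swan_normalize(fx$M, fx$U, fx$manifest, seed = 5)
  expect_identical(out, out2)
  # an empty stratum is reported by name
  man_bad <- data.table::copy(man)[design_type == "I" & n_cpgs == 2,
                                   n_cpgs := 1L]
  expect_error(swan_normalize(fx$M, fx$U, man_bad, seed = 1), "stratum 2")
})

test_that("SWAN interpolation keeps within-type order and non-negativity", {
  fx <- swan_fixture(seed = 24, balanced = FALSE)
  out <- swan_normalize(fx$M, fx$U, fx$manifest, seed = 6)
  man <- fx$manifest
  for (ch in c("M", "U")) for (j in 1:2) for (ty in c("I", "II")) {
    idx <- man$design_type == ty
    expect_identical(order(fx[[ch]][idx, j]), order(out[[ch]][idx, j]))
  }
  expect_true(all(out$M >= 0) && all(out$U >= 0))
  expect_identical(dim(out$M), dim(fx$M))
})

test_that("pairwise correlations are reported on the x100 scale", {
  x <- runif(500)
  bm <- make_betas(list(x, x), list(1 - x, runif(500)))
  r <- pairwise_correlation(bm)
  expect_equal(unname(diag(r)), rep(100, 4))
  expect_equal(r[1, 2], 100)
  expect_equal(r[1, 3], -100)
  expect_equal(r, t(r))
  expect_error(pairwise_correlation(beta_matrix(matrix(x, ncol = 1), "BS", 1)),
               "two arrays")
})

test_that("preprocessing accounts for every probe and flags failed cells", {
  ds <- calibrated_sim(n_probes = 3000, seed = 23, fail_rate = 0.05)
  pp <- preprocess_dataset(ds)
  expect_equal(pp$n_input, 3000)
  expect_equal(pp$n_kept + sum(!pp$mask$keep), pp$n_input)
  expect_lt(pp$n_kept, pp$n_input)  # 5% cell failures must cost some probes
  expect_equal(nrow(pp$betas$values), pp$n_kept)
  expect_true(all(pp$betas$values >= 0 & pp$betas$values <= 1))
})

test_that("beta_matrix validates its labels", {
  v <- matrix(0.5, 2, 2)
  expect_error(beta_matrix(v, c("BS", "BS"), c(1, 1)), "duplicated")
  expect_error(beta_matrix(v, c("BS", "x"), c(1, 2)), "arm")
  expect_error(beta_matrix(v * 3, c("BS", "oxBS"), c(1, 1)), "\\[0, 1\\]")
})
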