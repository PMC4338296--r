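test_that("groupwise statistics pool within-arm variance", {
  bm <- make_betas(list(c(0.5, 0.5), c(0.5, 0.5)), list(c(0.4, 0.4), c(0.4, 0.4)))
  gs <- groupwise_stats(bm)
  expect_equal(gs$delta, c(0.1, 0.1))
  expect_equal(gs$s_sq, c(0, 0))
  expect_equal(gs$d, c(2L, 2L))

  bm2 <- make_betas(list(0.6, 0.4), list(0.5, 0.5))
  gs2 <- groupwise_stats(bm2)
  expect_equal(gs2$delta, 0)
  expect_equal(gs2$s_sq, 0.01)  # ((0.1^2 + 0.1^2) + 0) / 2

  # exchangeability within arms
  v <- matrix(runif(40), 5, 8)
  arm <- rep(c("BS", "oxBS"), each = 4)
  a <- groupwise_stats(beta_matrix(v, arm, c(1:4, 1:4)))
  b <- groupwise_stats(beta_matrix(v[, c(3, 1, 4, 2, 6, 5, 8, 7)], arm,
                                   c(1:4, 1:4)))
  expect_equal(a$delta, b$delta)
  expect_equal(a$s_sq, b$s_sq)

  expect_error(groupwise_stats(make_betas(list(0.5), list(0.4, 0.4))),
               "2 replicates")
})

test_that("trigamma inversion round-trips against the function", {
  v <- 10^seq(log10(1e-4), log10(10), length.out = 60)
  x <- trigamma_inverse(v)
  expect_equal(trigamma(x), v, tolerance = 1e-8)
  expect_identical(trigamma_inverse(0), Inf)
})

test_that("variance hierarchy recovers a scaled chi-square prior", {
  set.seed(31)
  s2 <- 4e-4 * rchisq(50000, df = 6) / 6
  fit <- fit_shrinkage(s2, d = 6)
  expect_lt(abs(fit$s0_sq / 4e-4 - 1), 0.05)
  expect_gt(fit$d0, 50)  # single-component prior: large d0 is correct

  # degenerate dispersion: complete pooling
  fit_eq <- fit_shrinkage(rep(3e-4, 500), d = 6)
  expect_identical(fit_eq$d0, Inf)
  expect_equal(squeeze_variance(rep(3e-4, 500), fit_eq), rep(3e-4, 500))

  expect_error(fit_shrinkage(rep(0, 100), d = 6), "zero")
})

test_that("variance squeezing interpolates between no pooling and complete pooling", {
  s2 <- c(1e-4, 6e-4)
  expect_equal(squeeze_variance(s2, list(d0 = 0, s0_sq = 2e-4, d = 6)), s2)
  expect_equal(squeeze_variance(s2, list(d0 = Inf, s0_sq = 2e-4, d = 6)),
               rep(2e-4, 2))
  expect_equal(squeeze_variance(6e-4, list(d0 = 6, s0_sq = 2e-4, d = 6)), 4e-4)
})

test_that("moderated F reduces to the classical pooled t-test at d0 = 0", {
  x <- c(0.62, 0.55, 0.60)
  y <- c(0.48, 0.52, 0.45)
  gs <- groupwise_stats(make_betas(as.list(x), as.list(y)))
  fit <- list(d0 = 0, s0_sq = 1, d = gs$d)
  mf <- moderated_f(gs$delta, gs$s_sq, 3, 3, fit)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(mf$p, tt$p.value, tolerance = 1e-12)
  expect_equal(mf$F, unname(tt$statistic^2), tolerance = 1e-12)

  expect_equal(moderated_f(0, 1e-4, 4, 4, fit), list(F = 0, p = 1))
  # scaling law: doubling the effect quadruples F
  f1 <- moderated_f(0.1, 1e-4, 4, 4, fit)$F
  f2 <- moderated_f(0.2, 1e-4, 4, 4, fit)$F
  expect_equal(f2 / f1, 4)
  # p monotone decreasing in |delta|
  ps <- moderated_f(seq(0, 0.3, by = 0.02), 1e-4, 4, 4,
                    list(d0 = 4, s0_sq = 1e-4, d = 6))$p
  expect_true(all(diff(ps) <= 0))
})

test_that("shrinkage fit and squeeze agree with an independent implementation", {
  skip_if_not_installed("limma")
  set.seed(32)
  s2 <- exp(rnorm(20000, log(3e-4), 0.8))
  fit <- fit_shrinkage(s2, d = 6)
  ref <- limma::squeezeVar(s2, df = 6)
  expect_equal(fit$d0, ref$df.prior, tolerance = 0.05)
  expect_equal(fit$s0_sq, ref$var.prior, tolerance = 0.05)
  expect_equal(squeeze_variance(s2, fit), ref$var.post, tolerance = 0.05)
})

test_that("BH step-up matches hand evaluation, brute force and p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      best <- Inf
      for (j in i:m) best <- min(best, p[o[j]] * m / j)
      q[o[i]] <- min(1, best)
    }
    q
  }
  set.seed(33)
  for (i in 1:1000) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, brute_bh(p), tolerance = 1e-14)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-14)
  }
})

test_that("significance calls split by threshold and sign", {
  res <- data.table::data.table(q = c(0.009, 0.009, 0.011, 0.5),
                                delta = c(0.05, -0.03, 0.4, 0))
  out <- call_probes(res, threshold = 0.01)
  expect_identical(out$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(out$sign, c("positive", "negative", "positive", NA))
  expect_identical(attr(out, "counts"), c(positive = 1L, negative = 1L))
})

test_that("pure-null simulations stay within the nominal FDR", {
  # all probes carry zero 5hmC: BH at 1% must call on average <= 1% of probes
  frac_called <- vapply(1:20, function(s) {
    ds <- simulate_dataset(sim_config(n_probes = 50000, seed = 100 + s,
                                      pi0 = 1))
    res <- diff_test(raw_betas(ds))
    mean(res$significant)
  }, 0)
  expect_lte(mean(frac_called), 0.01)
})
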