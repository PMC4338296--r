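test_that("gene-feature annotation honours the 1 kb flank and precedence", {
  genes <- tiny_gene_model()
  # + strand gene gp: TSS at 10000; - strand gene gm: TSS at 52000
  pos <- c(9500,   # 500 bp 5' of gp TSS -> upstream
           10900,  # inside gp intron
           11700,  # gp 3'UTR
           12500,  # 500 bp past gp TTS -> downstream
           30000,  # 10 kb from anything -> intergenic
           52400,  # 400 bp 5' of gm TSS (minus strand) -> upstream
           49500,  # past gm TTS on minus strand -> downstream
           50100,  # inside gm body, no feature -> other
           10100)  # gp 5'UTR
  cat <- annotate_gene_regions(probes_at(pos), genes)
  expect_identical(cat, c("upstream", "intron", "3utr", "downstream",
                          "intergenic", "upstream", "downstream", "other",
                          "5utr"))

  # UTR rows also covered by an exon row: UTR wins
  g2 <- data.table::data.table(
    chrom = "chrT", start = c(1000L, 1000L, 1000L), end = c(3000L, 1200L, 1400L),
    name = c("gx:tx", "gx:5utr", "gx:exon"), score = 0L, strand = "+")
  expect_identical(annotate_gene_regions(probes_at(1100), g2), "5utr")
  expect_identical(annotate_gene_regions(probes_at(1300), g2), "exon")
})

test_that("island context follows the 0-2 kb shore and 2-4 kb shelf bands", {
  islands <- data.table::data.table(chrom = "chrT", start = 20000L,
                                    end = 21000L)
  ctx <- function(p) annotate_island_context(probes_at(p), islands)
  expect_identical(ctx(20500), "island")
  expect_identical(ctx(19999), "shore")    # 1 bp off the start edge
  expect_identical(ctx(21000 + 1499), "shore")
  expect_identical(ctx(21000 + 1999), "shore")
  expect_identical(ctx(21000 + 2000), "shelf")
  expect_identical(ctx(21000 + 3999), "shelf")  # 4000 bp away: still shelf
  expect_identical(ctx(21000 + 4000), "open_sea")
  # overlapping islands are merged before distances are taken
  both <- data.table::data.table(chrom = "chrT",
                                 start = c(20000L, 20800L),
                                 end = c(21000L, 21600L))
  expect_identical(annotate_island_context(probes_at(21300), both), "island")
})

test_that("interval annotation agrees with a brute-force scan", {
  set.seed(51)
  for (rep in 1:5) {
    n_isl <- sample(3:30, 1)
    starts <- sort(sample.int(200000, n_isl))
    islands <- data.table::data.table(chrom = "chrT", start = starts,
                                      end = starts + sample(200:2000, n_isl,
                                                            replace = TRUE))
    probes <- probes_at(sample.int(210000, 400))
    got <- annotate_island_context(probes, islands)
    # brute force over merged intervals
    brute <- vapply(probes$pos, function(p) {
      d <- Inf
      for (i in seq_len(n_isl)) {
        s <- islands$start[i]; e <- islands$end[i]
        di <- if (p >= s && p < e) 0 else if (p < s) s - p else p - e + 1
        d <- min(d, di)
      }
      if (d == 0) "island" else if (d <= 2000) "shore"
      else if (d <= 4000) "shelf" else "open_sea"
    }, "")
    expect_identical(got, brute)
  }
})

test_that("annotation is a partition and matches the simulator's own labels", {
  tr <- simulate_truth(sim_config(n_probes = 4000, seed = 52))
  gc <- annotate_gene_regions(tr, attr(tr, "genes"))
  ic <- annotate_island_context(tr, attr(tr, "islands"))
  expect_false(anyNA(gc))
  expect_false(anyNA(ic))
  # independent arithmetic in the simulator assigned the same labels
  expect_identical(gc, tr$region_label)
  expect_identical(ic, tr$island_context)
})

test_that("regional summaries conserve counts and are order-invariant", {
  set.seed(53)
  n <- 500
  est <- data.table::data.table(
    probe_id = sprintf("p%03d", 1:n),
    level_5mc = runif(n), level_5hmc = runif(n, -0.1, 0.4),
    level_c = 0, significant = runif(n) < 0.3,
    sign = "positive")
  cats <- sample(c("island", "shore", "open_sea"), n, replace = TRUE)
  s <- summarize_by_region(est, cats)
  expect_equal(sum(s$n), n)
  expect_true(all(s$prop_sig_pos >= 0 & s$prop_sig_pos <= 1))
  expect_equal(sum(s$n_sig_pos), sum(est$significant & est$level_5hmc > 0))

  perm <- sample(n)
  s2 <- summarize_by_region(est[perm], cats[perm])
  expect_equal(s, s2)

  one <- summarize_by_region(est, rep("exon", n))
  expect_equal(one$n, n)
})

test_that("island-low methylation structure survives the full pipeline", {
  ds <- calibrated_sim(n_probes = 8000, seed = 54)
  bm <- raw_betas(ds)
  est <- estimate_levels(bm, diff_test(bm))
  ic <- annotate_island_context(ds$truth, ds$islands)
  s <- summarize_by_region(est, ic)
  expect_lt(s[s$category == "island", ]$mc_median,
            s[s$category == "open_sea", ]$mc_median)
})

test_that("TSS profile uses signed strand-aware distances", {
  genes <- tiny_gene_model()
  # probes 300 bp upstream / 300 bp downstream of each TSS
  probes <- probes_at(c(9700, 10300, 52300, 51700))
  est <- data.table::data.table(level_5mc = c(0.1, 0.2, 0.3, 0.4),
                                level_5hmc = 0.05)
  prof <- tss_profile(probes, genes, est, bin_bp = 200)
  # upstream probes (both strands) fall in the [-400, -200) bin
  expect_true(all(c(-400, 200) %in% prof$bin_start))
  up <- prof[prof$bin_start == -400, ]
  expect_equal(up$n, 2L)
  expect_equal(up$mc_median, median(c(0.1, 0.3)))
  dn <- prof[prof$bin_start == 200, ]
  expect_equal(dn$n, 2L)
})

test_that("malformed BED input is reported with a line number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t300\t250"), f)
  expect_error(read_bed(f), "line 2")
})
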