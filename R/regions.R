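#' Read a BED file (3 or 6 columns, 0-based half-open)
#'
#' @param path BED file path.
#' @return `GRanges` (1-based closed internally, as usual for Bioconductor);
#'   BED6 name/score/strand carried through, with malformed rows reported by
#'   line number.
#' @export
read_bed <- function(path) {
  dt <- tryCatch(fread(path, header = FALSE, sep = "\t"),
                 error = function(e) stop("cannot parse BED file ", path,
                                          ": ", conditionMessage(e),
                                          call. = FALSE))
  if (ncol(dt) < 3)
    stop("malformed BED ", path, ": fewer than 3 columns", call. = FALSE)
  names(dt)[1:3] <- c("chrom", "start", "end")
  bad <- which(!is.numeric(dt$start) | !is.numeric(dt$end) |
                 dt$start < 0 | dt$end <= dt$start)
  if (length(bad))
    stop("malformed BED ", path, ": invalid interval at line ", bad[1],
         call. = FALSE)
  gr <- GenomicRanges::GRanges(
    dt$chrom,
    IRanges::IRanges(start = dt$start + 1L, end = dt$end),
    strand = if (ncol(dt) >= 6) dt[[6]] else "*"
  )
  if (ncol(dt) >= 4) gr$name <- dt[[4]]
  gr
}

# BED6 gene features with name "<gene>:<feature>"; feature "tx" marks the
# transcript body (strand-aware TSS/TTS source).
.gene_granges <- function(genes) {
  gr <- if (inherits(genes, "GRanges")) genes else {
    GenomicRanges::GRanges(genes$chrom,
                           IRanges::IRanges(genes$start + 1L, genes$end),
                           strand = genes$strand, name = genes$name)
  }
  parts <- strsplit(gr$name, ":", fixed = TRUE)
  gr$gene_id <- vapply(parts, `[`, "", 1L)
  gr$feature <- vapply(parts, function(p) p[length(p)], "")
  gr
}

.probe_granges <- function(probes) {
  GenomicRanges::GRanges(probes$chrom,
                         IRanges::IRanges(probes$pos + 1L, width = 1L))
}

#' Assign each probe one gene-feature category
#'
#' Categories: `5utr`, `3utr`, `exon`, `intron`, `upstream`, `downstream`,
#' `other`, `intergenic`.  Upstream/downstream are strand-aware `flank_bp`
#' windows off the transcript 5' and 3' ends.  Probes overlapping multiple
#' features take the highest-precedence one
#' (5'UTR > 3'UTR > exon > intron > upstream > downstream), across all
#' overlapping genes; probes inside a transcript body but in none of its
#' defined features are `other`; probes touching no gene or flank are
#' `intergenic`.
#'
#' @param probes manifest-like table with `chrom` and 0-based `pos`.
#' @param genes gene model: BED6 `data.table`/`GRanges` with
#'   `name = "<gene>:<feature>"` rows (`tx`, `5utr`, `exon`, `intron`,
#'   `3utr`), or a path readable by [read_bed()].
#' @param flank_bp upstream/downstream window, default 1000.
#' @return Character vector of categories, one per probe.
#' @export
annotate_gene_regions <- function(probes, genes, flank_bp = 1000) {
  if (is.character(genes) && length(genes) == 1L) genes <- read_bed(genes)
  gr <- .gene_granges(genes)
  pg <- .probe_granges(probes)
  tx <- gr[gr$feature == "tx"]
  cat <- rep(NA_character_, length(pg))
  hit <- function(target) {
    IRanges::overlapsAny(pg, target, ignore.strand = TRUE)
  }
  sets <- list(
    `5utr` = gr[gr$feature == "5utr"],
    `3utr` = gr[gr$feature == "3utr"],
    exon = gr[gr$feature == "exon"],
    intron = gr[gr$feature == "intron"],
    upstream = GenomicRanges::flank(tx, flank_bp, start = TRUE),
    downstream = GenomicRanges::flank(tx, flank_bp, start = FALSE)
  )
  for (nm in names(sets)) {
    idx <- is.na(cat) & hit(sets[[nm]])
    cat[idx] <- nm
  }
  cat[is.na(cat) & hit(tx)] <- "other"
  cat[is.na(cat)] <- "intergenic"
  cat
}

#' Assign each probe a CpG island context
#'
#' Distance to the nearest merged island edge classifies each probe:
#' 0 (inside) -> `island`; 1..`shore_bp` -> `shore`;
#' `shore_bp`+1..`shelf_bp` -> `shelf`; beyond -> `open_sea` (half-open
#' outer boundaries: a probe exactly `shelf_bp` away is still shelf).
#'
#' @param probes manifest-like table with `chrom` and 0-based `pos`.
#' @param islands BED3 `data.table`/`GRanges` of islands (merged on load),
#'   or a path readable by [read_bed()].
#' @param shore_bp,shelf_bp outer shore/shelf distances, defaults 2000 and
#'   4000 bp.
#' @return Character vector: `island`, `shore`, `shelf` or `open_sea`.
#' @export
annotate_island_context <- function(probes, islands, shore_bp = 2000,
                                    shelf_bp = 4000) {
  if (is.character(islands) && length(islands) == 1L)
    islands <- read_bed(islands)
  igr <- if (inherits(islands, "GRanges")) islands else
    GenomicRanges::GRanges(islands$chrom,
                           IRanges::IRanges(islands$start + 1L, islands$end))
  igr <- GenomicRanges::reduce(igr, ignore.strand = TRUE)
  pg <- .probe_granges(probes)
  ctx <- rep("open_sea", length(pg))
  if (!length(igr)) return(ctx)
  nd <- GenomicRanges::distanceToNearest(pg, igr, ignore.strand = TRUE)
  d <- rep(NA_real_, length(pg))
  # GRanges distance is the gap; nearest-edge bp distance is gap + 1 for
  # non-overlapping pairs and 0 inside
  gap <- S4Vectors::mcols(nd)$distance
  d[S4Vectors::queryHits(nd)] <- ifelse(gap == 0, 0, gap + 1)
  ov <- IRanges::overlapsAny(pg, igr, ignore.strand = TRUE)
  d[ov] <- 0
  # gap == 0 also occurs for immediately adjacent (1 bp away) probes
  adj <- !ov & !is.na(d) & d == 0
  d[adj] <- 1
  ctx[!is.na(d) & d == 0] <- "island"
  ctx[!is.na(d) & d > 0 & d <= shore_bp] <- "shore"
  ctx[!is.na(d) & d > shore_bp & d <= shelf_bp] <- "shelf"
  ctx
}

#' Summarize modification levels by annotation category
#'
#' @param estimates an [estimate_levels()] table with significance calls.
#' @param categories character vector (one per estimate row), e.g. from
#'   [annotate_gene_regions()] or [annotate_island_context()].
#' @return `data.table`, one row per category: probe count, count and
#'   proportion of significant positive 5hmC probes, and median/quartiles of
#'   `level_5mc` and `level_5hmc`.
#' @export
summarize_by_region <- function(estimates, categories) {
  stopifnot(length(categories) == nrow(estimates))
  dt <- copy(estimates)[, category := categories]
  out <- dt[, {
    sp <- significant == TRUE & level_5hmc > 0
    list(n = .N,
         n_sig_pos = sum(sp),
         prop_sig_pos = mean(sp),
         mc_q25 = quantile(level_5mc, 0.25, names = FALSE),
         mc_median = median(level_5mc),
         mc_q75 = quantile(level_5mc, 0.75, names = FALSE),
         hmc_q25 = quantile(level_5hmc, 0.25, names = FALSE),
         hmc_median = median(level_5hmc),
         hmc_q75 = quantile(level_5hmc, 0.75, names = FALSE))
  }, by = category]
  setorder(out, category)[]
}

#' Modification profile around transcription start sites
#'
#' Bins probes by signed distance to the nearest strand-aware TSS (negative
#' = upstream of the gene) and reports median 5mC and 5hmC per bin.
#'
#' @param probes manifest-like table with `chrom` and 0-based `pos`, rows
#'   aligned with `estimates`.
#' @param genes gene model as in [annotate_gene_regions()]; TSSs are the 5'
#'   ends of its `tx` rows.
#' @param estimates an [estimate_levels()] table.
#' @param bin_bp bin width, default 200 bp.
#' @param max_bp profile half-width, default 4000 bp.
#' @return `data.table`: `bin_start` (signed bp), `bin_mid`, `n`,
#'   `mc_median`, `hmc_median`.
#' @export
tss_profile <- function(probes, genes, estimates, bin_bp = 200,
                        max_bp = 4000) {
  if (is.character(genes) && length(genes) == 1L) genes <- read_bed(genes)
  gr <- .gene_granges(genes)
  tx <- gr[gr$feature == "tx"]
  tss_pos <- ifelse(as.character(GenomicRanges::strand(tx)) == "-",
                    GenomicRanges::end(tx), GenomicRanges::start(tx))
  tss <- GenomicRanges::GRanges(GenomicRanges::seqnames(tx),
                                IRanges::IRanges(tss_pos, width = 1L))
  pg <- .probe_granges(probes)
  nd <- GenomicRanges::nearest(pg, tss, ignore.strand = TRUE)
  ok <- !is.na(nd)
  signed <- rep(NA_real_, length(pg))
  delta_bp <- GenomicRanges::start(pg)[ok] - tss_pos[nd[ok]]
  neg <- as.character(GenomicRanges::strand(tx))[nd[ok]] == "-"
  signed[ok] <- ifelse(neg, -delta_bp, delta_bp)
  dt <- data.table(signed = signed,
                   level_5mc = estimates$level_5mc,
                   level_5hmc = estimates$level_5hmc)
  dt <- dt[!is.na(signed) & abs(signed) <= max_bp]
  dt[, bin_start := floor(signed / bin_bp) * bin_bp]
  out <- dt[, .(n = .N, mc_median = median(level_5mc),
                hmc_median = median(level_5hmc)), by = bin_start]
  out[, bin_mid := bin_start + bin_bp / 2]
  setorder(out, bin_start)[]
}
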