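#' Assign regions to proximal genes
#'
#' A region is assigned to every gene whose genic-or-upstream footprint
#' (gene body plus up to 5 kb upstream of the TSS: upstream_1to5kb,
#' promoter, 5'UTR, exon, intron, 3'UTR) it overlaps by at least 1 bp.
#' Regions overlapping no footprint (intergenic) are never assigned. When a
#' region touches several feature types of one gene, the reported feature is
#' the highest-priority one (promoter > five_utr > exon > intron >
#' three_utr > upstream_1to5kb).
#'
#' @param regions `GRanges` or data.frame (chrom/start/end, BED convention).
#' @param genes a `GeneModelSet`.
#' @return data.frame: chrom, start, end, gene_id, feature — one row per
#'   (region, gene) pair.
#' @export
assign_proximal_genes <- function(regions, genes) {
  if (is.data.frame(regions)) {
    regions <- bed_granges(regions$chrom, regions$start, regions$end)
  }
  fg <- gene_feature_granges(genes)
  hits <- GenomicRanges::findOverlaps(regions, fg, ignore.strand = TRUE)
  if (!length(hits)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), gene_id = character(),
                      feature = character()))
  }
  qh <- S4Vectors::queryHits(hits)
  prio <- c(promoter = 1, five_utr = 2, exon = 3, intron = 4, three_utr = 5,
            upstream_1to5kb = 6)
  df <- data.frame(
    region = qh,
    gene_id = S4Vectors::mcols(fg)$gene_id[S4Vectors::subjectHits(hits)],
    feature = S4Vectors::mcols(fg)$feature[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  df <- df[order(df$region, df$gene_id, prio[df$feature]), , drop = FALSE]
  df <- df[!duplicated(df[c("region", "gene_id")]), , drop = FALSE]
  bed <- granges_bed(regions)
  out <- data.frame(chrom = bed$chrom[df$region], start = bed$start[df$region],
                    end = bed$end[df$region], gene_id = df$gene_id,
                    feature = df$feature, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter a differential-expression table to significant genes
#'
#' Both cutoffs are strict: |log2fc| > lfc_threshold and
#' padj < padj_threshold.
#'
#' @param deg data.frame with gene_id, log2fc, padj (see [read_track()]).
#' @param lfc_threshold minimum |log2 fold change| (default 1.5).
#' @param padj_threshold maximum adjusted p (default 0.05).
#' @return character vector of gene ids.
#' @export
deg_filter <- function(deg, lfc_threshold = 1.5, padj_threshold = 0.05) {
  unique(deg$gene_id[abs(deg$log2fc) > lfc_threshold &
                       deg$padj < padj_threshold])
}

#' Hypergeometric overlap test of two gene sets in a universe
#'
#' Enrichment p is the upper tail P(X >= observed) of the hypergeometric
#' distribution; depletion is reported separately as the lower tail
#' P(X <= observed). The expected overlap is n1 * n2 / N.
#'
#' @param set1,set2 character vectors (will be intersected with universe).
#' @param universe character vector defining the universe.
#' @return data.frame with one row: n1, n2, N, observed, expected, p_enrich,
#'   p_deplete.
#' @export
overlap_test <- function(set1, set2, universe) {
  s1 <- unique(intersect(set1, universe))
  s2 <- unique(intersect(set2, universe))
  hyper_overlap(length(s1), length(s2), length(unique(universe)),
                length(intersect(s1, s2)))
}

#' Hypergeometric overlap test from set sizes
#'
#' @param n1,n2 sizes of the two sets.
#' @param N universe size.
#' @param observed overlap size.
#' @return see [overlap_test()].
#' @export
hyper_overlap <- function(n1, n2, N, observed) {
  stopifnot(n1 <= N, n2 <= N, observed <= min(n1, n2), N >= 1)
  expected <- n1 * n2 / N
  p_enrich <- if (n1 == 0 || n2 == 0) 1 else {
    stats::phyper(observed - 1, n2, N - n2, n1, lower.tail = FALSE)
  }
  p_deplete <- stats::phyper(observed, n2, N - n2, n1, lower.tail = TRUE)
  data.frame(n1 = n1, n2 = n2, N = N, observed = observed,
             expected = expected, p_enrich = p_enrich,
             p_deplete = p_deplete)
}

#' DEG enrichment among proximal genes
#'
#' @param proximal_genes character vector of region-proximal gene ids.
#' @param degs character vector of differentially expressed gene ids.
#' @param universe character vector of all testable genes (mandatory —
#'   the choice of universe drives the expectation and must be explicit).
#' @return see [overlap_test()].
#' @export
deg_enrichment <- function(proximal_genes, degs, universe) {
  if (!all(degs %in% universe)) {
    warning("some DEG ids are outside the universe and are dropped")
  }
  overlap_test(proximal_genes, degs, universe)
}

#' Directional methylation-expression association (2x2 chi-square)
#'
#' Tests whether genes with lower methylation tend to show higher expression
#' (and vice versa) using a chi-square test with Yates continuity correction
#' (df 1, two-sided). Rows are methylation direction in the focal group
#' (lower, higher); columns are expression direction (higher, lower).
#'
#' @param table 2x2 matrix or the four counts `c(a, b, c, d)` read row-wise:
#'   a = lower meth/higher expr, b = lower meth/lower expr,
#'   c = higher meth/higher expr, d = higher meth/lower expr.
#' @return list with `chi2` and `p`.
#' @export
directional_association <- function(table) {
  m <- if (is.matrix(table)) table else matrix(table, 2, 2, byrow = TRUE)
  stopifnot(all(dim(m) == 2), all(m >= 0))
  n <- sum(m)
  if (n == 0) stop("empty contingency table")
  expected <- outer(rowSums(m), colSums(m)) / n
  if (any(expected == 0)) return(list(chi2 = 0, p = 1))
  dev <- pmax(0, abs(m - expected) - 0.5)  # Yates continuity correction
  chi2 <- sum(dev^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Distance from TSS positions to the nearest region
#'
#' @param tss data.frame with chrom, pos (1-based TSS), and optionally
#'   gene_id and direction (e.g. DEG up/down) for stratification.
#' @param sdmrs `GRanges` or data.frame of regions.
#' @return data.frame with the tss columns plus `distance` (unsigned bp,
#'   0 when the TSS lies inside a region), and attribute `ecdf` (stats::ecdf
#'   of the distances; per-direction ecdfs in attribute `ecdf_by` when a
#'   direction column is present).
#' @export
tss_distance_distribution <- function(tss, sdmrs) {
  if (is.data.frame(sdmrs)) {
    sdmrs <- bed_granges(sdmrs$chrom, sdmrs$start, sdmrs$end)
  }
  tg <- cpg_granges(tss$chrom, tss$pos)
  hits <- GenomicRanges::distanceToNearest(tg, sdmrs, ignore.strand = TRUE)
  d <- rep(NA_real_, nrow(tss))
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  out <- cbind(tss, distance = d)
  ok <- !is.na(d)
  attr(out, "ecdf") <- if (any(ok)) stats::ecdf(d[ok]) else NULL
  if (!is.null(tss$direction)) {
    attr(out, "ecdf_by") <- lapply(split(d[ok], tss$direction[ok]),
                                   stats::ecdf)
  }
  out
}

#' Cross-species ortholog overlap test
#'
#' Maps a mouse gene set and a human gene set onto a mouse-human ortholog
#' table restricted to one chromosome class (autosomal or X) and tests the
#' overlap hypergeometrically, with the universe being all ortholog pairs of
#' that class.
#'
#' @param mouse_genes,human_genes character vectors of gene ids.
#' @param orthologs data.frame with mouse_gene, human_gene, chrom_class
#'   (see [read_track()] kind "ortholog_map").
#' @param chrom_class "autosomal" or "X".
#' @return see [overlap_test()].
#' @export
ortholog_overlap_test <- function(mouse_genes, human_genes, orthologs,
                                  chrom_class = c("autosomal", "X")) {
  chrom_class <- match.arg(chrom_class)
  uni <- orthologs[orthologs$chrom_class == chrom_class, , drop = FALSE]
  in1 <- uni$mouse_gene %in% mouse_genes
  in2 <- uni$human_gene %in% human_genes
  hyper_overlap(sum(in1), sum(in2), nrow(uni), sum(in1 & in2))
}
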