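#' Known sex/genotype group labels
#'
#' Five groups cross sex phenotype with sex-chromosome complement: XX females,
#' XY sex-reversed females, XY males, XO females, and XX Paf-carrier females
#' (the littermate controls of the XO group).
#' @export
COHORT_GROUPS <- c("XX.F", "XY.F", "XY.M", "XO.F", "XXPaf.F")

#' Construct a MethylomeSample
#'
#' One sample's per-CpG methylation calls: for each CpG (1-based position),
#' the number of methylated reads and the total read count.
#'
#' @param sample_id sample identifier.
#' @param group group label (one of [COHORT_GROUPS] or user-defined).
#' @param sites data.frame with columns `chrom`, `pos`, `meth`, `total`.
#' @return an object of class `MethylomeSample`.
#' @export
methylome_sample <- function(sample_id, group, sites) {
  stopifnot(is.character(sample_id), length(sample_id) == 1,
            is.character(group), length(group) == 1)
  if (nrow(sites) == 0) {
    sites <- data.frame(chrom = character(), pos = integer(),
                        meth = integer(), total = integer())
  }
  need <- c("chrom", "pos", "meth", "total")
  if (!all(need %in% names(sites))) {
    stop("sites must have columns chrom, pos, meth, total")
  }
  sites <- sites[need]
  sites$pos <- as.integer(sites$pos)
  sites$meth <- as.integer(sites$meth)
  sites$total <- as.integer(sites$total)
  if (any(sites$total <= 0)) stop("total_count must be positive")
  if (any(sites$meth < 0)) stop("meth_count must be non-negative")
  bad <- which(sites$meth > sites$total)
  if (length(bad)) {
    stop("meth_count > total_count at row ", bad[1],
         " (", sites$chrom[bad[1]], ":", sites$pos[bad[1]], ")")
  }
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  if (anyDuplicated(paste(sites$chrom, sites$pos))) {
    stop("duplicate (chrom, pos) in methylome sample '", sample_id, "'")
  }
  rownames(sites) <- NULL
  structure(list(sample_id = sample_id, group = group, sites = sites),
            class = "MethylomeSample")
}

#' @export
print.MethylomeSample <- function(x, ...) {
  cat("MethylomeSample", x$sample_id, "(group", paste0(x$group, "):"),
      nrow(x$sites), "CpG sites on",
      length(unique(x$sites$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Methylation levels of a sample
#' @param sample a `MethylomeSample`.
#' @return numeric vector meth/total in `[0, 1]`.
#' @export
meth_levels <- function(sample) {
  sample$sites$meth / sample$sites$total
}

#' Read a per-CpG methylation report
#'
#' Expects a TSV with columns chrom, pos (1-based), meth_count, total_count
#' (a strand-collapsed cytosine report). An optional header line is detected
#' by a non-numeric second field. Gzip files are read transparently.
#'
#' @param path path to the report.
#' @param sample_id,group labels attached to the sample.
#' @return a `MethylomeSample`, sorted by (chrom, pos).
#' @export
read_cpg_report <- function(path, sample_id, group) {
  raw <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  raw <- raw[nzchar(raw)]
  if (length(raw) && is.na(suppressWarnings(as.numeric(
        strsplit(raw[1], "\t", fixed = TRUE)[[1]][2])))) {
    raw <- raw[-1]
  }
  if (!length(raw)) {
    return(methylome_sample(sample_id, group,
                            data.frame(chrom = character(), pos = integer(),
                                       meth = integer(), total = integer())))
  }
  parts <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4)) {
    stop("malformed CpG report row at line ", which(nf < 4)[1], " of ", path)
  }
  m <- matrix(unlist(lapply(parts, `[`, 1:4)), ncol = 4, byrow = TRUE)
  num <- suppressWarnings(cbind(as.numeric(m[, 2]), as.numeric(m[, 3]),
                                as.numeric(m[, 4])))
  if (anyNA(num)) {
    stop("malformed CpG report row at line ", which(rowSums(is.na(num)) > 0)[1],
         " of ", path)
  }
  methylome_sample(sample_id, group,
                   data.frame(chrom = m[, 1], pos = num[, 1],
                              meth = num[, 2], total = num[, 3]))
}

#' Write a per-CpG methylation report
#'
#' Inverse of [read_cpg_report()]; round-trips exactly.
#' @param sample a `MethylomeSample`.
#' @param path output path (TSV, with header).
#' @export
write_cpg_report <- function(sample, path) {
  s <- sample$sites
  utils::write.table(
    data.frame(chrom = s$chrom, pos = s$pos, meth_count = s$meth,
               total_count = s$total),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove CpG sites overlapping SNP intervals
#'
#' Sites whose 1-based position falls inside any interval of the 0-based
#' half-open SNP mask are dropped; everything else is untouched. An empty
#' mask is the identity.
#'
#' @param sample a `MethylomeSample`.
#' @param snps a `GRanges` (use [read_track()] with kind "bed") or a
#'   data.frame with chrom/start/end in BED convention.
#' @return the filtered `MethylomeSample`.
#' @export
mask_snps <- function(sample, snps) {
  if (is.data.frame(snps)) snps <- bed_granges(snps$chrom, snps$start, snps$end)
  if (length(snps) == 0 || nrow(sample$sites) == 0) return(sample)
  hits <- IRanges::overlapsAny(cpg_granges(sample$sites$chrom,
                                           sample$sites$pos), snps)
  sample$sites <- sample$sites[!hits, , drop = FALSE]
  rownames(sample$sites) <- NULL
  sample
}

#' Filter CpG sites by sequencing depth
#'
#' Retains sites with `min_depth <= total <= max_depth` (both bounds
#' inclusive). High-coverage sites are removed to guard against PCR
#' duplication bias; low-coverage sites to stabilise level estimates.
#'
#' @param sample a `MethylomeSample`.
#' @param min_depth,max_depth inclusive depth bounds (defaults 10 and 500).
#' @return the filtered `MethylomeSample`.
#' @export
filter_coverage <- function(sample, min_depth = 10L, max_depth = 500L) {
  if (min_depth <= 0 || min_depth > max_depth) {
    stop("need 0 < min_depth <= max_depth")
  }
  keep <- sample$sites$total >= min_depth & sample$sites$total <= max_depth
  sample$sites <- sample$sites[keep, , drop = FALSE]
  rownames(sample$sites) <- NULL
  sample
}

read_tsv_rows <- function(path, n_min, what) {
  raw <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  raw <- raw[nzchar(raw)]
  if (!length(raw)) return(list())
  parts <- strsplit(raw, "\t", fixed = TRUE)
  if (any(lengths(parts) < n_min)) {
    stop("malformed ", what, " row at line ", which(lengths(parts) < n_min)[1],
         " of ", path)
  }
  parts
}

#' Read an annotation or table file
#'
#' Dialects:
#' \describe{
#'   \item{bed}{BED3+; returns an unlabeled `GRanges`.}
#'   \item{bed_labeled}{BED4+ with label in column 4 (and, if present, a
#'     second label in column 5, stored as `label2` -- used for RepeatMasker
#'     subfamily/family pairs).}
#'   \item{gene_models}{BED12; returns a gene-model set with derived
#'     promoter (<1 kb upstream of TSS), 1--5 kb upstream, 5'UTR, exon,
#'     intron and 3'UTR intervals (see [build_gene_models()]).}
#'   \item{deg_table}{TSV gene_id, log2fc, padj, chrom (header optional).}
#'   \item{ortholog_map}{TSV mouse_gene, human_gene, chrom_class
#'     (autosomal|X).}
#' }
#'
#' @param path input path. BED coordinates are 0-based half-open.
#' @param kind one of bed, bed_labeled, gene_models, deg_table, ortholog_map.
#' @return see dialect list.
#' @export
read_track <- function(path, kind = c("bed", "bed_labeled", "gene_models",
                                      "deg_table", "ortholog_map")) {
  kind <- match.arg(kind)
  if (kind %in% c("bed", "bed_labeled")) {
    parts <- read_tsv_rows(path, if (kind == "bed") 3L else 4L, "BED")
    if (!length(parts)) return(GenomicRanges::GRanges())
    chrom <- vapply(parts, `[`, "", 1)
    start <- as.numeric(vapply(parts, `[`, "", 2))
    end <- as.numeric(vapply(parts, `[`, "", 3))
    if (anyNA(start) || anyNA(end)) stop("non-numeric BED coordinate in ", path)
    if (any(end <= start) || any(start < 0)) {
      stop("BED coordinate violation (need 0 <= start < end) in ", path)
    }
    gr <- bed_granges(chrom, start, end)
    if (kind == "bed_labeled") {
      S4Vectors::mcols(gr)$label <- vapply(parts, `[`, "", 4)
      if (all(lengths(parts) >= 5)) {
        S4Vectors::mcols(gr)$label2 <- vapply(parts, `[`, "", 5)
      }
    }
    return(gr)
  }
  if (kind == "deg_table") {
    parts <- read_tsv_rows(path, 4L, "DEG table")
    if (length(parts) && is.na(suppressWarnings(as.numeric(parts[[1]][2])))) {
      parts <- parts[-1]
    }
    df <- data.frame(
      gene_id = vapply(parts, `[`, "", 1),
      log2fc = as.numeric(vapply(parts, `[`, "", 2)),
      padj = as.numeric(vapply(parts, `[`, "", 3)),
      chrom = vapply(parts, `[`, "", 4),
      stringsAsFactors = FALSE)
    if (anyNA(df$log2fc) || anyNA(df$padj)) stop("non-numeric DEG field in ", path)
    if (any(df$padj < 0 | df$padj > 1)) stop("padj outside [0,1] in ", path)
    return(df)
  }
  if (kind == "ortholog_map") {
    parts <- read_tsv_rows(path, 3L, "ortholog map")
    if (length(parts) && parts[[1]][1] %in% c("mouse_gene", "mouse")) {
      parts <- parts[-1]
    }
    df <- data.frame(
      mouse_gene = vapply(parts, `[`, "", 1),
      human_gene = vapply(parts, `[`, "", 2),
      chrom_class = vapply(parts, `[`, "", 3),
      stringsAsFactors = FALSE)
    if (!all(df$chrom_class %in% c("autosomal", "X"))) {
      stop("ortholog chrom_class must be 'autosomal' or 'X' in ", path)
    }
    return(df)
  }
  # gene_models: BED12
  parts <- read_tsv_rows(path, 12L, "BED12")
  df <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    start = as.numeric(vapply(parts, `[`, "", 2)),
    end = as.numeric(vapply(parts, `[`, "", 3)),
    gene_id = vapply(parts, `[`, "", 4),
    strand = vapply(parts, `[`, "", 6),
    thick_start = as.numeric(vapply(parts, `[`, "", 7)),
    thick_end = as.numeric(vapply(parts, `[`, "", 8)),
    block_sizes = vapply(parts, `[`, "", 11),
    block_starts = vapply(parts, `[`, "", 12),
    stringsAsFactors = FALSE)
  build_gene_models(df)
}

parse_csv_ints <- function(x) as.numeric(strsplit(sub(",$", "", x), ",")[[1]])

#' Build gene models with derived regulatory intervals
#'
#' From BED12-style gene records, derives the strand-aware feature map used
#' throughout: promoter (<1 kb upstream of the TSS), upstream (1--5 kb
#' upstream, abutting the promoter at exactly 1 kb), 5'UTR and 3'UTR (from
#' the thick/CDS bounds), exons and introns (from the block structure). All
#' stored coordinates are 0-based half-open.
#'
#' @param df data.frame with chrom, start, end, gene_id, strand, thick_start,
#'   thick_end, block_sizes, block_starts (comma strings, BED12 columns
#'   11-12). thick_start == thick_end denotes a non-coding gene (no UTRs).
#' @return object of class `GeneModelSet`: `$genes` (one row per gene with
#'   tss) and `$features` (data.frame of labeled intervals).
#' @export
build_gene_models <- function(df) {
  stopifnot(all(df$strand %in% c("+", "-")))
  if (any(df$end <= df$start)) stop("gene end must exceed start")
  feats <- vector("list", nrow(df))
  tss <- ifelse(df$strand == "+", df$start, df$end)  # 0-based TSS coordinate
  for (i in seq_len(nrow(df))) {
    g <- df[i, ]
    sizes <- parse_csv_ints(g$block_sizes)
    offs <- parse_csv_ints(g$block_starts)
    ex_s <- g$start + offs
    ex_e <- ex_s + sizes
    if (any(ex_e > g$end)) stop("exon block outside gene body: ", g$gene_id)
    plus <- g$strand == "+"
    if (plus) {
      prom <- c(max(0, g$start - 1000), g$start)
      up <- c(max(0, g$start - 5000), max(0, g$start - 1000))
    } else {
      prom <- c(g$end, g$end + 1000)
      up <- c(g$end + 1000, g$end + 5000)
    }
    rows <- list(
      data.frame(feature = "promoter", start = prom[1], end = prom[2]),
      data.frame(feature = "upstream_1to5kb", start = up[1], end = up[2]))
    rows[[3]] <- data.frame(feature = "exon", start = ex_s, end = ex_e)
    if (length(ex_s) > 1) {
      rows[[4]] <- data.frame(feature = "intron",
                              start = ex_e[-length(ex_e)], end = ex_s[-1])
    }
    if (g$thick_end > g$thick_start) {
      utr_left <- intersect_blocks(ex_s, ex_e, g$start, g$thick_start)
      utr_right <- intersect_blocks(ex_s, ex_e, g$thick_end, g$end)
      if (nrow(utr_left)) {
        utr_left$feature <- if (plus) "five_utr" else "three_utr"
        rows[[length(rows) + 1]] <- utr_left[c("feature", "start", "end")]
      }
      if (nrow(utr_right)) {
        utr_right$feature <- if (plus) "three_utr" else "five_utr"
        rows[[length(rows) + 1]] <- utr_right[c("feature", "start", "end")]
      }
    }
    f <- do.call(rbind, rows)
    f <- f[f$end > f$start, , drop = FALSE]
    f$gene_id <- g$gene_id
    f$chrom <- g$chrom
    f$strand <- g$strand
    feats[[i]] <- f
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  genes <- data.frame(gene_id = df$gene_id, chrom = df$chrom,
                      strand = df$strand, start = df$start, end = df$end,
                      tss = tss, stringsAsFactors = FALSE)
  structure(list(genes = genes, features = features), class = "GeneModelSet")
}

intersect_blocks <- function(bs, be, lo, hi) {
  s <- pmax(bs, lo); e <- pmin(be, hi)
  keep <- e > s
  data.frame(start = s[keep], end = e[keep])
}

#' @export
print.GeneModelSet <- function(x, ...) {
  cat("GeneModelSet:", nrow(x$genes), "genes,", nrow(x$features),
      "feature intervals\n")
  invisible(x)
}

#' Feature intervals of a gene-model set as GRanges
#' @param models a `GeneModelSet`.
#' @param features optional character vector restricting feature types.
#' @return `GRanges` with mcols gene_id, feature.
#' @export
gene_feature_granges <- function(models, features = NULL) {
  f <- models$features
  if (!is.null(features)) f <- f[f$feature %in% features, , drop = FALSE]
  bed_granges(f$chrom, f$start, f$end, strand = f$strand,
              gene_id = f$gene_id, feature = f$feature)
}

#' Gene bodies as GRanges
#' @param models a `GeneModelSet`.
#' @return `GRanges` with mcols gene_id.
#' @export
gene_body_granges <- function(models) {
  g <- models$genes
  bed_granges(g$chrom, g$start, g$end, strand = g$strand, gene_id = g$gene_id)
}

#' Write intervals as BED
#'
#' @param gr `GRanges`; mcols (label, label2, ...) become columns 4+.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  df <- granges_bed(gr)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  out <- cbind(df[c("chrom", "start", "end")], mc)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
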