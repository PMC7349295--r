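#' CpG-island geography: islands, shores, shelves, inter-CGI
#'
#' Shores are the 2 kb flanks of islands; shelves the next 2 kb beyond the
#' shores; everything else is inter-CGI. The four categories are disjoint
#' and cover the genome. Where flanks of nearby islands would overlap, the
#' position is assigned to the nearer feature (island > shore > shelf),
#' which falls out of the set-difference construction: any base within 2 kb
#' of some island is shore, within 4 kb is at most shelf. Intervals are
#' truncated at chromosome ends.
#'
#' @param islands `GRanges` of CpG islands (or data.frame chrom/start/end in
#'   BED convention).
#' @param genome named vector of chromosome lengths.
#' @param flank_bp width of each flank tier (default 2000).
#' @return list of class `CgiGeography` with `GRanges` elements islands,
#'   shores, shelves, inter_cgi.
#' @export
build_cgi_geography <- function(islands, genome, flank_bp = 2000L) {
  if (is.data.frame(islands)) {
    islands <- bed_granges(islands$chrom, islands$start, islands$end)
  }
  genome_gr <- GenomicRanges::GRanges(
    names(genome), IRanges::IRanges(1, as.integer(genome)))
  GenomeInfoDb::seqlevels(islands) <- names(genome)
  # out-of-bound islands get a proper error below, not a GRanges warning
  suppressWarnings(GenomeInfoDb::seqlengths(islands) <- as.integer(genome))
  if (length(islands) &&
      any(GenomicRanges::end(islands) >
          genome[as.character(GenomicRanges::seqnames(islands))])) {
    stop("island outside chromosome bounds")
  }
  isl <- GenomicRanges::reduce(islands)
  # widening beyond the chromosome end is expected here; trim immediately
  tier1 <- GenomicRanges::trim(suppressWarnings(isl + flank_bp))
  tier2 <- GenomicRanges::trim(suppressWarnings(isl + 2L * flank_bp))
  shores <- GenomicRanges::setdiff(tier1, isl)
  shelves <- GenomicRanges::setdiff(tier2, GenomicRanges::union(isl, tier1))
  inter <- GenomicRanges::setdiff(genome_gr, tier2, ignore.strand = TRUE)
  structure(list(islands = isl, shores = shores, shelves = shelves,
                 inter_cgi = inter), class = "CgiGeography")
}

#' @export
print.CgiGeography <- function(x, ...) {
  for (nm in names(x)) {
    cat(sprintf("%-10s %5d intervals, %d bp\n", nm, length(x[[nm]]),
                sum(GenomicRanges::width(x[[nm]]))))
  }
  invisible(x)
}

#' Annotate regions against CGI geography, genic features and chromatin states
#'
#' Each region contributes one count to every category it overlaps by at
#' least 1 bp (multi-label: annotation frequencies, not a partition). Genic
#' categories are upstream_1to5kb, promoter, five_utr, exon, intron,
#' three_utr, and intergenic for regions overlapping none of these; CGI
#' categories are island/shore/shelf/inter_cgi; chromatin categories are the
#' state-track labels verbatim.
#'
#' @param regions `GRanges` or data.frame (chrom/start/end, BED convention).
#' @param cgi a `CgiGeography`, or NULL to skip.
#' @param genes a `GeneModelSet`, or NULL to skip.
#' @param chromatin labeled `GRanges` (mcols `label`), or NULL to skip.
#' @return data.frame: track, category, count, frequency (count / number of
#'   regions).
#' @export
annotate_regions <- function(regions, cgi = NULL, genes = NULL,
                             chromatin = NULL) {
  if (is.data.frame(regions)) {
    regions <- bed_granges(regions$chrom, regions$start, regions$end)
  }
  n <- length(regions)
  rows <- list()
  count_vs <- function(track_gr) {
    sum(IRanges::overlapsAny(regions, track_gr, ignore.strand = TRUE))
  }
  if (!is.null(cgi)) {
    for (nm in c("islands", "shores", "shelves", "inter_cgi")) {
      cat_nm <- c(islands = "island", shores = "shore", shelves = "shelf",
                  inter_cgi = "inter_cgi")[[nm]]
      rows[[length(rows) + 1]] <- data.frame(
        track = "cgi", category = cat_nm, count = count_vs(cgi[[nm]]))
    }
  }
  if (!is.null(genes)) {
    feats <- c("upstream_1to5kb", "promoter", "five_utr", "exon", "intron",
               "three_utr")
    fg <- gene_feature_granges(genes)
    hit_any <- rep(FALSE, n)
    for (f in feats) {
      sub <- fg[S4Vectors::mcols(fg)$feature == f]
      hits <- IRanges::overlapsAny(regions, sub, ignore.strand = TRUE)
      hit_any <- hit_any | hits
      rows[[length(rows) + 1]] <- data.frame(
        track = "genic", category = f, count = sum(hits))
    }
    rows[[length(rows) + 1]] <- data.frame(
      track = "genic", category = "intergenic", count = sum(!hit_any))
  }
  if (!is.null(chromatin)) {
    labs <- sort(unique(S4Vectors::mcols(chromatin)$label))
    for (lb in labs) {
      sub <- chromatin[S4Vectors::mcols(chromatin)$label == lb]
      rows[[length(rows) + 1]] <- data.frame(
        track = "chromatin", category = lb, count = count_vs(sub))
    }
  }
  out <- do.call(rbind, rows)
  out$frequency <- if (n > 0) out$count / n else NA_real_
  rownames(out) <- NULL
  out
}

# log-spaced distance bins for nearest-gene matching
DIST_BREAKS <- c(-0.5, 0.5, 1e3, 1e4, 1e5, Inf)
DIST_BIN_NAMES <- c("0", "(0,1kb]", "(1kb,10kb]", "(10kb,100kb]", ">100kb")

dist_bins <- function(d) {
  cut(d, breaks = DIST_BREAKS, labels = DIST_BIN_NAMES)
}

nearest_gene_distance <- function(gr, gene_bodies) {
  hits <- GenomicRanges::distanceToNearest(gr, gene_bodies,
                                           ignore.strand = TRUE)
  d <- rep(NA_real_, length(gr))
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  if (anyNA(d)) stop("a region's chromosome carries no gene; cannot match")
  d
}

# batch-pooled sampler of fixed-width regions stratified by nearest-gene
# distance bin. Draws uniform regions in batches, bins them, and serves
# requests per bin; errors when a bin stays unsatisfiable after the effort
# cap (the rejection-sampling contract: 10,000 tries per requested region).
matched_sampler <- function(gene_bodies, genome, width, rng_batch = 20000L) {
  chrom <- names(genome)
  lens <- as.integer(genome)
  ok <- lens >= width
  chrom <- chrom[ok]; lens <- lens[ok]
  wts <- (lens - width + 1) / sum(lens - width + 1)
  pools <- stats::setNames(vector("list", length(DIST_BIN_NAMES)),
                           DIST_BIN_NAMES)
  for (b in DIST_BIN_NAMES) pools[[b]] <- data.frame(chrom = character(),
                                                     start = integer())
  refill <- function() {
    ci <- sample.int(length(chrom), rng_batch, replace = TRUE, prob = wts)
    st <- floor(stats::runif(rng_batch) * (lens[ci] - width + 1))  # 0-based
    gr <- bed_granges(chrom[ci], st, st + width)
    hits <- GenomicRanges::distanceToNearest(gr, gene_bodies,
                                             ignore.strand = TRUE)
    d <- rep(NA_real_, length(gr))
    d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
    # candidates on geneless chromosomes have no defined distance and can
    # never satisfy a bin; drop them
    keep <- !is.na(d)
    ci <- ci[keep]; st <- st[keep]
    bins <- as.character(dist_bins(d[keep]))
    for (b in unique(bins)) {
      add <- data.frame(chrom = chrom[ci[bins == b]],
                        start = as.integer(st[bins == b]))
      pools[[b]] <<- rbind(pools[[b]], add)
    }
  }
  draw <- function(bin_counts) {
    need <- bin_counts[bin_counts > 0]
    tries <- 0L
    while (any(vapply(names(need), function(b) nrow(pools[[b]]),
                      0L) < need)) {
      tries <- tries + rng_batch
      if (tries > 10000L * sum(need) + rng_batch) {
        short <- names(need)[vapply(names(need),
                                    function(b) nrow(pools[[b]]), 0L) < need]
        stop("cannot satisfy distance bin '", short[1],
             "' on this genome (rejection limit reached)")
      }
      refill()
    }
    out <- lapply(names(need), function(b) {
      take <- seq_len(need[[b]])
      got <- pools[[b]][take, , drop = FALSE]
      pools[[b]] <<- pools[[b]][-take, , drop = FALSE]
      got$bin <- b
      got
    })
    do.call(rbind, out)
  }
  list(draw = draw, width = width)
}

#' Random regions matched on distance to the nearest gene
#'
#' Generates one random fixed-width region per query region such that the
#' matched set reproduces the query set's histogram of nearest-gene
#' distances over log-spaced bins (0, (0,1kb], (1kb,10kb], (10kb,100kb],
#' >100kb). Distance is measured to the nearest gene-body boundary, 0 when
#' overlapping. Sampling is uniform within a bin via rejection; a bin that
#' cannot be filled raises an error naming it. Deterministic under a set
#' seed.
#'
#' @param query `GRanges` or data.frame of query regions.
#' @param genes a `GeneModelSet` or `GRanges` of gene bodies.
#' @param genome named vector of chromosome lengths.
#' @param width width of generated regions in bp (default 300).
#' @param seed optional RNG seed (set for reproducibility).
#' @return `GRanges` of matched regions (same length as query) with mcols
#'   `bin`.
#' @export
generate_matched_random_regions <- function(query, genes, genome,
                                            width = 300L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(query)) {
    query <- bed_granges(query$chrom, query$start, query$end)
  }
  gene_bodies <- if (inherits(genes, "GeneModelSet")) {
    gene_body_granges(genes)
  } else genes
  qd <- nearest_gene_distance(query, gene_bodies)
  counts <- table(dist_bins(qd))
  smp <- matched_sampler(gene_bodies, genome, width)
  got <- smp$draw(stats::setNames(as.integer(counts), names(counts)))
  bed_granges(got$chrom, got$start, got$start + width, bin = got$bin)
}

#' Enrichment decision from a permutation incidence
#'
#' A family is enriched when the incidence (permutations in which the
#' observed count strictly exceeds the null count) strictly exceeds 99.5%
#' of permutations: 996/1000 is enriched, 995/1000 is not.
#'
#' @param incidence integer vector of incidences.
#' @param n_perm number of permutations.
#' @return logical vector.
#' @export
enrichment_flag <- function(incidence, n_perm) {
  stopifnot(all(incidence >= 0), all(incidence <= n_perm))
  incidence > 0.995 * n_perm
}

#' Permutation enrichment of repeat families around called regions
#'
#' For each repeat family (and subfamily, when the track carries one) the
#' observed statistic is the number of (region, repeat element) overlapping
#' pairs. The null is built from `n_perm` fresh distance-matched random
#' region sets ([generate_matched_random_regions()]); the incidence is the
#' number of permutations in which the observed count strictly exceeds the
#' null count, and a family is flagged enriched when the incidence exceeds
#' 99.5% of permutations (996/1000 at the default). Depletion is reported
#' symmetrically.
#'
#' @param sdmrs `GRanges` or data.frame of regions under test.
#' @param repeats `GRanges` with mcols `family` (and optionally `subfamily`).
#' @param genes `GeneModelSet` or gene-body `GRanges` for distance matching.
#' @param genome named vector of chromosome lengths.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param counting "element" (a region overlapping two elements counts 2) or
#'   "region" (0/1 per region).
#' @return data.frame: level, family, subfamily, observed, null_mean,
#'   incidence_over, incidence_under, enriched, depleted.
#' @export
repeat_enrichment <- function(sdmrs, repeats, genes, genome, n_perm = 1000L,
                              seed = 1L, counting = c("element", "region")) {
  counting <- match.arg(counting)
  set.seed(seed)
  if (is.data.frame(sdmrs)) {
    sdmrs <- bed_granges(sdmrs$chrom, sdmrs$start, sdmrs$end)
  }
  gene_bodies <- if (inherits(genes, "GeneModelSet")) {
    gene_body_granges(genes)
  } else genes
  fam <- S4Vectors::mcols(repeats)$family
  if (is.null(fam)) stop("repeat track must carry a 'family' mcols column")
  sub <- S4Vectors::mcols(repeats)$subfamily
  units <- data.frame(level = "family", family = unique(fam),
                      subfamily = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(sub)) {
    u <- unique(data.frame(family = fam, subfamily = sub))
    units <- rbind(units, data.frame(level = "subfamily", family = u$family,
                                     subfamily = u$subfamily))
  }
  unit_idx <- lapply(seq_len(nrow(units)), function(i) {
    if (units$level[i] == "family") which(fam == units$family[i])
    else which(fam == units$family[i] & sub == units$subfamily[i])
  })
  count_units <- function(gr) {
    hits <- GenomicRanges::findOverlaps(gr, repeats, ignore.strand = TRUE)
    sh <- S4Vectors::subjectHits(hits)
    qh <- S4Vectors::queryHits(hits)
    vapply(unit_idx, function(idx) {
      m <- sh %in% idx
      if (counting == "element") sum(m) else length(unique(qh[m]))
    }, 0L)
  }
  observed <- count_units(sdmrs)

  qd <- nearest_gene_distance(sdmrs, gene_bodies)
  counts <- table(dist_bins(qd))
  need <- stats::setNames(as.integer(counts), names(counts))
  smp <- matched_sampler(gene_bodies, genome, 300L)
  null_counts <- matrix(0L, n_perm, nrow(units))
  for (k in seq_len(n_perm)) {
    got <- smp$draw(need)
    null_counts[k, ] <- count_units(
      bed_granges(got$chrom, got$start, got$start + 300L))
  }
  over <- colSums(sweep(null_counts, 2, observed, `<`))
  under <- colSums(sweep(null_counts, 2, observed, `>`))
  data.frame(
    units,
    observed = observed,
    null_mean = colMeans(null_counts),
    incidence_over = over,
    incidence_under = under,
    enriched = enrichment_flag(over, n_perm),
    depleted = enrichment_flag(under, n_perm),
    stringsAsFactors = FALSE)
}
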