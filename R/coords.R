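#' Coordinate conventions
#'
#' All interval tracks (BED input, annotation tracks, called regions on disk)
#' use the BED convention: 0-based, half-open \code{[start, end)}. CpG sites
#' use the cytosine-report convention: 1-based positions. Conversion between
#' the two happens only through the helpers below, so the off-by-one lives in
#' exactly one place.
#'
#' @name coordinates
#' @keywords internal
NULL

#' Convert a 1-based position to a 0-based half-open single-base interval
#'
#' @param pos integer vector of 1-based positions.
#' @return list with `start` (0-based) and `end` (half-open) vectors.
#' @export
pos_to_bed <- function(pos) {
  stopifnot(is.numeric(pos), all(pos >= 1))
  list(start = as.integer(pos) - 1L, end = as.integer(pos))
}

#' Convert a 0-based half-open interval to 1-based closed coordinates
#'
#' @param start,end numeric vectors, 0-based half-open.
#' @return list with 1-based inclusive `first` and `last` positions.
#' @export
bed_to_pos <- function(start, end) {
  stopifnot(all(end > start), all(start >= 0))
  list(first = as.integer(start) + 1L, last = as.integer(end))
}

#' Build a GRanges from 0-based half-open coordinates
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 0-based half-open bounds.
#' @param strand strand characters ("+", "-", "."); "." maps to "*".
#' @param ... further metadata columns.
#' @return a `GRanges` (internally 1-based closed, as IRanges requires).
#' @export
bed_granges <- function(chrom, start, end, strand = NULL, ...) {
  if (length(chrom) == 0) {
    return(GenomicRanges::GRanges())
  }
  stopifnot(all(end > start), all(start >= 0), all(nzchar(chrom)))
  s <- if (is.null(strand)) "*" else gsub("\\.", "*", strand)
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)),
    strand = s,
    ...
  )
}

#' Extract 0-based half-open coordinates from a GRanges
#'
#' @param gr a `GRanges`.
#' @return data.frame with chrom, start (0-based), end (half-open), strand.
#' @export
granges_bed <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = gsub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    stringsAsFactors = FALSE
  )
}

#' GRanges of single-base ranges for 1-based CpG positions
#' @param chrom,pos chromosome names and 1-based positions.
#' @keywords internal
cpg_granges <- function(chrom, pos) {
  if (length(chrom) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
}
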