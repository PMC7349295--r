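#' Region calling from per-CpG test results (scan caller)
#'
#' Builds candidate regions from runs of significant CpGs and applies the
#' standard output constraints: minimum length 50 bp, at least 3 CpGs,
#' at least half of the region's CpGs significant, absolute mean methylation
#' difference above 20%, and a final merge of same-direction regions lying
#' within 100 bp (inclusive) of each other.
#'
#' Candidate construction: seed CpGs are those with p < p_threshold; maximal
#' runs of same-direction seeds in which consecutive seeds are at most
#' link_gap bp apart form candidates, which are extended to include every
#' tested (non-seed) CpG interior to the run. After merging, all four
#' constraints are re-asserted on the merged regions.
#'
#' @param records DMC record data.frame from [wald_dmc()] (all tested sites,
#'   sorted by chrom then pos).
#' @param p_threshold seed significance cutoff (default 1e-5).
#' @param delta_threshold minimum |mean delta| (strict; default 0.20).
#' @param min_len minimum region length in bp (default 50).
#' @param min_cpg minimum CpGs spanned (default 3).
#' @param merge_gap maximum gap for the final merge, inclusive (default 100).
#' @param link_gap maximum spacing of consecutive seeds in a run
#'   (default 300, of the order of the smoothing span).
#' @param min_sig_frac minimum fraction of significant CpGs (default 0.5).
#' @return DMR data.frame: chrom, start, end (0-based half-open), n_cpg,
#'   mean_delta, direction, source = "scan", stat (sum of seed Wald stats).
#' @export
call_dmr_scan <- function(records, p_threshold = 1e-5, delta_threshold = 0.20,
                          min_len = 50L, min_cpg = 3L, merge_gap = 100L,
                          link_gap = 300L, min_sig_frac = 0.5) {
  if (nrow(records) == 0) return(empty_dmr())
  o <- order(records$chrom, records$pos)
  if (any(o != seq_along(o))) stop("records must be sorted by (chrom, pos)")
  out <- lapply(split(records, records$chrom), function(rc) {
    scan_one_chrom(rc, p_threshold, delta_threshold, min_len, min_cpg,
                   merge_gap, link_gap, min_sig_frac)
  })
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0) return(empty_dmr())
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_dmr <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             n_cpg = integer(), mean_delta = numeric(),
             direction = character(), source = character(), stat = numeric(),
             stringsAsFactors = FALSE)
}

scan_one_chrom <- function(rc, p_thr, d_thr, min_len, min_cpg, merge_gap,
                           link_gap, min_sig_frac) {
  seed <- rc$p < p_thr
  si <- which(seed)
  if (!length(si)) return(NULL)
  spos <- rc$pos[si]
  sdir <- rc$direction[si]
  # break runs where spacing exceeds link_gap or direction flips
  brk <- c(TRUE, diff(spos) > link_gap | sdir[-1] != sdir[-length(sdir)])
  run <- cumsum(brk)
  regions <- lapply(split(seq_along(si), run), function(ii) {
    first <- spos[ii[1]]; last <- spos[ii[length(ii)]]
    summarize_region(rc, first, last, sdir[ii[1]], p_thr)
  })
  reg <- do.call(rbind, regions)
  reg <- filter_scan(reg, min_len, min_cpg, min_sig_frac, d_thr)
  if (nrow(reg) == 0) return(NULL)
  # merge same-direction survivors within merge_gap (inclusive), then
  # recompute summaries and re-assert all constraints
  reg <- reg[order(reg$start), , drop = FALSE]
  grp <- cumsum(c(TRUE, !(reg$start[-1] - reg$end[-nrow(reg)] <= merge_gap &
                          reg$direction[-1] == reg$direction[-nrow(reg)])))
  merged <- lapply(split(seq_len(nrow(reg)), grp), function(ii) {
    summarize_region(rc, reg$start[ii[1]] + 1L, reg$end[ii[length(ii)]],
                     reg$direction[ii[1]], p_thr)
  })
  mg <- do.call(rbind, merged)
  filter_scan(mg, min_len, min_cpg, min_sig_frac, d_thr)
}

summarize_region <- function(rc, first_pos, last_pos, direction, p_thr) {
  inside <- rc$pos >= first_pos & rc$pos <= last_pos
  sig <- inside & rc$p < p_thr
  data.frame(
    chrom = rc$chrom[1], start = first_pos - 1L, end = last_pos,
    n_cpg = sum(inside), mean_delta = mean(rc$delta[inside]),
    direction = direction, source = "scan",
    stat = sum(rc$wald[sig]), sig_frac = sum(sig) / sum(inside),
    stringsAsFactors = FALSE)
}

filter_scan <- function(reg, min_len, min_cpg, min_sig_frac, d_thr) {
  if (is.null(reg) || nrow(reg) == 0) return(empty_dmr())
  keep <- (reg$end - reg$start) >= min_len & reg$n_cpg >= min_cpg &
    reg$sig_frac >= min_sig_frac & abs(reg$mean_delta) > d_thr
  out <- reg[keep, setdiff(names(reg), "sig_frac"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Region calling on fixed 300 bp tiles with overdispersion correction
#'
#' The genome is tiled with non-overlapping windows (step = width). Per tile,
#' counts are pooled per group across replicates and CpGs (after a per-CpG
#' depth filter), compared with a two-proportion chi-square statistic, and
#' the statistic is deflated by a per-tile overdispersion factor
#' c-hat = max(1, replicate-level Pearson X^2 / df) before the p-value is
#' taken from a chi-square with 1 df. Q-values are Benjamini-Hochberg across
#' all tested tiles; calling requires q < q_threshold and
#' |delta| > delta_threshold (both strict).
#'
#' @param samples list of `MethylomeSample`.
#' @param design a `ComparisonDesign`.
#' @param width tile width in bp (default 300).
#' @param min_depth,max_depth per-CpG depth bounds applied before pooling
#'   (defaults 10 and 500).
#' @param q_threshold BH q cutoff (default 0.05).
#' @param delta_threshold minimum |pooled delta| (default 0.20).
#' @param min_cpg minimum CpGs per tile after filtering (default 1).
#' @return DMR data.frame (source = "tile", stat = q-value).
#' @export
call_dmr_tiles <- function(samples, design, width = 300L, min_depth = 10L,
                           max_depth = 500L, q_threshold = 0.05,
                           delta_threshold = 0.20, min_cpg = 1L) {
  if (width <= 0) stop("width must be positive")
  groups <- vapply(samples, `[[`, "", "group")
  bi <- which(groups == design$baseline)
  oi <- which(groups == design$other)
  if (!length(bi) || !length(oi)) stop("empty group in ", design$name)
  filt <- lapply(samples[c(bi, oi)], filter_coverage, min_depth, max_depth)
  is_b <- rep(c(TRUE, FALSE), c(length(bi), length(oi)))
  tab <- do.call(rbind, lapply(seq_along(filt), function(j) {
    s <- filt[[j]]$sites
    if (!nrow(s)) return(NULL)
    data.frame(chrom = s$chrom, tile = (s$pos - 1L) %/% width,
               pos = s$pos, meth = s$meth, total = s$total, rep = j,
               baseline = is_b[j], stringsAsFactors = FALSE)
  }))
  if (is.null(tab) || nrow(tab) == 0) return(empty_dmr())
  key <- paste(tab$chrom, tab$tile)
  res <- lapply(split(tab, key), tile_stats)
  df <- do.call(rbind, res)
  df <- df[df$n_cpg >= min_cpg & df$ok, , drop = FALSE]
  if (nrow(df) == 0) return(empty_dmr())
  df$q <- stats::p.adjust(df$p, method = "BH")
  keep <- df$q < q_threshold & abs(df$delta) > delta_threshold
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0) return(empty_dmr())
  out <- data.frame(
    chrom = df$chrom, start = df$tile * width,
    end = df$tile * width + width, n_cpg = df$n_cpg,
    mean_delta = df$delta,
    direction = ifelse(df$delta < 0, "hypo", "hyper"),
    source = "tile", stat = df$q, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

tile_stats <- function(tt) {
  bm <- sum(tt$meth[tt$baseline]); bt <- sum(tt$total[tt$baseline])
  om <- sum(tt$meth[!tt$baseline]); ot <- sum(tt$total[!tt$baseline])
  ok <- bt > 0 && ot > 0
  n_cpg <- length(unique(tt$pos))
  if (!ok) {
    return(data.frame(chrom = tt$chrom[1], tile = tt$tile[1], n_cpg = n_cpg,
                      delta = NA_real_, p = NA_real_, ok = FALSE))
  }
  pb <- bm / bt; po <- om / ot
  pp <- (bm + om) / (bt + ot)
  if (pp <= 0 || pp >= 1) {
    stat <- 0
  } else {
    # Pearson X^2 of the pooled 2x2 (meth/unmeth x group)
    stat <- (bm - bt * pp)^2 / (bt * pp * (1 - pp)) +
            (om - ot * pp)^2 / (ot * pp * (1 - pp))
  }
  # within-group heterogeneity of the per-CpG per-replicate counts against
  # the pooled group proportion -> overdispersion factor (counting every
  # observation keeps the estimate usable on sparse tiles)
  x2 <- 0; dfree <- 0
  for (b in c(TRUE, FALSE)) {
    sub <- tt[tt$baseline == b, , drop = FALSE]
    pg <- sum(sub$meth) / sum(sub$total)
    if (nrow(sub) > 1 && pg > 0 && pg < 1) {
      x2 <- x2 + sum((sub$meth - sub$total * pg)^2 /
                       (sub$total * pg * (1 - pg)))
      dfree <- dfree + nrow(sub) - 1
    }
  }
  chat <- if (dfree > 0) max(1, x2 / dfree) else 1
  p <- stats::pchisq(stat / chat, df = 1, lower.tail = FALSE)
  data.frame(chrom = tt$chrom[1], tile = tt$tile[1], n_cpg = n_cpg,
             delta = po - pb, p = p, ok = TRUE)
}

#' Union of scan and tile regions with scan priority
#'
#' All scan regions are kept; a tile region is kept only if it overlaps no
#' scan region by at least 1 bp. Provenance stays in the `source` column.
#'
#' @param scan,tiles DMR data.frames from the two callers (one comparison).
#' @return combined DMR data.frame sorted by position.
#' @export
union_dmr <- function(scan, tiles) {
  if (nrow(tiles) == 0) return(scan)
  if (nrow(scan) == 0) {
    out <- tiles
  } else {
    tg <- bed_granges(tiles$chrom, tiles$start, tiles$end)
    sg <- bed_granges(scan$chrom, scan$start, scan$end)
    out <- rbind(scan, tiles[!IRanges::overlapsAny(tg, sg), , drop = FALSE])
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write DMR records as BED6+
#'
#' Columns: chrom, start, end, name = source, score = round(1000 |mean
#' delta|), strand = ".", then n_cpg, mean_delta, direction, stat.
#' @param dmrs DMR data.frame.
#' @param path output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  out <- data.frame(
    chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
    name = dmrs$source, score = round(1000 * abs(dmrs$mean_delta)),
    strand = ".", n_cpg = dmrs$n_cpg, mean_delta = dmrs$mean_delta,
    direction = dmrs$direction, stat = dmrs$stat)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read DMR records written by [write_dmr_bed()]
#' @param path BED6+ path.
#' @return DMR data.frame.
#' @export
read_dmr_bed <- function(path) {
  parts <- read_tsv_rows(path, 10L, "DMR BED")
  if (!length(parts)) return(empty_dmr())
  data.frame(
    chrom = vapply(parts, `[`, "", 1),
    start = as.integer(vapply(parts, `[`, "", 2)),
    end = as.integer(vapply(parts, `[`, "", 3)),
    n_cpg = as.integer(vapply(parts, `[`, "", 7)),
    mean_delta = as.numeric(vapply(parts, `[`, "", 8)),
    direction = vapply(parts, `[`, "", 9),
    source = vapply(parts, `[`, "", 4),
    stat = as.numeric(vapply(parts, `[`, "", 10)),
    stringsAsFactors = FALSE)
}
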