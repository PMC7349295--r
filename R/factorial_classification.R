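#' Default factorial classification rules
#'
#' Boolean rules over comparison membership, evaluated per site/region:
#' \describe{
#'   \item{x_dosage}{significant in all three comparisons that contrast one
#'     X against two X (XX.F vs XY.M, XX.F vs XY.F, XXPaf.F vs XO.F).}
#'   \item{y_linked}{significant in both comparisons that contrast presence
#'     vs absence of a Y, but not in the X-dosage-only contrast.}
#'   \item{phenotype}{significant in both comparisons that contrast
#'     phenotypic males against females (XX.F vs XY.M and XY.F vs XY.M).}
#' }
#' Precedence (x_dosage > y_linked > phenotype) resolves multi-rule hits;
#' sites matching no rule are "unclassified".
#'
#' @return list with `rules` (named character expressions) and `precedence`.
#' @export
default_class_rules <- function() {
  list(
    rules = c(
      x_dosage = "XX.F_vs_XY.M & XX.F_vs_XY.F & XXPaf.F_vs_XO.F",
      y_linked = "XX.F_vs_XY.M & XX.F_vs_XY.F & !XXPaf.F_vs_XO.F",
      phenotype = "XX.F_vs_XY.M & XY.F_vs_XY.M"),
    precedence = c("x_dosage", "y_linked", "phenotype"))
}

#' Chromosome class helper: sex chromosome or autosome
#' @param chrom chromosome names.
#' @return logical, TRUE for chrX/chrY (also bare X/Y).
#' @export
is_sex_chrom <- function(chrom) {
  sub("^chr", "", chrom) %in% c("X", "Y")
}

# membership matrix (logical, elements x comparisons) -> classification
apply_class_rules <- function(membership, rules, precedence) {
  comp <- colnames(membership)
  cls <- rep("unclassified", nrow(membership))
  env_df <- as.data.frame(membership)
  for (r in rev(precedence)) {  # apply lowest precedence first, overwrite up
    expr <- parse(text = rules[[r]])[[1]]
    vars <- all.vars(expr)
    unknown <- setdiff(vars, comp)
    if (length(unknown)) {
      stop("rule '", r, "' references unknown comparison(s): ",
           paste(unknown, collapse = ", "))
    }
    hit <- eval(expr, envir = env_df)
    cls[hit] <- r
  }
  cls
}

#' UpSet-style intersection counts of sDMC sets
#'
#' Sites are keyed by exact (chrom, pos). Each site is counted once, in the
#' exact subset of comparisons that called it (mutually exclusive counts),
#' split into autosomal and sex-chromosome tallies.
#'
#' @param dmc_sets named list of called-DMC data.frames (chrom, pos), one
#'   per comparison.
#' @return data.frame: subset (comma-joined comparison names), degree,
#'   autosomal, sex_chrom, total. All non-empty subsets are listed,
#'   including zero-count ones.
#' @export
intersect_dmc_sets <- function(dmc_sets) {
  stopifnot(length(dmc_sets) >= 2, !is.null(names(dmc_sets)))
  comp <- names(dmc_sets)
  keys <- lapply(dmc_sets, function(d) paste(d$chrom, d$pos))
  universe <- unique(unlist(keys))
  membership <- vapply(keys, function(k) universe %in% k,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(NULL, comp))
  chroms <- vapply(strsplit(universe, " ", fixed = TRUE), `[`, "", 1)
  upset_counts(membership, is_sex_chrom(chroms))
}

#' UpSet-style intersection counts of DMR sets (overlap keyed)
#'
#' Regions from all comparisons are clustered by >= 1 bp overlap (connected
#' components of the overlap graph across the pooled set); each cluster is
#' one element whose membership is the set of comparisons contributing at
#' least one region to it.
#'
#' @param dmr_sets named list of DMR data.frames (chrom, start, end).
#' @return as [intersect_dmc_sets()].
#' @export
intersect_dmr_sets <- function(dmr_sets) {
  stopifnot(length(dmr_sets) >= 2, !is.null(names(dmr_sets)))
  comp <- names(dmr_sets)
  pooled <- do.call(rbind, lapply(comp, function(nm) {
    d <- dmr_sets[[nm]]
    if (nrow(d) == 0) return(NULL)
    data.frame(chrom = d$chrom, start = d$start, end = d$end, comparison = nm,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pooled)) {
    return(upset_counts(matrix(FALSE, 0, length(comp),
                               dimnames = list(NULL, comp)), logical(0)))
  }
  gr <- bed_granges(pooled$chrom, pooled$start, pooled$end)
  clust <- cluster_by_overlap(gr)
  membership <- vapply(comp, function(nm) {
    tabulate(clust[pooled$comparison == nm], max(clust)) > 0
  }, logical(max(clust)))
  membership <- matrix(membership, nrow = max(clust),
                       dimnames = list(NULL, comp))
  cl_chrom <- tapply(pooled$chrom, clust, `[`, 1)
  upset_counts(membership, is_sex_chrom(cl_chrom))
}

# connected components of the >=1 bp overlap graph; min.gapwidth = 0 keeps
# merely abutting ranges apart (no shared base = no overlap)
cluster_by_overlap <- function(gr) {
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  GenomicRanges::findOverlaps(gr, red, select = "first")
}

upset_counts <- function(membership, sexchrom) {
  comp <- colnames(membership)
  n <- length(comp)
  subsets <- lapply(seq_len(2^n - 1), function(mask) {
    comp[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
  })
  rows <- lapply(subsets, function(ss) {
    inset <- if (nrow(membership)) {
      rowSums(membership[, ss, drop = FALSE]) == length(ss) &
        rowSums(membership) == length(ss)
    } else logical(0)
    data.frame(subset = paste(ss, collapse = ","), degree = length(ss),
               autosomal = sum(inset & !sexchrom),
               sex_chrom = sum(inset & sexchrom),
               total = sum(inset), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$degree, out$subset), ] -> out
  rownames(out) <- NULL
  out
}

#' Classify sDMC sites into factorial effect classes
#'
#' Site membership across comparisons (exact chrom/pos) is evaluated against
#' boolean rules; precedence resolves sites matching several rules. Every
#' site in the union receives exactly one class.
#'
#' @param dmc_sets named list of called-DMC data.frames per comparison.
#' @param rules,precedence see [default_class_rules()]; any rule referencing
#'   an unknown comparison is an error.
#' @return data.frame: chrom, pos, membership (comma list), class.
#' @export
classify_dmc <- function(dmc_sets, rules = default_class_rules()$rules,
                         precedence = default_class_rules()$precedence) {
  comp <- names(dmc_sets)
  keys <- lapply(dmc_sets, function(d) paste(d$chrom, d$pos))
  universe <- unique(unlist(keys))
  membership <- vapply(keys, function(k) universe %in% k,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(NULL, comp))
  parts <- strsplit(universe, " ", fixed = TRUE)
  df <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    pos = as.integer(vapply(parts, `[`, "", 2)),
    membership = apply(membership, 1, function(m) {
      paste(comp[m], collapse = ",")
    }),
    class = apply_class_rules(membership, rules, precedence),
    stringsAsFactors = FALSE)
  df[order(df$chrom, df$pos), ] -> df
  rownames(df) <- NULL
  df
}

#' Classify DMRs into factorial effect classes (overlap membership)
#'
#' Regions are clustered by >= 1 bp overlap across comparisons; each
#' cluster's membership feeds the same rules as [classify_dmc()].
#'
#' @param dmr_sets named list of DMR data.frames per comparison.
#' @inheritParams classify_dmc
#' @return data.frame: chrom, start, end (cluster span), membership, class.
#' @export
classify_dmr <- function(dmr_sets, rules = default_class_rules()$rules,
                         precedence = default_class_rules()$precedence) {
  comp <- names(dmr_sets)
  pooled <- do.call(rbind, lapply(comp, function(nm) {
    d <- dmr_sets[[nm]]
    if (nrow(d) == 0) return(NULL)
    data.frame(chrom = d$chrom, start = d$start, end = d$end, comparison = nm,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pooled)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      membership = character(), class = character()))
  }
  gr <- bed_granges(pooled$chrom, pooled$start, pooled$end)
  clust <- cluster_by_overlap(gr)
  nc <- max(clust)
  membership <- vapply(comp, function(nm) {
    tabulate(clust[pooled$comparison == nm], nc) > 0
  }, logical(nc))
  membership <- matrix(membership, nrow = nc, dimnames = list(NULL, comp))
  df <- data.frame(
    chrom = as.character(tapply(pooled$chrom, clust, `[`, 1)),
    start = as.integer(tapply(pooled$start, clust, min)),
    end = as.integer(tapply(pooled$end, clust, max)),
    membership = apply(membership, 1, function(m) {
      paste(comp[m], collapse = ",")
    }),
    class = apply_class_rules(membership, rules, precedence),
    stringsAsFactors = FALSE)
  df[order(df$chrom, df$start), ] -> df
  rownames(df) <- NULL
  df
}

#' Per-chromosome, per-direction counts
#'
#' Tallies records (sites or regions carrying a `direction` column) by
#' chromosome and direction; the counts partition the input exactly.
#'
#' @param records data.frame with chrom and direction columns.
#' @return data.frame chrom, direction, count.
#' @export
per_chromosome_counts <- function(records) {
  if (nrow(records) == 0) {
    return(data.frame(chrom = character(), direction = character(),
                      count = integer()))
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(records))),
                          by = list(chrom = records$chrom,
                                    direction = records$direction), FUN = sum)
  agg[order(agg$chrom, agg$direction), ] -> agg
  rownames(agg) <- NULL
  agg
}
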