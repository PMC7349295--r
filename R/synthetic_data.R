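#' Configuration for the synthetic WGBS cohort generator
#'
#' The generator emulates a five-group mouse cohort (XX females, XY females,
#' XY males, XO females, XX Paf-carrier females; 3 replicates each except 2
#' for XXPaf.F) of whole-genome bisulfite counts with planted effect regions
#' in three factorial classes:
#' \describe{
#'   \item{phenotype}{applies to phenotypic males (XY.M), on autosomes.}
#'   \item{x_dosage}{applies to two-X groups (XX.F, XXPaf.F), on chrX.}
#'   \item{y_linked}{applies to Y-carriers (XY.M, XY.F).}
#' }
#' Per CpG and sample, depth is Poisson(coverage_mean) truncated at >= 1 and
#' the methylated count is beta-binomial with intra-class correlation
#' `rho`. Background CpGs sit at `baseline_background` (hypermethylated
#' genome), island CpGs at `baseline_island`. Planted regions carry a shift
#' of `delta * sign` for affected groups, clipped into [0.02, 0.98] (clips
#' are counted). chrY CpGs exist only in Y-carrier samples. Planted regions
#' are made CpG-dense (`effect_n_cpg` CpGs each), emulating the CpG-island
#' shore / promoter context where regulatory differential methylation
#' concentrates. Expression: one gene is placed over each planted phenotype
#' region and receives, with probability `coupling`, an opposite-direction
#' fold change in the comparisons where phenotypic males differ.
#'
#' @param chroms named vector of chromosome lengths. Default: chr1 3 Mb
#'   (autosome), chrX 1.5 Mb, chrY 0.3 Mb.
#' @param cpg_per_kb mean background CpG density per kb (default 10).
#' @param n_islands number of 1 kb CpG islands (default 30).
#' @param island_cpg_per_kb CpG density inside islands (default 80).
#' @param groups named vector of replicate counts.
#' @param coverage_mean expected per-CpG depth (default 20).
#' @param baseline_island,baseline_background baseline methylation levels
#'   (defaults 0.10 and 0.85).
#' @param rho beta-binomial intra-class correlation (default 0.05).
#' @param missing_rate per-sample per-CpG dropout rate (default 0.05).
#' @param xxpaf_rho_factor variance inflation for the mixed-background
#'   XXPaf.F group; 1 disables it (default 1; set 2 to emulate their
#'   genetic heterogeneity).
#' @param effects named list with per-class planted-region settings, each a
#'   list(n, width, delta, sign). Defaults: 8 regions per class, 300 bp,
#'   delta 0.3, sign -1 (hypomethylation in affected groups).
#' @param effect_n_cpg CpGs guaranteed inside each planted region
#'   (default 12).
#' @param n_genes number of background genes (default 60).
#' @param gene_width gene-body width in bp (default 5000).
#' @param coupling probability that a phenotype-region gene is differentially
#'   expressed in the opposite direction (default 0.8).
#' @param deg_lfc absolute log2 fold change of coupled genes (default 2).
#' @param n_states number of chromatin-state labels in the emitted state
#'   track (default 5).
#' @param repeat_families named list of repeat-family settings, each a
#'   list(n, width, multiplier, subfamilies). Defaults: L1, Alu, ERVK, MIR,
#'   all unbiased (multiplier 1).
#' @param seed RNG seed for [simulate_cohort()] (default 1).
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(
    chroms = c(chr1 = 3e6, chrX = 1.5e6, chrY = 3e5),
    cpg_per_kb = 10,
    n_islands = 30L,
    island_cpg_per_kb = 80,
    groups = c(XX.F = 3L, XY.F = 3L, XY.M = 3L, XO.F = 3L, XXPaf.F = 2L),
    coverage_mean = 20,
    baseline_island = 0.10,
    baseline_background = 0.85,
    rho = 0.05,
    missing_rate = 0.05,
    xxpaf_rho_factor = 1,
    effects = list(
      phenotype = list(n = 8L, width = 300L, delta = 0.3, sign = -1),
      x_dosage = list(n = 8L, width = 300L, delta = 0.3, sign = -1),
      y_linked = list(n = 8L, width = 300L, delta = 0.3, sign = -1)),
    effect_n_cpg = 12L,
    n_genes = 60L,
    gene_width = 5000L,
    coupling = 0.8,
    deg_lfc = 2,
    n_states = 5L,
    repeat_families = list(
      L1 = list(n = 1500L, width = 400L, multiplier = 1,
                subfamilies = c("L1Md_T", "L1Md_A")),
      Alu = list(n = 4500L, width = 150L, multiplier = 1,
                 subfamilies = "B1"),
      ERVK = list(n = 500L, width = 400L, multiplier = 1,
                  subfamilies = "IAP"),
      MIR = list(n = 2000L, width = 150L, multiplier = 1,
                 subfamilies = "MIR3")),
    seed = 1L) {
  cfg <- as.list(environment())
  for (cl in names(cfg$effects)) {
    e <- cfg$effects[[cl]]
    if (e$n > 0 && (e$delta <= 0 || e$delta > 1)) {
      stop("planted delta must be in (0, 1]")
    }
  }
  if (any(cfg$groups < 2)) stop("replicate counts must be >= 2")
  if (!all(c("chr1", "chrX") %in% names(chroms))) {
    stop("chroms must include at least one autosome named chr1 and chrX")
  }
  structure(cfg, class = "SimulationConfig")
}

Y_CARRIERS <- c("XY.M", "XY.F")
TWO_X_GROUPS <- c("XX.F", "XXPaf.F")

affected_groups <- function(class) {
  switch(class,
         phenotype = "XY.M",
         x_dosage = TWO_X_GROUPS,
         y_linked = Y_CARRIERS,
         stop("unknown effect class ", class))
}

# chromosomes eligible for each planted class in the default scenario
class_chroms <- function(class, chroms) {
  autosomes <- setdiff(names(chroms), c("chrX", "chrY"))
  switch(class,
         phenotype = autosomes,
         x_dosage = "chrX",
         y_linked = c(autosomes, "chrX"))
}

#' Simulate a five-group WGBS cohort with planted effects
#'
#' See [simulation_config()] for the generative model. All randomness flows
#' from `config$seed`: identical configurations produce identical output.
#'
#' @param config a `SimulationConfig`.
#' @return list with
#'   \describe{
#'     \item{samples}{list of `MethylomeSample` (one per replicate).}
#'     \item{truth}{`TruthSet`: `planted_regions` (BED-convention intervals
#'       with class, delta, sign), `deg_truth` (gene, comparison, true_lfc,
#'       class), `clipped` (count of mu values clipped into [0.02, 0.98]).}
#'     \item{tracks}{list: `genome` (named lengths), `cgi` (islands GRanges),
#'       `genes` (`GeneModelSet`), `chromatin` (labeled GRanges), `repeats`
#'       (GRanges with family/subfamily).}
#'     \item{deg_tables}{named list of DEG data.frames per comparison
#'       (gene_id, log2fc, padj, chrom).}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  chroms <- config$chroms

  # --- CpG islands and their track
  isl_chrom <- sample(names(chroms), config$n_islands, replace = TRUE,
                      prob = chroms / sum(chroms))
  isl_start <- vapply(isl_chrom, function(ch) {
    floor(stats::runif(1) * (chroms[[ch]] - 1000))
  }, 0)
  islands <- data.frame(chrom = isl_chrom, start = isl_start,
                        end = isl_start + 1000)
  islands <- islands[order(islands$chrom, islands$start), , drop = FALSE]

  # --- planted effect regions: non-overlapping across all classes, outside
  # islands, away from chromosome ends
  planted <- place_planted_regions(config, islands)

  # --- CpG map: background + island + guaranteed CpGs in planted regions
  cpgs <- lay_cpgs(config, islands, planted)

  # --- baseline methylation per CpG
  in_island <- overlaps_pos(cpgs, islands)
  base_mu <- ifelse(in_island, config$baseline_island,
                    config$baseline_background)

  # per-class shift masks
  shift <- stats::setNames(vector("list", nrow(planted)),
                           rownames(planted))
  clipped <- 0L

  # --- samples
  samples <- list()
  for (g in names(config$groups)) {
    mu_g <- base_mu
    for (i in seq_len(nrow(planted))) {
      if (!(g %in% affected_groups(planted$class[i]))) next
      inside <- cpgs$chrom == planted$chrom[i] &
        cpgs$pos > planted$start[i] & cpgs$pos <= planted$end[i]
      mu_g[inside] <- mu_g[inside] + planted$delta[i] * planted$sign[i]
    }
    nclip <- sum(mu_g < 0.02 | mu_g > 0.98)
    clipped <- clipped + nclip * config$groups[[g]]
    mu_g <- pmin(0.98, pmax(0.02, mu_g))
    rho_g <- config$rho * if (g == "XXPaf.F") config$xxpaf_rho_factor else 1
    keep_chrom <- if (g %in% Y_CARRIERS) rep(TRUE, nrow(cpgs)) else
      cpgs$chrom != "chrY"
    for (r in seq_len(config$groups[[g]])) {
      idx <- which(keep_chrom & stats::runif(nrow(cpgs)) >= config$missing_rate)
      depth <- stats::rpois(length(idx), config$coverage_mean)
      depth[depth == 0] <- 1L
      a <- mu_g[idx] * (1 - rho_g) / rho_g
      b <- (1 - mu_g[idx]) * (1 - rho_g) / rho_g
      p <- stats::rbeta(length(idx), a, b)
      meth <- stats::rbinom(length(idx), depth, p)
      samples[[length(samples) + 1]] <- methylome_sample(
        sprintf("%s_r%d", g, r), g,
        data.frame(chrom = cpgs$chrom[idx], pos = cpgs$pos[idx],
                   meth = meth, total = depth))
    }
  }

  # --- genes: one over each phenotype region (for coupling), rest uniform
  genes <- place_genes(config, planted)
  models <- build_gene_models(genes)

  # --- expression truth and per-comparison DEG tables
  deg <- make_deg_tables(config, planted, genes)

  # --- chromatin state track: fixed-grain random segmentation
  chromatin <- make_state_track(chroms, config$n_states)

  truth <- structure(
    list(planted_regions = planted, deg_truth = deg$truth,
         repeat_bias = vapply(config$repeat_families, `[[`, 0, "multiplier"),
         clipped = clipped),
    class = "TruthSet")

  repeats <- simulate_repeat_track(config, truth)

  list(samples = samples, truth = truth,
       tracks = list(genome = chroms,
                     cgi = bed_granges(islands$chrom, islands$start,
                                       islands$end),
                     genes = models, chromatin = chromatin,
                     repeats = repeats),
       deg_tables = deg$tables)
}

place_planted_regions <- function(config, islands) {
  chroms <- config$chroms
  taken <- islands  # avoid islands and previously placed regions
  rows <- list()
  for (cl in names(config$effects)) {
    e <- config$effects[[cl]]
    if (e$n == 0) next
    elig <- intersect(class_chroms(cl, chroms), names(chroms))
    for (i in seq_len(e$n)) {
      for (try in 1:1000) {
        ch <- if (length(elig) == 1) elig else
          sample(elig, 1, prob = chroms[elig] / sum(chroms[elig]))
        st <- floor(stats::runif(1) * (chroms[[ch]] - e$width - 2000)) + 1000
        cand <- data.frame(chrom = ch, start = st, end = st + e$width)
        clash <- any(taken$chrom == ch &
                       taken$start < cand$end + 600 &
                       taken$end > cand$start - 600)
        if (!clash) break
        if (try == 1000) stop("cannot place planted regions; genome too full")
      }
      taken <- rbind(taken, cand)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, start = st, end = st + e$width, class = cl,
        delta = e$delta, sign = e$sign, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               class = character(), delta = numeric(), sign = numeric())
  rownames(out) <- NULL
  out
}

lay_cpgs <- function(config, islands, planted) {
  chroms <- config$chroms
  pieces <- list()
  for (ch in names(chroms)) {
    n_bg <- stats::rpois(1, chroms[[ch]] / 1000 * config$cpg_per_kb)
    pos <- floor(stats::runif(n_bg) * chroms[[ch]]) + 1
    isl <- islands[islands$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(isl))) {
      n_i <- stats::rpois(1, (isl$end[i] - isl$start[i]) / 1000 *
                            config$island_cpg_per_kb)
      pos <- c(pos, isl$start[i] + floor(stats::runif(n_i) *
                                           (isl$end[i] - isl$start[i])) + 1)
    }
    pl <- planted[planted$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(pl))) {
      w <- pl$end[i] - pl$start[i]
      pos <- c(pos, pl$start[i] + floor(seq(0.5, w - 0.5,
                                            length.out = config$effect_n_cpg)))
    }
    pieces[[ch]] <- data.frame(chrom = ch, pos = sort(unique(as.integer(pos))))
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

overlaps_pos <- function(cpgs, bed) {
  if (nrow(bed) == 0) return(rep(FALSE, nrow(cpgs)))
  IRanges::overlapsAny(cpg_granges(cpgs$chrom, cpgs$pos),
                       bed_granges(bed$chrom, bed$start, bed$end))
}

place_genes <- function(config, planted) {
  chroms <- config$chroms
  auto_x <- chroms[setdiff(names(chroms), "chrY")]
  ph <- planted[planted$class == "phenotype", , drop = FALSE]
  rows <- list()
  # one gene whose body covers each phenotype region
  for (i in seq_len(nrow(ph))) {
    center <- (ph$start[i] + ph$end[i]) / 2
    st <- max(0, floor(center - config$gene_width / 2))
    rows[[length(rows) + 1]] <- data.frame(
      chrom = ph$chrom[i], start = st, end = st + config$gene_width,
      gene_id = sprintf("geneP%03d", i), strand = sample(c("+", "-"), 1),
      stringsAsFactors = FALSE)
  }
  n_bg <- max(0, config$n_genes - nrow(ph))
  ch <- sample(names(auto_x), n_bg, replace = TRUE,
               prob = auto_x / sum(auto_x))
  for (i in seq_len(n_bg)) {
    st <- floor(stats::runif(1) * (auto_x[[ch[i]]] - config$gene_width))
    rows[[length(rows) + 1]] <- data.frame(
      chrom = ch[i], start = st, end = st + config$gene_width,
      gene_id = sprintf("geneB%03d", i), strand = sample(c("+", "-"), 1),
      stringsAsFactors = FALSE)
  }
  g <- do.call(rbind, rows)
  # single-exon models, fully coding (no UTRs) -- enough structure for
  # promoter/upstream/exon annotation
  data.frame(g[c("chrom", "start", "end", "gene_id", "strand")],
             thick_start = g$start, thick_end = g$end,
             block_sizes = as.character(g$end - g$start),
             block_starts = "0", stringsAsFactors = FALSE)
}

# comparisons in which the focal (other-vs-baseline) groups differ in sex
# phenotype; coupled genes become DEGs there with sign opposite to the
# methylation shift (low methylation in males -> high expression in males)
PHENOTYPE_DEG_COMPARISONS <- c("XX.F_vs_XY.M", "XY.F_vs_XY.M")

make_deg_tables <- function(config, planted, genes) {
  ph_genes <- genes$gene_id[grepl("^geneP", genes$gene_id)]
  coupled <- ph_genes[stats::runif(length(ph_genes)) < config$coupling]
  ph <- planted[planted$class == "phenotype", , drop = FALSE]
  sign_expr <- -ph$sign[match(coupled, sprintf("geneP%03d", seq_len(nrow(ph))))]
  truth <- data.frame(
    gene_id = rep(coupled, length(PHENOTYPE_DEG_COMPARISONS)),
    comparison = rep(PHENOTYPE_DEG_COMPARISONS, each = length(coupled)),
    true_lfc = rep(sign_expr * config$deg_lfc,
                   length(PHENOTYPE_DEG_COMPARISONS)),
    class = rep("phenotype", 2 * length(coupled)),
    stringsAsFactors = FALSE)
  tables <- lapply(stats::setNames(nm = names(default_designs())), function(cmp) {
    tl <- truth[truth$comparison == cmp, , drop = FALSE]
    lfc <- stats::rnorm(nrow(genes), 0, 0.3)
    padj <- stats::runif(nrow(genes), 0.1, 1)
    hit <- match(tl$gene_id, genes$gene_id)
    lfc[hit] <- tl$true_lfc + stats::rnorm(length(hit), 0, 0.2)
    padj[hit] <- stats::runif(length(hit), 1e-8, 1e-3)
    data.frame(gene_id = genes$gene_id, log2fc = lfc, padj = padj,
               chrom = genes$chrom, stringsAsFactors = FALSE)
  })
  list(truth = truth, tables = tables)
}

make_state_track <- function(chroms, n_states) {
  labels <- c("TssA", "Enh", "Tx", "Het", "Quies")[seq_len(min(5, n_states))]
  rows <- list()
  for (ch in names(chroms)) {
    brk <- sort(unique(c(0, floor(stats::runif(
      max(1, round(chroms[[ch]] / 10000)) ) * chroms[[ch]]), chroms[[ch]])))
    rows[[ch]] <- data.frame(
      chrom = ch, start = brk[-length(brk)], end = brk[-1],
      label = sample(labels, length(brk) - 1, replace = TRUE))
  }
  df <- do.call(rbind, rows)
  df <- df[df$end > df$start, , drop = FALSE]
  bed_granges(df$chrom, df$start, df$end, label = df$label)
}

#' Simulate a RepeatMasker-like track with optional planted overlap bias
#'
#' Repeat elements are placed uniformly on the genome, except that families
#' with `multiplier` m != 1 are placed so that planted truth regions overlap
#' them at m times the background rate: with probability
#' q = (m - 1) p0 / (1 - p0) (p0 = uniform-placement overlap probability) an
#' element is dropped onto a random planted region instead of a uniform
#' position; for m < 1 an element landing on a planted region is kept only
#' with probability m and otherwise re-placed off the planted set.
#'
#' @param config a `SimulationConfig` (uses `repeat_families`, `chroms`).
#' @param truth a `TruthSet` (uses `planted_regions`).
#' @return `GRanges` with mcols `family`, `subfamily`.
#' @export
simulate_repeat_track <- function(config, truth) {
  chroms <- config$chroms
  planted <- truth$planted_regions
  G <- sum(chroms)
  rows <- list()
  for (fam in names(config$repeat_families)) {
    f <- config$repeat_families[[fam]]
    if (f$multiplier < 0) stop("repeat multiplier must be >= 0")
    if (f$n == 0) next
    # probability that one uniformly placed element overlaps >=1 planted
    # region: sum over regions of (region width + element width - 1) / G
    p0 <- if (nrow(planted)) {
      min(0.99, sum(planted$end - planted$start + f$width - 1) / G)
    } else 0
    q <- if (f$multiplier > 1 && p0 > 0) {
      min(1, (f$multiplier - 1) * p0 / (1 - p0))
    } else 0
    ch <- sample(names(chroms), f$n, replace = TRUE,
                 prob = chroms / sum(chroms))
    st <- vapply(ch, function(c1) {
      floor(stats::runif(1) * max(1, chroms[[c1]] - f$width))
    }, 0)
    if (nrow(planted)) {
      redirect <- stats::runif(f$n) < q
      for (i in which(redirect)) {
        r <- planted[sample(nrow(planted), 1), ]
        lo <- max(0, r$start - f$width + 1)
        st[i] <- lo + floor(stats::runif(1) * (r$end - lo))
        ch[i] <- r$chrom
      }
      if (f$multiplier < 1) {
        pgr <- bed_granges(planted$chrom, planted$start, planted$end)
        for (i in seq_len(f$n)) {
          for (try in 1:1000) {
            hit <- IRanges::overlapsAny(
              bed_granges(ch[i], st[i], st[i] + f$width), pgr)
            if (!hit || stats::runif(1) < f$multiplier) break
            ch[i] <- sample(names(chroms), 1, prob = chroms / sum(chroms))
            st[i] <- floor(stats::runif(1) * max(1, chroms[[ch[i]]] - f$width))
          }
        }
      }
    }
    rows[[fam]] <- data.frame(
      chrom = ch, start = st, end = st + f$width, family = fam,
      subfamily = sample(f$subfamilies, f$n, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(GenomicRanges::GRanges())
  df <- do.call(rbind, rows)
  bed_granges(df$chrom, df$start, df$end, family = df$family,
              subfamily = df$subfamily)
}

#' Write all generator outputs to a directory
#'
#' Emits the formats [read_track()] and [read_cpg_report()] consume:
#' per-sample CpG reports, cgi.bed, genes.bed12, chromatin.bed,
#' repeats.bed, deg_<comparison>.tsv, truth tables, genome.tsv and the
#' configuration (JSON).
#'
#' @param cohort result of [simulate_cohort()].
#' @param config the `SimulationConfig` used.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$samples) {
    write_cpg_report(s, file.path(dir, paste0(s$sample_id, ".cpg.tsv")))
  }
  write_bed(cohort$tracks$cgi, file.path(dir, "cgi.bed"))
  write_bed(cohort$tracks$chromatin, file.path(dir, "chromatin.bed"))
  rp <- cohort$tracks$repeats
  S4Vectors::mcols(rp) <- S4Vectors::mcols(rp)[c("subfamily", "family")]
  write_bed(rp, file.path(dir, "repeats.bed"))
  g <- cohort$tracks$genes$genes
  bed12 <- data.frame(g$chrom, g$start, g$end, g$gene_id, 0, g$strand,
                      g$start, g$end, "0", 1, g$end - g$start, "0")
  utils::write.table(bed12, file.path(dir, "genes.bed12"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (cmp in names(cohort$deg_tables)) {
    utils::write.table(cohort$deg_tables[[cmp]],
                       file.path(dir, paste0("deg_", cmp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(cohort$truth$planted_regions,
                     file.path(dir, "truth_regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$deg_truth,
                     file.path(dir, "truth_deg.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(chrom = names(config$chroms), length = config$chroms),
    file.path(dir, "genome.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  cfg <- unclass(config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
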