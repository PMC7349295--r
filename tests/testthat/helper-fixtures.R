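# shared fixture builders -- everything is generated in code, no data files

# a MethylomeSample from parallel vectors
mk_sample <- function(chrom, pos, meth, total, id = "s1", group = "XX.F") {
  methylome_sample(id, group,
                   data.frame(chrom = chrom, pos = pos, meth = meth,
                              total = total))
}

# n sites on one chromosome with given levels and constant depth
mk_flat_sample <- function(n, level = 0.5, depth = 10L, chrom = "chr1",
                           spacing = 1000L, id = "s1", group = "XX.F") {
  pos <- seq.int(spacing, by = spacing, length.out = n)
  mk_sample(chrom, pos, round(level * depth), depth, id, group)
}

# a BED12-style gene record row
mk_gene_row <- function(gene_id, chrom, start, end, strand,
                        thick_start = start, thick_end = end,
                        block_sizes = as.character(end - start),
                        block_starts = "0") {
  data.frame(chrom = chrom, start = start, end = end, gene_id = gene_id,
             strand = strand, thick_start = thick_start,
             thick_end = thick_end, block_sizes = block_sizes,
             block_starts = block_starts, stringsAsFactors = FALSE)
}

# random DMR-like table
mk_random_regions <- function(n, chroms = c("chr1", "chrX"), max_pos = 1e5,
                              width_range = c(50, 500)) {
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  st <- sample.int(max_pos, n)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = st,
             end = st + w, stringsAsFactors = FALSE)
}

# brute-force overlap of a single interval pair (0-based half-open)
bf_overlap <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))

# tiny cohort config for fast end-to-end tests
small_config <- function(seed, ...) {
  simulation_config(
    chroms = c(chr1 = 6e5, chrX = 4e5, chrY = 1e5),
    n_islands = 8L,
    effects = list(
      phenotype = list(n = 3L, width = 300L, delta = 0.3, sign = -1),
      x_dosage = list(n = 3L, width = 300L, delta = 0.3, sign = -1),
      y_linked = list(n = 3L, width = 300L, delta = 0.3, sign = -1)),
    n_genes = 25L,
    repeat_families = list(
      L1 = list(n = 40L, width = 300L, multiplier = 1,
                subfamilies = "L1Md_T"),
      Alu = list(n = 40L, width = 150L, multiplier = 1, subfamilies = "B1")),
    seed = seed, ...)
}

# reciprocal-overlap matching of truth regions vs called regions;
# returns indices of truth rows recovered and called rows matching truth
match_regions <- function(truth, called, frac = 0.5) {
  if (nrow(truth) == 0 || nrow(called) == 0) {
    return(list(truth_hit = integer(), called_hit = integer()))
  }
  th <- integer(); ch <- integer()
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(nrow(called))) {
      if (truth$chrom[i] != called$chrom[j]) next
      ov <- bf_overlap(truth$start[i], truth$end[i],
                       called$start[j], called$end[j])
      if (ov >= frac * (truth$end[i] - truth$start[i]) &&
          ov >= frac * (called$end[j] - called$start[j])) {
        th <- c(th, i); ch <- c(ch, j)
      }
    }
  }
  list(truth_hit = unique(th), called_hit = unique(ch))
}
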