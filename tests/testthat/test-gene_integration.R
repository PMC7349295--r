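test_that("proximal gene assignment honours the 5 kb upstream cutoff", {
  genes <- build_gene_models(rbind(
    mk_gene_row("gA", "chr1", 50000, 60000, "+"),
    mk_gene_row("gB", "chr1", 62000, 70000, "+")))
  # 3 kb upstream of gA's TSS (TSS 50000): [46900,47100) -> upstream_1to5kb
  a <- assign_proximal_genes(
    data.frame(chrom = "chr1", start = 46900L, end = 47100L), genes)
  expect_equal(a$gene_id, "gA")
  expect_equal(a$feature, "upstream_1to5kb")
  # 6 kb upstream -> unassigned
  expect_equal(nrow(assign_proximal_genes(
    data.frame(chrom = "chr1", start = 43900L, end = 44100L), genes)), 0)
  # a region spanning gA's body and gB's promoter -> two assignments
  b <- assign_proximal_genes(
    data.frame(chrom = "chr1", start = 59000L, end = 61500L), genes)
  expect_setequal(b$gene_id, c("gA", "gB"))
  expect_equal(b$feature[b$gene_id == "gB"], "promoter")
})

test_that("proximal assignment matches a brute-force interval scan", {
  set.seed(161)
  rows <- lapply(1:12, function(i) {
    st <- sample.int(2e5, 1)
    mk_gene_row(paste0("g", i), sample(c("chr1", "chrX"), 1), st, st + 4000,
                sample(c("+", "-"), 1))
  })
  genes <- build_gene_models(do.call(rbind, rows))
  regions <- mk_random_regions(60, max_pos = 2.1e5)
  got <- assign_proximal_genes(regions, genes)
  gdf <- genes$genes
  for (i in seq_len(nrow(regions))) {
    hits <- character()
    for (j in seq_len(nrow(gdf))) {
      if (regions$chrom[i] != gdf$chrom[j]) next
      foot_s <- if (gdf$strand[j] == "+") gdf$start[j] - 5000 else gdf$start[j]
      foot_e <- if (gdf$strand[j] == "+") gdf$end[j] else gdf$end[j] + 5000
      if (bf_overlap(regions$start[i], regions$end[i], foot_s, foot_e) > 0) {
        hits <- c(hits, gdf$gene_id[j])
      }
    }
    mine <- got$gene_id[got$start == regions$start[i] &
                          got$chrom == regions$chrom[i]]
    expect_setequal(mine, hits)
  }
})

test_that("deg_filter applies strict cutoffs and matches enumeration", {
  deg <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(1.5, -2.0, 2.0, 0.2),
                    padj = c(0.01, 0.01, 0.05, 0.001),
                    chrom = "chr1")
  expect_equal(deg_filter(deg), "b")  # 1.5 exactly and padj 0.05 excluded

  set.seed(171)
  deg2 <- data.frame(gene_id = sprintf("g%03d", 1:200),
                     log2fc = stats::runif(200, -3, 3),
                     padj = stats::runif(200), chrom = "chr1")
  expect_setequal(deg_filter(deg2),
                  deg2$gene_id[abs(deg2$log2fc) > 1.5 & deg2$padj < 0.05])
})

test_that("hypergeometric overlap reproduces closed forms and tail sums", {
  # printed expectations from the cross-species comparisons
  expect_equal(round(hyper_overlap(1087, 2128, 15212, 266)$expected, 2),
               152.06)
  expect_equal(round(hyper_overlap(403, 550, 567, 399)$expected, 2), 390.92)
  expect_equal(round(hyper_overlap(313, 361, 15212, 10)$expected, 2), 7.43)
  expect_equal(round(hyper_overlap(393, 287, 567, 226)$expected, 2), 198.93)

  # p matches a brute-force hypergeometric tail sum on a small universe
  set.seed(181)
  for (rep in 1:5) {
    N <- sample(30:200, 1)
    n1 <- sample.int(N, 1); n2 <- sample.int(N, 1)
    obs <- sample(max(0, n1 + n2 - N):min(n1, n2), 1)
    got <- hyper_overlap(n1, n2, N, obs)
    ks <- max(0, n1 + n2 - N):min(n1, n2)
    pmf <- choose(n2, ks) * choose(N - n2, n1 - ks) / choose(N, n1)
    expect_equal(got$p_enrich, sum(pmf[ks >= obs]), tolerance = 1e-10)
    expect_equal(got$p_deplete, sum(pmf[ks <= obs]), tolerance = 1e-10)
    expect_equal(got$expected, n1 * n2 / N)
  }

  # degenerate cases
  expect_equal(overlap_test(character(), c("a"), c("a", "b"))$p_enrich, 1)
  d <- overlap_test(c("a", "b"), c("a", "b"), c("a", "b"))
  expect_equal(d$observed, 2)
  expect_equal(d$expected, 2)
})

test_that("directional association reproduces the printed contingency tests", {
  # 42 lower-meth/higher-expr, 4 lower/lower, 1 higher/higher, 21 higher/lower
  t1 <- directional_association(c(42, 4, 1, 21))
  expect_equal(t1$p, 2.511e-11, tolerance = 1e-3)
  t2 <- directional_association(c(37, 2, 0, 9))
  expect_equal(t2$p, 1.478e-8, tolerance = 1e-3)
  # agrees with the reference implementation (independent oracle)
  ref <- stats::chisq.test(matrix(c(42, 4, 1, 21), 2, byrow = TRUE))
  expect_equal(t1$chi2, unname(ref$statistic))
  expect_equal(t1$p, unname(ref$p.value))

  # invariance under simultaneous swap of both row and column labels
  swapped <- directional_association(matrix(c(21, 1, 4, 42), 2, byrow = TRUE))
  expect_equal(swapped$chi2, t1$chi2)
  expect_equal(swapped$p, t1$p)

  # balanced table: statistic floors at 0, p = 1
  bal <- directional_association(c(10, 10, 10, 10))
  expect_equal(bal$chi2, 0)
  expect_equal(bal$p, 1)
})

test_that("TSS distances match a brute-force nearest search", {
  sdmrs <- data.frame(chrom = "chr1", start = c(12000L, 30000L),
                      end = c(12300L, 30500L))
  tss <- data.frame(chrom = "chr1", pos = c(10000L, 12100L, 40000L),
                    direction = c("up", "up", "down"))
  out <- tss_distance_distribution(tss, sdmrs)
  # gap convention: bases strictly between (12001..30000 vs TSS 10000 ->
  # 2000; TSS 40000 vs last region base 30500 -> 9499)
  expect_equal(out$distance, c(2000, 0, 9499))
  expect_s3_class(attr(out, "ecdf"), "ecdf")
  expect_named(attr(out, "ecdf_by"), c("down", "up"))

  set.seed(191)
  for (rep in 1:5) {
    s <- mk_random_regions(10, chroms = "chr1", max_pos = 1e5)
    t <- data.frame(chrom = "chr1", pos = sample.int(1.1e5, 20))
    got <- tss_distance_distribution(t, s)$distance
    # gap convention: bases strictly between the point and the region
    bf <- vapply(t$pos, function(p) {
      min(vapply(seq_len(nrow(s)), function(j) {
        if (p > s$start[j] && p <= s$end[j]) 0
        else if (p <= s$start[j]) s$start[j] - p
        else p - s$end[j] - 1
      }, 0))
    }, 0)
    expect_equal(got, bf)
  }
})

test_that("ortholog overlap tests use the class-restricted universe", {
  set.seed(201)
  orth <- data.frame(
    mouse_gene = sprintf("m%03d", 1:100),
    human_gene = sprintf("h%03d", 1:100),
    chrom_class = rep(c("autosomal", "X"), c(70, 30)))
  mouse <- sprintf("m%03d", sample.int(100, 40))
  human <- sprintf("h%03d", sample.int(100, 50))
  res <- ortholog_overlap_test(mouse, human, orth, "X")
  xs <- orth[orth$chrom_class == "X", ]
  n1 <- sum(xs$mouse_gene %in% mouse)
  n2 <- sum(xs$human_gene %in% human)
  expect_equal(res$N, 30)
  expect_equal(res$n1, n1)
  expect_equal(res$n2, n2)
  expect_equal(res$observed,
               sum(xs$mouse_gene %in% mouse & xs$human_gene %in% human))
  # empty set: observed 0, expected 0, p 1
  e <- ortholog_overlap_test(character(), human, orth, "X")
  expect_equal(e$observed, 0)
  expect_equal(e$expected, 0)
  expect_equal(e$p_enrich, 1)
})
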