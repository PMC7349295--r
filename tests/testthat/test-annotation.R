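test_that("CGI geography tiers and boundary truncation", {
  genome <- c(chr1 = 2e5)
  geo <- build_cgi_geography(
    data.frame(chrom = "chr1", start = 100000L, end = 101000L), genome)
  sh <- granges_bed(geo$shores)
  expect_equal(sh$start, c(98000L, 101000L))
  expect_equal(sh$end, c(100000L, 103000L))
  sv <- granges_bed(geo$shelves)
  expect_equal(sv$start, c(96000L, 103000L))
  expect_equal(sv$end, c(98000L, 105000L))

  # island at the chromosome start: left flanks truncated away
  geo2 <- build_cgi_geography(
    data.frame(chrom = "chr1", start = 0L, end = 500L), genome)
  sh2 <- granges_bed(geo2$shores)
  expect_equal(nrow(sh2), 1)
  expect_equal(c(sh2$start, sh2$end), c(500L, 2500L))

  expect_error(build_cgi_geography(
    data.frame(chrom = "chr1", start = 0L, end = 3e5), genome), "bounds")
})

test_that("overlapping flanks resolve to the nearer island (priority)", {
  genome <- c(chr1 = 1e5)
  # two islands 3 kb apart: the 3 kb between is all shore (within 2 kb of
  # one island or the other), never shelf
  geo <- build_cgi_geography(
    data.frame(chrom = "chr1", start = c(10000L, 14000L),
               end = c(11000L, 15000L)), genome)
  mid <- bed_granges("chr1", 11000, 14000)
  shore_cov <- sum(GenomicRanges::width(GenomicRanges::intersect(
    geo$shores, mid)))
  shelf_cov <- sum(GenomicRanges::width(GenomicRanges::intersect(
    geo$shelves, mid)))
  expect_equal(shore_cov, 3000)
  expect_equal(shelf_cov, 0)
})

test_that("CGI categories partition the genome for random island sets", {
  set.seed(131)
  genome <- c(chr1 = 3e5, chr2 = 1e5)
  for (rep in 1:5) {
    n <- sample(1:6, 1)
    ch <- sample(names(genome), n, replace = TRUE)
    st <- vapply(ch, function(c1) sample.int(genome[[c1]] - 2000, 1), 1L)
    geo <- build_cgi_geography(
      data.frame(chrom = ch, start = st, end = st + sample(200:2000, n)),
      genome)
    covered <- sum(vapply(geo, function(g) {
      sum(GenomicRanges::width(g))
    }, 0))
    expect_equal(covered, sum(genome))
    # pairwise disjoint
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(sum(GenomicRanges::width(GenomicRanges::intersect(
        geo[[i]], geo[[j]], ignore.strand = TRUE))), 0)
    }
  }
})

test_that("annotate_regions is multi-label with an intergenic fallback", {
  genome <- c(chr1 = 1e5)
  geo <- build_cgi_geography(
    data.frame(chrom = "chr1", start = 50000L, end = 51000L), genome)
  # gene A exon at [20000,25000); gene B TSS at 20500 (+ strand): its
  # promoter [19500,20500) overlaps gene A's exon region
  genes <- build_gene_models(rbind(
    mk_gene_row("A", "chr1", 20000, 25000, "+"),
    mk_gene_row("B", "chr1", 20500, 30000, "+")))
  states <- bed_granges("chr1", c(0, 60000), c(60000, 1e5),
                        label = c("Enh", "Quies"))
  # region inside A's exon and B's promoter
  r <- data.frame(chrom = "chr1", start = 20100L, end = 20200L)
  tab <- annotate_regions(r, cgi = geo, genes = genes, chromatin = states)
  cnt <- function(track, cat) tab$count[tab$track == track &
                                          tab$category == cat]
  expect_equal(cnt("genic", "exon"), 1)
  expect_equal(cnt("genic", "promoter"), 1)
  expect_equal(cnt("genic", "intergenic"), 0)
  expect_equal(cnt("cgi", "inter_cgi"), 1)
  expect_equal(cnt("chromatin", "Enh"), 1)
  expect_equal(cnt("chromatin", "Quies"), 0)

  # region overlapping nothing genic
  r2 <- data.frame(chrom = "chr1", start = 90000L, end = 90300L)
  tab2 <- annotate_regions(r2, cgi = geo, genes = genes, chromatin = states)
  expect_equal(tab2$count[tab2$track == "genic" &
                            tab2$category == "intergenic"], 1)
  expect_equal(tab2$count[tab2$track == "cgi" &
                            tab2$category == "inter_cgi"], 1)
})

test_that("annotation counts match a brute-force overlap tally", {
  set.seed(141)
  genome <- c(chr1 = 1e5, chrX = 5e4)
  isl <- data.frame(chrom = "chr1", start = c(10000L, 40000L),
                    end = c(11000L, 41000L))
  geo <- build_cgi_geography(isl, genome)
  regions <- mk_random_regions(100, chroms = c("chr1", "chrX"),
                               max_pos = 45000)
  tab <- annotate_regions(regions, cgi = geo)
  for (nm in c("islands", "shores", "shelves", "inter_cgi")) {
    cat_nm <- c(islands = "island", shores = "shore", shelves = "shelf",
                inter_cgi = "inter_cgi")[[nm]]
    bed <- granges_bed(geo[[nm]])
    bf <- sum(vapply(seq_len(nrow(regions)), function(i) {
      any(bed$chrom == regions$chrom[i] &
            bed$start < regions$end[i] & regions$start[i] < bed$end)
    }, TRUE))
    expect_equal(tab$count[tab$category == cat_nm], bf)
  }
})

test_that("matched random regions reproduce the query distance histogram", {
  set.seed(151)
  genome <- c(chr1 = 5e5, chrX = 2e5)
  genes <- build_gene_models(rbind(
    mk_gene_row("g1", "chr1", 100000, 110000, "+"),
    mk_gene_row("g2", "chr1", 300000, 310000, "-"),
    mk_gene_row("g3", "chrX", 50000, 60000, "+")))
  gb <- gene_body_granges(genes)
  query <- mk_random_regions(40, chroms = c("chr1", "chrX"), max_pos = 1.8e5,
                             width_range = c(100, 400))
  matched <- generate_matched_random_regions(query, genes, genome, seed = 3)
  expect_equal(length(matched), nrow(query))
  expect_true(all(GenomicRanges::width(matched) == 300))
  dist_of <- function(gr) {
    h <- GenomicRanges::distanceToNearest(gr, gb, ignore.strand = TRUE)
    S4Vectors::mcols(h)$distance
  }
  qd <- dist_of(bed_granges(query$chrom, query$start, query$end))
  md <- dist_of(matched)
  brk <- c(-0.5, 0.5, 1e3, 1e4, 1e5, Inf)
  expect_equal(as.vector(table(cut(md, brk))),
               as.vector(table(cut(qd, brk))))

  # all-overlapping query -> all matched regions overlap a gene
  q2 <- data.frame(chrom = "chr1", start = 100500L + 0:4 * 1000L,
                   end = 101000L + 0:4 * 1000L)
  m2 <- generate_matched_random_regions(q2, genes, genome, seed = 4)
  expect_true(all(IRanges::overlapsAny(m2, gb)))

  # determinism under seed
  m3 <- generate_matched_random_regions(query, genes, genome, seed = 3)
  expect_identical(granges_bed(m3), granges_bed(matched))
})

test_that("enrichment incidence threshold is strict at 99.5%", {
  expect_true(enrichment_flag(996L, 1000L))
  expect_false(enrichment_flag(995L, 1000L))
  expect_error(enrichment_flag(1001L, 1000L))
})

test_that("repeat placement bias matches its analytic expectation", {
  # multiplier 3 for Alu: expected overlap pairs ~ 3x the uniform rate
  cfg <- small_config(seed = 17)
  cfg$repeat_families$Alu$multiplier <- 3
  set.seed(cfg$seed)
  planted <- data.frame(
    chrom = rep(c("chr1", "chrX"), each = 5),
    start = c(1:5 * 1e5, 1:5 * 7e4), class = "phenotype",
    delta = 0.3, sign = -1)
  planted$end <- planted$start + 300L
  truth <- structure(list(planted_regions = planted), class = "TruthSet")
  reps <- lapply(1:6, function(i) {
    set.seed(1000 + i)
    simulate_repeat_track(cfg, truth)
  })
  count_fam <- function(gr, fam) {
    sub <- gr[S4Vectors::mcols(gr)$family == fam]
    length(GenomicRanges::findOverlaps(
      bed_granges(planted$chrom, planted$start, planted$end), sub))
  }
  alu <- mean(vapply(reps, count_fam, 0, fam = "Alu"))
  l1 <- mean(vapply(reps, count_fam, 0, fam = "L1"))
  G <- sum(cfg$chroms)
  e_alu <- 40 * sum(planted$end - planted$start + 150 - 1) / G
  e_l1 <- 40 * sum(planted$end - planted$start + 300 - 1) / G
  # biased family near 3x expectation, unbiased near 1x (binomial-ish noise)
  expect_gt(alu, 1.8 * e_alu)
  expect_lt(l1, 3 * e_l1)
  cfg_bad <- cfg
  cfg_bad$repeat_families$Alu$multiplier <- -1
  expect_error(simulate_repeat_track(cfg_bad, truth), "multiplier")

  # zero families -> empty track
  cfg0 <- small_config(seed = 18)
  cfg0$repeat_families <- list()
  expect_equal(length(simulate_repeat_track(cfg0, truth)), 0)
})
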