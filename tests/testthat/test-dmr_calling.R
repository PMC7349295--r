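# hand-constructable DMC record table
mk_records <- function(pos, p, delta, chrom = "chr1") {
  data.frame(chrom = chrom, pos = as.integer(pos), delta = delta,
             wald = sign(delta) * 6, p = p,
             direction = ifelse(delta < 0, "hypo", "hyper"),
             stringsAsFactors = FALSE)
}

test_that("scan caller finds a single planted run and applies constraints", {
  # 5 significant CpGs spanning 200 bp among null neighbours
  pos <- c(500, 700, 1000, 1050, 1100, 1150, 1200, 1500, 2000)
  p <- c(1, 1, 1e-8, 1e-8, 1e-8, 1e-8, 1e-8, 1, 1)
  delta <- c(0, 0, 0.4, 0.4, 0.4, 0.4, 0.4, 0, 0)
  dmrs <- call_dmr_scan(mk_records(pos, p, delta))
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$start, 999)   # 0-based
  expect_equal(dmrs$end, 1200)
  expect_equal(dmrs$n_cpg, 5)
  expect_equal(dmrs$mean_delta, 0.4)
  expect_equal(dmrs$direction, "hyper")

  # a run of only 2 seeds is rejected (min 3 CpGs)
  expect_equal(nrow(call_dmr_scan(mk_records(
    c(1000, 1100), c(1e-8, 1e-8), c(0.4, 0.4)))), 0)

  # a 3-seed run spanning less than 50 bp is rejected
  expect_equal(nrow(call_dmr_scan(mk_records(
    c(1000, 1010, 1040), rep(1e-8, 3), rep(0.4, 3)))), 0)

  # interior non-seed CpGs dilute mean_delta and count toward n_cpg
  pos2 <- c(1000, 1060, 1120, 1180, 1240)
  p2 <- c(1e-8, 1, 1e-8, 1, 1e-8)
  d2 <- c(0.4, 0.1, 0.4, 0.1, 0.4)
  out2 <- call_dmr_scan(mk_records(pos2, p2, d2))
  expect_equal(out2$n_cpg, 5)
  expect_equal(out2$mean_delta, mean(d2))

  expect_error(call_dmr_scan(mk_records(c(200, 100), c(1, 1), c(0, 0))),
               "sorted")
})

test_that("same-direction regions within 100 bp merge (inclusive)", {
  # two qualifying runs (link_gap 150 splits them); the gap between spans
  # [999,1120) and [1319,1440) is 199 bp: no merge at merge_gap 100,
  # merged at merge_gap 199
  rec <- mk_records(c(1000, 1060, 1120, 1320, 1380, 1440),
                    rep(1e-8, 6), rep(0.4, 6))
  out_nomerge <- call_dmr_scan(rec, link_gap = 150, merge_gap = 100)
  expect_equal(nrow(out_nomerge), 2)
  out_merge <- call_dmr_scan(rec, link_gap = 150, merge_gap = 199)
  expect_equal(nrow(out_merge), 1)
  expect_equal(out_merge$n_cpg, 6)

  # opposite directions never merge
  rec2 <- mk_records(c(1000, 1060, 1120, 1260, 1320, 1380),
                     rep(1e-8, 6), c(0.4, 0.4, 0.4, -0.4, -0.4, -0.4))
  out2 <- call_dmr_scan(rec2)
  expect_equal(nrow(out2), 2)
  expect_setequal(out2$direction, c("hyper", "hypo"))
})

test_that("merge boundary is exactly gap <= 100", {
  mk2 <- function(gap) {
    a <- c(1000, 1060, 1120)
    b <- 1120 + gap + c(1, 61, 121)  # second span starts gap bp after end
    mk_records(c(a, b), rep(1e-8, 6), rep(0.4, 6))
  }
  # link_gap 100 keeps the runs separate at seed spacing > 100
  expect_equal(nrow(call_dmr_scan(mk2(100), link_gap = 100)), 1)  # gap 100: merged
  expect_equal(nrow(call_dmr_scan(mk2(101), link_gap = 100)), 2)  # gap 101: not
})

test_that("tile caller statistics and calling behave", {
  des <- comparison_design("XX.F", "XY.M")
  # identical pooled proportions -> no call
  sb <- mk_flat_sample(6, 0.5, 20L, spacing = 40L, id = "b1", group = "XX.F")
  so <- mk_flat_sample(6, 0.5, 20L, spacing = 40L, id = "o1", group = "XY.M")
  expect_equal(nrow(call_dmr_tiles(list(sb, so), des)), 0)

  # planted tile with delta 0.5 at 20x, 3v3 is called
  set.seed(71)
  pos <- sort(c(sample(1:280, 8), sample(1000:5000, 40)))
  mk <- function(id, group, shift) {
    depth <- pmax(1L, stats::rpois(length(pos), 20))
    lvl <- ifelse(pos <= 300, 0.3 + shift, 0.8)
    mk_sample("chr1", pos, stats::rbinom(length(pos), depth, lvl), depth,
              id, group)
  }
  samp <- c(lapply(1:3, function(i) mk(paste0("b", i), "XX.F", 0.5)),
            lapply(1:3, function(i) mk(paste0("o", i), "XY.M", 0)))
  tiles <- call_dmr_tiles(samp, des)
  expect_true(nrow(tiles) >= 1)
  first <- tiles[tiles$start == 0, ]
  expect_equal(nrow(first), 1)
  expect_equal(first$direction, "hypo")
  expect_lt(first$mean_delta, -0.2)
  expect_equal(first$source, "tile")

  expect_error(call_dmr_tiles(samp, des, width = 0), "width")
})

test_that("tile caller false-call rate under an all-null simulation", {
  set.seed(81)
  pos <- sort(sample.int(3e5, 3000))  # ~1000 occupied tiles
  rho <- 0.05
  mk <- function(id, group) {
    depth <- pmax(10L, stats::rpois(length(pos), 20))
    a <- 0.7 * (1 - rho) / rho; b <- 0.3 * (1 - rho) / rho
    p <- stats::rbeta(length(pos), a, b)
    mk_sample("chr1", pos, stats::rbinom(length(pos), depth, p), depth,
              id, group)
  }
  samp <- c(lapply(1:3, function(i) mk(paste0("b", i), "XX.F")),
            lapply(1:3, function(i) mk(paste0("o", i), "XY.M")))
  tiles <- call_dmr_tiles(samp, comparison_design("XX.F", "XY.M"))
  # BH at q<0.05 + |delta|>0.2: expect essentially nothing; allow the
  # binomial 99% upper bound for 1000 tiles at rate 0.05
  expect_lte(nrow(tiles), 68)
})

test_that("union keeps scan priority and is idempotent", {
  scan <- data.frame(chrom = "chr1", start = c(100L, 900L),
                     end = c(400L, 1200L), n_cpg = 5L, mean_delta = 0.3,
                     direction = "hyper", source = "scan", stat = 10)
  tiles <- data.frame(chrom = "chr1", start = c(300L, 600L, 1200L),
                      end = c(600L, 900L, 1500L), n_cpg = 2L,
                      mean_delta = 0.3, direction = "hyper",
                      source = "tile", stat = 0.01)
  u <- union_dmr(scan, tiles)
  # tile [300,600) overlaps scan -> dropped; [600,900) and [1200,1500) abut
  # scans without sharing a base -> kept
  expect_equal(sum(u$source == "scan"), 2)
  expect_equal(sort(u$start[u$source == "tile"]), c(600L, 1200L))
  expect_identical(union_dmr(u, tiles), u)

  # randomized brute-force overlap-filter oracle
  set.seed(91)
  for (rep in 1:3) {
    s <- mk_random_regions(25)
    t <- mk_random_regions(25)
    s$n_cpg <- 5L; s$mean_delta <- 0.3; s$direction <- "hyper"
    s$source <- "scan"; s$stat <- 1
    t$n_cpg <- 2L; t$mean_delta <- 0.3; t$direction <- "hyper"
    t$source <- "tile"; t$stat <- 0.01
    u2 <- union_dmr(s, t)
    keep_bf <- vapply(seq_len(nrow(t)), function(j) {
      !any(t$chrom[j] == s$chrom &
             pmin(t$end[j], s$end) - pmax(t$start[j], s$start) > 0)
    }, TRUE)
    expect_equal(sum(u2$source == "tile"), sum(keep_bf))
  }
})

test_that("scan output always satisfies the region constraints", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 300
    pos <- sort(sample.int(50000, n))
    p <- 10^stats::runif(n, -9, 0)
    delta <- stats::runif(n, -0.6, 0.6)
    out <- call_dmr_scan(mk_records(pos, p, delta))
    if (nrow(out) == 0) next
    expect_true(all(out$end - out$start >= 50))
    expect_true(all(out$n_cpg >= 3))
    expect_true(all(abs(out$mean_delta) > 0.20))
    expect_true(all(out$direction %in% c("hyper", "hypo")))
    # merged same-direction regions are separated by > 100 bp
    for (ch in unique(out$chrom)) {
      oc <- out[out$chrom == ch, ]
      if (nrow(oc) > 1) {
        gaps <- oc$start[-1] - oc$end[-nrow(oc)]
        same <- oc$direction[-1] == oc$direction[-nrow(oc)]
        expect_true(all(gaps[same] > 100))
      }
    }
  }
})

test_that("DMR BED round-trips", {
  d <- data.frame(chrom = "chr1", start = 10L, end = 400L, n_cpg = 7L,
                  mean_delta = -0.31, direction = "hypo", source = "scan",
                  stat = -55.2)
  path <- withr::local_tempfile(fileext = ".bed")
  write_dmr_bed(d, path)
  expect_equal(read_dmr_bed(path), d)
})
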