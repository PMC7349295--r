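#' Define a two-group comparison
#'
#' Each differential test contrasts an `other` group against a `baseline`
#' group; reported methylation differences are other minus baseline, and the
#' direction label (hyper/hypo) describes the other group relative to the
#' baseline.
#'
#' @param baseline,other group labels (must differ).
#' @param name optional comparison name; defaults to "baseline_vs_other".
#' @return a `ComparisonDesign`.
#' @export
comparison_design <- function(baseline, other, name = NULL) {
  stopifnot(is.character(baseline), is.character(other), baseline != other)
  if (is.null(name)) name <- paste0(baseline, "_vs_", other)
  structure(list(name = name, baseline = baseline, other = other),
            class = "ComparisonDesign")
}

#' The four standard comparisons of the factorial design
#'
#' Baselines follow the convention that the first-named group is the
#' baseline: XX.F vs XY.M (sex), XY.F vs XY.M (phenotype at fixed XY),
#' XX.F vs XY.F (complement at fixed female phenotype), XXPaf.F vs XO.F
#' (X dosage at fixed female phenotype).
#'
#' @return named list of `ComparisonDesign` objects.
#' @export
default_designs <- function() {
  d <- list(
    comparison_design("XX.F", "XY.M"),
    comparison_design("XY.F", "XY.M"),
    comparison_design("XX.F", "XY.F"),
    comparison_design("XXPaf.F", "XO.F"))
  stats::setNames(d, vapply(d, `[[`, "", "name"))
}

# windowed sums of per-replicate counts at the union positions of one
# chromosome; positions and site positions must be sorted
window_sums <- function(union_pos, site_pos, values, half_window) {
  lo <- findInterval(union_pos - half_window - 0.5, site_pos) + 1L
  hi <- findInterval(union_pos + half_window + 0.5, site_pos)
  cs <- c(0, cumsum(values))
  cs[hi + 1L] - cs[lo]
}

#' Window-smoothed group methylation estimates
#'
#' For every CpG observed in any sample of either group, pools methylated and
#' total counts over all of the group's replicates within +/- window_bp/2 of
#' the site (uniform weights, no kernel). Per group this yields the smoothed
#' level mu-hat, the effective coverage (pooled total / number of
#' replicates), and a method-of-moments beta-binomial overdispersion
#' estimate phi-hat, obtained from the Pearson chi-square of all per-CpG,
#' per-replicate counts in the window against the pooled level (floored at
#' zero; pooling every count pair rather than only replicate totals gives
#' the estimate enough degrees of freedom to be usable at 2-3 replicates).
#' Sites with zero pooled total in either group are dropped and tallied in
#' the `dropped` attribute.
#'
#' @param samples list of `MethylomeSample` (both groups mixed).
#' @param design a `ComparisonDesign`.
#' @param window_bp smoothing window width in bp (default 500, i.e. +/-250).
#' @return data.frame (class `SmoothedSites`) with chrom, pos and per group
#'   (suffix `_b` baseline, `_o` other): mu (smoothed level), cov (pooled
#'   window total), neff (cov / replicates), phi (overdispersion as an
#'   intra-class correlation at the pooled depth); attribute `dropped`
#'   counts removed sites.
#' @export
smooth_methylation <- function(samples, design, window_bp = 500L) {
  groups <- vapply(samples, `[[`, "", "group")
  bi <- which(groups == design$baseline)
  oi <- which(groups == design$other)
  if (!length(bi) || !length(oi)) {
    stop("empty group in comparison ", design$name)
  }
  half <- window_bp / 2
  use <- c(bi, oi)
  chroms <- sort(unique(unlist(lapply(samples[use],
                                      function(s) unique(s$sites$chrom)))))
  out <- vector("list", length(chroms))
  dropped <- 0L
  for (k in seq_along(chroms)) {
    ch <- chroms[k]
    per <- lapply(samples[use], function(s) {
      s$sites[s$sites$chrom == ch, , drop = FALSE]
    })
    union_pos <- sort(unique(unlist(lapply(per, `[[`, "pos"))))
    n <- length(union_pos)
    J <- length(use)
    wm <- matrix(0, n, J)   # windowed meth per replicate
    wt <- matrix(0, n, J)   # windowed total per replicate
    wq <- matrix(0, n, J)   # windowed sum of meth^2/total per replicate
    wc <- matrix(0, n, J)   # windowed count of covered CpGs per replicate
    for (j in seq_len(J)) {
      p <- per[[j]]
      if (!nrow(p)) next
      wm[, j] <- window_sums(union_pos, p$pos, p$meth, half)
      wt[, j] <- window_sums(union_pos, p$pos, p$total, half)
      wq[, j] <- window_sums(union_pos, p$pos, p$meth^2 / p$total, half)
      wc[, j] <- window_sums(union_pos, p$pos, rep(1, nrow(p)), half)
    }
    bj <- seq_along(bi)
    oj <- length(bi) + seq_along(oi)
    gb <- group_smooth(wm[, bj, drop = FALSE], wt[, bj, drop = FALSE],
                       wq[, bj, drop = FALSE], wc[, bj, drop = FALSE])
    go <- group_smooth(wm[, oj, drop = FALSE], wt[, oj, drop = FALSE],
                       wq[, oj, drop = FALSE], wc[, oj, drop = FALSE])
    keep <- gb$cov > 0 & go$cov > 0
    dropped <- dropped + sum(!keep)
    out[[k]] <- data.frame(
      chrom = ch, pos = union_pos,
      mu_b = gb$mu, mu_o = go$mu,
      cov_b = gb$cov, cov_o = go$cov,
      neff_b = gb$neff, neff_o = go$neff,
      phi_b = gb$phi, phi_o = go$phi)[keep, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  attr(res, "design") <- design
  class(res) <- c("SmoothedSites", "data.frame")
  res
}

# Per-group pooled level and method-of-moments overdispersion. The Pearson
# chi-square of every per-CpG, per-replicate count pair (m_i, t_i) in the
# window against the pooled mu, X2 = sum_i (m_i - t_i mu)^2 / (mu(1-mu)t_i)
# = (sum m_i^2/t_i - 2 mu sum m_i + mu^2 sum t_i) / (mu(1-mu)), has
# expectation (n_obs - 1) c under variance inflation c; so
# c-hat = max(1, X2 / (n_obs - 1)), reported as the intra-class correlation
# phi = (c-hat - 1) / (T - 1) at pooled depth T.
group_smooth <- function(wm, wt, wq, wc) {
  pooled_m <- rowSums(wm)
  pooled_t <- rowSums(wt)
  J <- ncol(wm)
  mu <- ifelse(pooled_t > 0, pooled_m / pooled_t, NA_real_)
  v <- mu * (1 - mu)
  nobs <- rowSums(wc)
  x2 <- ifelse(v > 0,
               (rowSums(wq) - 2 * mu * pooled_m + mu^2 * pooled_t) / v, 0)
  chat <- ifelse(nobs > 1, pmax(1, x2 / (nobs - 1)), 1)
  phi <- ifelse(pooled_t > 1, (chat - 1) / (pooled_t - 1), 0)
  phi[is.na(phi)] <- 0
  list(mu = mu, cov = pooled_t, neff = pooled_t / J, phi = phi)
}

#' Per-CpG Wald tests on smoothed estimates
#'
#' The statistic is delta / sqrt(v_b + v_o) with, per group,
#' v = mu(1-mu) (1 + (T - 1) phi) / T — the variance of a beta-binomial
#' proportion at the pooled window depth T and intra-class correlation phi.
#' When both groups are degenerate (mu in {0,1}, phi = 0) the variance is
#' floored at 1/(4 T) per group so the statistic stays finite. P-values are
#' two-sided normal tails; no multiple-testing correction is applied at the
#' CpG level (calling uses a fixed stringent p cutoff instead).
#'
#' @param smoothed a `SmoothedSites` from [smooth_methylation()].
#' @return data.frame of DMC records: chrom, pos, delta (other - baseline),
#'   wald, p, direction ("hyper"/"hypo" of other vs baseline; ties "hyper"
#'   at delta 0 never pass calling thresholds).
#' @export
wald_dmc <- function(smoothed) {
  vb <- wald_var(smoothed$mu_b, smoothed$cov_b, smoothed$phi_b)
  vo <- wald_var(smoothed$mu_o, smoothed$cov_o, smoothed$phi_o)
  vsum <- vb + vo
  floorv <- 1 / (4 * smoothed$cov_b) + 1 / (4 * smoothed$cov_o)
  vsum <- ifelse(vsum <= 0, floorv, vsum)
  delta <- smoothed$mu_o - smoothed$mu_b
  wald <- delta / sqrt(vsum)
  data.frame(
    chrom = smoothed$chrom, pos = smoothed$pos, delta = delta, wald = wald,
    p = 2 * stats::pnorm(-abs(wald)),
    direction = ifelse(delta < 0, "hypo", "hyper"),
    stringsAsFactors = FALSE)
}

wald_var <- function(mu, neff, phi) {
  mu * (1 - mu) * (1 + (neff - 1) * phi) / neff
}

#' Smooth and test in one step
#' @inheritParams smooth_methylation
#' @return DMC record data.frame as from [wald_dmc()], sorted by (chrom, pos).
#' @export
dmc_test <- function(samples, design, window_bp = 500L) {
  wald_dmc(smooth_methylation(samples, design, window_bp))
}

#' Call significant differentially methylated CpG sites
#'
#' Both thresholds are strict: p < p_threshold and |delta| > delta_threshold.
#' A record at exactly the threshold is excluded.
#'
#' @param records DMC record data.frame from [wald_dmc()].
#' @param p_threshold p-value cutoff (default 1e-5).
#' @param delta_threshold methylation-difference cutoff (default 0.20).
#' @return the retained subset.
#' @export
call_dmc <- function(records, p_threshold = 1e-5, delta_threshold = 0.20) {
  keep <- records$p < p_threshold & abs(records$delta) > delta_threshold
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the most variable CpG sites across samples
#'
#' Ranks complete-case sites (observed in every sample) by the across-sample
#' variance of raw methylation levels and returns the top n; the resulting
#' matrix is the usual input to PCA / heatmap QC.
#'
#' @param samples list of `MethylomeSample`.
#' @param n number of sites to keep (default 2500).
#' @return list with `sites` (chrom, pos, variance, ranked) and `levels`
#'   (site x sample matrix of raw levels).
#' @export
select_top_variable <- function(samples, n = 2500L) {
  keys <- lapply(samples, function(s) paste(s$sites$chrom, s$sites$pos))
  common <- Reduce(intersect, keys)
  if (!length(common)) {
    return(list(sites = data.frame(chrom = character(), pos = integer(),
                                   variance = numeric()),
                levels = matrix(numeric(), 0, length(samples))))
  }
  lev <- vapply(samples, function(s) {
    idx <- match(common, paste(s$sites$chrom, s$sites$pos))
    s$sites$meth[idx] / s$sites$total[idx]
  }, numeric(length(common)))
  lev <- matrix(lev, nrow = length(common))
  colnames(lev) <- vapply(samples, `[[`, "", "sample_id")
  v <- apply(lev, 1, stats::var)
  ord <- order(v, decreasing = TRUE)
  take <- ord[seq_len(min(n, length(ord)))]
  parts <- strsplit(common[take], " ", fixed = TRUE)
  list(
    sites = data.frame(chrom = vapply(parts, `[`, "", 1),
                       pos = as.integer(vapply(parts, `[`, "", 2)),
                       variance = v[take], stringsAsFactors = FALSE),
    levels = lev[take, , drop = FALSE])
}
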