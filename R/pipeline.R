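#' Default stage thresholds
#'
#' The defaults are the ones the analysis is defined with: 500 bp smoothing
#' window, sDMC at p < 1e-5 and |delta| > 0.20; scan regions >= 50 bp,
#' >= 3 CpGs, merged within 100 bp; 300 bp tiles at q < 0.05; per-CpG depth
#' in [10, 500]; 1000 permutations for repeat enrichment; proximal genes up
#' to 5 kb upstream of the TSS; DEGs at |log2fc| > 1.5 and padj < 0.05.
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(window = 500L, p = 1e-5, delta = 0.20,
       dmr_min_len = 50L, dmr_min_cpg = 3L, dmr_merge_gap = 100L,
       dmr_link_gap = 300L, dmr_min_sig_frac = 0.5,
       tile_width = 300L, tile_q = 0.05,
       depth_min = 10L, depth_max = 500L,
       n_perm = 1000L,
       deg_lfc = 1.5, deg_padj = 0.05)
}

#' Assemble and validate a pipeline run configuration
#'
#' Every threshold must be present explicitly (no hidden defaults at run
#' time); the configuration is echoed verbatim into the run manifest.
#'
#' @param simulation a `SimulationConfig` (the pipeline's input cohort).
#' @param thresholds complete named list as from [default_thresholds()].
#' @param out_dir output directory.
#' @param seed integer master seed; per-stage seeds are derived from it.
#' @return validated `RunConfig` list.
#' @export
run_config <- function(simulation = simulation_config(),
                       thresholds = default_thresholds(),
                       out_dir = tempfile("run"), seed = 1L) {
  missing <- setdiff(names(default_thresholds()), names(thresholds))
  if (length(missing)) {
    stop("run configuration is missing threshold(s): ",
         paste(missing, collapse = ", "))
  }
  structure(list(simulation = simulation, thresholds = thresholds,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "RunConfig")
}

# deterministic per-stage seed: master seed plus a fixed offset per stage
# name (documented derivation; keeps every stage individually reproducible)
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, enrich = 211L)
  (seed + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full pipeline on a simulated cohort
#'
#' Stages: simulate, coverage filter, per-CpG testing and sDMC calling for
#' the four standard comparisons, region calling (scan + tiles + union),
#' factorial classification, annotation, repeat enrichment, and
#' methylation-expression integration. Outputs are written under
#' `config$out_dir`; the returned manifest lists per-stage output files and
#' summary counts. Reruns with the same config and seed are identical
#' (timestamps aside).
#'
#' @param config a `RunConfig`.
#' @param comparisons which of the standard comparisons to run (default all
#'   four).
#' @return the manifest list (also written as manifest.json).
#' @export
run_pipeline <- function(config, comparisons = names(default_designs())) {
  stopifnot(inherits(config, "RunConfig"))
  th <- config$thresholds
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  manifest <- list(seed = config$seed, thresholds = th, stages = list())

  sim_args <- unclass(config$simulation)
  sim_args$seed <- stage_seed(config$seed, "simulate")
  sim <- do.call(simulation_config, sim_args)
  cohort <- simulate_cohort(sim)
  write_cohort(cohort, sim, file.path(config$out_dir, "cohort"))
  manifest$stages$simulate <- list(
    n_samples = length(cohort$samples),
    n_cpg = nrow(cohort$samples[[1]]$sites),
    n_planted = nrow(cohort$truth$planted_regions))

  filtered <- lapply(cohort$samples, filter_coverage,
                     min_depth = th$depth_min, max_depth = th$depth_max)
  manifest$stages$filter <- list(
    sites_after = vapply(filtered, function(s) nrow(s$sites), 0L))

  designs <- default_designs()[comparisons]
  dmc_sets <- list(); dmr_sets <- list(); dmc_counts <- list()
  for (cmp in names(designs)) {
    records <- dmc_test(filtered, designs[[cmp]], window_bp = th$window)
    called <- call_dmc(records, th$p, th$delta)
    scan <- call_dmr_scan(records, th$p, th$delta, th$dmr_min_len,
                          th$dmr_min_cpg, th$dmr_merge_gap, th$dmr_link_gap,
                          th$dmr_min_sig_frac)
    tiles <- call_dmr_tiles(cohort$samples, designs[[cmp]], th$tile_width,
                            th$depth_min, th$depth_max, th$tile_q, th$delta)
    dmrs <- union_dmr(scan, tiles)
    utils::write.table(called, file.path(config$out_dir,
                                         paste0("sdmc_", cmp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_dmr_bed(dmrs, file.path(config$out_dir,
                                  paste0("sdmr_", cmp, ".bed")))
    dmc_sets[[cmp]] <- called
    dmr_sets[[cmp]] <- dmrs
    dmc_counts[[cmp]] <- list(tested = nrow(records), sdmc = nrow(called),
                              scan = nrow(scan), tile = nrow(tiles),
                              sdmr = nrow(dmrs))
  }
  manifest$stages$differential <- dmc_counts

  cls_dmc <- classify_dmc(dmc_sets)
  cls_dmr <- classify_dmr(dmr_sets)
  upset <- intersect_dmc_sets(dmc_sets)
  utils::write.table(cls_dmc, file.path(config$out_dir, "classified_dmc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cls_dmr, file.path(config$out_dir, "classified_dmr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(upset, file.path(config$out_dir, "upset_dmc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$classification <- list(
    n_classified_dmc = nrow(cls_dmc),
    by_class = as.list(table(cls_dmc$class)),
    n_classified_dmr = nrow(cls_dmr))

  cgi <- build_cgi_geography(cohort$tracks$cgi, cohort$tracks$genome)
  anno <- lapply(dmr_sets, function(d) {
    if (nrow(d) == 0) return(NULL)
    annotate_regions(d, cgi = cgi, genes = cohort$tracks$genes,
                     chromatin = cohort$tracks$chromatin)
  })
  manifest$stages$annotation <- lapply(anno, function(a) {
    if (is.null(a)) 0L else sum(a$count)
  })

  enr <- lapply(names(dmr_sets), function(cmp) {
    d <- dmr_sets[[cmp]]
    if (nrow(d) == 0) return(NULL)
    repeat_enrichment(d, cohort$tracks$repeats, cohort$tracks$genes,
                      cohort$tracks$genome, n_perm = th$n_perm,
                      seed = stage_seed(config$seed, "enrich"))
  })
  names(enr) <- names(dmr_sets)
  for (cmp in names(enr)) {
    if (!is.null(enr[[cmp]])) {
      utils::write.table(enr[[cmp]],
                         file.path(config$out_dir,
                                   paste0("repeat_enrichment_", cmp, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  manifest$stages$enrichment <- lapply(enr, function(e) {
    if (is.null(e)) list(enriched = character()) else
      list(enriched = e$family[e$level == "family" & e$enriched])
  })

  integ <- list()
  universe <- cohort$tracks$genes$genes$gene_id
  for (cmp in intersect(names(dmr_sets), names(cohort$deg_tables))) {
    d <- dmr_sets[[cmp]]
    if (nrow(d) == 0) next
    assign <- assign_proximal_genes(d, cohort$tracks$genes)
    degs <- deg_filter(cohort$deg_tables[[cmp]], th$deg_lfc, th$deg_padj)
    test <- deg_enrichment(unique(assign$gene_id), degs, universe)
    tab <- meth_expr_table(d, assign, cohort$deg_tables[[cmp]], degs)
    dir_test <- if (sum(tab) > 0) directional_association(tab) else
      list(chi2 = NA_real_, p = NA_real_)
    integ[[cmp]] <- list(n_proximal = length(unique(assign$gene_id)),
                         n_deg = length(degs),
                         overlap = test$observed, expected = test$expected,
                         p_enrich = test$p_enrich, chi2_p = dir_test$p)
  }
  manifest$stages$integration <- integ

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Build the 2x2 methylation-direction by expression-direction table
#'
#' For genes that are both region-proximal and differentially expressed,
#' cross-tabulates the methylation direction of the proximal region(s)
#' (majority mean_delta sign; "lower" = hypomethylated in the focal group)
#' against the DEG direction ("higher" = positive log2fc). Layout matches
#' [directional_association()]: rows lower/higher methylation, columns
#' higher/lower expression.
#'
#' @param dmrs DMR data.frame for the comparison.
#' @param assignments output of [assign_proximal_genes()] on `dmrs`.
#' @param deg_table full DEG data.frame.
#' @param degs character vector of significant genes ([deg_filter()]).
#' @return 2x2 integer matrix.
#' @export
meth_expr_table <- function(dmrs, assignments, deg_table, degs) {
  common <- intersect(unique(assignments$gene_id), degs)
  m <- matrix(0L, 2, 2,
              dimnames = list(meth = c("lower", "higher"),
                              expr = c("higher", "lower")))
  key <- paste(dmrs$chrom, dmrs$start, dmrs$end)
  for (g in common) {
    a <- assignments[assignments$gene_id == g, , drop = FALSE]
    deltas <- dmrs$mean_delta[match(paste(a$chrom, a$start, a$end), key)]
    meth_dir <- if (mean(sign(deltas)) <= 0) "lower" else "higher"
    lfc <- deg_table$log2fc[match(g, deg_table$gene_id)]
    expr_dir <- if (lfc > 0) "higher" else "lower"
    m[meth_dir, expr_dir] <- m[meth_dir, expr_dir] + 1L
  }
  m
}
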