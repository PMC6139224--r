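#' Run the full methylation-expression integration pipeline
#'
#' Convenience wrapper chaining every stage on a cohort's matrices:
#' covariate-adjusted differential expression with probe-to-gene collapse
#' and DEG calling; probe filtering, rank-sum differential methylation, DMP
#' calling and gene collapse; probe annotation; max-|r| probe pairing over
#' the common gene universe; and MeDEG classification.
#'
#' @param cohort A list with elements `expression`, `methylation`,
#'   `detection`, `metadata`, `expr_annotation`, `meth_annotation`,
#'   `gene_models`, `cpg_islands` (as produced by [generate_cohort()] or
#'   [read_cohort()]).
#' @param use_covariates Adjust the expression model for age, sex and the
#'   first two expression principal components (default TRUE).
#' @param p_thresh,fc_thresh DEG thresholds (defaults 0.05 / 1.5).
#' @param db_thresh DMP median beta-difference threshold (default 0.12).
#' @param p_detect Detection p-value threshold (default 0.01).
#' @param max_dist Maximum probe-to-TSS mapping distance (default 10000).
#' @return List with `deg_probes`, `degs`, `dmp_stats`, `dmgs`, `contexts`,
#'   `universe`, `pairs`, `medegs`, `filtered_beta`.
#' @export
#' @examples
#' ch <- generate_cohort(sim_config(n_genes = 60, n_meth_probes = 150,
#'                                  n_deg = 10, n_dmp = 12,
#'                                  n_medeg_inverse = 3, n_medeg_positive = 1,
#'                                  seed = 42))
#' res <- run_integration_pipeline(ch)
#' glance(res$medegs)
run_integration_pipeline <- function(cohort, use_covariates = TRUE,
                                     p_thresh = 0.05, fc_thresh = 1.5,
                                     db_thresh = 0.12, p_detect = 0.01,
                                     max_dist = 10000) {
  covs <- if (use_covariates) {
    build_covariates(cohort$expression, cohort$metadata)
  }
  deg_probes <- test_differential_expression(
    cohort$expression, cohort$metadata, covariates = covs,
    annotation = cohort$expr_annotation
  )
  degs <- deg_probes |>
    collapse_probes_to_genes() |>
    call_degs(p_thresh = p_thresh, fc_thresh = fc_thresh)

  filtered <- filter_probes(cohort$methylation, cohort$detection,
                            cohort$meth_annotation, p_detect = p_detect)
  dmp_stats <- test_differential_methylation(filtered, cohort$metadata) |>
    call_dmps(p_thresh = p_thresh, db_thresh = db_thresh)

  contexts <- annotate_probes(cohort$meth_annotation, cohort$gene_models,
                              cohort$cpg_islands, max_dist = max_dist)
  dmgs <- collapse_dmps_to_genes(dmp_stats, contexts)

  universe <- build_common_gene_universe(cohort$expr_annotation, contexts)
  pairs <- pair_probes_by_max_correlation(
    cohort$expression, cohort$methylation, universe,
    cohort$expr_annotation, contexts
  )
  medegs <- identify_medegs(degs, dmgs, pairs, contexts)

  list(deg_probes = deg_probes, degs = degs, dmp_stats = dmp_stats,
       dmgs = dmgs, contexts = contexts, universe = universe, pairs = pairs,
       medegs = medegs, filtered_beta = filtered)
}
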