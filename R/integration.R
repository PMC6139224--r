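# Joining the expression and methylation layers per gene and classifying
# methylation-regulated differentially expressed genes (MeDEGs).

#' Pearson correlation coefficient
#'
#' Standard product-moment correlation with input validation. Zero variance
#' in either vector yields `NA` with a warning (such pairs are excluded from
#' probe pairing).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation coefficient in \[-1, 1\], or `NA`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need at least 3 paired observations.")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Zero variance: correlation undefined, returning NA.")
    return(NA_real_)
  }
  cor(x, y)
}

#' Genes represented on both platforms
#'
#' The common gene universe: genes with at least one expression probe and at
#' least one methylation probe mapped to them (nearest TSS within the
#' mapping distance, as recorded in the context table).
#'
#' @param expr_annotation Expression probe annotation (`probe_id`,
#'   `gene_id`).
#' @param meth_contexts Per-probe context table from [annotate_probes()].
#' @return Tibble with a `gene_id` column (sorted); warns when empty.
#' @export
build_common_gene_universe <- function(expr_annotation, meth_contexts) {
  expr_genes <- unique(expr_annotation$gene_id[!is.na(expr_annotation$gene_id)])
  meth_genes <- unique(meth_contexts$gene_id[!is.na(meth_contexts$gene_id)])
  common <- sort(intersect(expr_genes, meth_genes))
  if (length(common) == 0) {
    warn("No genes shared between the expression and methylation platforms.")
  }
  message(sprintf("Common gene universe: %d gene(s).", length(common)))
  tibble(gene_id = common)
}

#' Pair expression and methylation probes by maximum absolute correlation
#'
#' For every gene in the universe, computes the Pearson correlation over all
#' pooled samples (cases and controls together) for every expression-probe
#' x methylation-probe pair and records the pair attaining the maximum
#' absolute correlation. Ties are broken towards the more negative
#' correlation, then lexicographic probe IDs. Pairs with undefined
#' correlation (zero variance) are skipped; genes with no defined pair are
#' dropped with a message.
#'
#' @param expr Wide expression tibble.
#' @param meth Wide beta tibble; must have exactly the same samples.
#' @param universe Gene universe from [build_common_gene_universe()].
#' @param expr_annotation Expression probe-to-gene map.
#' @param meth_contexts Methylation probe context table (probe-to-gene map).
#' @return Tibble `gene_id`, `expr_probe_id`, `meth_probe_id`, `r`,
#'   `n_pairs_considered`.
#' @export
pair_probes_by_max_correlation <- function(expr, meth, universe,
                                           expr_annotation, meth_contexts) {
  es <- sample_cols(expr)
  ms <- sample_cols(meth)
  if (!setequal(es, ms)) {
    abort("Expression and methylation matrices cover different samples.")
  }
  em <- as_probe_matrix(expr)
  mm <- as_probe_matrix(meth)[, colnames(as_probe_matrix(expr)), drop = FALSE]
  ea <- expr_annotation[expr_annotation$probe_id %in% rownames(em), ]
  e_by_gene <- split(match(ea$probe_id, rownames(em)), ea$gene_id)
  m_map <- meth_contexts[!is.na(meth_contexts$gene_id) &
                           meth_contexts$probe_id %in% rownames(mm), ]
  m_by_gene <- split(match(m_map$probe_id, rownames(mm)), m_map$gene_id)

  ng <- nrow(universe)
  gene_out <- expr_out <- meth_out <- character(ng)
  r_out <- numeric(ng)
  npairs_out <- integer(ng)
  kept <- 0L
  dropped <- 0L
  for (g in universe$gene_id) {
    ei <- e_by_gene[[g]]
    mi <- m_by_gene[[g]]
    if (is.null(ei) || is.null(mi)) { dropped <- dropped + 1L; next }
    ei <- ei[order(rownames(em)[ei])]
    mi <- mi[order(rownames(mm)[mi])]
    ex <- t(em[ei, , drop = FALSE])
    mx <- t(mm[mi, , drop = FALSE])
    ok_e <- apply(ex, 2, sd) > 0
    ok_m <- apply(mx, 2, sd) > 0
    if (!any(ok_e) || !any(ok_m)) { dropped <- dropped + 1L; next }
    rmat <- cor(ex[, ok_e, drop = FALSE], mx[, ok_m, drop = FALSE])
    rv <- as.vector(rmat)
    eid <- rep(rownames(rmat), times = ncol(rmat))
    mid <- rep(colnames(rmat), each = nrow(rmat))
    # max |r|; ties -> more negative r, then lexicographic probe IDs
    best <- order(-abs(rv), rv, eid, mid)[1]
    e_idx <- (best - 1L) %% nrow(rmat) + 1L
    m_idx <- (best - 1L) %/% nrow(rmat) + 1L
    kept <- kept + 1L
    gene_out[kept] <- g
    expr_out[kept] <- rownames(rmat)[e_idx]
    meth_out[kept] <- colnames(rmat)[m_idx]
    r_out[kept] <- rv[best]
    npairs_out[kept] <- length(ei) * length(mi)
  }
  if (dropped > 0) {
    message(sprintf("%d gene(s) had no correlatable probe pair.", dropped))
  }
  keep <- seq_len(kept)
  tibble(gene_id = gene_out[keep], expr_probe_id = expr_out[keep],
         meth_probe_id = meth_out[keep], r = r_out[keep],
         n_pairs_considered = npairs_out[keep])
}

medeg_class_levels <- c("inverse-up-hypo", "inverse-down-hyper",
                        "positive-up-hyper", "positive-down-hypo")

promoter_regions <- c("TSS1500", "TSS200", "5'UTR", "1stExon")

#' Identify and classify methylation-regulated DEGs
#'
#' Intersects the called DEG genes with the differentially methylated genes
#' and classifies every overlap gene by the signs of its expression and
#' methylation changes: opposite signs are *inverse* (up-hypo or
#' down-hyper), concordant signs *positive* (up-hyper or down-hypo). The
#' max-|r| pair correlation is attached as supporting evidence and
#' `promoter_dmp` flags genes whose selected DMP lies in a promoter
#' category (TSS1500, TSS200, 5'UTR or first exon).
#'
#' @param degs Gene-level `deg_stats` tibble with `is_deg` (from
#'   [call_degs()]).
#' @param dmgs Gene-level DMG table from [collapse_dmps_to_genes()].
#' @param pairs Gene pair records from [pair_probes_by_max_correlation()].
#' @param contexts Probe context table from [annotate_probes()].
#' @return A `medeg_tbl` tibble with `gene_id`, `log2_fc`, `fc`,
#'   `delta_beta`, `r`, `class`, `promoter_dmp`; overlap counts are
#'   available via [glance()].
#' @export
identify_medegs <- function(degs, dmgs, pairs, contexts) {
  deg_genes <- degs$gene_id[degs$is_deg]
  overlap <- intersect(deg_genes, dmgs$gene_id)
  missing_pairs <- setdiff(overlap, pairs$gene_id)
  if (length(missing_pairs) > 0) {
    abort(sprintf("Overlap gene(s) missing a pair record: %s",
                  paste(head(missing_pairs, 5), collapse = ", ")))
  }
  out <- tibble(gene_id = sort(overlap)) |>
    left_join(select(degs, "gene_id", "log2_fc", "fc"), by = "gene_id") |>
    left_join(select(dmgs, "gene_id", meth_probe_id = "probe_id",
                     "delta_beta"), by = "gene_id") |>
    left_join(select(pairs, "gene_id", "r"), by = "gene_id") |>
    mutate(
      class = case_when(
        .data$log2_fc > 0 & .data$delta_beta < 0 ~ "inverse-up-hypo",
        .data$log2_fc < 0 & .data$delta_beta > 0 ~ "inverse-down-hyper",
        .data$log2_fc > 0 & .data$delta_beta > 0 ~ "positive-up-hyper",
        .default = "positive-down-hypo"
      ),
      promoter_dmp = contexts$region[
        match(.data$meth_probe_id, contexts$probe_id)] %in% promoter_regions
    )
  class(out) <- c("medeg_tbl", class(out))
  out
}

#' Overlap counts for a MeDEG table
#'
#' @param x A `medeg_tbl` from [identify_medegs()].
#' @param ... Unused.
#' @return One-row tibble with the total overlap, inverse/positive counts,
#'   the per-class counts, and `pct_promoter_inverse`: the percentage of
#'   inverse (methylation-regulated) genes whose selected DMP sits in a
#'   promoter category, rounded to the nearest integer.
#' @method glance medeg_tbl
#' @export
glance.medeg_tbl <- function(x, ...) {
  inv <- grepl("^inverse", x$class)
  tibble(
    n_overlap = nrow(x),
    n_inverse = sum(inv),
    n_positive = sum(grepl("^positive", x$class)),
    n_inverse_up_hypo = sum(x$class == "inverse-up-hypo"),
    n_inverse_down_hyper = sum(x$class == "inverse-down-hyper"),
    n_positive_up_hyper = sum(x$class == "positive-up-hyper"),
    n_positive_down_hypo = sum(x$class == "positive-down-hypo"),
    pct_promoter_inverse = if (any(inv)) {
      round(100 * mean(x$promoter_dmp[inv]))
    } else NA_real_
  )
}
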