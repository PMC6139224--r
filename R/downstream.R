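# Downstream interpretation: hypergeometric gene-set enrichment, clinical
# subgroup contrasts of MeDEG expression, and qPCR relative quantities.

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path Path to a `.gmt` file.
#' @return Tibble with `set_name`, `description` and a `genes` list-column.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    set_name = map_chr(parts, 1),
    description = map_chr(parts, 2),
    genes = map(parts, ~ unique(.x[-(1:2)]))
  )
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided upper-tail hypergeometric test per gene set: the probability of
#' observing at least the attained overlap between the query and the set,
#' drawing `|query|` genes from the background without replacement. Sets are
#' intersected with the background before testing; p-values are BH-adjusted
#' across sets. This is a generic enrichment stand-in: with a different
#' database its p-values will not match any specific curated-tool output.
#'
#' @param query Character vector of query genes; must be a subset of
#'   `background`.
#' @param collections Gene sets: a named list of character vectors, or a
#'   tibble from [read_gmt()].
#' @param background Character vector of background genes (non-empty).
#' @return Tibble `set_name`, `overlap`, `set_size`, `query_size`,
#'   `background_size`, `p_raw`, `p_adj`, sorted by `p_raw`.
#' @export
hypergeometric_enrichment <- function(query, collections, background) {
  background <- unique(background)
  if (length(background) == 0) abort("`background` must be non-empty.")
  query <- unique(query)
  if (!all(query %in% background)) {
    abort("`query` must be a subset of `background`.")
  }
  if (is.data.frame(collections)) {
    sets <- setNames(collections$genes, collections$set_name)
  } else {
    sets <- collections
  }
  N <- length(background)
  q <- length(query)
  rows <- imap(sets, function(genes, nm) {
    s <- intersect(unique(genes), background)
    k <- length(intersect(s, query))
    tibble(
      set_name = nm, overlap = k, set_size = length(s),
      query_size = q, background_size = N,
      p_raw = phyper(k - 1, length(s), N - length(s), q, lower.tail = FALSE)
    )
  })
  out <- list_rbind(rows)
  out$p_adj <- adjust_bh(out$p_raw)
  arrange(out, .data$p_raw)
}

#' Compare gene levels between clinical subgroups of cases
#'
#' Two-sided Wilcoxon rank-sum test per gene between case samples with and
#' without the clinical flag (by default interstitial lung disease, the
#' `ild` metadata column). Significance is declared at raw p < 0.05 --
#' deliberately uncorrected, as is conventional for small exploratory
#' subgroup contrasts; interpret accordingly.
#'
#' @param values Wide gene-by-sample tibble (first column gene/probe IDs).
#' @param metadata Sample metadata with `sample_id`, `group` and the
#'   subgroup flag column.
#' @param flag Name of the 0/1 subgroup column (default `"ild"`).
#' @param p_thresh Raw p-value threshold (default 0.05).
#' @return Tibble `gene_id`, `delta` (flagged minus unflagged median),
#'   `direction`, `p_raw`, `significant`.
#' @export
compare_subgroups <- function(values, metadata, flag = "ild",
                              p_thresh = 0.05) {
  if (!flag %in% names(metadata)) {
    abort(sprintf("Metadata has no '%s' column.", flag))
  }
  cases <- filter(metadata, .data$group == "case")
  in_sub <- cases$sample_id[cases[[flag]] == 1]
  out_sub <- cases$sample_id[cases[[flag]] == 0]
  if (length(in_sub) < 2 || length(out_sub) < 2) {
    abort("Both subgroups must contain at least 2 samples.")
  }
  m <- as_probe_matrix(values)
  rows <- map(rownames(m), function(g) {
    x <- m[g, in_sub]
    y <- m[g, out_sub]
    wt <- wilcoxon_rank_sum(x, y)
    tibble(gene_id = g,
           delta = median(x) - median(y),
           direction = if_else(median(x) < median(y), "lower", "higher"),
           p_raw = wt$p_value)
  })
  list_rbind(rows) |>
    mutate(significant = .data$p_raw < p_thresh)
}

#' qPCR relative quantity by the 2^-ddCt method
#'
#' `rq = 2^-[(ct_target - ct_reference) - (calibrator_ct_target -
#' calibrator_ct_reference)]`: the target cycle threshold is normalized to a
#' housekeeping reference gene within each sample, then to a calibrator
#' sample. A relative quantity of 1 means no change relative to the
#' calibrator; each cycle of advantage doubles the quantity.
#'
#' @param ct_target,ct_reference Cycle thresholds in the sample (finite).
#' @param calibrator_ct_target,calibrator_ct_reference Cycle thresholds in
#'   the calibrator.
#' @return Relative quantities (> 0), vectorized over samples.
#' @export
#' @examples
#' relative_quantity(24, 20, 26, 20)  # ddCt = -2 -> 4
relative_quantity <- function(ct_target, ct_reference,
                              calibrator_ct_target, calibrator_ct_reference) {
  cts <- c(ct_target, ct_reference, calibrator_ct_target,
           calibrator_ct_reference)
  if (any(!is.finite(cts))) abort("All Ct values must be finite.")
  ddct <- (ct_target - ct_reference) -
    (calibrator_ct_target - calibrator_ct_reference)
  2^(-ddct)
}
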