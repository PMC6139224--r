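#' Filter methylation probes by detection quality and chromosome
#'
#' Removes any probe whose detection p-value exceeds `p_detect` in at least
#' one sample, and any probe annotated to the X or Y chromosome (both sexes
#' are analysed together). A removal log with counts by reason is attached
#' as an attribute and retrievable with [removal_log()].
#'
#' @param beta Wide probe-by-sample tibble of beta values.
#' @param detect Companion detection p-value tibble, same probes and samples.
#' @param annotation Probe annotation with `probe_id`, `chrom`, `pos`; every
#'   probe in `beta` must be present.
#' @param p_detect Detection p-value threshold (default 0.01).
#' @return The retained rows of `beta`, with attributes `removal_log`
#'   (tibble of `reason`, `n`) and `removed_probes`.
#' @export
filter_probes <- function(beta, detect, annotation, p_detect = 0.01) {
  if (!identical(beta$probe_id, detect$probe_id)) {
    abort("`beta` and `detect` must cover the same probes in the same order.")
  }
  missing <- setdiff(beta$probe_id, annotation$probe_id)
  if (length(missing) > 0) {
    abort(sprintf(
      "%d probe(s) absent from annotation: %s%s",
      length(missing), paste(head(missing, 5), collapse = ", "),
      if (length(missing) > 5) ", ..." else ""
    ))
  }
  dm <- as_probe_matrix(detect)
  stopifnot_probability(dm, "detection p-values")
  fail_detect <- rowSums(dm > p_detect) > 0
  chrom <- annotation$chrom[match(beta$probe_id, annotation$probe_id)]
  on_sex <- chrom %in% c("chrX", "chrY", "X", "Y")
  removed <- tibble(
    probe_id = beta$probe_id[fail_detect | on_sex],
    reason = if_else(fail_detect[fail_detect | on_sex],
                     "detection", "sex_chromosome")
  )
  out <- beta[!(fail_detect | on_sex), ]
  attr(out, "removal_log") <- removed |>
    count(.data$reason, name = "n") |>
    bind_rows(tibble(reason = "retained", n = nrow(out)))
  attr(out, "removed_probes") <- removed
  out
}

#' @rdname filter_probes
#' @param x An object returned by [filter_probes()].
#' @export
removal_log <- function(x) attr(x, "removal_log")

# Normal-approximation two-sided p for the rank-sum statistic, with tie and
# continuity corrections. `w` is the rank sum of the first group (size m out
# of m + n2 observations); `tie_sum` is sum(t^3 - t) over tied groups.
ranksum_normal_p <- function(w, m, n2, tie_sum = 0) {
  N <- m + n2
  e <- m * (N + 1) / 2
  v <- (m * n2 / 12) * ((N + 1) - tie_sum / (N * (N - 1)))
  z <- pmax(abs(w - e) - 0.5, 0)
  ifelse(v <= 0, 1, pmin(2 * stats::pnorm(-z / sqrt(v)), 1))
}

#' Wilcoxon rank-sum test for two samples
#'
#' Exact permutation p-value when the pooled size is at most 12 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' corrections. The reported statistic is the rank sum of `x` in the pooled
#' ranking.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return List with `statistic` (rank sum of `x`) and `p_value`
#'   (two-sided).
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value  # 1/3 by exact enumeration
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("Both groups must be non-empty.")
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_along(x)])
  has_ties <- anyDuplicated(pooled) > 0
  if (length(pooled) <= 12 && !has_ties) {
    p <- wilcox.test(x, y, exact = TRUE)$p.value
  } else {
    ts <- if (has_ties) {
      t <- table(pooled); sum(t^3 - t)
    } else 0
    p <- ranksum_normal_p(w, length(x), length(y), ts)
  }
  list(statistic = w, p_value = p)
}

#' Probe-level differential methylation
#'
#' For every probe, compares case and control beta values and reports the
#' effect size `delta_beta` (median beta in cases minus median beta in
#' controls) and a p-value, BH-adjusted across all tested probes.
#'
#' The default test is the unadjusted Wilcoxon rank-sum test (normal
#' approximation with tie and continuity corrections at usual cohort sizes,
#' consistent with [wilcoxon_rank_sum()]). A rank test cannot absorb
#' covariates, so `method = "ols"` offers a parallel mode that fits
#' `logit(beta) ~ group + covariates` per probe by ordinary least squares,
#' mirroring the expression model; both modes share the delta-beta effect
#' filter applied later by [call_dmps()].
#'
#' @param beta Wide probe-by-sample beta tibble (typically filtered by
#'   [filter_probes()]).
#' @param metadata Sample metadata with `sample_id` and `group`; both groups
#'   need >= 3 samples.
#' @param method `"ranksum"` (default) or `"ols"`.
#' @param covariates Optional covariate tibble for `method = "ols"`; PCs, if
#'   wanted, should be computed on the logit-transformed beta matrix.
#' @return A `dmp_stats` tibble with `probe_id`, `delta_beta`, `w_stat`,
#'   `p_raw`, `p_adj`.
#' @export
test_differential_methylation <- function(beta, metadata,
                                          method = c("ranksum", "ols"),
                                          covariates = NULL) {
  method <- match.arg(method)
  check_samples(beta, metadata, "methylation matrix")
  m <- as_probe_matrix(beta)
  m <- m[, metadata$sample_id, drop = FALSE]
  stopifnot_probability(m, "beta values")
  tab <- table(metadata$group)
  if (length(tab) < 2 || any(tab < 3)) {
    abort("Both groups must be present with at least 3 samples each.")
  }
  is_case <- metadata$group == "case"
  med_case <- apply(m[, is_case, drop = FALSE], 1, median)
  med_ctrl <- apply(m[, !is_case, drop = FALSE], 1, median)
  delta <- med_case - med_ctrl

  if (method == "ranksum") {
    ranks <- t(apply(m, 1, rank))
    w <- rowSums(ranks[, is_case, drop = FALSE])
    tie_sum <- numeric(nrow(m))
    tied <- apply(m, 1, anyDuplicated) > 0
    if (any(tied)) {
      tie_sum[tied] <- apply(m[tied, , drop = FALSE], 1, function(v) {
        t <- table(v); sum(t^3 - t)
      })
    }
    p_raw <- ranksum_normal_p(w, sum(is_case), sum(!is_case), tie_sum)
  } else {
    eps <- 1e-6
    lg <- logit(pmin(pmax(m, eps), 1 - eps))
    fit <- test_differential_expression(
      as_probe_tibble(lg), metadata, covariates = covariates
    )
    w <- rep(NA_real_, nrow(m))
    p_raw <- fit$p_raw[match(rownames(m), fit$probe_id)]
  }
  out <- tibble(
    probe_id = rownames(m),
    delta_beta = unname(delta),
    w_stat = unname(w),
    p_raw = unname(p_raw),
    p_adj = adjust_bh(unname(p_raw))
  )
  class(out) <- c("dmp_stats", class(out))
  out
}

#' Call differentially methylated positions
#'
#' Flags probes with BH-adjusted p-value strictly below `p_thresh` and
#' absolute median beta difference strictly above `db_thresh`. Direction is
#' `"hypo"` when the case median is lower, `"hyper"` when higher.
#'
#' @param stats A `dmp_stats` tibble.
#' @param p_thresh Adjusted p-value threshold (default 0.05, strict).
#' @param db_thresh Median beta-difference threshold (default 0.12, strict).
#' @return The input with `is_dmp` and `direction` columns added.
#' @export
call_dmps <- function(stats, p_thresh = 0.05, db_thresh = 0.12) {
  out <- stats |>
    mutate(
      is_dmp = .data$p_adj < p_thresh & abs(.data$delta_beta) > db_thresh,
      direction = if_else(.data$is_dmp,
                          if_else(.data$delta_beta < 0, "hypo", "hyper"),
                          NA_character_)
    )
  class(out) <- unique(c("dmp_stats", class(out)))
  out
}

#' Collapse called DMPs to differentially methylated genes
#'
#' For each gene owning at least one called DMP, keeps the probe with the
#' largest absolute delta-beta (ties broken by smaller adjusted p-value,
#' then lexicographic probe ID). The winning probe decides the gene's
#' direction label; genes carrying DMPs in both directions are additionally
#' flagged.
#'
#' @param dmps A `dmp_stats` tibble with `is_dmp`/`direction` columns (from
#'   [call_dmps()]).
#' @param mapping Probe-to-gene map with `probe_id`, `gene_id` (e.g. from
#'   [annotate_probes()]). DMPs that map to no gene are dropped with a
#'   message.
#' @return Tibble with one row per differentially methylated gene:
#'   the selected probe's statistics plus `n_dmps` and `both_directions`.
#' @export
collapse_dmps_to_genes <- function(dmps, mapping) {
  called <- filter(dmps, .data$is_dmp)
  called <- left_join(called,
                      select(mapping, "probe_id", "gene_id"),
                      by = "probe_id")
  n_drop <- sum(is.na(called$gene_id))
  if (n_drop > 0) {
    message(sprintf("Dropping %d DMP(s) mapped to no gene.", n_drop))
  }
  called |>
    filter(!is.na(.data$gene_id)) |>
    group_by(.data$gene_id) |>
    mutate(n_dmps = n(),
           both_directions = n_distinct(.data$direction) > 1) |>
    arrange(desc(abs(.data$delta_beta)), .data$p_adj, .data$probe_id,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$gene_id) |>
    relocate("gene_id")
}

#' Direction summary of called DMPs
#'
#' Counts hypo- and hypermethylated DMPs with percentages rounded to the
#' nearest integer.
#'
#' @param dmps A `dmp_stats` tibble with `is_dmp` and `direction`.
#' @return Tibble with `direction`, `n`, `percent`.
#' @export
summarize_dmp_directions <- function(dmps) {
  called <- filter(dmps, .data$is_dmp)
  called |>
    count(.data$direction, name = "n") |>
    mutate(percent = round(100 * .data$n / sum(.data$n)))
}
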