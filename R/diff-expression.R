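#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`: p-values
#' are multiplied by `n / rank`, a right-to-left cumulative minimum enforces
#' monotonicity, and results are capped at 1. Output order matches input
#' order.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04))
adjust_bh <- function(p_values) {
  if (!is.numeric(p_values)) abort("`p_values` must be numeric.")
  stopifnot_probability(p_values, "p_values")
  p.adjust(p_values, method = "BH")
}

#' Per-sample principal-component scores of an expression matrix
#'
#' Computes sample scores on the top-`k` principal axes of the probe-centred
#' matrix (each probe centred across samples), for use as covariates that
#' absorb population stratification. The sign of each component is fixed by
#' making the largest-magnitude probe loading positive.
#'
#' @param matrix Wide probe-by-sample tibble (first column probe IDs).
#' @param k Number of components (default 2); must be < number of samples.
#' @return Tibble with `sample_id` and `pc1` ... `pck` columns; scores have
#'   zero mean across samples.
#' @export
compute_covariate_pcs <- function(matrix, k = 2) {
  m <- as_probe_matrix(matrix)
  n <- ncol(m)
  if (k >= n) abort("`k` must be smaller than the number of samples.")
  if (nrow(m) < 2) abort("Need at least 2 probes to compute PCs.")
  centred <- m - rowMeans(m)
  sv <- svd(centred, nu = k, nv = k)
  scores <- sweep(sv$v[, seq_len(k), drop = FALSE], 2,
                  sv$d[seq_len(k)], `*`)
  for (j in seq_len(k)) {
    if (sv$d[j] < 1e-12) {
      scores[, j] <- 0
    } else {
      load <- sv$u[, j]
      if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
    }
  }
  out <- as_tibble(scores, .name_repair = ~ paste0("pc", seq_len(k)))
  bind_cols(tibble(sample_id = colnames(m)), out)
}

#' Assemble the covariate set for differential expression
#'
#' Bundles age, sex and the first `k` expression principal components
#' (computed from all probes, before any filtering) into one tibble.
#'
#' @param matrix Wide probe-by-sample expression tibble.
#' @param metadata Sample metadata with `sample_id`, `age`, `sex`.
#' @param k Number of principal components (default 2).
#' @return Tibble with columns `sample_id`, `age`, `sex`, `pc1`, ..., `pck`.
#' @export
build_covariates <- function(matrix, metadata, k = 2) {
  check_samples(matrix, metadata, "expression matrix")
  pcs <- compute_covariate_pcs(matrix, k = k)
  metadata |>
    select("sample_id", "age", "sex") |>
    left_join(pcs, by = "sample_id")
}

# design matrix for the per-probe OLS fit; errors on singular designs
# naming the offending column
build_design <- function(metadata, covariates) {
  X <- cbind(`(Intercept)` = 1, group = as.numeric(metadata$group == "case"))
  if (!is.null(covariates)) {
    cv <- covariates[match(metadata$sample_id, covariates$sample_id), ]
    if (anyNA(cv$sample_id)) abort("`covariates` must cover every sample.")
    for (nm in setdiff(names(cv), "sample_id")) {
      v <- cv[[nm]]
      if (is.character(v) || is.factor(v)) v <- as.numeric(v == "M")
      X <- cbind(X, v)
      colnames(X)[ncol(X)] <- nm
    }
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    abort(sprintf("Design matrix is singular; collinear column(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  X
}

#' Probe-level differential expression by covariate-adjusted linear models
#'
#' Fits, per probe, an ordinary least-squares model
#' `log2 value ~ group + covariates` and reports the group coefficient (the
#' covariate-adjusted log2 fold change, case minus control), its
#' t-statistic, the two-sided p-value, and Benjamini-Hochberg adjusted
#' p-values across all tested probes. The signed linear fold change is the
#' back-transformed coefficient, `sign(log2FC) * 2^|log2FC|`, so that the
#' effect estimate and the p-value come from the same model.
#'
#' Probes with identical values in every sample are reported with
#' `log2_fc = 0`, `t_stat = 0` and `p_raw = 1` rather than erroring.
#'
#' @param matrix Wide probe-by-sample expression tibble (log2 scale, no
#'   missing values).
#' @param metadata Sample metadata with `sample_id` and `group`
#'   (`"case"`/`"control"`), both groups with >= 3 samples.
#' @param covariates Optional covariate tibble from [build_covariates()]
#'   (or any tibble with `sample_id` plus numeric columns; a character
#'   `sex` column is coded as an indicator for `"M"`). `NULL` fits the
#'   group-only model, which reduces to the classical pooled two-sample
#'   t-test.
#' @param annotation Optional probe-to-gene annotation
#'   (`probe_id`, `gene_id`) merged into the result.
#' @return A `deg_stats` tibble with columns `probe_id`, `gene_id`,
#'   `log2_fc`, `fc`, `t_stat`, `p_raw`, `p_adj`.
#' @export
test_differential_expression <- function(matrix, metadata, covariates = NULL,
                                         annotation = NULL) {
  check_samples(matrix, metadata, "expression matrix")
  m <- as_probe_matrix(matrix)
  m <- m[, metadata$sample_id, drop = FALSE]
  if (anyNA(m)) abort("Expression matrix contains missing values.")
  tab <- table(metadata$group)
  if (length(tab) < 2 || any(tab < 3)) {
    abort("Both groups must be present with at least 3 samples each.")
  }
  X <- build_design(metadata, covariates)
  n <- nrow(X); p <- ncol(X); df <- n - p
  fit <- stats::lm.fit(X, t(m))
  coefs <- fit$coefficients
  if (is.null(dim(coefs))) {
    coefs <- matrix(coefs, ncol = 1, dimnames = list(names(coefs), NULL))
  }
  beta_g <- unname(coefs["group", ])
  res <- t(m) - X %*% coefs
  sigma2 <- colSums(res^2) / df
  xtx_inv <- solve(crossprod(X))
  se <- sqrt(sigma2 * xtx_inv["group", "group"])
  t_stat <- beta_g / se
  p_raw <- 2 * pt(-abs(t_stat), df)
  # degenerate probes: no variance at all -> no signal
  const_probe <- matrixStats_rowvar(m) < 1e-24
  beta_g[const_probe] <- 0
  t_stat[const_probe] <- 0
  p_raw[const_probe] <- 1
  p_raw[!const_probe & sigma2 < 1e-24] <- 0   # perfect fit, nonzero effect
  out <- tibble(
    probe_id = rownames(m),
    log2_fc = beta_g,
    fc = ifelse(beta_g < 0, -2^(-beta_g), 2^beta_g),
    t_stat = unname(t_stat),
    p_raw = unname(p_raw),
    p_adj = adjust_bh(unname(p_raw))
  )
  if (!is.null(annotation)) {
    out <- left_join(out, select(annotation, "probe_id", "gene_id"),
                     by = "probe_id") |>
      relocate("gene_id", .after = "probe_id")
  }
  class(out) <- c("deg_stats", class(out))
  out
}

matrixStats_rowvar <- function(m) {
  rowSums((m - rowMeans(m))^2) / max(ncol(m) - 1, 1)
}

#' Collapse probe-level statistics to one row per gene
#'
#' Keeps, for each gene, the probe with the largest absolute fold change;
#' ties are broken by smaller adjusted p-value, then lexicographic probe ID.
#' Probes without a gene assignment are dropped (with a message giving the
#' count).
#'
#' @param stats Probe-level `deg_stats` tibble (with a `gene_id` column, or
#'   supply `annotation`).
#' @param annotation Optional `probe_id`/`gene_id` map if `stats` lacks
#'   `gene_id`.
#' @return Gene-level tibble, one row per gene, same columns as `stats`.
#' @export
collapse_probes_to_genes <- function(stats, annotation = NULL) {
  if (!is.null(annotation)) {
    stats <- stats |>
      select(-any_of("gene_id")) |>
      left_join(select(annotation, "probe_id", "gene_id"), by = "probe_id") |>
      relocate("gene_id", .after = "probe_id")
  }
  if (!"gene_id" %in% names(stats)) {
    abort("`stats` must carry `gene_id` (or supply `annotation`).")
  }
  n_drop <- sum(is.na(stats$gene_id))
  if (n_drop > 0) {
    message(sprintf("Dropping %d probe(s) with no gene assignment.", n_drop))
  }
  out <- stats |>
    filter(!is.na(.data$gene_id)) |>
    arrange(desc(abs(.data$fc)), .data$p_adj, .data$probe_id) |>
    distinct(.data$gene_id, .keep_all = TRUE) |>
    arrange(.data$gene_id)
  class(out) <- unique(c("deg_stats", class(out)))
  out
}

#' Call differentially expressed genes
#'
#' Flags genes with BH-adjusted p-value strictly below `p_thresh` and
#' absolute fold change strictly above `fc_thresh`, and labels the direction
#' of change.
#'
#' @param gene_stats Gene-level `deg_stats` tibble.
#' @param p_thresh Adjusted p-value threshold (default 0.05, strict).
#' @param fc_thresh Linear fold-change threshold (default 1.5, strict).
#' @return The input with logical `is_deg` and `direction`
#'   (`"up"`/`"down"`, NA for non-DEGs) columns added.
#' @export
call_degs <- function(gene_stats, p_thresh = 0.05, fc_thresh = 1.5) {
  out <- gene_stats |>
    mutate(
      is_deg = .data$p_adj < p_thresh & abs(.data$fc) > fc_thresh,
      direction = if_else(.data$is_deg,
                          if_else(.data$log2_fc > 0, "up", "down"),
                          NA_character_)
    )
  class(out) <- unique(c("deg_stats", class(out)))
  out
}
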