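#' Configuration for the synthetic paired cohort generator
#'
#' Bundles and validates all knobs of [generate_cohort()]. The defaults
#' emulate a two-group PBMC microarray study of 18 cases and 19 controls with
#' planted differential expression (|fold change| = 2 on the log2 scale),
#' planted differential methylation (beta-difference 0.20) and a subset of
#' genes whose expression and promoter methylation are coupled through a
#' shared per-sample latent factor.
#'
#' @param n_case,n_control Number of case / control samples.
#' @param n_genes Number of genes on the synthetic chromosome.
#' @param n_expr_probes_per_gene Expression probes per gene (1-3). When > 1,
#'   one designated probe per gene carries the full planted effect and the
#'   others an attenuated (x0.5) effect, exercising the max-|FC| collapse.
#' @param n_meth_probes Number of CpG methylation probes.
#' @param n_deg Number of genes with a planted expression effect.
#' @param n_dmp Number of probes with a planted methylation effect.
#' @param n_medeg_inverse,n_medeg_positive Number of planted
#'   methylation-regulated genes with inverse / positive coupling. These genes
#'   are a subset of the planted DEGs and each owns one planted DMP probe.
#' @param log2_fc_effect Planted absolute log2 fold change for DEGs.
#' @param delta_beta_effect Planted absolute difference of median beta for
#'   DMPs, on the beta scale; the corresponding logit-scale shift is computed
#'   exactly from each probe's baseline.
#' @param coupling_strength Correlation loading in (0, 1] of the shared
#'   latent factor inside the noise of coupled genes. Noise is mixed as
#'   `sd * (rho * f + sqrt(1 - rho^2) * e)` on both layers (sign flipped on
#'   the methylation side for the inverse class), so the marginal noise
#'   standard deviation is unchanged and the planted cross-layer noise
#'   correlation is `-rho^2` (inverse) or `+rho^2` (positive).
#' @param expr_noise_sd,meth_noise_sd Noise standard deviations (log2 units /
#'   logit units).
#' @param frac_failed_detection Fraction of methylation probes given a failed
#'   detection p-value (> 0.01) in one random sample.
#' @param frac_sex_chrom Fraction of methylation probes annotated to
#'   chrX/chrY, exercising the sex-chromosome removal filter.
#' @param n_background_factors,background_sd Number and per-probe loading
#'   standard deviation (log2 units) of global latent factors affecting all
#'   expression probes, independent of disease group. They emulate the
#'   population-stratification / composition structure that the expression
#'   principal-component covariates are intended to absorb: with the
#'   defaults the top two expression PCs track these factors rather than
#'   the planted group signal. Set `n_background_factors = 0` for a
#'   structure-free matrix.
#' @param n_ild Number of case samples flagged with interstitial lung
#'   disease in the metadata.
#' @param age_effect,sex_effect Optional per-unit covariate effects on
#'   expression (log2 per year of centred age; log2 for male sex). Default 0;
#'   set nonzero to test covariate adjustment.
#' @param promoter_medeg_frac Fraction of coupled methylation probes placed
#'   in a promoter category (TSS200/TSS1500/5'UTR/first exon) rather than the
#'   gene body.
#' @param seed Integer seed; fully determines the generated cohort.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 50, n_meth_probes = 120, n_deg = 10,
#'                   n_dmp = 12, n_medeg_inverse = 3, n_medeg_positive = 1)
sim_config <- function(n_case = 18, n_control = 19,
                       n_genes = 2000, n_expr_probes_per_gene = 2,
                       n_meth_probes = 5000,
                       n_deg = 100, n_dmp = 150,
                       n_medeg_inverse = 20, n_medeg_positive = 5,
                       log2_fc_effect = 1.0, delta_beta_effect = 0.20,
                       coupling_strength = 0.8,
                       expr_noise_sd = 0.3, meth_noise_sd = 0.3,
                       frac_failed_detection = 0.01,
                       frac_sex_chrom = 0.02,
                       n_background_factors = 2, background_sd = 0.2,
                       n_ild = min(10, n_case),
                       age_effect = 0, sex_effect = 0,
                       promoter_medeg_frac = 0.6,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_case", "n_control", "n_genes", "n_expr_probes_per_gene",
              "n_meth_probes", "n_deg", "n_dmp", "n_medeg_inverse",
              "n_medeg_positive", "n_ild")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (length(v) != 1 || is.na(v) || v < 0 || v != round(v)) {
      abort(sprintf("`%s` must be a single non-negative integer.", nm))
    }
  }
  if (n_expr_probes_per_gene < 1 || n_expr_probes_per_gene > 3) {
    abort("`n_expr_probes_per_gene` must be 1, 2 or 3.")
  }
  if (delta_beta_effect <= 0 || delta_beta_effect >= 1) {
    abort("`delta_beta_effect` must lie strictly in (0, 1).")
  }
  if (coupling_strength <= 0 || coupling_strength > 1) {
    abort("`coupling_strength` must lie in (0, 1].")
  }
  n_medeg <- n_medeg_inverse + n_medeg_positive
  if (n_medeg > min(n_deg, n_dmp)) {
    abort("n_medeg_inverse + n_medeg_positive must not exceed min(n_deg, n_dmp).")
  }
  if (n_deg > n_genes) abort("`n_deg` cannot exceed `n_genes`.")
  n_sex <- round(frac_sex_chrom * n_meth_probes)
  if (n_dmp > n_meth_probes - n_sex) {
    abort("`n_dmp` cannot exceed the number of autosomal methylation probes.")
  }
  if (n_ild > n_case) abort("`n_ild` cannot exceed `n_case`.")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# uniform integer draw in [lo, hi], vectorized, degenerate-safe
runif_int <- function(lo, hi) {
  lo + floor(runif(length(lo)) * pmax(hi - lo + 1, 1))
}

# Strand-aware position for a probe of a given placement category.
# Categories are named so that genome annotation re-derives them from
# coordinates alone.
place_probe <- function(cat, g, spacing) {
  plus <- g$strand == "+"
  lo <- hi <- integer(nrow(g))
  up <- function(off_lo, off_hi) {
    list(lo = ifelse(plus, g$tss - off_hi, g$tss + off_lo),
         hi = ifelse(plus, g$tss - off_lo, g$tss + off_hi))
  }
  res <- switch(cat,
    TSS200  = up(1, 200),
    TSS1500 = up(201, 1500),
    `5'UTR` = list(lo = ifelse(plus, g$tx_start, g$cds_end),
                   hi = ifelse(plus, g$cds_start - 1, g$tx_end - 1)),
    `1stExon` = list(lo = ifelse(plus, g$cds_start, g$first_exon_end),
                     hi = ifelse(plus, g$first_exon_end - 1, g$cds_end - 1)),
    Body = list(lo = ifelse(plus, g$first_exon_end, g$cds_start),
                hi = ifelse(plus, g$cds_end - 1, g$first_exon_end - 1)),
    `3'UTR` = list(lo = ifelse(plus, g$cds_end, g$tx_start),
                   hi = ifelse(plus, g$tx_end - 1, g$cds_start - 1)),
    IGR = list(lo = g$slot + spacing - 1500, hi = g$slot + spacing - 500),
    abort(sprintf("unknown placement category '%s'", cat))
  )
  runif_int(res$lo, res$hi)
}

#' Generate a synthetic paired expression/methylation cohort
#'
#' Builds a complete in-memory study: a log2 expression matrix, a beta-value
#' methylation matrix with companion detection p-values, sample metadata
#' (group, age, sex, ILD flag), probe and gene annotation on a synthetic
#' linear chromosome, CpG island intervals, and the planted ground truth.
#'
#' Expression values are per-gene Gaussian baselines (mean ~ N(8, 1.5) on the
#' log2 scale) plus noise; planted DEGs are shifted by the signed log2 fold
#' change in cases. Beta values are the inverse logit of Gaussian latents, so
#' group shifts and coupling compose additively on the logit scale while all
#' values stay strictly inside (0, 1); the latent shift of each planted DMP
#' is solved exactly so that the population median beta difference equals the
#' target. Coupled (MeDEG) genes share a per-sample standard-normal factor
#' that is mixed into the noise of both layers with loading
#' `coupling_strength` (negated on the methylation side for the inverse
#' class), leaving marginal noise variances unchanged.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `cohort` with elements `expression`,
#'   `methylation`, `detection` (wide probe-by-sample tibbles), `metadata`,
#'   `expr_annotation`, `meth_annotation`, `gene_models`, `cpg_islands`, and
#'   `truth` (list of tibbles `degs`, `dmps`, `medegs`).
#' @export
#' @examples
#' ch <- generate_cohort(sim_config(n_genes = 40, n_meth_probes = 100,
#'                                  n_deg = 8, n_dmp = 10,
#'                                  n_medeg_inverse = 2, n_medeg_positive = 1,
#'                                  seed = 7))
#' dim(ch$expression)
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created by sim_config().")
  }
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_case + cfg$n_control
  spacing <- 30000L

  ## ---- samples -------------------------------------------------------
  sample_id <- sprintf("S%03d", seq_len(n))
  group <- c(rep("control", cfg$n_control), rep("case", cfg$n_case))
  ild <- integer(n)
  if (cfg$n_ild > 0) {
    ild[cfg$n_control + sample(cfg$n_case, cfg$n_ild)] <- 1L
  }
  metadata <- tibble(
    sample_id = sample_id,
    group = group,
    age = round(rnorm(n, 43, 10), 1),
    sex = sample(c("M", "F"), n, replace = TRUE),
    ild = ild
  )
  case <- as.numeric(group == "case")

  ## ---- gene models ---------------------------------------------------
  ng <- cfg$n_genes
  gene_id <- if (ng > 0) sprintf("G%05d", seq_len(ng)) else character(0)
  slot <- (seq_len(ng) - 1L) * spacing
  strand <- sample(c("+", "-"), ng, replace = TRUE)
  tx_len <- runif_int(rep(8000L, ng), rep(20000L, ng))
  utr5 <- runif_int(rep(300L, ng), rep(600L, ng))
  utr3 <- runif_int(rep(300L, ng), rep(600L, ng))
  exon1 <- runif_int(rep(700L, ng), rep(1200L, ng))
  tx_start <- slot + 5000L
  tx_end <- tx_start + tx_len
  plus <- strand == "+"
  gene_models <- tibble(
    gene_id = gene_id, chrom = rep("chr1", ng), strand = strand,
    tss = ifelse(plus, tx_start, tx_end - 1L),
    tx_start = tx_start, tx_end = tx_end,
    cds_start = ifelse(plus, tx_start + utr5, tx_start + utr3),
    cds_end = ifelse(plus, tx_end - utr3, tx_end - utr5),
    first_exon_end = ifelse(plus, tx_start + exon1, tx_end - 1L - exon1)
  )
  gene_models$slot <- slot

  ## ---- CpG islands (1 kb around ~30% of TSSs) ------------------------
  isl_genes <- if (ng > 0) sort(sample(ng, round(0.3 * ng))) else integer(0)
  cpg_islands <- tibble(
    chrom = rep("chr1", length(isl_genes)),
    start = pmax(gene_models$tss[isl_genes] - 500L, 0L),
    end = gene_models$tss[isl_genes] + 500L
  ) |> arrange(.data$start)

  ## ---- planted identities --------------------------------------------
  n_medeg <- cfg$n_medeg_inverse + cfg$n_medeg_positive
  deg_idx <- if (cfg$n_deg > 0) sample(ng, cfg$n_deg) else integer(0)
  medeg_idx <- deg_idx[seq_len(n_medeg)]
  medeg_class <- c(
    rep(c("inverse-up-hypo", "inverse-down-hyper"),
        length.out = cfg$n_medeg_inverse),
    rep(c("positive-up-hyper", "positive-down-hypo"),
        length.out = cfg$n_medeg_positive)
  )
  # signed log2 FC per planted DEG; MeDEG signs follow their class
  fc_sign <- ifelse(runif(cfg$n_deg) < 0.5, 1, -1)
  if (n_medeg > 0) {
    fc_sign[seq_len(n_medeg)] <- ifelse(grepl("-up-", medeg_class), 1, -1)
  }
  deg_fc <- fc_sign * cfg$log2_fc_effect
  gene_fc <- setNames(numeric(ng), gene_id)
  gene_fc[deg_idx] <- deg_fc

  ## ---- shared coupling factors ---------------------------------------
  rho <- cfg$coupling_strength
  f_medeg <- if (n_medeg > 0) {
    matrix(rnorm(n_medeg * n), n_medeg, n)
  } else {
    matrix(numeric(0), 0, n)
  }

  ## ---- expression matrix ---------------------------------------------
  k <- cfg$n_expr_probes_per_gene
  expr_gene <- rep(gene_id, each = k)
  expr_probe <- if (ng > 0) {
    paste0(expr_gene, "_p", rep(seq_len(k), ng))
  } else character(0)
  expr_annotation <- tibble(probe_id = expr_probe, gene_id = expr_gene,
                            quality_ok = TRUE)
  base_g <- rnorm(ng, 8, 1.5)
  attenuation <- rep(c(1, rep(0.5, k - 1)), ng)   # designated probe first
  eff <- rep(gene_fc, each = k) * attenuation
  noise <- matrix(rnorm(ng * k * n, 0, cfg$expr_noise_sd), ng * k, n)
  if (n_medeg > 0) {
    for (j in seq_len(n_medeg)) {
      rows <- which(expr_gene == gene_id[medeg_idx[j]])
      z <- matrix(rnorm(length(rows) * n), length(rows), n)
      noise[rows, ] <- cfg$expr_noise_sd *
        (rho * matrix(f_medeg[j, ], length(rows), n, byrow = TRUE) +
           sqrt(1 - rho^2) * z)
    }
  }
  if (ng > 0) {
    age_c <- metadata$age - mean(metadata$age)
    covar <- cfg$age_effect * age_c + cfg$sex_effect * (metadata$sex == "M")
    expr_mat <- rep(base_g, each = k) + outer(eff, case) + noise +
      matrix(covar, ng * k, n, byrow = TRUE)
    nbf <- cfg$n_background_factors
    if (nbf > 0) {
      loadings <- matrix(rnorm(ng * k * nbf, 0, cfg$background_sd),
                         ng * k, nbf)
      factors <- matrix(rnorm(nbf * n), nbf, n)
      expr_mat <- expr_mat + loadings %*% factors
    }
  } else {
    expr_mat <- matrix(numeric(0), 0, n)
  }
  colnames(expr_mat) <- sample_id
  rownames(expr_mat) <- expr_probe

  ## ---- methylation probe annotation ----------------------------------
  nm <- cfg$n_meth_probes
  n_sex <- round(cfg$frac_sex_chrom * nm)
  if (n_medeg + n_sex > nm) abort("Not enough methylation probes for the requested truth.")
  probe_id <- sprintf("cg%06d", seq_len(nm))
  chrom <- rep("chr1", nm)
  pos <- integer(nm)
  assigned_gene <- rep(NA_character_, nm)
  placement <- rep(NA_character_, nm)

  idx_medeg_probe <- seq_len(n_medeg)
  idx_sex <- n_medeg + seq_len(n_sex)
  idx_rest <- setdiff(seq_len(nm), c(idx_medeg_probe, idx_sex))

  promoter_cats <- c("TSS200", "TSS1500", "5'UTR", "1stExon")
  if (n_medeg > 0) {
    n_prom <- round(cfg$promoter_medeg_frac * n_medeg)
    cats <- c(sample(promoter_cats, n_prom, replace = TRUE),
              rep("Body", n_medeg - n_prom))
    g <- gene_models[medeg_idx, ]
    for (cat in unique(cats)) {
      sel <- cats == cat
      if (cat == "Body") {
        # keep coupled body probes within the nearest-TSS mapping window
        gs <- g[sel, ]
        p <- gs$strand == "+"
        lo <- ifelse(p, gs$first_exon_end, pmax(gs$cds_start, gs$tss - 9000L))
        hi <- ifelse(p, pmin(gs$cds_end - 1L, gs$tss + 9000L),
                     gs$first_exon_end - 1L)
        pos[idx_medeg_probe[sel]] <- runif_int(lo, hi)
      } else {
        pos[idx_medeg_probe[sel]] <- place_probe(cat, g[sel, ], spacing)
      }
    }
    assigned_gene[idx_medeg_probe] <- gene_id[medeg_idx]
    placement[idx_medeg_probe] <- cats
  }
  if (n_sex > 0) {
    chrom[idx_sex] <- sample(c("chrX", "chrY"), n_sex, replace = TRUE)
    pos[idx_sex] <- runif_int(rep(1e6L, n_sex), rep(5e7L, n_sex))
    placement[idx_sex] <- "sex"
  }
  if (length(idx_rest) > 0) {
    pool <- setdiff(seq_len(ng), medeg_idx)
    if (length(pool) == 0) pool <- seq_len(max(ng, 1))
    if (ng == 0) {
      pos[idx_rest] <- seq_along(idx_rest) * 1000L
      placement[idx_rest] <- "IGR"
    } else {
      gi <- pool[runif_int(rep(1L, length(idx_rest)), rep(length(pool), length(idx_rest)))]
      cats <- sample(c("TSS200", "TSS1500", "5'UTR", "1stExon",
                       "Body", "3'UTR", "IGR"),
                     length(idx_rest), replace = TRUE,
                     prob = c(.08, .10, .08, .06, .34, .08, .26))
      g <- gene_models[gi, ]
      for (cat in unique(cats)) {
        sel <- cats == cat
        pos[idx_rest[sel]] <- place_probe(cat, g[sel, ], spacing)
      }
      assigned_gene[idx_rest] <- gene_id[gi]
      placement[idx_rest] <- cats
    }
  }
  meth_annotation <- tibble(probe_id = probe_id, chrom = chrom, pos = pos)

  ## ---- planted DMPs ---------------------------------------------------
  extra_dmp <- cfg$n_dmp - n_medeg
  dmp_idx <- c(idx_medeg_probe,
               if (extra_dmp > 0) sample(idx_rest, extra_dmp) else integer(0))
  db_sign <- ifelse(runif(cfg$n_dmp) < 0.5, 1, -1)
  if (n_medeg > 0) {
    db_sign[seq_len(n_medeg)] <- ifelse(grepl("hypo$", medeg_class), -1, 1)
  }
  # hypo = lower in cases, so the case shift carries the planted sign
  is_dmp_probe <- logical(nm)
  is_dmp_probe[dmp_idx] <- TRUE

  ## ---- methylation matrix --------------------------------------------
  b0 <- runif(nm, 0.1, 0.9)
  b0[dmp_idx] <- runif(cfg$n_dmp, 0.3, 0.6)
  mu <- logit(b0)
  delta <- numeric(nm)
  delta[dmp_idx] <- logit(b0[dmp_idx] + db_sign * cfg$delta_beta_effect) - mu[dmp_idx]
  mnoise <- matrix(rnorm(nm * n, 0, cfg$meth_noise_sd), nm, n)
  if (n_medeg > 0) {
    inv_sign <- ifelse(grepl("^inverse", medeg_class), -1, 1)
    for (j in seq_len(n_medeg)) {
      z <- rnorm(n)
      mnoise[idx_medeg_probe[j], ] <- cfg$meth_noise_sd *
        (inv_sign[j] * rho * f_medeg[j, ] + sqrt(1 - rho^2) * z)
    }
  }
  latent <- mu + outer(delta, case) + mnoise
  beta <- inv_logit(latent)
  colnames(beta) <- sample_id
  rownames(beta) <- probe_id

  ## ---- detection p-values --------------------------------------------
  det <- matrix(runif(nm * n, 0, 0.001), nm, n,
                dimnames = list(probe_id, sample_id))
  n_fail <- round(cfg$frac_failed_detection * nm)
  if (n_fail > 0) {
    fail_probe <- sample(nm, n_fail)
    fail_sample <- runif_int(rep(1L, n_fail), rep(n, n_fail))
    det[cbind(fail_probe, fail_sample)] <- runif(n_fail, 0.02, 0.5)
  }

  ## ---- ground truth ---------------------------------------------------
  deg_class <- rep("deg", cfg$n_deg)
  if (n_medeg > 0) deg_class[seq_len(n_medeg)] <- medeg_class
  truth <- list(
    degs = tibble(gene_id = gene_id[deg_idx], log2_fc = deg_fc,
                  class = deg_class),
    dmps = tibble(probe_id = probe_id[dmp_idx],
                  gene_id = assigned_gene[dmp_idx],
                  delta_beta = db_sign * cfg$delta_beta_effect,
                  class = c(if (n_medeg > 0) medeg_class,
                            rep("dmp", max(extra_dmp, 0)))),
    medegs = {
      medeg_gene <- gene_id[medeg_idx]
      tibble(gene_id = medeg_gene,
             expr_probe_id = paste0(medeg_gene, "_p1"),
             meth_probe_id = probe_id[idx_medeg_probe],
             class = medeg_class)
    }
  )

  structure(list(
    expression = as_probe_tibble(expr_mat),
    methylation = as_probe_tibble(beta),
    detection = as_probe_tibble(det),
    metadata = metadata,
    expr_annotation = expr_annotation,
    meth_annotation = meth_annotation,
    gene_models = select(gene_models, -"slot"),
    cpg_islands = cpg_islands,
    truth = truth,
    config = cfg
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d expression probes x %d samples; %d CpG probes; %d genes\n",
    nrow(x$expression), length(sample_cols(x$expression)),
    nrow(x$methylation), nrow(x$gene_models)
  ))
  cat(sprintf("  planted: %d DEG genes, %d DMP probes, %d MeDEG genes\n",
              nrow(x$truth$degs), nrow(x$truth$dmps), nrow(x$truth$medegs)))
  invisible(x)
}
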