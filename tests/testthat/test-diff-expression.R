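test_that("BH adjustment matches the step-up oracle", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(11, {
    for (i in 1:50) {
      p <- runif(sample(1:12, 1))
      expect_equal(adjust_bh(p), bh_oracle(p))
    }
  })
  expect_error(adjust_bh(c(0.2, 1.3)), "0, 1")
  expect_error(adjust_bh("a"), "numeric")
})

test_that("covariate PCs reproduce an eigendecomposition oracle", {
  withr::with_seed(4, {
    m <- matrix(rnorm(200), 20, 10,
                dimnames = list(paste0("p", 1:20), paste0("s", 1:10)))
  })
  tbl <- tibble::as_tibble(m, rownames = "probe_id")
  pcs <- compute_covariate_pcs(tbl, k = 2)
  centred <- m - rowMeans(m)
  eig <- eigen(crossprod(centred))
  for (j in 1:2) {
    oracle <- eig$vectors[, j] * sqrt(eig$values[j])
    got <- pcs[[paste0("pc", j)]]
    expect_equal(abs(got), abs(oracle), tolerance = 1e-8)
  }
  expect_equal(colMeans(pcs[, -1]), c(pc1 = 0, pc2 = 0), tolerance = 1e-10)
})

test_that("PC scores handle rank-1 and constant matrices", {
  pattern <- c(1, 3, -2, 0.5, 4, -1)
  m <- outer(c(2, -1, 0.5, 3), pattern)
  dimnames(m) <- list(paste0("p", 1:4), paste0("s", 1:6))
  tbl <- tibble::as_tibble(m, rownames = "probe_id")
  pcs <- compute_covariate_pcs(tbl, k = 2)
  # rank-1: all variance on PC1, PC2 numerically zero
  expect_gt(var(pcs$pc1), 0)
  expect_equal(var(pcs$pc2), 0, tolerance = 1e-12)
  const <- tibble::as_tibble(matrix(5, 3, 5, dimnames = list(paste0("p", 1:3),
                                                             paste0("s", 1:5))),
                             rownames = "probe_id")
  pc0 <- compute_covariate_pcs(const, k = 2)
  expect_equal(unname(as.matrix(pc0[, -1])), matrix(0, 5, 2))
  expect_error(compute_covariate_pcs(tbl, k = 6), "smaller")
})

test_that("the group t-statistic reduces to the pooled two-sample t", {
  md <- two_group_metadata(6, 6)
  withr::with_seed(8, {
    vals <- matrix(rnorm(5 * 12, 8), 5, 12)
  })
  tbl <- wide_matrix(vals, paste0("p", 1:5), md$sample_id)
  res <- test_differential_expression(tbl, md, covariates = NULL)
  for (i in 1:5) {
    ct <- t.test(vals[i, md$group == "case"], vals[i, md$group == "control"],
                 var.equal = TRUE)
    expect_equal(res$t_stat[i], unname(ct$statistic), tolerance = 1e-10)
    expect_equal(res$p_raw[i], ct$p.value, tolerance = 1e-10)
    expect_equal(res$log2_fc[i], unname(diff(rev(ct$estimate))),
                 tolerance = 1e-10)
  }
})

test_that("constant probes are degenerate, not errors", {
  md <- two_group_metadata(4, 4)
  vals <- rbind(rep(7, 8), rnorm(8))
  tbl <- wide_matrix(vals, c("flat", "noisy"), md$sample_id)
  res <- test_differential_expression(tbl, md)
  expect_equal(res$log2_fc[res$probe_id == "flat"], 0)
  expect_equal(res$p_raw[res$probe_id == "flat"], 1)
  expect_equal(res$fc[res$probe_id == "flat"], 1)
})

test_that("a design confounded with group errors and names the column", {
  md <- two_group_metadata(4, 4)
  covs <- tibble::tibble(sample_id = md$sample_id,
                         batch = as.numeric(md$group == "case"))
  tbl <- wide_matrix(rnorm(16), c("p1", "p2"), md$sample_id)
  expect_error(test_differential_expression(tbl, md, covariates = covs),
               "batch")
})

test_that("the group coefficient recovers a planted log2 fold change", {
  # sampling-distribution check: planted effect 1.0, sd 0.3, n = 18 + 19
  hits <- withr::with_seed(21, {
    vapply(1:200, function(i) {
      y <- c(rnorm(19, 8, 0.3), rnorm(18, 9, 0.3))
      md <- two_group_metadata(19, 18)
      tbl <- wide_matrix(matrix(y, 1), "p1", md$sample_id)
      fit <- test_differential_expression(tbl, md)
      abs(fit$log2_fc - 1) <= 0.25
    }, logical(1))
  })
  expect_gte(mean(hits), 0.95)
})

test_that("statistics are invariant to permuting samples with metadata", {
  ch <- small_cohort(seed = 31)
  md <- ch$metadata
  res1 <- test_differential_expression(ch$expression, md,
                                       build_covariates(ch$expression, md))
  perm <- withr::with_seed(1, sample(nrow(md)))
  md2 <- md[perm, ]
  expr2 <- ch$expression[, c(1, 1 + perm)]
  res2 <- test_differential_expression(expr2, md2,
                                       build_covariates(expr2, md2))
  expect_equal(res1$log2_fc, res2$log2_fc, tolerance = 1e-9)
  expect_equal(res1$p_raw, res2$p_raw, tolerance = 1e-9)
})

test_that("probe-to-gene collapse keeps the max-|FC| probe with tie rules", {
  stats <- tibble::tibble(
    probe_id = c("a", "b", "c", "d", "e"),
    gene_id = c("g1", "g1", "g2", "g3", "g3"),
    log2_fc = c(log2(1.8), -1, 0.3, log2(1.6), -log2(1.6)),
    fc = c(1.8, -2.0, 2^0.3, 1.6, -1.6),
    t_stat = 1, p_raw = 0.01,
    p_adj = c(0.02, 0.02, 0.05, 0.04, 0.01)
  )
  out <- collapse_probes_to_genes(stats)
  expect_equal(out$probe_id[out$gene_id == "g1"], "b")   # |-2.0| > 1.8
  expect_equal(out$probe_id[out$gene_id == "g2"], "c")   # single probe
  expect_equal(out$probe_id[out$gene_id == "g3"], "e")   # tie -> smaller p_adj
  # full tie falls back to lexicographic probe id
  tie <- stats
  tie$p_adj <- 0.02
  tie$fc <- c(1.6, -1.6, 1, 1.6, -1.6)
  out2 <- collapse_probes_to_genes(tie)
  expect_equal(out2$probe_id[out2$gene_id == "g1"], "a")
  # unmapped probes are dropped with a message
  stats$gene_id[3] <- NA
  expect_message(collapse_probes_to_genes(stats), "1 probe")
})

test_that("DEG calling applies strict thresholds on both axes", {
  gs <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    probe_id = paste0("p", 1:4),
    log2_fc = c(log2(1.6), log2(1.5), 1, -log2(1.7)),
    fc = c(1.6, 1.5, 2.0, -1.7),
    t_stat = 2, p_raw = 0.01,
    p_adj = c(0.04, 0.04, 0.05, 0.01)
  )
  out <- call_degs(gs)
  expect_equal(out$is_deg, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$direction, c("up", NA, NA, "down"))
})
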