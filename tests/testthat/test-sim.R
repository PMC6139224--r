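test_that("the same config and seed reproduce the cohort bit for bit", {
  cfg <- sim_config(n_genes = 60, n_meth_probes = 150, n_deg = 8, n_dmp = 10,
                    n_medeg_inverse = 2, n_medeg_positive = 1, seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$methylation, b$methylation)
  expect_identical(a$detection, b$detection)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(sim_config(n_genes = 60, n_meth_probes = 150,
                                   n_deg = 8, n_dmp = 10,
                                   n_medeg_inverse = 2, n_medeg_positive = 1,
                                   seed = 6))
  expect_false(identical(a$expression, c2$expression))
})

test_that("matrix dimensions follow the configuration", {
  cfg <- sim_config(n_genes = 100, n_expr_probes_per_gene = 2,
                    n_meth_probes = 250, n_deg = 10, n_dmp = 15,
                    n_medeg_inverse = 3, n_medeg_positive = 1, seed = 2)
  ch <- generate_cohort(cfg)
  expect_equal(dim(ch$expression), c(200, 38))   # probe_id + 37 samples
  expect_equal(dim(ch$methylation), c(250, 38))
  expect_equal(dim(ch$detection), c(250, 38))
  expect_equal(nrow(ch$metadata), 37)
  expect_equal(sum(ch$metadata$group == "case"), 18)
  expect_equal(sum(ch$metadata$group == "control"), 19)
  expect_equal(sum(ch$metadata$ild), 10)
})

test_that("beta values stay inside (0,1) and detection p inside [0,1]", {
  ch <- small_cohort(seed = 3)
  b <- as.matrix(ch$methylation[, -1])
  d <- as.matrix(ch$detection[, -1])
  expect_true(all(b > 0 & b < 1))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("planted inverse MeDEGs carry strong negative pooled correlation", {
  # expected value frozen from a 3000-rep Monte-Carlo of the generative
  # model (mean r = -0.898, sd 0.029 per gene)
  ch <- generate_cohort(sim_config(n_genes = 500, n_meth_probes = 1000,
                                   n_deg = 40, n_dmp = 50,
                                   n_medeg_inverse = 20,
                                   n_medeg_positive = 0, seed = 17))
  em <- as.matrix(tibble::column_to_rownames(ch$expression, "probe_id"))
  mm <- as.matrix(tibble::column_to_rownames(ch$methylation, "probe_id"))
  tr <- ch$truth$medegs
  rs <- mapply(function(e, m) cor(em[e, ], mm[m, ]),
               tr$expr_probe_id, tr$meth_probe_id)
  expect_lt(mean(rs), -0.5)
  expect_gt(mean(rs), -0.97)
})

test_that("positive-class MeDEGs couple with the opposite sign", {
  ch <- generate_cohort(sim_config(n_genes = 300, n_meth_probes = 600,
                                   n_deg = 20, n_dmp = 25,
                                   n_medeg_inverse = 0,
                                   n_medeg_positive = 10, seed = 19))
  em <- as.matrix(tibble::column_to_rownames(ch$expression, "probe_id"))
  mm <- as.matrix(tibble::column_to_rownames(ch$methylation, "probe_id"))
  tr <- ch$truth$medegs
  rs <- mapply(function(e, m) cor(em[e, ], mm[m, ]),
               tr$expr_probe_id, tr$meth_probe_id)
  expect_gt(mean(rs), 0.5)
})

test_that("planted DMP median beta differences track the target over seeds", {
  diffs <- unlist(lapply(1:50, function(s) {
    ch <- generate_cohort(sim_config(n_genes = 40, n_meth_probes = 120,
                                     n_deg = 5, n_dmp = 15,
                                     n_medeg_inverse = 2,
                                     n_medeg_positive = 0, seed = 100 + s))
    b <- as.matrix(tibble::column_to_rownames(ch$methylation, "probe_id"))
    is_case <- ch$metadata$group == "case"
    p <- ch$truth$dmps$probe_id
    apply(b[p, is_case], 1, median) - apply(b[p, !is_case], 1, median)
  }))
  expect_lt(abs(mean(abs(diffs)) - 0.20), 0.05)
})

test_that("unplanted probes carry no group effect when noise vanishes", {
  ch <- generate_cohort(sim_config(n_genes = 50, n_meth_probes = 120,
                                   n_deg = 5, n_dmp = 8,
                                   n_medeg_inverse = 1, n_medeg_positive = 0,
                                   expr_noise_sd = 1e-5, meth_noise_sd = 1e-5,
                                   n_background_factors = 0, seed = 23))
  em <- as.matrix(tibble::column_to_rownames(ch$expression, "probe_id"))
  is_case <- ch$metadata$group == "case"
  signal_probes <- ch$expression$probe_id[
    sub("_p[0-9]+$", "", ch$expression$probe_id) %in% ch$truth$degs$gene_id]
  null_expr <- setdiff(ch$expression$probe_id, signal_probes)
  gaps <- abs(rowMeans(em[null_expr, is_case]) -
                rowMeans(em[null_expr, !is_case]))
  expect_lt(max(gaps), 1e-4)
})

test_that("truth identities exist in their matrices and annotations", {
  ch <- small_cohort(seed = 7)
  expect_true(all(ch$truth$dmps$probe_id %in% ch$methylation$probe_id))
  expect_true(all(ch$truth$degs$gene_id %in% ch$expr_annotation$gene_id))
  expect_true(all(ch$truth$medegs$meth_probe_id %in% ch$methylation$probe_id))
  expect_true(all(ch$truth$medegs$expr_probe_id %in% ch$expression$probe_id))
  expect_true(all(ch$truth$medegs$gene_id %in% ch$truth$degs$gene_id))
  # class signs consistent with planted effects
  tr <- merge(ch$truth$medegs, ch$truth$degs, by = "gene_id")
  expect_true(all(sign(tr$log2_fc) == ifelse(grepl("-up-", tr$class.x), 1, -1)))
})

test_that("inconsistent configurations are rejected", {
  expect_error(sim_config(n_deg = -1), "non-negative")
  expect_error(sim_config(n_medeg_inverse = 80, n_medeg_positive = 30,
                          n_deg = 100, n_dmp = 100), "exceed")
  expect_error(sim_config(n_deg = 50, n_genes = 40), "n_genes")
  expect_error(sim_config(delta_beta_effect = 1.2), "0, 1")
  expect_error(generate_cohort(list()), "sim_config")
})

test_that("a written cohort reads back with full precision", {
  ch <- small_cohort(seed = 9)
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  back <- read_cohort(dir)
  expect_equal(back$expression, ch$expression, ignore_attr = TRUE)
  expect_equal(back$methylation, ch$methylation, ignore_attr = TRUE)
  expect_equal(back$detection, ch$detection, ignore_attr = TRUE)
  expect_equal(back$gene_models, ch$gene_models, ignore_attr = TRUE)
  expect_identical(back$expression$probe_id, ch$expression$probe_id)
  # truth file carries exactly the configured counts
  expect_equal(sum(back$truth$layer == "expr"), 20)
  expect_equal(sum(back$truth$layer == "meth"), 30)
})

test_that("an empty cohort writes valid headers-only files", {
  ch <- generate_cohort(sim_config(n_genes = 0, n_meth_probes = 0,
                                   n_deg = 0, n_dmp = 0,
                                   n_medeg_inverse = 0, n_medeg_positive = 0,
                                   frac_sex_chrom = 0, seed = 1))
  dir <- withr::local_tempdir()
  paths <- write_cohort(ch, dir)
  expect_true(all(file.exists(paths)))
  back <- read_cohort(dir)
  expect_equal(nrow(back$expression), 0)
  expect_equal(nrow(back$methylation), 0)
  expect_equal(nrow(back$truth), 0)
})
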