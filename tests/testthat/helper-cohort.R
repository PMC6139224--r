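# Shared fixtures, built in code.

# a reduced cohort that keeps every structural feature of the default study
# at a fraction of the size
small_cohort <- function(seed = 1, ...) {
  args <- modifyList(
    list(n_genes = 150, n_meth_probes = 400, n_deg = 20, n_dmp = 30,
         n_medeg_inverse = 6, n_medeg_positive = 2, seed = seed),
    list(...)
  )
  generate_cohort(do.call(sim_config, args))
}

# two-class feature matrix for the diagnostic-panel search: 19 controls vs
# 18 cases, 6 informative features separated by 3 pooled SDs, 14 noise
make_panel_features <- function(seed, n_informative = 6, n_noise = 14,
                                effect = 3) {
  withr::with_seed(seed, {
    n_control <- 19; n_case <- 18
    n <- n_control + n_case
    labels <- c(rep("control", n_control), rep("case", n_case))
    p <- n_informative + n_noise
    x <- matrix(rnorm(n * p), n, p)
    x[labels == "case", seq_len(n_informative)] <-
      x[labels == "case", seq_len(n_informative)] + effect
    colnames(x) <- sprintf("gene%02d", seq_len(p))
    rownames(x) <- sprintf("S%02d", seq_len(n))
    list(x = x, labels = labels)
  })
}

# quick wide-matrix constructor: first column probe_id, one column/sample
wide_matrix <- function(values, probe_ids, sample_ids) {
  m <- matrix(values, nrow = length(probe_ids),
              dimnames = list(probe_ids, sample_ids))
  tibble::as_tibble(m, rownames = "probe_id")
}

two_group_metadata <- function(n_control = 5, n_case = 5) {
  n <- n_control + n_case
  tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n)),
    group = c(rep("control", n_control), rep("case", n_case)),
    age = seq(30, 60, length.out = n),
    sex = rep(c("M", "F"), length.out = n),
    ild = 0L
  )
}
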