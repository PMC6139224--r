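# On-disk layout of a cohort: plain TSV matrices (first column = probe ID,
# header row = sample IDs), TSV annotation tables, BED3 CpG islands and a
# flat truth table. Doubles are written with 17 significant digits so a
# round trip reproduces values exactly.

fmt_doubles <- function(tbl) {
  mutate(tbl, across(where(is.double), ~ sprintf("%.17g", .x)))
}

write_tsv_exact <- function(tbl, path) {
  readr::write_tsv(fmt_doubles(tbl), path, progress = FALSE)
}

cohort_files <- c(
  expression = "expression.tsv", methylation = "methylation.tsv",
  detection = "detection.tsv", metadata = "metadata.tsv",
  expr_annotation = "expr_annotation.tsv",
  meth_annotation = "meth_annotation.tsv",
  gene_models = "gene_models.tsv", cpg_islands = "cpg_islands.bed",
  truth = "truth.tsv"
)

#' Write a cohort to a directory of plain-text files
#'
#' Matrices and annotation tables are written as TSV (matrices with the
#' probe ID in the first column and one column per sample), CpG islands as
#' headerless BED3, and the planted truth as a flat table with columns
#' `id`, `layer` (`expr`/`meth`), `planted_effect`, `class`.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create directory '%s'.", out_dir))
  }
  paths <- file.path(out_dir, cohort_files)
  names(paths) <- names(cohort_files)
  for (nm in c("expression", "methylation", "detection", "metadata",
               "expr_annotation", "meth_annotation", "gene_models")) {
    write_tsv_exact(cohort[[nm]], paths[[nm]])
  }
  readr::write_tsv(cohort$cpg_islands, paths[["cpg_islands"]],
                   col_names = FALSE, progress = FALSE)
  truth_flat <- bind_rows(
    cohort$truth$degs |>
      transmute(id = .data$gene_id, layer = "expr",
                planted_effect = .data$log2_fc, class = .data$class),
    cohort$truth$dmps |>
      transmute(id = .data$probe_id, layer = "meth",
                planted_effect = .data$delta_beta, class = .data$class)
  )
  write_tsv_exact(truth_flat, paths[["truth"]])
  invisible(paths)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files.
#' @return A list with the same matrix/annotation elements as a generated
#'   cohort, plus the flat `truth` tibble.
#' @export
read_cohort <- function(dir) {
  pth <- function(nm) file.path(dir, cohort_files[[nm]])
  rd <- function(nm, ...) {
    readr::read_tsv(pth(nm), show_col_types = FALSE, progress = FALSE, ...)
  }
  out <- list(
    expression = rd("expression"),
    methylation = rd("methylation"),
    detection = rd("detection"),
    metadata = rd("metadata"),
    expr_annotation = rd("expr_annotation"),
    meth_annotation = rd("meth_annotation"),
    gene_models = rd("gene_models"),
    cpg_islands = readr::read_tsv(
      pth("cpg_islands"), col_names = c("chrom", "start", "end"),
      show_col_types = FALSE, progress = FALSE
    ),
    truth = rd("truth")
  )
  structure(out, class = "cohort")
}
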