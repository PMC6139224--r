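# Internal helpers shared across modules.

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

#' Convert a wide probe-by-sample tibble to a numeric matrix
#'
#' Matrices travel through the pipeline as tibbles whose first column is the
#' probe identifier and whose remaining columns are samples (the on-disk TSV
#' layout). This converts to a rownamed numeric matrix for computation.
#'
#' @param tbl A tibble with an ID column followed by numeric sample columns.
#' @param id_col Name of the identifier column.
#' @return A numeric matrix with probe IDs as rownames.
#' @keywords internal
#' @noRd
as_probe_matrix <- function(tbl, id_col = 1L) {
  ids <- tbl[[id_col]]
  m <- as.matrix(tbl[, -id_col, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

as_probe_tibble <- function(m, id_name = "probe_id") {
  out <- as_tibble(m, .name_repair = "minimal")
  bind_cols(tibble(!!id_name := rownames(m) %||% character(0)), out)
}

sample_cols <- function(tbl, id_col = 1L) names(tbl)[-id_col]

stopifnot_probability <- function(x, what) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) {
    abort(sprintf("%s must lie in [0, 1]; %d value(s) outside.", what, sum(bad)))
  }
  invisible(x)
}

# Align a matrix-tibble's sample columns against metadata sample_id,
# erroring on mismatch.
check_samples <- function(tbl, metadata, layer = "matrix") {
  sc <- sample_cols(tbl)
  if (!setequal(sc, metadata$sample_id)) {
    abort(sprintf(
      "Sample columns of the %s do not match metadata sample_id (%d vs %d samples).",
      layer, length(sc), nrow(metadata)
    ))
  }
  invisible(tbl)
}
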