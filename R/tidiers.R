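# broom-style accessors for fitted objects.

#' Tidy the per-sample predictions of a panel result
#'
#' @param x A `panel_result`.
#' @param ... Unused.
#' @return Tibble with `sample`, `truth`, `predicted`, `correct`.
#' @method tidy panel_result
#' @export
tidy.panel_result <- function(x, ...) {
  mutate(x$per_sample_predictions,
         correct = .data$truth == .data$predicted)
}

#' One-row summary of a panel result
#'
#' @param x A `panel_result`.
#' @param ... Unused.
#' @return Tibble with the panel, its size, LOOCV accuracy and the chosen
#'   hyperparameters.
#' @method glance panel_result
#' @export
glance.panel_result <- function(x, ...) {
  tibble(
    panel = paste(x$feature_ids, collapse = "+"),
    panel_size = length(x$feature_ids),
    loocv_accuracy = x$loocv_accuracy,
    cost = x$chosen_cost,
    gamma = x$chosen_gamma,
    n_samples = x$n_samples
  )
}
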