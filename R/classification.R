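# Radial-kernel SVM diagnostics: leave-one-out cross-validation over a
# cost/gamma grid, forward feature-panel search, and 2D hierarchical
# clustering with misclassification counting.

#' SVM tuning configuration
#'
#' Hyperparameter grids for the radial-kernel SVM. Defaults follow the
#' customary coarse log2 grids: cost `2^-5 ... 2^15` and gamma
#' `2^-15 ... 2^3`, in multiplicative steps of 4.
#'
#' @param cost_grid,gamma_grid Positive numeric grids.
#' @param seed Integer seed (the fit itself is deterministic; the seed keys
#'   any randomized consumer code).
#' @return List of class `svm_config`.
#' @export
svm_config <- function(cost_grid = 2^seq(-5, 15, by = 2),
                       gamma_grid = 2^seq(-15, 3, by = 2),
                       seed = 1L) {
  if (length(cost_grid) == 0 || length(gamma_grid) == 0 ||
      any(cost_grid <= 0) || any(gamma_grid <= 0)) {
    abort("Hyperparameter grids must be non-empty and strictly positive.")
  }
  structure(list(cost_grid = sort(cost_grid), gamma_grid = sort(gamma_grid),
                 seed = as.integer(seed)),
            class = "svm_config")
}

# scale `newx` by training-fold statistics; constant features get sd 1 so
# no information leaks from the held-out sample
fold_scale <- function(train, newx) {
  mu <- colMeans(train)
  s <- apply(train, 2, sd)
  s[s == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, s, `/`),
       newx = sweep(sweep(newx, 2, mu), 2, s, `/`))
}

#' Leave-one-out cross-validated radial SVM with grid tuning
#'
#' For every (cost, gamma) pair on the grid, runs full leave-one-out
#' cross-validation: each sample is predicted once by a radial-kernel SVM
#' trained on the remaining samples, with features standardized by
#' training-fold statistics only. The grid point with maximal LOOCV accuracy
#' is reported; ties prefer the smallest cost, then the smallest gamma
#' (smoother models). Grid points that can no longer beat the incumbent are
#' abandoned early, which does not change the result.
#'
#' @param features Numeric matrix or data frame, samples x features
#'   (rownames/row order = samples). No missing values.
#' @param labels Two-class labels, one per sample, each class with >= 2
#'   samples.
#' @param config An [svm_config()].
#' @return A `panel_result`: list with `feature_ids`, `loocv_accuracy`,
#'   `per_sample_predictions` (tibble `sample`, `truth`, `predicted`),
#'   `chosen_cost`, `chosen_gamma`, `n_samples`.
#' @export
loocv_svm <- function(features, labels, config = svm_config()) {
  loocv_svm_impl(features, labels, config, beat = -1L)
}

# `beat`: minimum correct count the search must strictly exceed to be of
# interest; grid points (and whole calls) that cannot are abandoned early.
# With beat = -1 the result is always complete.
loocv_svm_impl <- function(features, labels, config, beat = -1L) {
  x <- as.matrix(features)
  if (anyNA(x)) abort("`features` must not contain missing values.")
  y <- factor(labels)
  if (nlevels(y) != 2 || any(table(y) < 2)) {
    abort("`labels` must contain exactly 2 classes with >= 2 samples each.")
  }
  n <- nrow(x)
  if (length(y) != n) abort("One label per sample is required.")
  best <- list(correct = beat, pred = NULL, cost = NA_real_, gamma = NA_real_)
  for (cost in config$cost_grid) {
    for (gamma in config$gamma_grid) {
      pred <- character(n)
      mistakes <- 0L
      # must beat the incumbent strictly; abort once that is impossible
      allowance <- n - (best$correct + 1L)
      aborted <- FALSE
      for (i in seq_len(n)) {
        sc <- fold_scale(x[-i, , drop = FALSE], x[i, , drop = FALSE])
        fit <- e1071::svm(sc$train, y[-i], kernel = "radial",
                          cost = cost, gamma = gamma, scale = FALSE)
        pred[i] <- as.character(predict(fit, sc$newx))
        if (pred[i] != as.character(y[i])) {
          mistakes <- mistakes + 1L
          if (mistakes > allowance) { aborted <- TRUE; break }
        }
      }
      if (!aborted) {
        correct <- n - mistakes
        if (correct > best$correct) {
          best <- list(correct = correct, pred = pred,
                       cost = cost, gamma = gamma)
        }
      }
      if (best$correct == n) break
    }
    if (best$correct == n) break
  }
  if (is.null(best$pred)) return(NULL)   # nothing beat the bound
  structure(list(
    feature_ids = colnames(x) %||% paste0("f", seq_len(ncol(x))),
    loocv_accuracy = best$correct / n,
    per_sample_predictions = tibble(
      sample = rownames(x) %||% paste0("s", seq_len(n)),
      truth = as.character(y),
      predicted = best$pred
    ),
    chosen_cost = best$cost,
    chosen_gamma = best$gamma,
    n_samples = n
  ), class = "panel_result")
}

#' Search for a diagnostic feature panel
#'
#' Greedy mode performs forward selection: at each step the candidate whose
#' addition maximizes LOOCV accuracy joins the panel (ties resolved by
#' lexicographic feature name), stopping at perfect accuracy, at
#' `max_size`, or when no addition improves accuracy (so accuracy along the
#' greedy path is non-decreasing). Exhaustive mode evaluates every subset
#' of each size up to `max_size` (candidate count capped at 30) and returns
#' the best subset overall, preferring smaller panels and then
#' lexicographic order on ties.
#'
#' @param features Samples x candidate-features matrix or data frame with
#'   column names.
#' @param labels Two-class labels per sample.
#' @param config An [svm_config()].
#' @param max_size Maximum panel size (default 6); must not exceed the
#'   number of candidates.
#' @param mode `"greedy"` (default) or `"exhaustive"`.
#' @return A `panel_result` (see [loocv_svm()]) with a `search_path` tibble
#'   (`size`, `feature_added`/`panel`, `accuracy`) attached. Warns when the
#'   final accuracy is not clearly above the majority-class rate (within
#'   two binomial standard errors of it), since tuning and selection alone
#'   lift LOOCV accuracy above chance on uninformative features.
#' @export
search_feature_panel <- function(features, labels, config = svm_config(),
                                 max_size = 6, mode = c("greedy", "exhaustive")) {
  mode <- match.arg(mode)
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (max_size > ncol(x)) {
    abort("`max_size` cannot exceed the number of candidate features.")
  }
  if (mode == "exhaustive" && ncol(x) > 30) {
    abort("Exhaustive mode supports at most 30 candidates.")
  }
  cand_all <- sort(colnames(x))
  y <- factor(labels)
  majority <- max(table(y)) / length(y)

  if (mode == "greedy") {
    panel <- character(0)
    acc <- -Inf
    result <- NULL
    path <- list()
    n <- length(y)
    while (length(panel) < max_size) {
      remaining <- setdiff(cand_all, panel)
      step_best <- NULL
      for (f in remaining) {   # sorted order: lexicographic tie-break
        bound <- if (is.null(step_best)) -1L else {
          as.integer(round(step_best$loocv_accuracy * n))
        }
        res <- loocv_svm_impl(x[, c(panel, f), drop = FALSE], y, config,
                              beat = bound)
        if (!is.null(res)) step_best <- res
        if (!is.null(step_best) && step_best$loocv_accuracy == 1) break
      }
      if (step_best$loocv_accuracy < acc) break   # no improvement possible
      panel <- step_best$feature_ids
      acc <- step_best$loocv_accuracy
      result <- step_best
      path[[length(path) + 1]] <- tibble(
        size = length(panel), feature_added = panel[length(panel)],
        accuracy = acc
      )
      if (acc == 1) break
    }
    result$search_path <- list_rbind(path)
  } else {
    result <- NULL
    path <- list()
    n <- length(y)
    for (size in seq_len(max_size)) {
      combos <- utils::combn(cand_all, size, simplify = FALSE)
      size_best <- NULL
      for (cb in combos) {
        bound <- if (is.null(size_best)) -1L else {
          as.integer(round(size_best$loocv_accuracy * n))
        }
        res <- loocv_svm_impl(x[, cb, drop = FALSE], y, config, beat = bound)
        if (!is.null(res)) size_best <- res
        if (!is.null(size_best) && size_best$loocv_accuracy == 1) break
      }
      path[[size]] <- tibble(size = size,
                             panel = paste(size_best$feature_ids,
                                           collapse = "+"),
                             accuracy = size_best$loocv_accuracy)
      if (is.null(result) ||
          size_best$loocv_accuracy > result$loocv_accuracy) {
        result <- size_best
      }
      if (result$loocv_accuracy == 1) break
    }
    result$search_path <- list_rbind(path)
  }
  # selection plus hyperparameter tuning inflate LOOCV accuracy even on
  # pure noise, so "chance level" is the majority rate plus its sampling
  # noise, not the majority rate itself
  chance_band <- majority + 2 * sqrt(majority * (1 - majority) / length(y))
  if (result$loocv_accuracy < chance_band) {
    warn(sprintf(
      "Panel accuracy (%.2f) is not clearly above the majority-class rate (%.2f): likely uninformative features.",
      result$loocv_accuracy, majority
    ))
  }
  result
}

#' @export
print.panel_result <- function(x, ...) {
  cat(sprintf("<panel_result> %d feature(s): %s\n", length(x$feature_ids),
              paste(x$feature_ids, collapse = ", ")))
  cat(sprintf("  LOOCV accuracy %.3f over %d samples (cost %g, gamma %g)\n",
              x$loocv_accuracy, x$n_samples, x$chosen_cost, x$chosen_gamma))
  invisible(x)
}

#' Two-dimensional hierarchical clustering of samples
#'
#' Agglomerative clustering of the sample columns of a feature matrix using
#' one-minus-Pearson correlation (default) or Euclidean distance with
#' average linkage, cut at two clusters.
#'
#' @param matrix Wide features-by-samples tibble (first column IDs) or a
#'   plain numeric matrix with sample columns.
#' @param distance `"pearson"` (one minus correlation) or `"euclidean"`.
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return List of class `sample_clustering`: `hclust`, `ordering` (sample
#'   names in dendrogram order) and `assignment` (named 2-cluster cut).
#' @export
hierarchical_cluster <- function(matrix, distance = c("pearson", "euclidean"),
                                 linkage = "average") {
  distance <- match.arg(distance)
  m <- if (is.data.frame(matrix)) as_probe_matrix(matrix) else as.matrix(matrix)
  if (ncol(m) < 2) abort("Need at least 2 samples to cluster.")
  if (distance == "pearson") {
    if (any(apply(m, 2, sd) == 0)) {
      abort("Correlation distance undefined: a sample has zero variance.")
    }
    d <- stats::as.dist(1 - cor(m))
  } else {
    d <- stats::dist(t(m))
  }
  hc <- stats::hclust(d, method = linkage)
  structure(list(
    hclust = hc,
    ordering = hc$labels[hc$order],
    assignment = stats::cutree(hc, k = 2)
  ), class = "sample_clustering")
}

#' Misclassification count of a 2-cluster assignment
#'
#' Maps the two clusters onto the two true group labels in the way that
#' minimizes disagreement (so the count is invariant to cluster
#' relabelling) and counts the samples whose true label differs from their
#' cluster's assigned label.
#'
#' @param assignment Integer cluster labels (1/2), e.g. from
#'   [hierarchical_cluster()]; order must match `truth`.
#' @param truth True group labels, same samples.
#' @return Integer misclassification count.
#' @export
cluster_misclassification <- function(assignment, truth) {
  if (length(assignment) != length(truth)) {
    abort("`assignment` and `truth` must have the same length.")
  }
  truth <- factor(truth)
  if (nlevels(truth) != 2) abort("`truth` must have exactly two groups.")
  a <- as.integer(factor(assignment))
  l <- levels(truth)
  map1 <- sum(truth != l[a])          # cluster 1 -> level 1, 2 -> level 2
  map2 <- sum(truth != l[3L - a])     # the swapped mapping
  as.integer(min(map1, map2))
}
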