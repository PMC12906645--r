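#' Enumerate base-model subsets
#'
#' All subsets of the given families of size `min_size` up to all of them,
#' in deterministic lexicographic-by-index order. With the five base
#' families and pairs upward this yields the 26 candidate ensembles
#' (C(5,2) + C(5,3) + C(5,4) + C(5,5)).
#'
#' @param families Character vector of model family names.
#' @param min_size Smallest subset size, default 2.
#' @return List of character vectors (the subsets).
#' @examples
#' length(enumerate_combinations(BASE_FAMILIES))  # 26
#' @export
enumerate_combinations <- function(families, min_size = 2L) {
  n <- length(families)
  if (n < min_size) {
    abort(paste0("Need at least ", min_size, " families; got ", n, "."))
  }
  out <- list()
  for (k in seq(min_size, n)) {
    out <- c(out, combn(families, k, simplify = FALSE))
  }
  out
}

eval_split <- function(P, w, y, threshold = 0.5) {
  metrics_report(y, ensemble_predict(P, w), threshold)
}

#' Exhaustive weighted-ensemble search over model subsets
#'
#' For every subset of the fitted base models (size >= `min_size`), the
#' prediction matrices are restricted to that subset's rows, the ensemble
#' weights are fitted with [optimize_weights()], and the result is scored on
#' the validation and test parts. The winning configuration is the subset
#' with the highest accuracy on the selection split, ties broken by higher
#' AUC on that split, then by smaller subset, then by enumeration order.
#'
#' Selection on the validation split (the default) is leakage-free;
#' `selection = "test"` scores candidates on the test part instead, which
#' reuses the test set for model selection and is provided only to mirror
#' protocols that do so.
#'
#' @param models List of `fitted_base_model`s (typically the five families).
#' @param split A preprocessed `data_split` (see [preprocess_split()]).
#' @param config A [gbwoem_config()]. Each subset re-initializes its weights
#'   with a subset-specific seed derived from `config$seed`.
#' @param selection `"validation"` (default) or `"test"`.
#' @param min_size Smallest subset size, default 2.
#' @return A `gbwoem_search`: `results` tibble (one row per subset with
#'   weights and train/val/test accuracy, AUC and F1), `fits` (the
#'   per-subset `gbwoem_fit`s), `best_index`, and `selection`.
#' @export
search_combinations <- function(models, split, config = gbwoem_config(),
                                selection = c("validation", "test"),
                                min_size = 2L) {
  selection <- match.arg(selection)
  stopifnot(inherits(split, "data_split"))
  families <- vapply(models, function(m) m$family, character(1))
  if (anyDuplicated(families)) abort("Model families must be distinct.")
  subsets <- enumerate_combinations(families, min_size)

  P <- lapply(split[c("train", "val", "test")],
              function(part) predict_matrix(models, part))
  y <- lapply(split[c("train", "val", "test")],
              function(part) part$.outcome)

  fits <- vector("list", length(subsets))
  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    sub <- subsets[[i]]
    sub_config <- config
    sub_config$seed <- config$seed + i  # subset-specific, reproducible
    fit <- optimize_weights(P$train[sub, , drop = FALSE], y$train,
                            P$val[sub, , drop = FALSE], y$val,
                            sub_config)
    fits[[i]] <- fit
    w <- fit$weights
    m_train <- eval_split(P$train[sub, , drop = FALSE], w, y$train)$metrics
    m_val <- eval_split(P$val[sub, , drop = FALSE], w, y$val)$metrics
    m_test <- eval_split(P$test[sub, , drop = FALSE], w, y$test)$metrics
    rows[[i]] <- tibble::tibble(
      subset = paste(sub, collapse = "+"),
      n_models = length(sub),
      weights = list(w),
      train_accuracy = m_train$accuracy,
      val_accuracy = m_val$accuracy,
      val_auc = m_val$auc,
      val_f1 = m_val$f1,
      test_accuracy = m_test$accuracy,
      test_auc = m_test$auc,
      test_f1 = m_test$f1,
      best_loss = fit$best_loss,
      iterations_run = fit$iterations_run
    )
  }
  results <- dplyr::bind_rows(rows)

  sel_acc <- if (selection == "validation") results$val_accuracy else results$test_accuracy
  sel_auc <- if (selection == "validation") results$val_auc else results$test_auc
  best_index <- order(-sel_acc, -sel_auc, results$n_models,
                      seq_len(nrow(results)))[1]

  structure(
    list(results = results, fits = fits, subsets = subsets,
         best_index = best_index, selection = selection, config = config),
    class = "gbwoem_search"
  )
}

#' Best configuration of a search
#'
#' @param search A `gbwoem_search`.
#' @return One-row tibble from the results table (with the fitted weights
#'   in the `weights` list-column).
#' @export
best_ensemble <- function(search) {
  stopifnot(inherits(search, "gbwoem_search"))
  search$results[search$best_index, , drop = FALSE]
}

#' @export
print.gbwoem_search <- function(x, ...) {
  best <- best_ensemble(x)
  cat(sprintf(
    "<gbwoem_search> %d candidate subsets, selected on %s\n",
    nrow(x$results), x$selection
  ))
  cat(sprintf(
    "  best: %s | val acc %.4f (AUC %.4f) | test acc %.4f (AUC %.4f)\n",
    best$subset, best$val_accuracy, best$val_auc,
    best$test_accuracy, best$test_auc
  ))
  invisible(x)
}

#' Tidy the search results
#'
#' @param x A `gbwoem_search`.
#' @param ... Unused.
#' @return The per-subset results tibble with the weight vectors flattened
#'   to a readable string column.
#' @method tidy gbwoem_search
#' @export
tidy.gbwoem_search <- function(x, ...) {
  res <- x$results
  res$weights <- vapply(
    res$weights,
    function(w) paste(sprintf("%s=%.4f", names(w), w), collapse = ";"),
    character(1)
  )
  res
}

#' One-row search summary
#'
#' @param x A `gbwoem_search`.
#' @param ... Unused.
#' @return Tibble with the candidate count, the selection split, and the
#'   winning subset's headline metrics.
#' @method glance gbwoem_search
#' @export
glance.gbwoem_search <- function(x, ...) {
  best <- best_ensemble(x)
  tibble::tibble(
    n_candidates = nrow(x$results),
    selection = x$selection,
    best_subset = best$subset,
    val_accuracy = best$val_accuracy,
    test_accuracy = best$test_accuracy,
    test_auc = best$test_auc
  )
}

#' Plot per-subset held-out accuracy
#'
#' @param object A `gbwoem_search`.
#' @param ... Unused.
#' @return A ggplot object: subsets ordered by validation accuracy, the
#'   winner highlighted.
#' @method autoplot gbwoem_search
#' @export
autoplot.gbwoem_search <- function(object, ...) {
  res <- object$results
  res$is_best <- seq_len(nrow(res)) == object$best_index
  ggplot2::ggplot(res, ggplot2::aes(
    x = stats::reorder(.data$subset, .data$val_accuracy),
    y = .data$val_accuracy, fill = .data$is_best
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#2c7fb8")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Validation accuracy") +
    ggplot2::theme_minimal()
}
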