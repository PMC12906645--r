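#' Base-learner families
#'
#' The ensemble combines five probabilistic binary classifiers, each behind a
#' single contract: fit on a numeric feature table, emit positive-class
#' probabilities in `[0, 1]`.
#'
#' @format Character vector of the five family codes.
#' @export
BASE_FAMILIES <- c("LR", "DTC", "RFC", "KNN", "MLP")

#' Default hyperparameter grids
#'
#' Modest per-family grids for grid-search tuning: tree depth for the
#' decision tree, forest size for the random forest, neighbour count for
#' k-NN, hidden-layer width for the MLP. Logistic regression is fitted
#' unpenalized, so its default grid holds the single standard configuration.
#' All grids are user-replaceable; they are experiment configuration, not
#' method.
#'
#' @param family One of `BASE_FAMILIES`.
#' @return A list of named hyperparameter lists (one per configuration).
#' @export
default_grid <- function(family) {
  switch(family,
    LR = list(list()),
    DTC = list(list(maxdepth = 3), list(maxdepth = 5), list(maxdepth = 10)),
    RFC = list(list(ntree = 100), list(ntree = 200)),
    KNN = list(list(k = 3), list(k = 5), list(k = 7)),
    MLP = list(list(size = 4), list(size = 8)),
    abort(paste0("Unknown base-model family: ", family))
  )
}

#' Specify a base model to tune
#'
#' @param family One of `"LR"`, `"DTC"`, `"RFC"`, `"KNN"`, `"MLP"`.
#' @param grid List of hyperparameter configurations (named lists) to search
#'   exhaustively; defaults to [default_grid()].
#' @param k_folds Number of stratified cross-validation folds (>= 2).
#' @param seed Integer seed fixing fold assignment and any stochastic
#'   learner initialization.
#' @return A `base_model_spec` list.
#' @export
base_model_spec <- function(family, grid = default_grid(family), k_folds = 5L,
                            seed = 1L) {
  family <- match.arg(family, BASE_FAMILIES)
  if (length(grid) < 1) abort("`grid` must hold at least one configuration.")
  if (k_folds < 2) abort("`k_folds` must be at least 2.")
  structure(
    list(family = family, grid = grid, k_folds = as.integer(k_folds),
         seed = as.integer(seed)),
    class = "base_model_spec"
  )
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so every fold holds both classes whenever counts permit.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      rows <- sample(which(y == cls))
      fold[rows] <- rep_len(seq_len(k), length(rows))
    }
  })
  for (f in seq_len(k)) {
    if (length(unique(y[fold != f])) < 2) {
      abort("A class is absent from some training fold; reduce `k_folds`.")
    }
  }
  fold
}

fit_family <- function(family, hyper, X, y, seed) {
  df <- as.data.frame(X)
  df$.y <- factor(y, levels = c(0, 1))
  withr::with_seed(seed, switch(family,
    LR = {
      args <- c(list(formula = .y ~ ., data = df, family = binomial()), hyper)
      suppressWarnings(do.call(glm, args))
    },
    DTC = {
      ctrl <- do.call(rpart::rpart.control,
                      c(hyper, list(xval = 0)))
      rpart::rpart(.y ~ ., data = df, method = "class", control = ctrl)
    },
    RFC = do.call(randomForest::randomForest,
                  c(list(x = as.data.frame(X), y = df$.y), hyper)),
    KNN = list(train = as.matrix(X), cl = df$.y,
               k = hyper$k %||% 5L, seed = seed),
    MLP = do.call(nnet::nnet,
                  c(list(formula = .y ~ ., data = df, trace = FALSE,
                         maxit = hyper$maxit %||% 200,
                         decay = hyper$decay %||% 0.01,
                         MaxNWts = 5000),
                    hyper[setdiff(names(hyper), c("maxit", "decay"))]))
  ))
}

predict_family <- function(family, fit, X) {
  df <- as.data.frame(X)
  p <- switch(family,
    LR = suppressWarnings(as.numeric(predict(fit, newdata = df,
                                             type = "response"))),
    DTC = as.numeric(predict(fit, newdata = df, type = "prob")[, "1"]),
    RFC = as.numeric(predict(fit, newdata = df, type = "prob")[, "1"]),
    KNN = {
      pred <- withr::with_seed(
        fit$seed,
        class::knn(fit$train, as.matrix(X), fit$cl, k = fit$k, prob = TRUE)
      )
      win <- attr(pred, "prob")
      as.numeric(ifelse(pred == "1", win, 1 - win))
    },
    MLP = as.numeric(predict(fit, newdata = df, type = "raw"))
  )
  pmin(pmax(p, 0), 1)
}

#' Tune a base model by grid search with stratified k-fold CV
#'
#' Every configuration in the grid is scored by mean held-fold accuracy
#' (labels at the 0.5 probability threshold) over stratified k folds; the
#' best configuration — ties broken by grid order — is refitted on all of
#' `train`.
#'
#' @param spec A [base_model_spec()].
#' @param train Preprocessed (numeric, complete) training feature table.
#' @return A `fitted_base_model` with the chosen hyperparameters, its mean
#'   CV accuracy, the full `cv_results` tibble, and the refitted model.
#' @export
tune_base_model <- function(spec, train) {
  stopifnot(inherits(spec, "base_model_spec"))
  assert_feature_table(train)
  if (length(unique(train$.outcome)) < 2) {
    abort("Both classes must be present in `train`.")
  }
  X <- train[feature_cols(train)]
  y <- train$.outcome
  fold <- stratified_folds(y, spec$k_folds, spec$seed)
  acc <- numeric(length(spec$grid))
  for (g in seq_along(spec$grid)) {
    fold_acc <- numeric(spec$k_folds)
    for (f in seq_len(spec$k_folds)) {
      hold <- fold == f
      fit <- fit_family(spec$family, spec$grid[[g]],
                        X[!hold, , drop = FALSE], y[!hold],
                        seed = spec$seed + 97L * f + g)
      p <- predict_family(spec$family, fit, X[hold, , drop = FALSE])
      fold_acc[f] <- mean(as.integer(p >= 0.5) == y[hold])
    }
    acc[g] <- mean(fold_acc)
  }
  best <- which.max(acc)  # first-listed wins ties
  final <- fit_family(spec$family, spec$grid[[best]], X, y, seed = spec$seed)
  structure(
    list(
      family = spec$family,
      chosen_hyperparameters = spec$grid[[best]],
      cv_accuracy = acc[best],
      cv_results = tibble::tibble(
        config = seq_along(spec$grid),
        hyperparameters = spec$grid,
        cv_accuracy = acc
      ),
      fit = final,
      feature_names = feature_cols(train),
      spec = spec
    ),
    class = "fitted_base_model"
  )
}

#' @export
print.fitted_base_model <- function(x, ...) {
  hp <- if (length(x$chosen_hyperparameters)) {
    paste(names(x$chosen_hyperparameters), unlist(x$chosen_hyperparameters),
          sep = "=", collapse = ", ")
  } else "defaults"
  cat(sprintf("<fitted_base_model> %s (%s), CV accuracy %.3f\n",
              x$family, hp, x$cv_accuracy))
  invisible(x)
}

#' Positive-class probabilities from a fitted base model
#'
#' @param object A `fitted_base_model`.
#' @param new_data Feature table matching the training schema.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.fitted_base_model <- function(object, new_data, ...) {
  missing_cols <- setdiff(object$feature_names, names(new_data))
  if (length(missing_cols) > 0) {
    abort(paste0("`new_data` lacks training columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  predict_family(object$family, object$fit,
                 new_data[object$feature_names])
}

#' Stack base-model probabilities into a prediction matrix
#'
#' Row i holds model i's positive-class probabilities over the table's
#' instances, in the order the models are given; row names are the family
#' codes. This models-by-instances matrix is the input to the weight
#' optimizer.
#'
#' @param models List of `fitted_base_model`s.
#' @param data Feature table matching the training schema.
#' @return Numeric matrix, `length(models)` rows by `nrow(data)` columns.
#' @export
predict_matrix <- function(models, data) {
  if (length(models) < 1) abort("`models` must be nonempty.")
  rows <- lapply(models, function(m) predict(m, data))
  P <- do.call(rbind, rows)
  rownames(P) <- vapply(models, function(m) m$family, character(1))
  P
}
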