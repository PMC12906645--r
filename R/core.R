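#' Configure the ensemble weight optimizer
#'
#' Collects the gradient-descent hyperparameters: learning rate, iteration
#' budget, early-stopping patience, the weight-initialization variant
#' (uniform `1/n`, or random draws normalized to sum to one), and the small
#' stabilizer added inside the logarithms of the loss.
#'
#' @param learning_rate Step size `alpha` > 0 for gradient descent.
#' @param num_iterations Maximum number of iterations (>= 0).
#' @param patience Consecutive non-improving validation-loss iterations
#'   tolerated before stopping (>= 1).
#' @param weight_init `"uniform"` (every weight `1/n`) or `"random"`
#'   (uniform draws on `[0, 1)` normalized to sum to 1).
#' @param epsilon Stabilizer added to probabilities inside `log()`;
#'   default `1e-10`.
#' @param gradient `"surrogate"` (default) uses the mean-squared-error
#'   gradient `(1/N) * P %*% (y_hat - y)`; `"bce"` uses the exact gradient
#'   of the epsilon-stabilized binary cross-entropy. See the methods
#'   vignette for why both exist.
#' @param seed Integer seed for random weight initialization.
#' @return A `gbwoem_config` list.
#' @export
gbwoem_config <- function(learning_rate = 0.01, num_iterations = 1000L,
                          patience = 10L, weight_init = c("uniform", "random"),
                          epsilon = 1e-10,
                          gradient = c("surrogate", "bce"), seed = 1L) {
  weight_init <- match.arg(weight_init)
  gradient <- match.arg(gradient)
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  if (epsilon <= 0) abort("`epsilon` must be positive.")
  if (num_iterations < 0) abort("`num_iterations` must be nonnegative.")
  if (patience < 1) abort("`patience` must be a positive integer.")
  structure(
    list(learning_rate = learning_rate,
         num_iterations = as.integer(num_iterations),
         patience = as.integer(patience),
         weight_init = weight_init,
         epsilon = epsilon,
         gradient = gradient,
         seed = as.integer(seed)),
    class = "gbwoem_config"
  )
}

#' Initialize ensemble weights
#'
#' `"uniform"` sets every weight to `1/n`; `"random"` draws n values
#' uniformly on `[0, 1)` and divides by their sum, so the initial weights
#' are nonnegative and sum to one exactly. After initialization the descent
#' leaves the weights unconstrained — they are not re-normalized.
#'
#' @param n Number of base models (>= 1).
#' @param mode `"uniform"` or `"random"`.
#' @param seed Integer seed for the random mode.
#' @return Numeric weight vector of length `n`.
#' @examples
#' init_weights(5, "uniform")  # 0.2 0.2 0.2 0.2 0.2
#' sum(init_weights(3, "random", seed = 7))  # 1
#' @export
init_weights <- function(n, mode = c("uniform", "random"), seed = 1L) {
  if (n < 1) abort("`n` must be at least 1.")
  if (!is.character(mode) || !all(mode %in% c("uniform", "random"))) {
    abort("Unknown weight initializer; use \"uniform\" or \"random\".")
  }
  mode <- match.arg(mode)
  if (mode == "uniform") {
    rep(1 / n, n)
  } else {
    w <- withr::with_seed(seed, runif(n))
    w / sum(w)
  }
}

#' Aggregate base-model probabilities with the current weights
#'
#' Computes the per-instance weighted sum of the base models' positive-class
#' probabilities, then clips to `[0, 1]`: because the weights are
#' unconstrained reals after descent, the raw sum can leave the unit
#' interval.
#'
#' @param P Models-by-instances probability matrix (see [predict_matrix()]).
#' @param w Weight vector, one weight per row of `P`.
#' @return Per-instance ensemble probability vector.
#' @export
ensemble_predict <- function(P, w) {
  P <- as.matrix(P)
  if (length(w) != nrow(P)) {
    abort(paste0("Weight count (", length(w), ") does not match model count (",
                 nrow(P), ")."))
  }
  pmin(pmax(as.numeric(crossprod(P, w)), 0), 1)
}

#' Epsilon-stabilized binary cross-entropy
#'
#' Mean negated log-likelihood of binary labels under predicted
#' probabilities, with a small constant inside each logarithm so that
#' predictions at exactly 0 or 1 stay finite:
#' `-(1/N) * sum(y * log(p + eps) + (1 - y) * log(1 - p + eps))`.
#'
#' @param y_true Binary label vector.
#' @param y_prob Probability vector in `[0, 1]`, same length.
#' @param epsilon Stabilizer, default `1e-10`.
#' @return Nonnegative finite mean loss.
#' @examples
#' bce_loss(c(1, 0), c(0.5, 0.5))  # log(2)
#' @export
bce_loss <- function(y_true, y_prob, epsilon = 1e-10) {
  if (length(y_true) == 0) abort("Empty input.")
  if (length(y_true) != length(y_prob)) abort("Length mismatch.")
  if (any(y_prob < 0 | y_prob > 1)) abort("Probabilities must lie in [0, 1].")
  -mean(y_true * log(y_prob + epsilon) +
          (1 - y_true) * log(1 - y_prob + epsilon))
}

# Squared-error surrogate whose exact gradient is the printed update
# direction; used for the descent property and the finite-difference oracle.
surrogate_loss <- function(y_true, y_prob) {
  mean((y_prob - y_true)^2) / 2
}

#' Gradient of the loss with respect to the ensemble weights
#'
#' The default (`"surrogate"`) direction is `(1/N) * P %*% (y_hat - y)` —
#' component i is `(1/N) * sum_j (y_hat_j - y_j) * p_ij`. This is the exact
#' gradient of the mean squared error between the aggregated probability
#' and the labels. The `"bce"` mode instead differentiates the
#' epsilon-stabilized cross-entropy itself.
#'
#' @param y_true Label vector.
#' @param y_ens Aggregated ensemble probability vector (already clipped).
#' @param P Models-by-instances probability matrix.
#' @param mode `"surrogate"` (default) or `"bce"`.
#' @param epsilon Stabilizer used by the `"bce"` mode.
#' @return Gradient vector over the weights.
#' @export
loss_gradient <- function(y_true, y_ens, P, mode = c("surrogate", "bce"),
                          epsilon = 1e-10) {
  mode <- match.arg(mode)
  P <- as.matrix(P)
  n_obs <- length(y_true)
  if (length(y_ens) != n_obs || ncol(P) != n_obs) abort("Dimension mismatch.")
  resid <- if (mode == "surrogate") {
    y_ens - y_true
  } else {
    -(y_true / (y_ens + epsilon) - (1 - y_true) / (1 - y_ens + epsilon))
  }
  as.numeric(P %*% resid) / n_obs
}

#' Fit ensemble weights by gradient descent with early stopping
#'
#' Implements the weight-optimization loop: aggregate with the current
#' weights, record epsilon-stabilized cross-entropy on the training and
#' validation parts, keep the weights attaining the best validation loss so
#' far (patience counter resets to 0 on any strict improvement, increments
#' otherwise, and the loop breaks once it reaches `patience`), then take a
#' gradient step `w <- w - alpha * grad`. The weights are never
#' re-normalized, so the fitted weights are unconstrained reals. The weights
#' recorded at the best validation iteration are returned.
#'
#' @param P_train,P_val Models-by-instances probability matrices for the
#'   training and validation parts (same model rows).
#' @param y_train,y_val Matching binary label vectors.
#' @param config A [gbwoem_config()].
#' @return A `gbwoem_fit`: best-validation `weights`, `init_weights`, a
#'   per-iteration `trace` tibble (`iteration`, `train_loss`, `val_loss`),
#'   `best_loss`, `best_iteration`, `iterations_run`, `stop_reason`
#'   (`"patience_exhausted"` or `"max_iterations"`), and the config.
#' @export
optimize_weights <- function(P_train, y_train, P_val, y_val, config = gbwoem_config()) {
  stopifnot(inherits(config, "gbwoem_config"))
  P_train <- as.matrix(P_train)
  P_val <- as.matrix(P_val)
  if (nrow(P_train) != nrow(P_val)) {
    abort("Train and validation matrices must share the model count.")
  }
  if (ncol(P_train) != length(y_train) || ncol(P_val) != length(y_val)) {
    abort("Label lengths must match the matrices.")
  }
  n_models <- nrow(P_train)
  w <- init_weights(n_models, config$weight_init, config$seed)
  init_w <- w

  max_iter <- config$num_iterations
  train_losses <- numeric(max_iter)
  val_losses <- numeric(max_iter)
  best_loss <- Inf
  best_w <- w
  best_iter <- NA_integer_
  count <- 0L
  stop_reason <- "max_iterations"
  t_run <- 0L

  for (t in seq_len(max_iter)) {
    y_hat_train <- ensemble_predict(P_train, w)
    y_hat_val <- ensemble_predict(P_val, w)
    train_losses[t] <- bce_loss(y_train, y_hat_train, config$epsilon)
    val_losses[t] <- bce_loss(y_val, y_hat_val, config$epsilon)
    t_run <- t
    if (val_losses[t] < best_loss) {
      best_loss <- val_losses[t]
      best_w <- w
      best_iter <- t
      count <- 0L
    } else {
      count <- count + 1L
    }
    if (count >= config$patience) {
      stop_reason <- "patience_exhausted"
      break
    }
    grad <- loss_gradient(y_train, y_hat_train, P_train,
                          mode = config$gradient, epsilon = config$epsilon)
    w <- w - config$learning_rate * grad
  }

  structure(
    list(
      weights = setNames(best_w, rownames(P_train)),
      init_weights = setNames(init_w, rownames(P_train)),
      trace = tibble::tibble(
        iteration = seq_len(t_run),
        train_loss = train_losses[seq_len(t_run)],
        val_loss = val_losses[seq_len(t_run)]
      ),
      best_loss = if (t_run > 0) best_loss else NA_real_,
      best_iteration = best_iter,
      iterations_run = t_run,
      stop_reason = stop_reason,
      config = config
    ),
    class = "gbwoem_fit"
  )
}

#' @export
print.gbwoem_fit <- function(x, ...) {
  cat(sprintf(
    "<gbwoem_fit> %d model(s), %d iteration(s) (%s), best val loss %.6f at iteration %s\n",
    length(x$weights), x$iterations_run, x$stop_reason,
    x$best_loss, as.character(x$best_iteration)
  ))
  w <- x$weights
  lbl <- if (is.null(names(w))) seq_along(w) else names(w)
  cat("  weights:", paste(sprintf("%s=%.4f", lbl, w), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy the fitted ensemble weights
#'
#' @param x A `gbwoem_fit`.
#' @param ... Unused.
#' @return Tibble with one row per base model: `model`, `init_weight`,
#'   `weight`.
#' @method tidy gbwoem_fit
#' @export
tidy.gbwoem_fit <- function(x, ...) {
  tibble::tibble(
    model = names(x$weights) %||% as.character(seq_along(x$weights)),
    init_weight = unname(x$init_weights),
    weight = unname(x$weights)
  )
}

#' One-row optimization summary
#'
#' @param x A `gbwoem_fit`.
#' @param ... Unused.
#' @return Tibble with `n_models`, `iterations_run`, `best_iteration`,
#'   `best_loss`, `stop_reason`.
#' @method glance gbwoem_fit
#' @export
glance.gbwoem_fit <- function(x, ...) {
  tibble::tibble(
    n_models = length(x$weights),
    iterations_run = x$iterations_run,
    best_iteration = x$best_iteration,
    best_loss = x$best_loss,
    stop_reason = x$stop_reason
  )
}

#' Plot the optimization trace
#'
#' Training and validation loss per iteration, with the best-validation
#' iteration marked.
#'
#' @param object A `gbwoem_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gbwoem_fit
#' @export
autoplot.gbwoem_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace, c("train_loss", "val_loss"),
                              names_to = "split", values_to = "loss")
  long$split <- sub("_loss$", "", long$split)
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$loss,
                                          colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Iteration", y = "Cross-entropy loss",
                  colour = "Split") +
    ggplot2::theme_minimal()
  if (!is.na(object$best_iteration)) {
    p <- p + ggplot2::geom_vline(xintercept = object$best_iteration,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}
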