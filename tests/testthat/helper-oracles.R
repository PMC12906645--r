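# Independent oracles and tiny fixtures shared across the suite.

# Pairwise-concordance AUC: P(random positive outscores random negative),
# ties counted one half. Quadratic scan, deliberately naive.
concordance_auc <- function(y_true, y_prob) {
  pos <- y_prob[y_true == 1]
  neg <- y_prob[y_true == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Central finite differences of the squared-error surrogate
# (1/2N) * sum((clip(P' w) - y)^2) with respect to the weights.
fd_surrogate_gradient <- function(y_true, P, w, h = 1e-5) {
  loss_at <- function(w) {
    pred <- pmin(pmax(as.numeric(crossprod(P, w)), 0), 1)
    mean((pred - y_true)^2) / 2
  }
  vapply(seq_along(w), function(i) {
    up <- w; up[i] <- up[i] + h
    dn <- w; dn[i] <- dn[i] - h
    (loss_at(up) - loss_at(dn)) / (2 * h)
  }, numeric(1))
}

# Random weight-optimization instance with predictions bounded away from
# 0/1 and simplex weights, so the clipped aggregate stays interior and the
# surrogate is differentiable everywhere visited.
random_interior_instance <- function(n_models, n_obs) {
  P <- matrix(runif(n_models * n_obs, 0.05, 0.95), nrow = n_models)
  w <- runif(n_models)
  w <- w / sum(w)
  y <- rbinom(n_obs, 1, 0.5)
  list(P = P, w = w, y = y)
}

# A tiny linearly separable table: one feature fully determines the class.
separable_table <- function(n_per_class = 10) {
  tibble::tibble(
    .outcome = rep(c(0L, 1L), each = n_per_class),
    x1 = c(runif(n_per_class, 0, 0.3), runif(n_per_class, 0.7, 1)),
    x2 = runif(2 * n_per_class)
  )
}

write_tiny_csv <- function(lines) {
  tf <- withr::local_tempfile(fileext = ".csv",
                              .local_envir = parent.frame())
  writeLines(lines, tf)
  tf
}

# Prediction matrices in which model "A" emits the true labels as
# probabilities and model "B" their complement.
oracle_pair_matrices <- function(y) {
  rbind(A = as.numeric(y), B = 1 - as.numeric(y))
}
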