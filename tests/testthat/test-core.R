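test_that("uniform initialization is 1/n and random initialization is a normalized simplex point", {
  expect_equal(init_weights(5, "uniform"), rep(0.2, 5))
  for (seed in 1:5) {
    w <- init_weights(3, "random", seed = seed)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0 & w <= 1))
  }
  expect_identical(init_weights(4, "random", seed = 7),
                   init_weights(4, "random", seed = 7))
  expect_error(init_weights(2, "banana"), "initializer")
  expect_error(init_weights(0), "at least 1")
})

test_that("ensemble aggregation is the clipped weighted sum", {
  expect_equal(ensemble_predict(matrix(c(0.3, 0.7), nrow = 1), 1.0),
               c(0.3, 0.7))
  P <- rbind(c(0.2, 0.8), c(0.2, 0.8))
  expect_equal(ensemble_predict(P, c(0.5, 0.5)), c(0.2, 0.8))
  # unconstrained weights can push the raw sum past 1; it is clipped
  expect_equal(ensemble_predict(rbind(1, 1), c(0.7, 0.7)), 1.0)
  expect_equal(ensemble_predict(rbind(0.5), c(-1)), 0.0)
  expect_error(ensemble_predict(P, c(1, 1, 1)), "model count")
})

test_that("the stabilized cross-entropy matches closed forms", {
  expect_equal(bce_loss(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-9)
  expect_equal(bce_loss(1, 1), -log(1 + 1e-10), tolerance = 1e-12)
  expect_equal(bce_loss(0, 1), -log(1e-10), tolerance = 1e-9)
  expect_true(is.finite(bce_loss(c(1, 0), c(0, 1))))  # epsilon guards log(0)
  expect_error(bce_loss(numeric(0), numeric(0)), "Empty")
  expect_error(bce_loss(c(1, 0), 0.5), "mismatch")
  expect_error(bce_loss(1, 1.5), "\\[0, 1\\]")
})

test_that("the gradient matches hand arithmetic and vanishes at zero residual", {
  # perfect predictions: zero residual, zero gradient
  P <- rbind(c(0.9, 0.1), c(0.2, 0.6))
  y <- c(1, 0)
  expect_equal(loss_gradient(y, y, P), c(0, 0))
  # single model, y = [0, 1], p = [1, 0], w = 1 -> grad 0.5
  P1 <- matrix(c(1, 0), nrow = 1)
  y_ens <- ensemble_predict(P1, 1)
  expect_equal(loss_gradient(c(0, 1), y_ens, P1), 0.5)
})

test_that("the gradient is exact for the squared-error surrogate (finite-difference oracle)", {
  withr::with_seed(123, {
    for (rep in seq_len(100)) {
      inst <- random_interior_instance(sample(2:5, 1), sample(5:50, 1))
      y_ens <- ensemble_predict(inst$P, inst$w)
      analytic <- loss_gradient(inst$y, y_ens, inst$P)
      numeric_grad <- fd_surrogate_gradient(inst$y, inst$P, inst$w)
      expect_equal(analytic, numeric_grad, tolerance = 1e-6)
    }
  })
})

test_that("a zero iteration budget returns the initial weights and an empty trace", {
  P <- matrix(runif(6), nrow = 2)
  fit <- optimize_weights(P, c(1, 0, 1), P, c(1, 0, 1),
                          gbwoem_config(num_iterations = 0))
  expect_equal(unname(fit$weights), c(0.5, 0.5))
  expect_equal(nrow(fit$trace), 0)
  expect_equal(fit$iterations_run, 0)
  expect_true(is.na(fit$best_loss))
})

test_that("a perfect single model sits at a stationary point", {
  y <- c(1, 0, 1, 1, 0)
  P <- matrix(y, nrow = 1)
  fit <- optimize_weights(P, y, P, y,
                          gbwoem_config(num_iterations = 50, patience = 100))
  expect_equal(unname(fit$weights), 1.0)
  expect_equal(fit$iterations_run, 50)
  expect_true(all(abs(fit$trace$train_loss - fit$trace$train_loss[1]) < 1e-12))
})

test_that("an oracle model outweighs an anti-oracle after optimization", {
  withr::with_seed(31, y <- rbinom(60, 1, 0.4))
  P <- oracle_pair_matrices(y)
  fit <- optimize_weights(P, y, P, y,
                          gbwoem_config(learning_rate = 0.05,
                                        num_iterations = 500, patience = 50,
                                        weight_init = "random", seed = 2))
  expect_gt(fit$weights["A"], fit$weights["B"])
})

test_that("early stopping halts within patience of the last improvement and restores best weights", {
  # One model; training pushes the weight up, while the validation part is
  # anti-correlated, so validation loss strictly worsens from the start.
  P_train <- matrix(rep(0.5, 10), nrow = 1)
  y_train <- rep(1, 10)
  P_val <- matrix(rep(0.6, 10), nrow = 1)
  y_val <- rep(0, 10)
  fit <- optimize_weights(P_train, y_train, P_val, y_val,
                          gbwoem_config(learning_rate = 0.5,
                                        num_iterations = 100, patience = 3))
  expect_equal(fit$stop_reason, "patience_exhausted")
  expect_lte(fit$iterations_run, 1 + 3)  # best at iteration 1
  expect_equal(fit$best_iteration, 1)
  expect_equal(unname(fit$weights), 1.0)  # uniform init for n = 1
  expect_true(all(diff(fit$trace$val_loss) > 0))
})

test_that("the returned weights reproduce the minimum validation loss", {
  withr::with_seed(77, {
    P_train <- matrix(runif(3 * 40, 0.05, 0.95), nrow = 3)
    P_val <- matrix(runif(3 * 20, 0.05, 0.95), nrow = 3)
    y_train <- rbinom(40, 1, 0.5)
    y_val <- rbinom(20, 1, 0.5)
  })
  fit <- optimize_weights(P_train, y_train, P_val, y_val,
                          gbwoem_config(num_iterations = 300, patience = 30))
  expect_equal(fit$best_loss, min(fit$trace$val_loss), tolerance = 1e-15)
  reaggregated <- bce_loss(y_val, ensemble_predict(P_val, fit$weights))
  expect_equal(reaggregated, fit$best_loss, tolerance = 1e-12)
  expect_equal(fit$trace$val_loss[fit$best_iteration], fit$best_loss)
})

test_that("descent reduces the surrogate training loss at learning rate 0.01", {
  withr::with_seed(55, {
    P_train <- matrix(runif(4 * 50, 0.05, 0.95), nrow = 4)
    y_train <- rbinom(50, 1, 0.5)
  })
  cfg <- gbwoem_config(learning_rate = 0.01, num_iterations = 200,
                       patience = 200)
  fit <- optimize_weights(P_train, y_train, P_train, y_train, cfg)
  w0 <- init_weights(4, "uniform")
  s0 <- gbwoem:::surrogate_loss(y_train, ensemble_predict(P_train, w0))
  # weights after the final recorded iteration
  s_final <- gbwoem:::surrogate_loss(
    y_train, ensemble_predict(P_train, fit$weights))
  expect_lte(s_final, s0)
  # the monitored cross-entropy also never ends above its start
  expect_lte(dplyr::last(fit$trace$train_loss), fit$trace$train_loss[1])
})

test_that("optimization is fully deterministic under seed, config, and inputs", {
  withr::with_seed(91, {
    P_train <- matrix(runif(3 * 30), nrow = 3)
    P_val <- matrix(runif(3 * 15), nrow = 3)
    y_train <- rbinom(30, 1, 0.5)
    y_val <- rbinom(15, 1, 0.5)
  })
  cfg <- gbwoem_config(weight_init = "random", seed = 13,
                       num_iterations = 150, patience = 15)
  f1 <- optimize_weights(P_train, y_train, P_val, y_val, cfg)
  f2 <- optimize_weights(P_train, y_train, P_val, y_val, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$weights, f2$weights)
})

test_that("tidy, glance and autoplot expose the fit", {
  y <- c(1, 0, 1, 0)
  P <- rbind(M1 = c(0.8, 0.2, 0.7, 0.3), M2 = c(0.6, 0.5, 0.4, 0.5))
  fit <- optimize_weights(P, y, P, y, gbwoem_config(num_iterations = 20))
  td <- tidy(fit)
  expect_named(td, c("model", "init_weight", "weight"))
  expect_equal(td$model, c("M1", "M2"))
  gl <- glance(fit)
  expect_equal(gl$n_models, 2)
  expect_s3_class(autoplot(fit), "ggplot")
})
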