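#' Describe a synthetic-data scenario
#'
#' A scenario captures the statistical shape of an imbalanced clinical
#' feature table: how many instances and features, the positive-class
#' fraction (the study's datasets range from 8.2% to 52.9% positives), how
#' separable the classes are, and how corrupted the measurements are.
#'
#' @param n_instances Number of rows.
#' @param n_numeric Number of numeric features. All numeric features are
#'   informative: class-conditionally Gaussian with unit within-class
#'   standard deviation and a between-class mean shift of
#'   `class_separation`.
#' @param n_categorical Number of categorical features (three levels each,
#'   class-dependent multinomials whose dependence grows with
#'   `class_separation`).
#' @param positive_fraction Positive-class proportion in (0, 1). The positive
#'   count is exact — `round(n_instances * positive_fraction)` — so small
#'   minority regimes like 8.2% are hit exactly even at modest n.
#' @param class_separation Nonnegative mean shift of the numeric features in
#'   within-class standard-deviation units; 0 means no class signal.
#' @param label_noise Fraction of labels flipped after feature generation.
#' @param invalid_zero_rate Fraction of cells zeroed in designated columns by
#'   [corrupt_table()].
#' @param missing_rate Fraction of feature cells blanked by [corrupt_table()].
#' @param seed Integer seed; identical spec and seed give identical tables.
#' @return A `scenario_spec` list.
#' @details The defaults emulate a mid-sized diabetes-registry table:
#'   768 instances, 8 numeric and 2 categorical features, 34.9% positives,
#'   moderate separability.
#' @export
scenario_spec <- function(n_instances = 768, n_numeric = 8, n_categorical = 2,
                          positive_fraction = 0.349, class_separation = 0.8,
                          label_noise = 0.02, invalid_zero_rate = 0,
                          missing_rate = 0, seed = 1L) {
  props <- c(positive_fraction = positive_fraction, label_noise = label_noise,
             invalid_zero_rate = invalid_zero_rate, missing_rate = missing_rate)
  if (any(props < 0) || any(props > 1)) {
    abort("All proportions must lie in [0, 1].")
  }
  if (n_instances < 1 || n_numeric < 0 || n_categorical < 0 ||
      n_numeric + n_categorical < 1) {
    abort("Counts must be positive (at least one feature).")
  }
  if (class_separation < 0) abort("`class_separation` must be nonnegative.")
  n_pos <- round(n_instances * positive_fraction)
  if (n_pos == 0 || n_pos == n_instances) {
    abort("`positive_fraction` yields zero instances of one class.")
  }
  structure(
    list(n_instances = as.integer(n_instances),
         n_numeric = as.integer(n_numeric),
         n_categorical = as.integer(n_categorical),
         positive_fraction = positive_fraction,
         class_separation = class_separation,
         label_noise = label_noise,
         invalid_zero_rate = invalid_zero_rate,
         missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

#' Read a scenario from a YAML or JSON config file
#'
#' @param path Path to a YAML (or JSON; JSON is valid YAML) file whose keys
#'   are [scenario_spec()] arguments.
#' @return A `scenario_spec`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  args <- yaml::read_yaml(path)
  do.call(scenario_spec, args)
}

#' Generate a seeded synthetic feature table
#'
#' Draws a binary-outcome feature table with the scenario's exact positive
#' count. Numeric features are class-conditionally Gaussian
#' (`N(0, 1)` for negatives, `N(class_separation, 1)` for positives);
#' categorical features are three-level multinomials whose level
#' probabilities tilt with class as separation grows. `label_noise` then
#' flips an exact rounded fraction of labels, leaving the features attached
#' to the original class — irreducible labelling error.
#'
#' @param spec A [scenario_spec()].
#' @return A feature-table tibble with `.outcome` plus columns
#'   `num_1..num_k` and `cat_1..cat_m`.
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  n <- spec$n_instances
  n_pos <- round(n * spec$positive_fraction)
  withr::with_seed(spec$seed, {
    y <- rep(0L, n)
    y[sample.int(n, n_pos)] <- 1L
    out <- tibble::tibble(.outcome = y)
    for (j in seq_len(spec$n_numeric)) {
      out[[paste0("num_", j)]] <- rnorm(n, mean = spec$class_separation * y)
    }
    # Blend the negative-class level distribution toward its reverse as
    # separation grows, bounded away from degeneracy.
    t_mix <- spec$class_separation / (1 + spec$class_separation)
    p_neg <- c(0.5, 0.3, 0.2)
    p_pos <- (1 - t_mix) * p_neg + t_mix * rev(p_neg)
    levels <- c("a", "b", "c")
    for (j in seq_len(spec$n_categorical)) {
      draws <- character(n)
      draws[y == 0L] <- sample(levels, sum(y == 0L), replace = TRUE,
                               prob = p_neg)
      draws[y == 1L] <- sample(levels, sum(y == 1L), replace = TRUE,
                               prob = p_pos)
      out[[paste0("cat_", j)]] <- draws
    }
    n_flip <- round(n * spec$label_noise)
    if (n_flip > 0) {
      flip <- sample.int(n, n_flip)
      out$.outcome[flip] <- 1L - out$.outcome[flip]
    }
    out
  })
}

#' Corrupt a feature table with invalid zeros and missing cells
#'
#' Applies the scenario's corruption rates: designated numeric columns
#' receive zeros at `invalid_zero_rate` (emulating invalid clinical zeros),
#' and random feature cells are blanked to `NA` at `missing_rate`. Labels are
#' never touched.
#'
#' @param data A feature table.
#' @param spec A [scenario_spec()] supplying the rates and seed.
#' @param zero_columns Columns receiving invalid zeros; defaults to the first
#'   numeric feature column when the rate is positive.
#' @return The corrupted feature table.
#' @export
corrupt_table <- function(data, spec, zero_columns = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  assert_feature_table(data, require_binary = FALSE)
  numeric_cols <- feature_cols(data)[vapply(data[feature_cols(data)],
                                            is.numeric, logical(1))]
  if (is.null(zero_columns) && spec$invalid_zero_rate > 0) {
    zero_columns <- numeric_cols[1]
  }
  withr::with_seed(spec$seed + 1L, {
    if (spec$invalid_zero_rate > 0) {
      for (col in zero_columns) {
        hit <- runif(nrow(data)) < spec$invalid_zero_rate
        v <- data[[col]]
        v[hit] <- 0
        data[[col]] <- v
      }
    }
    if (spec$missing_rate > 0) {
      for (col in feature_cols(data)) {
        hit <- runif(nrow(data)) < spec$missing_rate
        v <- data[[col]]
        v[hit] <- NA
        data[[col]] <- v
      }
    }
  })
  data
}
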