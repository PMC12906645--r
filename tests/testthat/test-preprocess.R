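test_that("read_feature_table maps the positive label to 1", {
  tf <- write_tiny_csv(c("x,diagnosis", "1.5,M", "2.0,B", "0.5,M", "3.1,B"))
  tab <- read_feature_table(tf, "diagnosis", positive_label = "M")
  expect_s3_class(tab, "tbl_df")
  expect_equal(nrow(tab), 4)
  expect_equal(tab$.outcome, c(1L, 0L, 1L, 0L))
  expect_setequal(tab$.outcome, c(0L, 1L))
  expect_named(tab, c(".outcome", "x"))
})

test_that("read_feature_table validates its target", {
  tf <- write_tiny_csv(c("x,diagnosis", "1,M", "2,B"))
  expect_error(read_feature_table(tf, "nope"), "not present")
  expect_error(read_feature_table(tempfile(), "diagnosis"), "not found")
  multi <- write_tiny_csv(c("x,grade", "1,a", "2,b", "3,c"))
  expect_error(read_feature_table(multi, "grade", positive_label = "a"),
               "distinct values")
  expect_error(read_feature_table(multi, "grade"), "binarize")
})

test_that("binarize_target pools the named classes into the positive class", {
  df <- tibble::tibble(
    x = 1:8,
    level = rep(c("Normal", "Overweight", "ObeseI", "ObeseII"), 2)
  )
  tab <- binarize_target(df, "level", c("ObeseI", "ObeseII"))
  expect_equal(tab$.outcome, rep(c(0L, 0L, 1L, 1L), 2))
  expect_equal(binarize_target(df, "level", unique(df$level))$.outcome,
               rep(1L, 8))
  expect_equal(binarize_target(df, "level", character(0))$.outcome,
               rep(0L, 8))
  expect_error(
    binarize_target(df, "level", "ObeseI", negative_classes = "Normal"),
    "not covered"
  )
})

test_that("invalid zeros are replaced by non-zero column statistics", {
  df <- tibble::tibble(.outcome = rep(0:1, 2),
                       a = c(0, 2, 4, 6), b = c(0, 5, 9, 7), c = c(1, 2, 3, 4))
  med <- impute_invalid_zeros(df, "a")
  expect_equal(med$a, c(4, 2, 4, 6))  # median of {2,4,6}
  mn <- impute_invalid_zeros(df, "b", strategy = "min")
  expect_equal(mn$b, c(5, 5, 9, 7))  # min of {5,9,7}
  # untouched outside the named columns / zero cells
  expect_identical(med$b, df$b)
  expect_identical(med$c, df$c)
  expect_identical(impute_invalid_zeros(df, "c")$c, df$c)
})

test_that("an all-zero column is left unmodified with a warning", {
  df <- tibble::tibble(.outcome = 0:1, z = c(0, 0))
  expect_warning(out <- impute_invalid_zeros(df, "z"), "entirely zero")
  expect_identical(out$z, df$z)
})

test_that("one-hot encoding uses the training vocabulary", {
  train <- tibble::tibble(.outcome = c(0L, 1L, 0L),
                          col = c("yes", "no", "yes"))
  enc <- encode_impute(train)
  expect_named(enc, c(".outcome", "col_no", "col_yes"))
  expect_true(all(enc$col_no + enc$col_yes == 1))  # exactly one hot per row
  test <- tibble::tibble(.outcome = c(1L, 0L), col = c("maybe", "no"))
  enc_test <- encode_impute(test, fit_on = train)
  expect_equal(unlist(enc_test[1, c("col_no", "col_yes")]),
               c(col_no = 0, col_yes = 0))  # unseen category -> all zero
})

test_that("missing values take the training median and mode", {
  train <- tibble::tibble(.outcome = c(0L, 1L, 0L, 1L),
                          num = c(1, 2, 5, 8), cat = c("a", "a", "b", "a"))
  test <- tibble::tibble(.outcome = c(0L, 1L),
                         num = c(NA, 4), cat = c(NA, "b"))
  enc <- encode_impute(test, fit_on = train)
  expect_equal(enc$num[1], 3.5)  # median(1,2,5,8)
  expect_equal(enc$cat_a[1], 1)  # mode "a"
  expect_false(anyNA(enc))
})

test_that("min-max scaling fits on the training part, clips, and handles constants", {
  train <- tibble::tibble(.outcome = c(0L, 1L), a = c(0, 10), k = c(3, 3))
  test <- tibble::tibble(.outcome = c(0L, 1L, 0L), a = c(5, 12, -1), k = c(3, 9, 3))
  out <- normalize_features(test, fit_on = train)
  expect_equal(out$a, c(0.5, 1, 0))  # interior, clipped high, clipped low
  expect_equal(out$k, c(0, 0, 0))    # constant training column -> 0
})

test_that("normalization is idempotent with the same fit table", {
  withr::with_seed(4, {
    tab <- tibble::tibble(.outcome = rep(0:1, 10), a = rnorm(20), b = runif(20))
  })
  once <- normalize_features(tab, fit_on = tab)
  twice <- normalize_features(once, fit_on = once)
  expect_equal(twice, once, tolerance = 1e-12)
})

test_that("stratified split gives exact apportioned counts and is seeded", {
  tab <- tibble::tibble(.outcome = rep(c(0L, 1L), each = 50), x = seq_len(100))
  sp <- stratified_split(tab, c(0.6, 0.2, 0.2), seed = 42)
  expect_equal(vapply(sp[c("train", "val", "test")], nrow, integer(1)),
               c(train = 60L, val = 20L, test = 20L))
  expect_equal(vapply(sp[c("train", "val", "test")],
                      function(p) sum(p$.outcome), integer(1)),
               c(train = 30L, val = 10L, test = 10L))
  # disjoint and exhaustive
  all_idx <- sort(unname(unlist(sp$indices)))
  expect_identical(all_idx, seq_len(100))
  # byte-identical rerun under the same seed
  sp2 <- stratified_split(tab, c(0.6, 0.2, 0.2), seed = 42)
  expect_identical(sp$indices, sp2$indices)
  expect_identical(sp$train, sp2$train)
})

test_that("each split part tracks the global class balance", {
  tab <- generate_table(scenario_spec(n_instances = 500,
                                      positive_fraction = 0.18,
                                      label_noise = 0, seed = 2))
  sp <- stratified_split(tab, seed = 7)
  overall <- mean(tab$.outcome)
  for (p in c("train", "val", "test")) {
    expect_lt(abs(mean(sp[[p]]$.outcome) - overall), 0.02)
  }
})

test_that("a minority class too small for three parts is an error", {
  tab <- tibble::tibble(.outcome = c(1L, 0L, 0L, 0L), x = 1:4)
  expect_error(stratified_split(tab, c(0.6, 0.2, 0.2), seed = 1),
               "Too few")
  expect_error(stratified_split(tab, c(0.6, 0.2), seed = 1), "fractions")
})
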