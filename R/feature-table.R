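#' Feature tables
#'
#' Throughout the package a *feature table* is a tibble holding one instance
#' per row: an integer outcome column `.outcome` with values in `{0, 1}`
#' (1 = positive class) plus any number of feature columns, numeric or
#' categorical. All preprocessing verbs take a feature table first and return
#' a tibble, so they chain with the pipe.
#'
#' @param data A data frame.
#' @param require_binary Check that `.outcome` holds only 0/1.
#' @return `data`, invisibly, after validation.
#' @keywords internal
assert_feature_table <- function(data, require_binary = TRUE) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.")
  }
  if (!".outcome" %in% names(data)) {
    abort("`data` must contain an `.outcome` column; see `read_feature_table()`.")
  }
  if (require_binary && !all(data$.outcome %in% c(0L, 1L))) {
    abort("`.outcome` must contain only 0 and 1.")
  }
  invisible(data)
}

feature_cols <- function(data) setdiff(names(data), ".outcome")

#' Read a delimited feature table with a binary target
#'
#' Reads a header-row delimited text file and maps its target column to the
#' integer outcome coding used throughout the package (`.outcome`, positive
#' class = 1). Feature columns keep their raw values (numeric or categorical
#' strings); encoding and scaling are separate, training-fitted steps.
#'
#' @param path Path to a delimited text file with a header row.
#' @param target_column Name of the target column.
#' @param positive_label The target value mapped to 1. May be omitted when the
#'   target is already coded 0/1.
#' @param positive_classes For a multi-class target: the set of labels mapped
#'   to 1 (all others become 0), as in collapsing several disease grades into
#'   one positive class.
#' @param delim Field delimiter, default comma.
#' @return A feature-table tibble with an `.outcome` column.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("x,diagnosis", "1,M", "2,B", "3,M", "4,B"), tf)
#' read_feature_table(tf, "diagnosis", positive_label = "M")
#' @export
read_feature_table <- function(path, target_column, positive_label = NULL,
                               positive_classes = NULL, delim = ",") {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path))
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!target_column %in% names(raw)) {
    abort(paste0("Target column `", target_column, "` not present in ", path))
  }
  if (!is.null(positive_classes)) {
    return(binarize_target(raw, target_column, positive_classes))
  }
  target <- raw[[target_column]]
  vals <- sort(unique(as.character(target[!is.na(target)])))
  if (is.null(positive_label)) {
    if (!all(vals %in% c("0", "1"))) {
      abort(paste0(
        "Target `", target_column, "` has values {",
        paste(vals, collapse = ", "),
        "}; supply `positive_label` or `positive_classes` to binarize."
      ))
    }
    y <- as.integer(as.character(target))
  } else {
    if (length(vals) > 2) {
      abort(paste0(
        "Target `", target_column, "` has ", length(vals),
        " distinct values; supply `positive_classes` to binarize."
      ))
    }
    y <- as.integer(as.character(target) == as.character(positive_label))
  }
  out <- dplyr::select(raw, -dplyr::all_of(target_column))
  out$.outcome <- y
  tibble::as_tibble(dplyr::relocate(out, ".outcome"))
}

#' Collapse a multi-class target to a binary outcome
#'
#' Maps every label in `positive_classes` to 1 and every other observed label
#' to 0 — the usual recoding when, say, all obesity grades are pooled into one
#' positive class against normal-weight controls. When `negative_classes` is
#' supplied, any observed label in neither set is an error.
#'
#' @param data A data frame still carrying its raw target column.
#' @param target_column Name of the target column.
#' @param positive_classes Labels mapped to 1.
#' @param negative_classes Optional explicit negative labels; observed labels
#'   outside both sets then signal an error.
#' @return A feature-table tibble: target column replaced by `.outcome`.
#' @export
binarize_target <- function(data, target_column, positive_classes,
                            negative_classes = NULL) {
  if (!target_column %in% names(data)) {
    abort(paste0("Target column `", target_column, "` not present."))
  }
  labels <- as.character(data[[target_column]])
  if (!is.null(negative_classes)) {
    covered <- labels %in% c(as.character(positive_classes),
                             as.character(negative_classes))
    if (!all(covered)) {
      abort(paste0(
        "Observed target labels not covered by the mapping: ",
        paste(unique(labels[!covered]), collapse = ", ")
      ))
    }
  }
  out <- dplyr::select(data, -dplyr::all_of(target_column))
  out$.outcome <- as.integer(labels %in% as.character(positive_classes))
  tibble::as_tibble(dplyr::relocate(out, ".outcome"))
}

#' Replace invalid zeros by a column statistic
#'
#' Clinical tables often encode missingness as a physiologically impossible 0
#' (zero blood pressure, zero BMI). For each named column, zeros are replaced
#' by the median or minimum of that column's *non-zero* values. Columns are
#' named by the caller; no automatic detection is attempted.
#'
#' @param data A feature table.
#' @param columns Character vector of numeric columns holding invalid zeros.
#' @param strategy `"median"` (default) or `"min"`, computed over non-zero
#'   values.
#' @return The feature table with zeros in `columns` replaced. A column that
#'   is entirely zero is left unmodified with a warning.
#' @examples
#' df <- tibble::tibble(.outcome = c(0L, 1L, 0L, 1L), bp = c(0, 2, 4, 6))
#' impute_invalid_zeros(df, "bp")  # 0 -> median(2, 4, 6) = 4
#' @export
impute_invalid_zeros <- function(data, columns, strategy = c("median", "min")) {
  strategy <- match.arg(strategy)
  assert_feature_table(data, require_binary = FALSE)
  missing_cols <- setdiff(columns, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Unknown columns: ", paste(missing_cols, collapse = ", ")))
  }
  for (col in columns) {
    v <- data[[col]]
    if (!is.numeric(v)) {
      abort(paste0("Column `", col, "` is not numeric."))
    }
    nz <- v[!is.na(v) & v != 0]
    if (length(nz) == 0) {
      warn(paste0("Column `", col, "` is entirely zero; left unmodified."))
      next
    }
    stat <- if (strategy == "median") median(nz) else min(nz)
    v[!is.na(v) & v == 0] <- stat
    data[[col]] <- v
  }
  data
}

# Per-column preprocessing statistics fitted on the training part only.
fit_encoding_stats <- function(fit_on) {
  cols <- feature_cols(fit_on)
  stats <- list()
  for (col in cols) {
    v <- fit_on[[col]]
    if (is.numeric(v)) {
      stats[[col]] <- list(type = "numeric", median = median(v, na.rm = TRUE))
    } else {
      v <- as.character(v)
      vocab <- sort(unique(v[!is.na(v)]))
      counts <- table(factor(v, levels = vocab))
      mode <- if (length(vocab)) vocab[which.max(counts)] else NA_character_
      stats[[col]] <- list(type = "categorical", vocab = vocab, mode = mode)
    }
  }
  stats
}

#' One-hot encode categoricals and impute missing values
#'
#' Categorical columns are expanded into indicator columns using the category
#' vocabulary observed in `fit_on` (normally the training part); a category
#' unseen in training maps to all-zero indicators. Missing numeric values are
#' replaced by the training median, missing categorical values by the training
#' mode. Fitting on the training part only keeps the step leakage-free.
#'
#' @param data Feature table to transform.
#' @param fit_on Feature table defining vocabularies and imputation
#'   statistics; defaults to `data` itself.
#' @return A fully numeric feature table with no missing values.
#' @export
encode_impute <- function(data, fit_on = data) {
  assert_feature_table(data, require_binary = FALSE)
  stats <- fit_encoding_stats(fit_on)
  pieces <- list(tibble::tibble(.outcome = data$.outcome))
  for (col in feature_cols(data)) {
    st <- stats[[col]]
    if (is.null(st)) {
      abort(paste0("Column `", col, "` absent from `fit_on` schema."))
    }
    v <- data[[col]]
    if (st$type == "numeric") {
      v[is.na(v)] <- st$median
      pieces[[length(pieces) + 1L]] <- tibble::tibble(!!col := as.numeric(v))
    } else {
      v <- as.character(v)
      v[is.na(v)] <- st$mode
      ind <- vapply(st$vocab, function(lev) as.numeric(v == lev),
                    numeric(length(v)))
      if (length(v) == 1L) ind <- matrix(ind, nrow = 1L)
      colnames(ind) <- paste(col, st$vocab, sep = "_")
      pieces[[length(pieces) + 1L]] <- tibble::as_tibble(ind)
    }
  }
  dplyr::bind_cols(pieces)
}

#' Min-max scale features to [0, 1]
#'
#' Scales every numeric feature column with the minimum and maximum observed
#' in `fit_on` (normally the training part). A column constant in `fit_on`
#' maps to 0; values outside the training range are clipped to `[0, 1]`.
#'
#' @param data Feature table to scale (numeric features).
#' @param fit_on Feature table defining per-column min/max; defaults to
#'   `data`.
#' @return The scaled feature table.
#' @export
normalize_features <- function(data, fit_on = data) {
  assert_feature_table(data, require_binary = FALSE)
  for (col in feature_cols(data)) {
    ref <- fit_on[[col]]
    if (is.null(ref)) abort(paste0("Column `", col, "` absent from `fit_on`."))
    if (!is.numeric(ref)) abort(paste0("Column `", col, "` is not numeric."))
    lo <- min(ref, na.rm = TRUE)
    hi <- max(ref, na.rm = TRUE)
    v <- data[[col]]
    if (hi > lo) {
      v <- (v - lo) / (hi - lo)
    } else {
      v <- rep(0, length(v))
    }
    data[[col]] <- pmin(pmax(v, 0), 1)
  }
  data
}

# Largest-remainder apportionment of n_c class members over the parts.
apportion <- function(n_c, fractions) {
  raw <- n_c * fractions
  base <- floor(raw)
  rem <- n_c - sum(base)
  if (rem > 0) {
    order_by_frac <- order(raw - base, decreasing = TRUE)
    base[order_by_frac[seq_len(rem)]] <- base[order_by_frac[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Partitions a feature table into three disjoint, exhaustive parts whose
#' class proportions match the whole (stratified). Validation-based early
#' stopping in the weight optimizer requires the three-way split. Counts per
#' class and part are apportioned by largest remainder, so a 50/50 table of
#' 100 rows at (0.6, 0.2, 0.2) yields exactly 30/10/10 positives.
#'
#' @param data A feature table with binary `.outcome`.
#' @param fractions Numeric length-3 vector (train, val, test), positive,
#'   summing to 1.
#' @param seed Integer seed; the same seed always reproduces the identical
#'   partition.
#' @return An object of class `data_split`: a list with tibbles `train`,
#'   `val`, `test`, the row `indices` of each part, and the `fractions` and
#'   `seed` used.
#' @export
stratified_split <- function(data, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  assert_feature_table(data)
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    abort("`fractions` must be three positive values summing to 1.")
  }
  parts <- c("train", "val", "test")
  idx <- setNames(vector("list", 3), parts)
  for (cls in c(0L, 1L)) {
    rows <- which(data$.outcome == cls)
    counts <- apportion(length(rows), fractions)
    if (any(counts < 1)) {
      abort(paste0(
        "Too few instances of class ", cls,
        " to populate every part (", length(rows), " available)."
      ))
    }
    shuffled <- withr::with_seed(seed + cls, sample(rows))
    cuts <- cumsum(counts)
    idx$train <- c(idx$train, shuffled[seq_len(cuts[1])])
    idx$val <- c(idx$val, shuffled[(cuts[1] + 1):cuts[2]])
    idx$test <- c(idx$test, shuffled[(cuts[2] + 1):cuts[3]])
  }
  idx <- lapply(idx, sort)
  structure(
    list(
      train = data[idx$train, , drop = FALSE],
      val = data[idx$val, , drop = FALSE],
      test = data[idx$test, , drop = FALSE],
      indices = idx,
      fractions = fractions,
      seed = as.integer(seed)
    ),
    class = "data_split"
  )
}

#' @export
print.data_split <- function(x, ...) {
  cat("Stratified data split (seed ", x$seed, ")\n", sep = "")
  for (p in c("train", "val", "test")) {
    tb <- x[[p]]
    cat(sprintf("  %-5s %5d instances, %5.1f%% positive\n", p, nrow(tb),
                100 * mean(tb$.outcome)))
  }
  invisible(x)
}

#' Apply the full training-fitted preprocessing to a split
#'
#' Convenience wrapper: encodes and imputes, then min-max scales, all three
#' parts of a split with statistics fitted on the training part only.
#'
#' @param split A `data_split`.
#' @return The split with all three parts numeric, complete, and scaled.
#' @export
preprocess_split <- function(split) {
  stopifnot(inherits(split, "data_split"))
  raw_train <- split$train
  train_enc <- encode_impute(raw_train)
  for (p in c("train", "val", "test")) {
    enc <- encode_impute(split[[p]], fit_on = raw_train)
    split[[p]] <- normalize_features(enc, fit_on = train_enc)
  }
  split
}
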