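#' Subject-level dataset container
#'
#' A `bf_dataset` bundles an N x d numeric feature matrix, binary labels,
#' feature names, subject ids, and an ordered log of preprocessing steps.
#' Raw (freshly loaded) datasets may contain missing feature values; after
#' [preprocess()] no missing values remain.
#'
#' @param features numeric matrix (subjects in rows).
#' @param labels integer/numeric vector of 0/1 outcome labels.
#' @param feature_names optional character vector of column names
#'   (default: taken from `colnames(features)`).
#' @param subject_ids optional character vector of row identifiers.
#' @param preprocessing_log list of transform records (internal).
#' @return An object of class `bf_dataset`.
#' @export
bf_dataset <- function(features, labels, feature_names = NULL,
                       subject_ids = NULL, preprocessing_log = list()) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  d <- ncol(features)
  if (n < 1L || d < 1L) {
    stop("dataset must have at least one row and one feature column")
  }
  if (length(labels) != n) {
    stop("labels length (", length(labels), ") != number of rows (", n, ")")
  }
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    stop("labels must contain only 0 and 1")
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(d))
  }
  if (length(feature_names) != d) stop("feature_names length != number of columns")
  if (anyDuplicated(feature_names)) stop("feature_names must be unique")
  if (is.null(subject_ids)) subject_ids <- as.character(seq_len(n))
  if (length(subject_ids) != n) stop("subject_ids length != number of rows")
  colnames(features) <- feature_names
  structure(
    list(
      features = features,
      labels = as.integer(labels),
      feature_names = feature_names,
      subject_ids = as.character(subject_ids),
      preprocessing_log = preprocessing_log
    ),
    class = "bf_dataset"
  )
}

#' @export
print.bf_dataset <- function(x, ...) {
  cat(sprintf(
    "<bf_dataset> %d subjects x %d features; prevalence %.3f; %d preprocessing steps\n",
    nrow(x$features), ncol(x$features), mean(x$labels),
    length(x$preprocessing_log)
  ))
  invisible(x)
}

#' @export
dim.bf_dataset <- function(x) dim(x$features)

# Row subset preserving metadata; used by splitters and CV folds.
dataset_rows <- function(ds, idx) {
  bf_dataset(ds$features[idx, , drop = FALSE], ds$labels[idx],
             ds$feature_names, ds$subject_ids[idx], ds$preprocessing_log)
}

#' Load a subject-level feature table from CSV
#'
#' Reads an RFC-4180 CSV with a header row; one column holds the binary
#' outcome label and every remaining column must be numeric (empty cells and
#' `NA` are treated as missing). An optional id column supplies subject ids;
#' otherwise row numbers are used. Row order is preserved.
#'
#' @param path path to the CSV file.
#' @param label_column name of the outcome column.
#' @param id_column optional name of a subject-id column.
#' @return A raw (unpreprocessed) [bf_dataset()].
#' @export
load_table <- function(path, label_column, id_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, na.strings = c("", "NA"),
                        stringsAsFactors = FALSE)
  if (!label_column %in% names(df)) {
    stop("label column '", label_column, "' not present in ", path)
  }
  labels <- df[[label_column]]
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    stop("label column '", label_column, "' must contain only 0 and 1")
  }
  ids <- NULL
  drop_cols <- label_column
  if (!is.null(id_column)) {
    if (!id_column %in% names(df)) stop("id column '", id_column, "' not present")
    ids <- as.character(df[[id_column]])
    drop_cols <- c(drop_cols, id_column)
  }
  feat_df <- df[setdiff(names(df), drop_cols)]
  if (ncol(feat_df) == 0L) stop("no feature columns remain after removing the label")
  for (j in seq_along(feat_df)) {
    col <- feat_df[[j]]
    if (!is.numeric(col)) {
      coerced <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(coerced))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric value in column '%s', row %d: '%s'",
                     names(feat_df)[j], bad[1L], col[bad[1L]]))
      }
      feat_df[[j]] <- coerced
    }
  }
  bf_dataset(as.matrix(feat_df), labels, names(feat_df), ids)
}

#' Write a dataset back to CSV
#'
#' Inverse of [load_table()]: emits subject ids, features, and the label
#' column. Values round-trip exactly (full double precision).
#'
#' @param ds a [bf_dataset()].
#' @param path output path.
#' @param label_column name for the outcome column.
#' @param id_column name for the subject-id column.
#' @return `path`, invisibly.
#' @export
write_table <- function(ds, path, label_column = "label", id_column = "subject_id") {
  df <- as.data.frame(ds$features, check.names = FALSE)
  out <- cbind(
    stats::setNames(data.frame(ds$subject_ids, stringsAsFactors = FALSE), id_column),
    df,
    stats::setNames(data.frame(ds$labels), label_column)
  )
  # format() at 17 significant digits guarantees bit-exact double round-trip
  num <- vapply(out, is.numeric, logical(1L)) & names(out) != label_column
  out[num] <- lapply(out[num], function(x) {
    s <- formatC(x, digits = 17, format = "g")
    s[is.na(x)] <- NA
    s
  })
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Preprocess a raw dataset
#'
#' Applies the standard feature-table cleaning pipeline: (1) drop columns
#' whose fraction of non-zero (observed) entries is below `min_nonzero_frac`;
#' (2) drop columns whose variance (over observed entries) is below
#' `min_variance`; (3) impute remaining missing entries with the column
#' median over observed values. Optionally, a per-column `(low, high)` clamp
#' table restricts values to plausible physiological ranges first (values
#' outside the range become missing). Filters run before imputation, and the
#' medians are computed on the full table (pre-split), so a downstream
#' train/validation split shares the imputation statistics; this mirrors
#' pipelines that preprocess once per cohort and implies a small amount of
#' information leakage across the internal split.
#'
#' @param ds raw [bf_dataset()].
#' @param min_nonzero_frac minimum fraction of non-zero entries (default 0.05).
#' @param min_variance minimum column variance (default 0.05).
#' @param ranges optional data.frame with columns `feature`, `low`, `high`.
#' @return A preprocessed [bf_dataset()] with a populated `preprocessing_log`.
#' @export
preprocess <- function(ds, min_nonzero_frac = 0.05, min_variance = 0.05,
                       ranges = NULL) {
  stopifnot(inherits(ds, "bf_dataset"))
  if (min_nonzero_frac < 0 || min_nonzero_frac >= 1) {
    stop("min_nonzero_frac must be in [0, 1)")
  }
  if (min_variance < 0) stop("min_variance must be >= 0")
  x <- ds$features
  log <- ds$preprocessing_log

  if (!is.null(ranges)) {
    for (k in seq_len(nrow(ranges))) {
      nm <- as.character(ranges$feature[k])
      if (!nm %in% colnames(x)) next
      col <- x[, nm]
      out_of_range <- !is.na(col) & (col < ranges$low[k] | col > ranges$high[k])
      if (any(out_of_range)) {
        x[out_of_range, nm] <- NA
        log[[length(log) + 1L]] <- list(step = "range_clamp", feature = nm,
                                        n_set_missing = sum(out_of_range))
      }
    }
  }

  nonzero_frac <- colMeans(x != 0 & !is.na(x))
  variance <- apply(x, 2L, stats::var, na.rm = TRUE)
  variance[is.na(variance)] <- 0
  drop <- nonzero_frac < min_nonzero_frac | variance < min_variance
  if (all(drop)) stop("preprocessing dropped every column; thresholds too strict?")
  if (any(drop)) {
    log[[length(log) + 1L]] <- list(
      step = "drop_columns",
      dropped = colnames(x)[drop],
      reason = ifelse(nonzero_frac[drop] < min_nonzero_frac,
                      "low_nonzero_fraction", "low_variance")
    )
    x <- x[, !drop, drop = FALSE]
  }

  n_imputed <- 0L
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) {
      x[miss, j] <- stats::median(x[!miss, j])
      n_imputed <- n_imputed + sum(miss)
    }
  }
  if (n_imputed > 0L) {
    log[[length(log) + 1L]] <- list(step = "median_impute", n_imputed = n_imputed)
  }

  bf_dataset(x, ds$labels, colnames(x), ds$subject_ids, log)
}

#' Deterministic stratified train/validation split
#'
#' Partitions the dataset into disjoint, exhaustive train and validation
#' parts, stratified by label so each part carries both classes whenever
#' the class counts allow, and validation prevalence tracks the full-data
#' prevalence to within rounding. The same seed always yields the same split.
#'
#' @param ds a [bf_dataset()] with both classes present.
#' @param validation_frac fraction held out for validation (default 0.20).
#' @param seed integer seed controlling the split.
#' @return list with elements `train` and `validation` ([bf_dataset()]s) and
#'   the row index vectors `train_idx`, `validation_idx`.
#' @export
split_train_validation <- function(ds, validation_frac = 0.20, seed = 1L) {
  stopifnot(inherits(ds, "bf_dataset"))
  n <- nrow(ds$features)
  if (n < 5L) stop("need at least 5 subjects to split")
  counts <- table(factor(ds$labels, levels = c(0, 1)))
  if (any(counts == 0L)) stop("both classes must be present to split")
  if (any(counts < 2L)) {
    stop("stratified split needs >= 2 subjects per class; class counts: ",
         paste(counts, collapse = "/"),
         ". Collect more minority-class subjects or merge labels.")
  }
  val_idx <- integer(0)
  local_rng(seed, {
    for (cls in c(0L, 1L)) {
      rows <- which(ds$labels == cls)
      n_val <- round(length(rows) * validation_frac)
      # keep at least one subject of each class on each side
      n_val <- max(1L, min(length(rows) - 1L, n_val))
      val_idx <- c(val_idx, sample(rows, n_val))
    }
  })
  val_idx <- sort(val_idx)
  train_idx <- setdiff(seq_len(n), val_idx)
  list(
    train = dataset_rows(ds, train_idx),
    validation = dataset_rows(ds, val_idx),
    train_idx = train_idx,
    validation_idx = val_idx
  )
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards, so library calls never perturb user randomness.
local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}

#' Summarize the preprocessing log as JSON
#'
#' @param ds a [bf_dataset()].
#' @return A JSON string describing every applied transform.
#' @export
preprocessing_log_json <- function(ds) {
  jsonlite::toJSON(ds$preprocessing_log, auto_unbox = TRUE, pretty = TRUE)
}
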