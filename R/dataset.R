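#' Construct a classification dataset
#'
#' The core container of the package: an encoded, fully numeric feature
#' matrix together with a categorical outcome label per row. All downstream
#' stages (splitting, wrapper feature selection, classification, metrics)
#' operate on this type.
#'
#' @param features numeric matrix, rows = samples, columns = encoded features.
#' @param labels character or factor vector of outcome classes, one per row.
#' @param feature_names optional character vector of column names; defaults to
#'   the matrix's column names or `f1..fD`.
#' @param class_names optional character vector fixing the class set and its
#'   order; defaults to the sorted distinct labels.
#' @return An object of class `gs_dataset` with elements `features`, `labels`,
#'   `feature_names`, `class_names`.
#' @examples
#' d <- gs_dataset(matrix(rnorm(20), 10, 2), rep(c("a", "b"), 5))
#' dim(d$features)
#' @export
gs_dataset <- function(features, labels, feature_names = NULL,
                       class_names = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.character(labels)
  if (nrow(features) != length(labels)) {
    stop("features has ", nrow(features), " rows but labels has length ",
         length(labels), call. = FALSE)
  }
  if (anyNA(features)) {
    stop("features contains missing values; encode or impute first",
         call. = FALSE)
  }
  if (anyNA(labels)) stop("labels contains missing values", call. = FALSE)
  if (is.null(feature_names)) {
    feature_names <- colnames(features) %||% paste0("f", seq_len(ncol(features)))
  }
  if (length(feature_names) != ncol(features)) {
    stop("feature_names length (", length(feature_names),
         ") != feature count (", ncol(features), ")", call. = FALSE)
  }
  if (is.null(class_names)) class_names <- sort(unique(labels))
  if (!all(labels %in% class_names)) {
    bad <- setdiff(unique(labels), class_names)
    stop("labels outside class_names: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  colnames(features) <- feature_names
  structure(
    list(features = features, labels = labels,
         feature_names = as.character(feature_names),
         class_names = as.character(class_names)),
    class = "gs_dataset"
  )
}

#' @export
print.gs_dataset <- function(x, ...) {
  cat("<gs_dataset> ", nrow(x$features), " samples x ", ncol(x$features),
      " features, ", length(x$class_names), " classes\n", sep = "")
  tab <- table(factor(x$labels, levels = x$class_names))
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of samples / features of a dataset
#' @param x a `gs_dataset`.
#' @export
dim.gs_dataset <- function(x) dim(x$features)

#' Read a dataset from a CSV file
#'
#' Reads an RFC-4180 CSV with a header row, removes the label column from the
#' feature block, and returns a [gs_dataset()]. All non-label columns must be
#' numeric and complete; an empty or non-numeric cell is reported with its
#' row and column.
#'
#' @param path path to an existing CSV file.
#' @param label_column name of the outcome column.
#' @return A [gs_dataset()]. Feature order follows the CSV header.
#' @export
load_csv <- function(path, label_column) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, check.names = FALSE, colClasses = "character",
                  na.strings = NULL)
  if (!label_column %in% names(raw)) {
    stop("label column '", label_column, "' not in header: ",
         paste(names(raw), collapse = ", "), call. = FALSE)
  }
  labels <- raw[[label_column]]
  feat_cols <- setdiff(names(raw), label_column)
  n <- nrow(raw)
  features <- matrix(NA_real_, n, length(feat_cols),
                     dimnames = list(NULL, feat_cols))
  for (j in seq_along(feat_cols)) {
    col <- raw[[feat_cols[j]]]
    empty <- !nzchar(trimws(col))
    if (any(empty)) {
      stop("empty cell at row ", which(empty)[1], ", column '", feat_cols[j],
           "'", call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(col))
    if (anyNA(num)) {
      bad <- which(is.na(num))[1]
      stop("non-numeric value '", col[bad], "' at row ", bad, ", column '",
           feat_cols[j], "'", call. = FALSE)
    }
    features[, j] <- num
  }
  gs_dataset(features, labels)
}

#' Write a dataset to CSV at full double precision
#'
#' Inverse of [load_csv()]: numbers are printed with 17 significant digits so
#' a read-back reproduces the matrix bit-for-bit.
#'
#' @param dataset a `gs_dataset`.
#' @param path output path.
#' @param label_column name to give the outcome column (default `"outcome"`).
#' @return `path`, invisibly.
#' @export
write_csv <- function(dataset, path, label_column = "outcome") {
  stopifnot(inherits(dataset, "gs_dataset"))
  if (label_column %in% dataset$feature_names) {
    stop("label_column collides with a feature name", call. = FALSE)
  }
  mat <- apply(dataset$features, 2, format_full)
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(dataset$features))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- dataset$feature_names
  df[[label_column]] <- dataset$labels
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Declarative feature encoding to a numeric, range-normalized matrix
#'
#' Turns a mixed-type table (data.frame) into a [gs_dataset()]-ready numeric
#' matrix under per-column rules, then min-max normalizes every column into
#' `domain_range`. Rules:
#' \describe{
#'   \item{`numeric`}{passthrough, then min-max to `domain_range`.}
#'   \item{`ordinal`}{a named `map` from category to rank, then min-max.}
#'   \item{`onehot`}{one 0/1 column per level (given or observed); the
#'     indicator columns are min-max normalized like any other column.}
#' }
#' A constant column maps to the midpoint of `domain_range` (divide-by-zero
#' guard that preserves the column count). Missing cells are rejected unless
#' `impute = TRUE`, which uses the column median (numeric) or mode
#' (categorical).
#'
#' @param raw_table data.frame of raw columns (label column excluded).
#' @param spec named list: for each column of `raw_table`, a list with
#'   `type` in `c("numeric", "ordinal", "onehot")` and, for ordinal, a named
#'   numeric `map`; for onehot, an optional character `levels`.
#' @param domain_range length-2 numeric, target range (default `c(-1, 1)`).
#' @param strict if `TRUE` (default) an unseen ordinal/onehot category is an
#'   error; otherwise unseen ordinals map to the midpoint rank and unseen
#'   onehot levels to all-zero indicators.
#' @param impute impute missing cells instead of rejecting them.
#' @return numeric matrix with generated column names.
#' @export
encode_features <- function(raw_table, spec, domain_range = c(-1, 1),
                            strict = TRUE, impute = FALSE) {
  stopifnot(is.data.frame(raw_table), is.numeric(domain_range),
            length(domain_range) == 2, domain_range[1] < domain_range[2])
  missing_rules <- setdiff(names(raw_table), names(spec))
  if (length(missing_rules)) {
    stop("no encoding rule for column(s): ",
         paste(missing_rules, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (nm in names(raw_table)) {
    rule <- spec[[nm]]
    col <- raw_table[[nm]]
    if (anyNA(col) || (is.character(col) && any(!nzchar(col)))) {
      if (!impute) {
        stop("missing value in column '", nm,
             "' (set impute = TRUE to impute)", call. = FALSE)
      }
      col <- impute_column(col)
    }
    enc <- switch(
      rule$type,
      numeric = {
        v <- as.numeric(col)
        if (anyNA(v)) stop("non-numeric cell in numeric column '", nm, "'",
                           call. = FALSE)
        matrix(v, ncol = 1, dimnames = list(NULL, nm))
      },
      ordinal = {
        map <- rule$map
        if (is.null(names(map))) stop("ordinal rule for '", nm,
                                      "' needs a named map", call. = FALSE)
        v <- unname(map[as.character(col)])
        if (anyNA(v)) {
          if (strict) {
            bad <- setdiff(unique(as.character(col)), names(map))
            stop("unseen category in '", nm, "': ",
                 paste(bad, collapse = ", "), call. = FALSE)
          }
          v[is.na(v)] <- mean(range(map))
        }
        matrix(v, ncol = 1, dimnames = list(NULL, nm))
      },
      onehot = {
        levs <- rule$levels %||% sort(unique(as.character(col)))
        unseen <- setdiff(unique(as.character(col)), levs)
        if (length(unseen) && strict) {
          stop("unseen category in '", nm, "': ",
               paste(unseen, collapse = ", "), call. = FALSE)
        }
        m <- vapply(levs, function(l) as.numeric(col == l),
                    numeric(length(col)))
        colnames(m) <- paste(nm, levs, sep = ".")
        m
      },
      stop("unknown encoding type '", rule$type, "' for column '", nm, "'",
           call. = FALSE)
    )
    out[[nm]] <- enc
  }
  mat <- do.call(cbind, out)
  minmax_normalize(mat, domain_range)
}

impute_column <- function(col) {
  if (is.numeric(col)) {
    col[is.na(col)] <- median(col, na.rm = TRUE)
  } else {
    col <- as.character(col)
    miss <- is.na(col) | !nzchar(col)
    tab <- table(col[!miss])
    col[miss] <- names(tab)[which.max(tab)]
  }
  col
}

#' Min-max normalize matrix columns into a target range
#'
#' Affine map of each column onto `domain_range`; a constant column is mapped
#' to the range midpoint.
#'
#' @param mat numeric matrix.
#' @param domain_range length-2 numeric target range.
#' @return matrix of the same shape.
#' @export
minmax_normalize <- function(mat, domain_range = c(-1, 1)) {
  lo <- domain_range[1]
  hi <- domain_range[2]
  apply_cols <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) return(rep((lo + hi) / 2, length(v)))
    lo + (v - r[1]) / (r[2] - r[1]) * (hi - lo)
  }
  out <- apply(mat, 2, apply_cols)
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(mat))
  dimnames(out) <- dimnames(mat)
  out
}

#' Deterministic train/test split
#'
#' Splits a dataset into train and test halves, stratified by class by
#' default (the outcome has four roughly balanced states, so stratification
#' keeps per-class proportions within one sample of the target fraction).
#'
#' The same seed always yields the same permutation, and the training set at
#' fraction `f` is the exact complement of the training set at `1 - f`
#' (splits at `f` and `1 - f` partition the data complementarily): the train
#' rows are taken from the front of the seeded permutation when `f >= 0.5`
#' and from the back otherwise.
#'
#' @param dataset a [gs_dataset()].
#' @param fraction training proportion in (0, 1); default 0.8 (an 80/20
#'   holdout).
#' @param seed integer seed; the same seed always yields the same partition.
#' @param stratified split within each class (default `TRUE`).
#' @return An object of class `gs_split`: list with `train`, `test`
#'   (both `gs_dataset`), `fraction`, `seed`, and the integer index vectors
#'   `train_idx`, `test_idx`.
#' @export
train_test_split <- function(dataset, fraction = 0.8, seed = 1L,
                             stratified = TRUE) {
  stopifnot(inherits(dataset, "gs_dataset"),
            is.numeric(fraction), fraction > 0, fraction < 1)
  n <- nrow(dataset$features)
  pick <- function(perm) {
    k <- floor(fraction * length(perm) + 0.5) # round half up
    if (k == 0L) return(integer(0))
    if (fraction >= 0.5) perm[seq_len(k)] else perm[seq.int(length(perm) - k + 1L, length(perm))]
  }
  train_idx <- with_rng_seed(seed, {
    if (stratified) {
      idx <- integer(0)
      for (cl in dataset$class_names) {
        rows <- which(dataset$labels == cl)
        if (length(rows) == 0L) next
        if (length(rows) < 2L) {
          stop("class '", cl, "' has a single sample; cannot stratify",
               call. = FALSE)
        }
        perm <- rows[sample.int(length(rows))]
        idx <- c(idx, pick(perm))
      }
      sort(idx)
    } else {
      sort(pick(sample.int(n)))
    }
  })
  test_idx <- setdiff(seq_len(n), train_idx)
  subset_ds <- function(rows) {
    gs_dataset(dataset$features[rows, , drop = FALSE], dataset$labels[rows],
               dataset$feature_names, dataset$class_names)
  }
  structure(
    list(train = subset_ds(train_idx), test = subset_ds(test_idx),
         fraction = fraction, seed = as.integer(seed),
         train_idx = train_idx, test_idx = test_idx),
    class = "gs_split"
  )
}

#' @export
print.gs_split <- function(x, ...) {
  cat("<gs_split> train ", nrow(x$train$features), " / test ",
      nrow(x$test$features), " (fraction ", x$fraction, ", seed ", x$seed,
      ")\n", sep = "")
  invisible(x)
}
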