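#' Feature tables
#'
#' A feature table is an ordinary tibble with one row per patient/sample and
#' a small set of reserved columns: `sample_id` (unique character keys),
#' `label` (a two-level factor; the *second* level is the positive/event
#' class), optionally `center` (acquisition center) and `.synthetic`
#' (`TRUE` for rows created by oversampling). Every other column is a numeric
#' feature. All preprocessing verbs in this package take such a tibble first
#' and return one, so calls chain with the pipe.
#'
#' @param x a data frame.
#' @param label_col name of the class-label column (renamed to `label`).
#' @param id_col name of the sample-id column (renamed to `sample_id`);
#'   `NULL` generates ids `S001, S002, ...`.
#' @param positive which label value is the positive (event) class; defaults
#'   to the rarer value.
#' @return A validated feature-table tibble.
#' @export
as_feature_table <- function(x, label_col = "label", id_col = "sample_id",
                             positive = NULL) {
  x <- as_tibble(x)
  if (!label_col %in% names(x)) {
    abort(paste0("label column '", label_col, "' not found"))
  }
  names(x)[names(x) == label_col] <- "label"
  if (is.null(id_col) || !id_col %in% names(x)) {
    x$sample_id <- sprintf("S%03d", seq_len(nrow(x)))
  } else {
    names(x)[names(x) == id_col] <- "sample_id"
  }
  x$sample_id <- as.character(x$sample_id)
  lev <- unique(as.character(x$label))
  if (length(lev) != 2) {
    abort(paste0("label must take exactly two values, got ", length(lev)))
  }
  if (is.null(positive)) {
    tab <- table(as.character(x$label))
    positive <- names(tab)[which.min(tab)]
  }
  lev <- c(setdiff(lex_order(lev), positive), positive)
  x$label <- factor(as.character(x$label), levels = lev)
  if (!".synthetic" %in% names(x)) x$.synthetic <- FALSE
  x <- dplyr::relocate(x, dplyr::any_of(RESERVED_COLS))
  check_feature_table(x)
  x
}

#' Validate a feature table
#'
#' @param x a feature-table tibble.
#' @param require_both_classes require both label classes non-empty.
#' @return `x`, invisibly; aborts with a precise report on violation.
#' @export
check_feature_table <- function(x, require_both_classes = TRUE) {
  if (!is.data.frame(x)) abort("feature table must be a data frame")
  for (col in c("sample_id", "label")) {
    if (!col %in% names(x)) abort(paste0("missing reserved column '", col, "'"))
  }
  if (anyDuplicated(x$sample_id)) {
    abort(paste0("duplicate sample_id: ",
                 paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", ")))
  }
  feats <- feature_names(x)
  if (anyDuplicated(feats)) abort("duplicate feature names")
  if (!is.factor(x$label) || nlevels(x$label) != 2) {
    abort("label must be a two-level factor (use as_feature_table())")
  }
  if (require_both_classes && any(table(x$label) == 0)) {
    abort("both label classes must be non-empty")
  }
  for (f in feats) {
    if (!is.numeric(x[[f]])) abort(paste0("feature '", f, "' is not numeric"))
  }
  miss <- which(is.na(as.matrix(x[feats])), arr.ind = TRUE)
  if (nrow(miss)) {
    abort(paste0("missing values not permitted: ",
                 paste(sprintf("row %s (%s), column %s",
                               miss[, 1], x$sample_id[miss[, 1]],
                               feats[miss[, 2]])[seq_len(min(5, nrow(miss)))],
                       collapse = "; "),
                 if (nrow(miss) > 5) sprintf(" ... and %d more", nrow(miss) - 5) else ""))
  }
  invisible(x)
}

#' Feature column names of a feature table
#' @param x a feature-table tibble.
#' @return Character vector of non-reserved column names.
#' @export
feature_names <- function(x) setdiff(names(x), RESERVED_COLS)

#' Numeric feature matrix of a feature table
#' @param x a feature-table tibble.
#' @param features optional subset of feature names.
#' @return Numeric matrix with `sample_id` rownames.
#' @export
feature_matrix <- function(x, features = NULL) {
  features <- features %||% feature_names(x)
  m <- as.matrix(x[features])
  rownames(m) <- x$sample_id
  storage.mode(m) <- "double"
  m
}

#' Positive (event) class of a feature table
#' @param x a feature-table tibble.
#' @return The label level treated as positive (the second factor level).
#' @export
positive_class <- function(x) levels(x$label)[2]

#' Read / write the cohort CSV dialect
#'
#' CSV with a header row; the first column is the sample id; `label` and
#' `center` are reserved; all other columns numeric features. Missing values
#' are rejected with a row/column report.
#'
#' @param path file path.
#' @param positive passed to [as_feature_table()].
#' @return A feature-table tibble.
#' @export
read_feature_table <- function(path, positive = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!ncol(x)) abort("empty file")
  names(x)[1] <- "sample_id"
  as_feature_table(x, positive = positive)
}

#' @rdname read_feature_table
#' @param x a feature-table tibble.
#' @export
write_feature_table <- function(x, path) {
  check_feature_table(x)
  out <- x
  out$label <- as.character(out$label)
  out$.synthetic <- NULL
  readr::write_csv(out, path)
  invisible(path)
}
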