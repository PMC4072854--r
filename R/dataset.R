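# ExpressionDataset container: objects x features matrix with optional
# timestamps (short time-series data: objects are genes, features are
# timepoints) and optional reference labels (cancer-style data: objects are
# samples). Objects are always rows.

#' Construct an expression dataset
#'
#' @param mat Numeric matrix, objects in rows, features in columns. Row and
#'   column names are used as object/feature ids (generated if absent).
#' @param timestamps Optional strictly increasing numeric vector, one value
#'   per feature (timepoint), for short time-series data.
#' @param labels Optional reference class labels, one per object (any atomic
#'   vector; stored as a factor).
#' @return An object of class `expr_dataset`.
#' @export
expression_dataset <- function(mat, timestamps = NULL, labels = NULL) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("'mat' must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(mat))) {
    stop("expression matrix contains missing or non-finite values; ",
         "missing values are not supported", call. = FALSE)
  }
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("obj%d", seq_len(nrow(mat)))
  }
  if (is.null(colnames(mat))) {
    colnames(mat) <- sprintf("f%d", seq_len(ncol(mat)))
  }
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat))) {
    stop("object and feature ids must be unique", call. = FALSE)
  }
  if (!is.null(timestamps)) {
    .check_timestamps(timestamps, ncol(mat))
  }
  if (!is.null(labels)) {
    if (length(labels) != nrow(mat)) {
      stop("'labels' must have one entry per object", call. = FALSE)
    }
    labels <- factor(labels)
    names(labels) <- rownames(mat)
  }
  structure(
    list(mat = mat, timestamps = timestamps, labels = labels),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("expression dataset: %d objects x %d features\n",
              nrow(x$mat), ncol(x$mat)))
  if (!is.null(x$timestamps)) {
    cat(sprintf("  timestamps: %s\n",
                paste(format(x$timestamps), collapse = ", ")))
  }
  if (!is.null(x$labels)) {
    cat(sprintf("  reference labels: %d classes\n", nlevels(x$labels)))
  }
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$mat)

#' Number of reference classes of a labelled dataset
#' @param data An `expr_dataset` with labels.
#' @return Integer number of classes.
#' @export
n_classes <- function(data) {
  stopifnot(inherits(data, "expr_dataset"))
  if (is.null(data$labels)) {
    stop("dataset has no reference labels", call. = FALSE)
  }
  nlevels(data$labels)
}

# ---- readers / writers ------------------------------------------------------

.fmt_num <- function(x) formatC(x, digits = 12, format = "g")

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of feature (or object) ids and a first column of row
#' ids. The orientation flag is mandatory because the two clustering
#' applications transpose the matrix: samples are the clustered objects for
#' cancer-style data, genes for time-series data.
#'
#' @param path Path to a TSV file.
#' @param orientation `"objects_in_rows"` or `"objects_in_columns"`.
#' @param timestamps,labels Optional; passed to [expression_dataset].
#' @return An `expr_dataset`.
#' @export
read_expression_tsv <- function(path,
                                orientation = c("objects_in_rows",
                                                "objects_in_columns"),
                                timestamps = NULL, labels = NULL) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, header = TRUE, row.names = 1,
                           check.names = FALSE, colClasses = "character")
  m <- as.matrix(raw)
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                 dimnames = dimnames(m)))
  bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]], path),
         call. = FALSE)
  }
  if (any(is.na(num))) {
    stop("expression file contains missing values; not supported",
         call. = FALSE)
  }
  if (orientation == "objects_in_columns") num <- t(num)
  expression_dataset(num, timestamps = timestamps, labels = labels)
}

#' Write an expression dataset as TSV (objects in rows)
#' @param data An `expr_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(data, path) {
  stopifnot(inherits(data, "expr_dataset"))
  m <- data$mat
  out <- cbind(id = rownames(m), apply(m, 2, .fmt_num))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read reference labels from a two-column TSV (object_id, class)
#' @param path Path to the file (header optional, autodetected by column
#'   count mismatch is not attempted: a header line `object_id<TAB>label`
#'   is skipped if present).
#' @return Named factor of labels.
#' @export
read_labels_tsv <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(tab) != 2) {
    stop("label file must have exactly two columns", call. = FALSE)
  }
  if (identical(tolower(tab[1, 1]), "object_id")) tab <- tab[-1, , drop = FALSE]
  if (anyDuplicated(tab[[1]])) {
    stop("duplicated object ids in label file", call. = FALSE)
  }
  stats::setNames(factor(tab[[2]]), tab[[1]])
}

#' Write labels / partitions as two-column TSV
#' @param labels Named vector (object_id -> cluster or class id).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(labels, path) {
  ids <- names(labels)
  if (is.null(ids)) ids <- sprintf("obj%d", seq_along(labels))
  utils::write.table(
    data.frame(object_id = ids, label = as.vector(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `term TAB description TAB gene1 TAB ...`.
#' Lines with no genes are skipped with a warning.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      warning(sprintf("skipping GMT line with no genes: '%s'",
                      substr(ln, 1, 40)), call. = FALSE)
      next
    }
    sets[[parts[1]]] <- parts[-(1:2)]
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicated term ids in GMT file", call. = FALSE)
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "synthetic") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
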