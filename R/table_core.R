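#' Construct a contingency table
#'
#' Dense non-negative integer counts over one or more categorical factors.
#' Cells are stored in row-major order over the factors in declared order:
#' the flat index of multi-index \eqn{(i_1, \dots, i_F)} is
#' \eqn{(((i_1 - 1) L_2 + i_2 - 1) L_3 + \dots) + i_F}. All flat indexing in
#' the package uses this single convention.
#'
#' @param counts numeric vector or array of non-negative integer counts. If a
#'   vector, `dims` must be given and `length(counts) == prod(dims)` (row-major
#'   cell order).
#' @param dims integer vector of per-factor level counts, each >= 2. Inferred
#'   from `dim(counts)` when `counts` is an array.
#' @param labels optional list of per-factor character vectors of level names.
#' @return An object of class `contingency_table` with elements `dims`,
#'   `counts` (flat, row-major), `n`, and `labels`.
#' @examples
#' ct <- contingency_table(c(933, 402, 51, 26, 661, 260, 44, 26), dims = c(2, 4))
#' ct$n
#' @export
contingency_table <- function(counts, dims = NULL, labels = NULL) {
  if (is.array(counts) && is.null(dims)) {
    # R arrays are column-major; convert to row-major flat order
    dims <- dim(counts)
    counts <- as.vector(aperm(counts, rev(seq_along(dims))))
  }
  if (is.null(dims)) stop("`dims` must be supplied when `counts` is a vector")
  dims <- as.integer(dims)
  if (any(dims < 2L)) stop("every factor must have at least 2 levels")
  counts <- as.numeric(counts)
  if (length(counts) != prod(dims)) {
    stop("length(counts) must equal prod(dims)")
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be non-negative integers")
  }
  counts <- round(counts)
  if (!is.null(labels)) {
    stopifnot(is.list(labels), length(labels) == length(dims))
    lens <- vapply(labels, length, integer(1))
    if (any(lens != dims)) stop("labels must match dims")
  }
  structure(
    list(dims = dims, counts = counts, n = sum(counts), labels = labels),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("Contingency table: ", paste(x$dims, collapse = " x "),
      "  (n = ", format(x$n), ")\n", sep = "")
  if (length(x$dims) == 2L) {
    m <- matrix(x$counts, nrow = x$dims[1], ncol = x$dims[2], byrow = TRUE)
    if (!is.null(x$labels)) dimnames(m) <- x$labels
    print(m)
  }
  invisible(x)
}

#' Flat cell index from a multi-index
#'
#' Row-major over factors in declared order.
#'
#' @param idx integer vector (or matrix, one multi-index per row) of 1-based
#'   level indices, one per factor.
#' @param dims per-factor level counts.
#' @return integer flat index (or vector of them).
#' @export
cell_index <- function(idx, dims) {
  if (is.matrix(idx)) return(apply(idx, 1L, cell_index, dims = dims))
  stopifnot(length(idx) == length(dims), all(idx >= 1L), all(idx <= dims))
  flat <- 0L
  for (f in seq_along(dims)) flat <- flat * dims[f] + (idx[f] - 1L)
  as.integer(flat + 1L)
}

#' Multi-index from a flat cell index
#'
#' @param flat 1-based flat index (row-major).
#' @param dims per-factor level counts.
#' @return integer vector of 1-based level indices.
#' @export
cell_multi_index <- function(flat, dims) {
  stopifnot(flat >= 1L, flat <= prod(dims))
  rem <- flat - 1L
  out <- integer(length(dims))
  for (f in rev(seq_along(dims))) {
    out[f] <- rem %% dims[f] + 1L
    rem <- rem %/% dims[f]
  }
  out
}

#' Multinomial maximum-likelihood cell probabilities
#'
#' The MLE of the cell-probability vector is `counts / n`, in cell order.
#'
#' @param table a [contingency_table].
#' @return An object of class `probability_vector`: `values` (probabilities in
#'   flat row-major cell order) and `dims`.
#' @examples
#' pi_hat <- mle_probabilities(load_fixture("degrees"))
#' @export
mle_probabilities <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  if (table$n <= 0) stop("table has n = 0: probabilities undefined")
  probability_vector(table$counts / table$n, table$dims)
}

#' Construct a probability vector over table cells
#'
#' @param values per-cell probabilities (flat row-major order); must lie in
#'   \[0, 1\] and sum to 1 within 1e-12 (small deviations from printed
#'   rounding can be repaired with `renormalize = TRUE`).
#' @param dims per-factor level counts.
#' @param renormalize divide by the sum before validating.
#' @return object of class `probability_vector`.
#' @export
probability_vector <- function(values, dims, renormalize = FALSE) {
  values <- as.numeric(values)
  dims <- as.integer(dims)
  if (length(values) != prod(dims)) stop("length(values) must equal prod(dims)")
  if (renormalize) values <- values / sum(values)
  if (any(values < -1e-12) || any(values > 1 + 1e-12)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (abs(sum(values) - 1) > 1e-12) stop("probabilities must sum to 1")
  structure(list(values = pmin(pmax(values, 0), 1), dims = dims),
            class = "probability_vector")
}

#' @export
print.probability_vector <- function(x, ...) {
  cat("Probability vector over a ", paste(x$dims, collapse = " x "),
      " table\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' Read a contingency table from a long-format CSV/TSV file
#'
#' One row per observed cell: one column per factor plus a count column.
#' Factor levels are taken in order of first appearance in the file (stable);
#' combinations absent from the file are filled with count 0.
#'
#' @param path file path; comma- or tab-separated (inferred from extension,
#'   override with `sep`).
#' @param factor_columns character vector of factor column names, in the
#'   declared factor order.
#' @param count_column name of the count column (default `"count"`).
#' @param sep field separator; `NULL` infers `"\t"` for `.tsv`, `","` otherwise.
#' @return a [contingency_table] with `labels` from the file's level values.
#' @export
from_long_csv <- function(path, factor_columns, count_column = "count",
                          sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c(factor_columns, count_column), names(df))
  if (length(missing_cols)) {
    stop("columns not found in file: ", paste(missing_cols, collapse = ", "))
  }
  cnt <- df[[count_column]]
  bad <- which(!is.finite(cnt) | cnt < 0 | abs(cnt - round(cnt)) > 1e-8)
  if (length(bad)) {
    stop("negative or non-integer count in row ", bad[1], " of ", path)
  }
  levels_by_factor <- lapply(factor_columns, function(fc) {
    unique(as.character(df[[fc]]))
  })
  dims <- vapply(levels_by_factor, length, integer(1))
  if (any(dims < 2L)) {
    stop("factor '", factor_columns[which(dims < 2L)[1]],
         "' has fewer than 2 levels")
  }
  idx <- vapply(seq_along(factor_columns), function(f) {
    match(as.character(df[[factor_columns[f]]]), levels_by_factor[[f]])
  }, integer(nrow(df)))
  if (nrow(df) == 1L) idx <- matrix(idx, nrow = 1L)
  flat <- apply(idx, 1L, cell_index, dims = dims)
  dup <- which(duplicated(flat))
  if (length(dup)) {
    stop("duplicate factor combination in row ", dup[1], " of ", path)
  }
  counts <- numeric(prod(dims))
  counts[flat] <- cnt
  names(levels_by_factor) <- factor_columns
  contingency_table(counts, dims = dims, labels = levels_by_factor)
}

#' Write a contingency table in long format
#'
#' Inverse of [from_long_csv()]: one row per cell (including zero cells), one
#' column per factor plus `"count"`.
#'
#' @param table a [contingency_table].
#' @param path output file path (`.tsv` writes tab-separated).
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(table, path) {
  stopifnot(inherits(table, "contingency_table"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  D <- prod(table$dims)
  mi <- t(vapply(seq_len(D), cell_multi_index, integer(length(table$dims)),
                 dims = table$dims))
  labs <- table$labels
  cols <- lapply(seq_along(table$dims), function(f) {
    if (is.null(labs)) mi[, f] else labs[[f]][mi[, f]]
  })
  names(cols) <- if (!is.null(labs) && !is.null(names(labs))) {
    names(labs)
  } else {
    paste0("factor", seq_along(table$dims))
  }
  df <- as.data.frame(cols, check.names = FALSE)
  df$count <- table$counts
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a probability vector with multi-index columns
#'
#' @param pi a [probability_vector].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_probabilities <- function(pi, path) {
  stopifnot(inherits(pi, "probability_vector"))
  D <- prod(pi$dims)
  mi <- t(vapply(seq_len(D), cell_multi_index, integer(length(pi$dims)),
                 dims = pi$dims))
  df <- as.data.frame(mi)
  names(df) <- paste0("level", seq_along(pi$dims))
  df$prob <- pi$values
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
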