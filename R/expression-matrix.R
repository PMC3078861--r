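#' ExpressionMatrix: features-by-samples expression with molecule kinds
#'
#' The central container of the package: a numeric matrix with features
#' (mRNAs and/or miRNAs) in rows and samples in columns, each row tagged
#' with its molecule kind and the scale its values are on. In the factor
#' model notation used throughout, the observed data matrix is
#' `D = t(values)` (samples x features): samples are the *variables* of the
#' factor analysis and features the *observations*.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param row_kinds character vector, one of `"mRNA"`/`"miRNA"` per row
#'   (recycled if length 1).
#' @param scale `"linear"` or `"log2"`; one per row (recycled if length 1).
#' @param row_ids,sample_ids identifiers; default to the dimnames of
#'   `values`, which must then be present.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (dimnamed matrix), `row_kinds`, `scale`.
#' @export
expression_matrix <- function(values, row_kinds, scale,
                              row_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(row_ids) && nrow(values) == 0) row_ids <- character(0)
  if (is.null(row_ids) || is.null(sample_ids))
    stop("row and sample identifiers are required (as dimnames or arguments)")
  row_ids <- as.character(row_ids)
  sample_ids <- as.character(sample_ids)
  if (length(row_ids) != nrow(values))
    stop("length(row_ids) != nrow(values)")
  if (length(sample_ids) != ncol(values))
    stop("length(sample_ids) != ncol(values)")
  if (anyDuplicated(row_ids))
    stop("duplicate row ids: ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  row_kinds <- match_kind(rep_len(row_kinds, nrow(values)))
  scale <- match_scale(rep_len(scale, nrow(values)))
  if (anyNA(values))
    stop("missing values in expression matrix; drop or reject them on load")
  dimnames(values) <- list(row_ids, sample_ids)
  structure(list(values = values, row_kinds = row_kinds, scale = scale),
            class = "ExpressionMatrix")
}

match_kind <- function(x) {
  if (!all(x %in% c("mRNA", "miRNA")))
    stop("row kind must be 'mRNA' or 'miRNA'")
  x
}

match_scale <- function(x) {
  if (!all(x %in% c("linear", "log2")))
    stop("scale must be 'linear' or 'log2'")
  x
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$row_kinds)
  cat("  kinds:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  scale:", paste(unique(x$scale), collapse = "/"), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Row identifiers of an ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @return character vector of feature ids.
#' @export
feature_ids <- function(x) rownames(x$values)

#' Sample identifiers of an ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an ExpressionMatrix by rows
#'
#' @param x an `ExpressionMatrix`.
#' @param i row index (logical, integer or character).
#' @return the subsetted `ExpressionMatrix`.
#' @export
subset_rows <- function(x, i) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (is.character(i)) i <- match(i, rownames(x$values))
  expression_matrix(x$values[i, , drop = FALSE],
                    row_kinds = x$row_kinds[i], scale = x$scale[i])
}
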