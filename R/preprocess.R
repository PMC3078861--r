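#' Log2-transform linear-scale rows
#'
#' Rows flagged `linear` are replaced by their base-2 logarithm; rows
#' already on the log2 scale (typically miRNA qPCR output) pass through
#' unchanged.
#'
#' @param mat an `ExpressionMatrix`.
#' @return the matrix with every row on the log2 scale.
#' @export
log2_transform <- function(mat) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  lin <- mat$scale == "linear"
  if (!any(lin)) return(mat)
  v <- mat$values[lin, , drop = FALSE]
  if (any(v <= 0)) {
    bad <- which(v <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive value in row '%s', sample '%s': cannot log2",
                 rownames(v)[bad[1]], colnames(v)[bad[2]]))
  }
  mat$values[lin, ] <- log2(v)
  mat$scale[lin] <- "log2"
  mat
}

#' Filter rows by maximum fold change
#'
#' Removes every row whose maximum fold change across samples is strictly
#' below `threshold` (a linear-scale ratio, default 2.5). On the log2 scale
#' this keeps rows with `max - min >= log2(threshold)`; a constant row has
#' fold change 1 and is always removed.
#'
#' @param mat an `ExpressionMatrix`, all rows on the log2 scale.
#' @param threshold linear-scale fold-change cutoff, > 1.
#' @return list with `matrix` (the kept rows, order preserved) and
#'   `removed` (count of dropped rows).
#' @export
max_fold_change_filter <- function(mat, threshold = 2.5) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (!all(mat$scale == "log2"))
    stop("fold-change filter expects log2-scale data; run log2_transform first")
  if (threshold <= 1) stop("fold-change threshold must exceed 1")
  rng <- apply(mat$values, 1, function(r) max(r) - min(r))
  keep <- rng >= log2(threshold)
  if (!any(keep)) warning("fold-change filter removed every row")
  list(matrix = subset_rows(mat, keep), removed = sum(!keep))
}

#' Row-wise normalization
#'
#' Two affine per-row rescalings of a log2 expression matrix:
#' * `unit_interval`: `y_ij = (x_ij - m_i) / (M_i - m_i)`, mapping each row
#'   onto \[0, 1\];
#' * `mean_anchored`: `y_ij = mu_i + (x_ij - m_i) / (M_i - m_i)`, mapping
#'   each row onto \[mu_i, mu_i + 1\] so between-row expression-level
#'   differences stay in the model.
#'
#' Here `M_i`, `m_i` and `mu_i` are the row maximum, minimum and mean. The
#' two outputs differ per row by the constant `mu_i`.
#'
#' @param mat an `ExpressionMatrix` with no constant rows.
#' @param mode `"unit_interval"` or `"mean_anchored"`.
#' @return the normalized `ExpressionMatrix`.
#' @export
normalize_rows <- function(mat, mode = c("unit_interval", "mean_anchored")) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  mode <- match.arg(mode)
  v <- mat$values
  M <- apply(v, 1, max)
  m <- apply(v, 1, min)
  if (any(M == m))
    stop("constant row(s) (",
         paste(utils::head(rownames(v)[M == m], 5), collapse = ", "),
         "): apply the fold-change filter first")
  y <- (v - m) / (M - m)
  if (mode == "mean_anchored") y <- y + rowMeans(v)
  mat$values <- y
  mat
}

#' Stack mRNA and miRNA matrices into one joint expression table
#'
#' Concatenates the rows of the two matrices over a shared sample set; the
#' miRNA columns are reordered to the mRNA sample order if permuted.
#'
#' @param mrna,mirna `ExpressionMatrix` objects on the same samples.
#' @return the joint `ExpressionMatrix` (mRNA rows first), kind tags
#'   preserved.
#' @export
stack_joint_matrix <- function(mrna, mirna) {
  stopifnot(inherits(mrna, "ExpressionMatrix"),
            inherits(mirna, "ExpressionMatrix"))
  s1 <- sample_ids(mrna); s2 <- sample_ids(mirna)
  if (!setequal(s1, s2))
    stop("sample sets differ; only in mRNA: ",
         paste(setdiff(s1, s2), collapse = ", "),
         "; only in miRNA: ", paste(setdiff(s2, s1), collapse = ", "))
  mirna_v <- mirna$values[, s1, drop = FALSE]
  common <- intersect(rownames(mrna$values), rownames(mirna_v))
  if (length(common))
    stop("feature id(s) present in both matrices: ",
         paste(utils::head(common, 5), collapse = ", "))
  expression_matrix(rbind(mrna$values, mirna_v),
                    row_kinds = c(mrna$row_kinds, mirna$row_kinds),
                    scale = c(mrna$scale, mirna$scale))
}

#' Full preprocessing chain
#'
#' log2-transforms the mRNA matrix, stacks it with the (already log2)
#' miRNA matrix, applies the maximum-fold-change filter and normalizes
#' rows. This is the canonical order: filtering precedes normalization so
#' constant rows never reach the division by the row range.
#'
#' @param mrna linear-scale mRNA `ExpressionMatrix`.
#' @param mirna log2-scale miRNA `ExpressionMatrix`.
#' @param fold_change linear fold-change cutoff (default 2.5).
#' @param mode normalization mode passed to [normalize_rows()], or
#'   `"none"` to keep the filtered log2 values (for data already on a
#'   common analysis scale, e.g. the synthetic generator's output).
#' @return list with `matrix` (the joint normalized `ExpressionMatrix`) and
#'   `log`, a data.frame of row counts per stage.
#' @export
preprocess_pipeline <- function(mrna, mirna, fold_change = 2.5,
                                mode = c("unit_interval", "mean_anchored",
                                         "none")) {
  mode <- match.arg(mode)
  joint <- stack_joint_matrix(log2_transform(mrna), mirna)
  n_in <- nrow(joint$values)
  filt <- max_fold_change_filter(joint, fold_change)
  out <- if (mode == "none") filt$matrix else normalize_rows(filt$matrix, mode)
  list(matrix = out,
       log = data.frame(stage = c("input", "fold_change_filter", "normalized"),
                        rows = c(n_in, n_in - filt$removed,
                                 nrow(out$values))))
}
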