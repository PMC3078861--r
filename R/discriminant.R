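#' Construct a 2x2 confusion table
#'
#' Rows are the true class and its complement, columns the predicted class
#' and its complement: `a` = true positives, `b` = false negatives,
#' `c` = false positives, `d` = true negatives.
#'
#' @param a,b,c,d non-negative integer counts.
#' @param class_name optional contrast label.
#' @param factor_subset optional integer vector of the factors used.
#' @return a `ConfusionTable`.
#' @export
confusion_table <- function(a, b, c, d, class_name = NA_character_,
                            factor_subset = integer(0)) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  structure(list(a = a, b = b, c = c, d = d, class_name = class_name,
                 factor_subset = factor_subset),
            class = "ConfusionTable")
}

#' @export
print.ConfusionTable <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("class", "complement"),
                              c("pred class", "pred complement")))
  if (!is.na(x$class_name)) cat("Contrast:", x$class_name, "\n")
  print(m)
  invisible(x)
}

as_matrix2 <- function(t) matrix(c(t$a, t$c, t$b, t$d), 2, 2)

#' Classification accuracy of a confusion table
#'
#' @param t a `ConfusionTable`.
#' @return `(a + d) / (a + b + c + d)`.
#' @export
accuracy <- function(t) {
  n <- t$a + t$b + t$c + t$d
  if (n == 0) stop("empty confusion table")
  (t$a + t$d) / n
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by full enumeration over all tables with the
#' observed margins: the p-value is the sum of the point hypergeometric
#' probabilities of every table whose probability does not exceed that of
#' the observed table (with a 1e-7 relative tolerance on the comparison,
#' the convention of `fisher.test`). Degenerate margins give p = 1.
#'
#' @param t a `ConfusionTable` (or 2x2 matrix).
#' @return the exact p-value.
#' @export
fisher_exact_two_sided <- function(t) {
  m <- if (inherits(t, "ConfusionTable")) as_matrix2(t) else t
  stopifnot(all(dim(m) == 2), all(m >= 0))
  r1 <- m[1, 1] + m[1, 2]
  r2 <- m[2, 1] + m[2, 2]
  c1 <- m[1, 1] + m[2, 1]
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  a_all <- lo:hi
  logp <- lchoose(r1, a_all) + lchoose(r2, c1 - a_all) - lchoose(n, c1)
  p_obs <- logp[a_all == m[1, 1]]
  sum(exp(logp[logp <= p_obs + log(1 + 1e-7)]))
}

# Two-class LDA with pooled covariance. Priors proportional to training
# class frequencies. Ridge fallback (1e-8 on the diagonal) when the pooled
# covariance is computationally singular.
lda_train <- function(X, y, ridge = 1e-8) {
  X <- as.matrix(X)
  n1 <- sum(y); n0 <- sum(!y)
  stopifnot(n1 >= 1, n0 >= 1)
  mu1 <- colMeans(X[y, , drop = FALSE])
  mu0 <- colMeans(X[!y, , drop = FALSE])
  ctr <- X
  ctr[y, ] <- sweep(X[y, , drop = FALSE], 2, mu1)
  ctr[!y, ] <- sweep(X[!y, , drop = FALSE], 2, mu0)
  S <- crossprod(ctr) / (n1 + n0 - 2)
  Sinv <- tryCatch(solve(S), error = function(e) {
    warning("singular pooled covariance; ridge regularization applied")
    solve(S + diag(ridge, ncol(S)))
  })
  list(mu1 = mu1, mu0 = mu0, Sinv = Sinv,
       log_prior1 = log(n1 / (n1 + n0)), log_prior0 = log(n0 / (n1 + n0)))
}

lda_predict <- function(fit, x) {
  x <- as.numeric(x)
  d1 <- fit$log_prior1 -
    0.5 * drop(t(x - fit$mu1) %*% fit$Sinv %*% (x - fit$mu1))
  d0 <- fit$log_prior0 -
    0.5 * drop(t(x - fit$mu0) %*% fit$Sinv %*% (x - fit$mu0))
  d1 > d0
}

#' Leave-one-out LDA confusion table
#'
#' Jack-knife classification: each sample is predicted by a two-class
#' linear discriminant (pooled covariance, priors proportional to
#' training-fold class frequencies) trained on the remaining samples, using
#' the selected factor columns of the loading matrix; the hits and misses
#' are aggregated into a 2x2 confusion table.
#'
#' @param L samples x l loading matrix.
#' @param labels logical vector (TRUE = class member), length `nrow(L)`.
#' @param subset integer vector of factor columns to use (default: all).
#' @param class_name carried into the returned table.
#' @return a `ConfusionTable`.
#' @export
loo_lda_confusion <- function(L, labels, subset = seq_len(ncol(L)),
                              class_name = NA_character_) {
  L <- as.matrix(L)
  labels <- as.logical(labels)
  stopifnot(length(labels) == nrow(L))
  if (sum(labels) < 2 || sum(!labels) < 2)
    stop("class '", if (sum(labels) < 2) "member" else "complement",
         "' has fewer than 2 samples: leave-one-out LDA is not estimable")
  X <- L[, subset, drop = FALSE]
  pred <- logical(nrow(X))
  for (i in seq_len(nrow(X))) {
    fit <- lda_train(X[-i, , drop = FALSE], labels[-i])
    pred[i] <- lda_predict(fit, X[i, ])
  }
  confusion_table(a = sum(labels & pred), b = sum(labels & !pred),
                  c = sum(!labels & pred), d = sum(!labels & !pred),
                  class_name = class_name, factor_subset = as.integer(subset))
}

# Ranking used throughout the search: higher accuracy first, then lower
# Fisher p, then smaller subset, then lexicographic subset order.
better_than <- function(acc1, p1, sub1, acc2, p2, sub2) {
  if (acc1 != acc2) return(acc1 > acc2)
  if (p1 != p2) return(p1 < p2)
  if (length(sub1) != length(sub2)) return(length(sub1) < length(sub2))
  paste(sub1, collapse = ",") < paste(sub2, collapse = ",")
}

#' Step-wise greedy factor-subset search
#'
#' Evaluates every single factor by leave-one-out LDA, keeps the best
#' (accuracy, then lower Fisher p), then iteratively adds the factor giving
#' the largest accuracy improvement, stopping when no addition improves
#' accuracy. Ties always favour fewer factors, then lower p, then
#' lexicographic order. With `exhaustive = TRUE` all `2^l - 1` subsets are
#' scored instead (practical for the l <= 5 models used here) — useful to
#' audit the greedy result.
#'
#' @param L samples x l loading matrix.
#' @param labels logical dichotomy labels.
#' @param class_name carried into the confusion table.
#' @param exhaustive score all subsets instead of the greedy path.
#' @return list with `subset`, `table` (a `ConfusionTable`), `accuracy`,
#'   `p_value`.
#' @export
greedy_factor_search <- function(L, labels, class_name = NA_character_,
                                 exhaustive = FALSE) {
  l <- ncol(L)
  evaluate <- function(subset) {
    t <- loo_lda_confusion(L, labels, subset, class_name)
    list(subset = subset, table = t, accuracy = accuracy(t),
         p_value = fisher_exact_two_sided(t))
  }
  if (exhaustive) {
    best <- NULL
    for (size in seq_len(l)) {
      for (subset in utils::combn(l, size, simplify = FALSE)) {
        cand <- evaluate(subset)
        if (is.null(best) ||
            better_than(cand$accuracy, cand$p_value, cand$subset,
                        best$accuracy, best$p_value, best$subset))
          best <- cand
      }
    }
    return(best)
  }
  singles <- lapply(seq_len(l), function(k) evaluate(k))
  best <- singles[[1]]
  for (cand in singles[-1])
    if (better_than(cand$accuracy, cand$p_value, cand$subset,
                    best$accuracy, best$p_value, best$subset))
      best <- cand
  repeat {
    remaining <- setdiff(seq_len(l), best$subset)
    if (!length(remaining)) break
    step_best <- NULL
    for (k in remaining) {
      cand <- evaluate(sort(c(best$subset, k)))
      if (is.null(step_best) ||
          better_than(cand$accuracy, cand$p_value, cand$subset,
                      step_best$accuracy, step_best$p_value, step_best$subset))
        step_best <- cand
    }
    if (step_best$accuracy > best$accuracy) best <- step_best else break
  }
  best
}

#' Select the factor model by discriminant performance
#'
#' Runs the factor-subset search for every candidate model and every
#' dichotomous contrast, drops models for which no contrast reaches Fisher
#' p < `alpha`, and among the retained models chooses by (number of
#' significant contrasts, summed accuracy), resolving ties in favour of the
#' model with fewer factors — so a larger model that merely matches a
#' smaller one is never chosen.
#'
#' @param models list of `FactorModel` objects (e.g. for l = 1..5).
#' @param meta a `SampleMetadata`, or a named list of logical label
#'   vectors.
#' @param alpha significance level for the Fisher test (default 0.05).
#' @param exhaustive passed to [greedy_factor_search()].
#' @return a `ModelSelectionReport`: list with `table` (one row per model x
#'   contrast), `retained` (logical per model), `chosen` (index into
#'   `models`, or NA if every model was rejected).
#' @export
select_model <- function(models, meta, alpha = 0.05, exhaustive = FALSE) {
  stopifnot(length(models) >= 1)
  samples <- rownames(models[[1]]$loadings)
  dich <- if (inherits(meta, "SampleMetadata"))
    dichotomies(meta, samples) else meta
  if (!length(dich)) stop("no valid dichotomy available")
  rows <- list()
  profile <- list()
  for (mi in seq_along(models)) {
    model <- models[[mi]]
    res <- lapply(names(dich), function(nm)
      greedy_factor_search(model$loadings, dich[[nm]], class_name = nm,
                           exhaustive = exhaustive))
    names(res) <- names(dich)
    for (nm in names(dich))
      rows[[length(rows) + 1L]] <- data.frame(
        model = mi, n_factors = model$n_factors, contrast = nm,
        subset = paste(res[[nm]]$subset, collapse = "+"),
        accuracy = res[[nm]]$accuracy, p_value = res[[nm]]$p_value,
        significant = res[[nm]]$p_value < alpha)
    profile[[mi]] <- res
  }
  tab <- do.call(rbind, rows)
  retained <- vapply(seq_along(models), function(mi)
    any(tab$significant[tab$model == mi]), logical(1))
  chosen <- NA_integer_
  if (any(retained)) {
    n_sig <- vapply(seq_along(models), function(mi)
      sum(tab$significant[tab$model == mi]), numeric(1))
    acc_sum <- vapply(seq_along(models), function(mi)
      sum(tab$accuracy[tab$model == mi]), numeric(1))
    nf <- vapply(models, function(m) m$n_factors, numeric(1))
    ord <- order(-n_sig, -acc_sum, nf)
    ord <- ord[retained[ord]]
    chosen <- ord[1]
  } else {
    warning("no model reaches significance on any contrast; chosen = none")
  }
  structure(list(table = tab, retained = retained, chosen = chosen,
                 details = profile),
            class = "ModelSelectionReport")
}

#' @export
print.ModelSelectionReport <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("chosen model:",
      if (is.na(x$chosen)) "none" else
        sprintf("#%d (%d factors)", x$chosen,
                x$table$n_factors[x$table$model == x$chosen][1]), "\n")
  invisible(x)
}
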