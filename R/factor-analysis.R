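#' Sample-sample correlation matrix
#'
#' Pearson correlation between sample columns computed across features. In
#' this package's orientation samples are the variables of the factor model
#' (loadings are per sample) and features the observations, so the
#' correlation matrix is m x m for m samples.
#'
#' @param joint an `ExpressionMatrix` (or plain features-x-samples matrix)
#'   with at least 3 feature rows.
#' @return symmetric m x m correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(joint) {
  v <- if (inherits(joint, "ExpressionMatrix")) joint$values else joint
  if (nrow(v) < 3) stop("need >= 3 features to estimate sample correlations")
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0))
    stop("constant sample column(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  R <- stats::cor(v)
  diag(R) <- 1
  (R + t(R)) / 2
}

#' Principal-axes factor extraction
#'
#' Fits the common factor model `R ~ L L' + Psi` by iterated principal
#' axes: communalities are initialized from squared multiple correlations
#' (`1 - 1/solve(R)[i,i]`), placed on the diagonal of `R`, and updated from
#' the eigendecomposition of the reduced matrix until the largest
#' communality change falls below `tol`. Loadings are the top-`l`
#' eigenvectors scaled by the square roots of their (positive) eigenvalues.
#' Heywood cases are clipped into \[0, 1\] and counted.
#'
#' @param R symmetric correlation matrix with unit diagonal.
#' @param l number of factors, `1 <= l < nrow(R)`.
#' @param tol convergence tolerance on communalities (default 1e-6).
#' @param max_iter iteration cap (default 100); non-convergence yields a
#'   warning and `converged = FALSE`, not an error.
#' @return a `FactorModel` (see [factor_model()]) with unrotated loadings.
#' @export
principal_axes_fa <- function(R, l, tol = 1e-6, max_iter = 100) {
  m <- nrow(R)
  stopifnot(isTRUE(all.equal(R, t(R), tolerance = 1e-8)),
            max(abs(diag(R) - 1)) < 1e-8)
  if (l < 1 || l >= m) stop("factor count must satisfy 1 <= l < m")
  eig_full <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  h2 <- tryCatch(pmin(pmax(1 - 1 / diag(solve(R)), 0), 1),
                 error = function(e) {
                   warning("singular correlation matrix; SMC initialization ",
                           "replaced by 1 - 1/diag")
                   pmin(pmax(1 - 1 / diag(R), 0), 1)
                 })
  converged <- FALSE
  clipped <- 0L
  iter <- 0L
  L <- NULL
  for (iter in seq_len(max_iter)) {
    Rh <- R
    diag(Rh) <- h2
    e <- eigen(Rh, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(l)], 0)
    L <- e$vectors[, seq_len(l), drop = FALSE] %*% diag(sqrt(ev), l)
    h2_new <- rowSums(L^2)
    out_of_range <- h2_new < 0 | h2_new > 1
    clipped <- clipped + sum(out_of_range)
    h2_new <- pmin(pmax(h2_new, 0), 1)
    delta <- max(abs(h2_new - h2))
    h2 <- h2_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("principal axes did not converge in ", max_iter, " iterations")
  rownames(L) <- rownames(R)
  factor_model(loadings = fix_loading_signs(L), communalities = h2,
               eigenvalues = eig_full, rotation = "none",
               factor_correlation = diag(l), converged = converged,
               iterations = iter, heywood_clips = clipped)
}

#' Construct a FactorModel container
#'
#' @param loadings samples x l loading matrix `L`.
#' @param communalities per-sample common variance, in \[0, 1\].
#' @param eigenvalues eigenvalues of the full correlation matrix,
#'   descending.
#' @param rotation one of `"none"`, `"varimax"`, `"promax"`.
#' @param factor_correlation l x l factor correlation (identity unless the
#'   rotation is oblique).
#' @param scores optional l x genes score matrix.
#' @param converged,iterations,heywood_clips extraction diagnostics.
#' @return an object of class `FactorModel`.
#' @export
factor_model <- function(loadings, communalities, eigenvalues,
                         rotation = "none",
                         factor_correlation = diag(ncol(loadings)),
                         scores = NULL, converged = TRUE, iterations = 0L,
                         heywood_clips = 0L) {
  l <- ncol(loadings)
  stopifnot(nrow(factor_correlation) == l)
  structure(list(n_factors = l, loadings = loadings,
                 communalities = communalities,
                 uniqueness = 1 - communalities,
                 eigenvalues = eigenvalues, rotation = rotation,
                 factor_correlation = factor_correlation, scores = scores,
                 converged = converged, iterations = iterations,
                 heywood_clips = heywood_clips),
            class = "FactorModel")
}

#' @export
print.FactorModel <- function(x, ...) {
  cat(sprintf("FactorModel: %d factor(s), %d samples, rotation=%s%s\n",
              x$n_factors, nrow(x$loadings), x$rotation,
              if (x$converged) "" else " (NOT converged)"))
  if (!is.null(x$scores))
    cat(sprintf("  scores: %d x %d\n", nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

# Deterministic sign convention: flip each loading column so that its
# largest-magnitude entry is positive.
fix_loading_signs <- function(L) {
  s <- apply(L, 2, function(col) sign(col[which.max(abs(col))]))
  s[s == 0] <- 1
  sweep(L, 2, s, `*`)
}

#' Kaiser criterion factor count
#'
#' Counts eigenvalues of the (unreduced) correlation matrix strictly
#' greater than the threshold `t`.
#'
#' @param eigenvalues eigenvalues sorted in descending order.
#' @param t variance threshold (default 1).
#' @return integer count (possibly 0; callers floor at 1 factor).
#' @export
kaiser_count <- function(eigenvalues, t = 1) {
  if (is.unsorted(rev(eigenvalues))) stop("eigenvalues must be descending")
  sum(eigenvalues > t)
}

#' Promax oblique rotation
#'
#' Varimax (with Kaiser row normalization) followed by an oblique
#' least-squares fit to the powered target `sign(A) * |A|^power`, with the
#' transformation columns rescaled so the implied factor correlation matrix
#' has unit diagonal. With a single factor the rotation is the identity.
#' The column span of the loadings is preserved.
#'
#' @param L unrotated loading matrix (samples x l).
#' @param power target exponent (conventional default 4).
#' @return list with `loadings` (pattern matrix, signs fixed),
#'   `factor_correlation` (Phi), and `rotmat`.
#' @export
promax_rotate <- function(L, power = 4) {
  l <- ncol(L)
  if (qr(L)$rank < l) stop("rank-deficient loadings: reduce the factor count")
  if (l == 1)
    return(list(loadings = fix_loading_signs(L),
                factor_correlation = matrix(1, 1, 1),
                rotmat = matrix(1, 1, 1)))
  vm <- stats::varimax(L, normalize = TRUE)
  A <- L %*% vm$rotmat
  P <- sign(A) * abs(A)^power
  Q <- solve(crossprod(A), crossprod(A, P))        # LS fit A Q ~ P
  d <- diag(solve(crossprod(Q)))
  Q <- Q %*% diag(sqrt(d), l)                       # unit-diagonal Phi
  Lr <- A %*% Q
  Phi <- solve(crossprod(Q))
  # sign convention on the pattern, mirrored into Phi
  s <- apply(Lr, 2, function(col) sign(col[which.max(abs(col))]))
  s[s == 0] <- 1
  Lr <- sweep(Lr, 2, s, `*`)
  Phi <- diag(s, l) %*% Phi %*% diag(s, l)
  Phi <- (Phi + t(Phi)) / 2
  diag(Phi) <- 1
  dimnames(Lr) <- dimnames(L)
  list(loadings = Lr, factor_correlation = Phi,
       rotmat = vm$rotmat %*% Q %*% diag(s, l))
}

#' Regression (Thomson) factor scores
#'
#' Scores each feature (gene) on every factor via the regression estimator:
#' the data are standardized per sample (the model's variables), and the
#' score weights are `W = R^-1 S` where `S = L Phi` is the structure
#' matrix. Scores are l x genes; each factor's scores average ~0 over
#' genes.
#'
#' @param joint the `ExpressionMatrix` the model was fitted on.
#' @param model a `FactorModel` (rotated or not).
#' @param R the sample correlation matrix used in fitting.
#' @return l x genes score matrix.
#' @export
regression_scores <- function(joint, model, R) {
  v <- if (inherits(joint, "ExpressionMatrix")) joint$values else joint
  stopifnot(ncol(v) == nrow(model$loadings))
  S <- model$loadings %*% model$factor_correlation
  W <- tryCatch(solve(R, S), error = function(e) {
    warning("singular correlation matrix in score estimation; ",
            "ridge fallback applied")
    solve(R + diag(1e-8, nrow(R)), S)
  })
  Z <- scale(v)                                     # per-sample standardize
  F <- t(Z %*% W)                                   # l x genes
  rownames(F) <- paste0("F", seq_len(model$n_factors))
  colnames(F) <- rownames(v)
  F
}

#' Select factor-associated genes by the two-sigma rule
#'
#' Per factor, the mean and standard deviation of the scores over all genes
#' define a band `mu +/- multiplier * sigma`; genes outside it are selected
#' and split by sign into a positive and a negative set.
#'
#' @param F l x genes score matrix.
#' @param multiplier band half-width in standard deviations (default 2).
#' @return list of `FactorGeneSet` objects, one per factor, each with
#'   `factor`, `positive_set`, `negative_set` (named numeric score
#'   vectors), `score_mean`, `score_sd`, `multiplier`.
#' @export
select_factor_genes <- function(F, multiplier = 2) {
  stopifnot(is.matrix(F), all(is.finite(F)))
  lapply(seq_len(nrow(F)), function(k) {
    s <- F[k, ]
    mu <- mean(s)
    sg <- stats::sd(s)
    if (sg == 0) {
      warning("factor ", k, " has zero score dispersion; nothing selected")
      pos <- neg <- s[0]
    } else {
      pos <- s[s > mu + multiplier * sg]
      neg <- s[s < mu - multiplier * sg]
    }
    structure(list(factor = k, positive_set = pos, negative_set = neg,
                   score_mean = mu, score_sd = sg, multiplier = multiplier),
              class = "FactorGeneSet")
  })
}

#' @export
print.FactorGeneSet <- function(x, ...) {
  cat(sprintf("FactorGeneSet F%d: %d positive, %d negative (mu=%.3g, sd=%.3g)\n",
              x$factor, length(x$positive_set), length(x$negative_set),
              x$score_mean, x$score_sd))
  invisible(x)
}

#' Fit the full factor model to a joint expression matrix
#'
#' Convenience wrapper: sample correlations, principal-axes extraction,
#' Promax rotation (identity when `l = 1`), regression scores, and the
#' Thurstone-style simple-structure diagnostic (counts of near-zero pattern
#' loadings, reported, not gated on).
#'
#' @param joint preprocessed joint `ExpressionMatrix`.
#' @param l number of factors; `"auto"` applies the Kaiser criterion with
#'   threshold `kaiser_t` (floored at 1).
#' @param rotation `"promax"` (default), `"varimax"` or `"none"`.
#' @param kaiser_t Kaiser threshold when `l = "auto"`.
#' @param promax_power target exponent for Promax.
#' @param tol,max_iter passed to [principal_axes_fa()].
#' @return a `FactorModel` with rotated loadings and scores attached.
#' @export
fit_factor_model <- function(joint, l = "auto", rotation = c("promax",
                             "varimax", "none"), kaiser_t = 1,
                             promax_power = 4, tol = 1e-6, max_iter = 100) {
  rotation <- match.arg(rotation)
  R <- sample_correlation(joint)
  if (identical(l, "auto")) {
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    l <- kaiser_count(ev, kaiser_t)
    if (l < 1) {
      warning("no eigenvalue above the Kaiser threshold; using 1 factor")
      l <- 1
    }
  }
  model <- principal_axes_fa(R, l, tol = tol, max_iter = max_iter)
  if (rotation == "promax" && l >= 1) {
    rot <- promax_rotate(model$loadings, power = promax_power)
    model$loadings <- rot$loadings
    model$factor_correlation <- rot$factor_correlation
    model$rotation <- "promax"
  } else if (rotation == "varimax" && l > 1) {
    vm <- stats::varimax(model$loadings, normalize = TRUE)
    model$loadings <- fix_loading_signs(model$loadings %*% vm$rotmat)
    model$rotation <- "varimax"
  }
  model$scores <- regression_scores(joint, model, R)
  model$simple_structure <- simple_structure_diagnostic(model$loadings)
  model$correlation <- R
  model
}

# Descriptive Thurstone-style diagnostic: near-zero loadings per row/column.
simple_structure_diagnostic <- function(L, eps = 0.1) {
  list(near_zero_per_sample = rowSums(abs(L) < eps),
       near_zero_per_factor = colSums(abs(L) < eps))
}
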