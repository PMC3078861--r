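#' Specification for a synthetic joint expression dataset
#'
#' Describes the world the generator emulates: a small cohort profiled for
#' mRNA (microarray, linear intensities) and miRNA (qPCR, log2) with a
#' low-rank latent-factor structure, class-separating sample loadings,
#' heavy-tailed gene scores, and blocks of miRNAs co-located in genomic
#' clusters that co-load on one factor (mimicking polycistronic
#' transcription). Defaults mirror the brain-tumor cohort the package's
#' methodology was developed on: 12 samples, 4,966 mRNAs, 93 miRNAs, 3
#' informative factors, score sd 0.75.
#'
#' @param n_samples number of samples.
#' @param n_mrna,n_mirna feature counts per molecule kind.
#' @param n_factors number of planted factors.
#' @param class_design data.frame with columns `contrast` (one of grade /
#'   anaplastic / glioblastoma / gliosarcoma), `factor`, `effect` (loading
#'   offset between the class and its complement, in loading units).
#' @param histotypes histotype assignment per sample (recycled counts must
#'   total `n_samples`).
#' @param n_signal signal genes per factor (split evenly between tails).
#' @param score_sd background score standard deviation.
#' @param signal_range planted |score| range for signal genes, in units of
#'   `score_sd`.
#' @param clusters data.frame with columns `name`, `size`, `factor`, `sign`
#'   (+1/-1 tail); members are drawn from the miRNA rows.
#' @param loading_sd baseline spread of sample loadings around class
#'   centres.
#' @param noise_sd standard deviation of the unique-factor (noise) term.
#' @param baseline_mean,baseline_sd per-gene baseline log2 expression.
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return a `SyntheticSpec` list.
#' @export
synthetic_spec <- function(n_samples = 12, n_mrna = 4966, n_mirna = 93,
                           n_factors = 3,
                           class_design = data.frame(
                             contrast = c("glioblastoma", "anaplastic",
                                          "gliosarcoma"),
                             factor = c(1L, 2L, 3L),
                             effect = c(3, 3, 3)),
                           histotypes = c(anaplastic = 2, glioblastoma = 6,
                                          gliosarcoma = 3,
                                          oligodendroglioma = 1),
                           n_signal = 40, score_sd = 0.75,
                           signal_range = c(3, 5),
                           clusters = data.frame(
                             name = c("mir-17-92-like", "mir-106-363-like"),
                             size = c(4L, 3L),
                             factor = c(3L, 3L),
                             sign = c(1, 1)),
                           loading_sd = 0.3, noise_sd = 0.1,
                           baseline_mean = 8, baseline_sd = 0.25,
                           seed = 1) {
  stopifnot(n_samples >= 4, n_mrna >= 1, n_mirna >= 1,
            n_factors >= 0, n_signal >= 1,
            sum(histotypes) == n_samples,
            all(class_design$factor <= max(n_factors, 1)),
            all(clusters$factor <= max(n_factors, 1)),
            sum(clusters$size) <= n_mirna,
            n_signal * n_factors <= n_mrna + n_mirna)
  structure(as.list(environment()), class = "SyntheticSpec")
}

#' Pure-noise variant of a synthetic spec
#'
#' Zero planted factors, no class-separating structure and no clusters:
#' expression is baseline plus i.i.d. noise. Used for null calibration of
#' the model-selection procedure.
#'
#' @param seed RNG seed.
#' @param n_mrna,n_mirna feature counts (defaults scaled down for speed).
#' @param noise_sd noise standard deviation (default 1: all variance is
#'   noise).
#' @return a `SyntheticSpec`.
#' @export
noise_spec <- function(seed = 1, n_mrna = 1000, n_mirna = 93,
                       noise_sd = 1) {
  sp <- synthetic_spec(n_mrna = n_mrna, n_mirna = n_mirna, seed = seed,
                       noise_sd = noise_sd)
  sp$n_factors <- 0L
  sp$class_design <- sp$class_design[0, ]
  sp$clusters <- sp$clusters[0, ]
  sp
}

#' Generate a synthetic joint dataset with known ground truth
#'
#' Draws the common factor model generatively: `D = L F + E` with
#' `E ~ N(0, noise_sd^2)` i.i.d., then adds a per-gene baseline so the
#' values look like log2 expression. Sample loadings are Gaussian around
#' class centres so each designed contrast is separated by its designated
#' factor with the stated effect size. Gene scores are background normal
#' (sd `score_sd`) on every factor; each factor additionally receives
#' `n_signal` dedicated signal genes whose |score| on that factor lies in
#' `signal_range * score_sd` (attenuated on the other factors), and the
#' planted genomic-cluster miRNAs receive near-identical scores in the
#' designated tail of their factor, mimicking polycistronic
#' co-transcription.
#'
#' @param spec a [synthetic_spec()].
#' @return a `SyntheticDataset`: list with `mrna` (linear-scale
#'   `ExpressionMatrix`), `mirna` (log2), `metadata` (`SampleMetadata`),
#'   `clusters` (list of `GenomicCluster`), and `truth` (planted
#'   `loadings`, `scores`, `signal_ids` per factor, `cluster_factor`,
#'   `spec`).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  m <- spec$n_samples
  n <- spec$n_mrna + spec$n_mirna
  l <- spec$n_factors
  ids <- c(sprintf("gene_%04d", seq_len(spec$n_mrna)),
           sprintf("mir_%03d", seq_len(spec$n_mirna)))
  kinds <- rep(c("mRNA", "miRNA"), c(spec$n_mrna, spec$n_mirna))
  sample_names <- sprintf("S%02d", seq_len(m))

  histo <- rep(names(spec$histotypes), spec$histotypes)
  meta <- sample_metadata(data.frame(
    sample_id = sample_names,
    grade = ifelse(histo %in% c("glioblastoma", "gliosarcoma"),
                   "high", "low"),
    histotype = histo, stringsAsFactors = FALSE))
  dich_all <- attr(meta, "dichotomies")

  # sample loadings: Gaussian jitter plus a simple-structure class pattern
  # (each class loads on its designated factor only), which is both what an
  # oblique simple-structure rotation is built to find and what disjoint
  # histotype classes produce: near-orthogonal planted columns
  L <- matrix(stats::rnorm(m * max(l, 1), sd = spec$loading_sd), m, max(l, 1))
  if (l > 0 && nrow(spec$class_design)) {
    for (r in seq_len(nrow(spec$class_design))) {
      f <- spec$class_design$factor[r]
      ind <- dich_all[[spec$class_design$contrast[r]]]
      L[, f] <- L[, f] + spec$class_design$effect[r] * ind
    }
  }
  rownames(L) <- sample_names

  # gene scores: background normal + dedicated signal genes + cluster blocks
  F <- matrix(stats::rnorm(max(l, 1) * n, sd = spec$score_sd), max(l, 1), n)
  colnames(F) <- ids
  signal_ids <- vector("list", max(l, 1))
  mirna_rows <- which(kinds == "miRNA")
  cluster_members <- list()
  if (l > 0) {
    # cluster miRNAs first (they are factor-3-style signal by construction)
    avail_mir <- mirna_rows
    if (nrow(spec$clusters)) {
      for (r in seq_len(nrow(spec$clusters))) {
        take <- avail_mir[seq_len(spec$clusters$size[r])]
        avail_mir <- setdiff(avail_mir, take)
        f <- spec$clusters$factor[r]
        base <- spec$clusters$sign[r] *
          stats::runif(1, spec$signal_range[1], spec$signal_range[2]) *
          spec$score_sd
        F[, take] <- stats::rnorm(max(l, 1) * length(take), sd = 0.1)
        F[f, take] <- base + stats::rnorm(length(take), sd = 0.05)
        cluster_members[[spec$clusters$name[r]]] <- ids[take]
        signal_ids[[f]] <- c(signal_ids[[f]], ids[take])
      }
    }
    # dedicated signal genes per factor, split between tails, mRNA rows
    avail <- setdiff(seq_len(n), unlist(lapply(cluster_members, match, ids)))
    picked <- sample(avail, spec$n_signal * l)
    for (f in seq_len(l)) {
      take <- picked[seq.int((f - 1) * spec$n_signal + 1, f * spec$n_signal)]
      mag <- stats::runif(length(take), spec$signal_range[1],
                          spec$signal_range[2]) * spec$score_sd
      sgn <- rep_len(c(1, -1), length(take))
      F[, take] <- stats::rnorm(max(l, 1) * length(take), sd = 0.25 * spec$score_sd)
      F[f, take] <- sgn * mag
      signal_ids[[f]] <- c(signal_ids[[f]], ids[take])
    }
  }

  baseline <- stats::rnorm(n, spec$baseline_mean, spec$baseline_sd)
  E <- matrix(stats::rnorm(m * n, sd = spec$noise_sd), m, n)
  D <- if (l > 0) L[, seq_len(l), drop = FALSE] %*%
    F[seq_len(l), , drop = FALSE] + E else E
  X <- t(D) + baseline                              # features x samples, log2
  dimnames(X) <- list(ids, sample_names)

  mrna <- expression_matrix(2^X[kinds == "mRNA", , drop = FALSE],
                            row_kinds = "mRNA", scale = "linear")
  mirna <- expression_matrix(X[kinds == "miRNA", , drop = FALSE],
                             row_kinds = "miRNA", scale = "log2")

  clusters <- make_synthetic_clusters(cluster_members, spec)
  truth <- list(loadings = if (l > 0) L[, seq_len(l), drop = FALSE] else
                  matrix(0, m, 0),
                scores = if (l > 0) F[seq_len(l), , drop = FALSE] else
                  matrix(0, 0, n),
                signal_ids = signal_ids[seq_len(max(l, 0))],
                cluster_factor = if (nrow(spec$clusters))
                  spec$clusters$factor else integer(0),
                spec = spec)
  structure(list(mrna = mrna, mirna = mirna, metadata = meta,
                 clusters = clusters, truth = truth),
            class = "SyntheticDataset")
}

# Invented genomic coordinates: members of each cluster tiled ~150 bp apart
# on one chromosome, the layout of a polycistronic transcript.
make_synthetic_clusters <- function(cluster_members, spec) {
  out <- list()
  chr_pool <- c("chr13", "chrX", paste0("chr", 1:12))
  for (i in seq_along(cluster_members)) {
    nm <- names(cluster_members)[i]
    mem <- cluster_members[[i]]
    start <- 1000L + (i - 1L) * 100000L + 150L * (seq_along(mem) - 1L)
    out[[nm]] <- structure(list(
      cluster_name = nm, chromosome = chr_pool[i], member_ids = mem,
      members = data.frame(member_id = mem, start = start,
                           end = start + 80L, stringsAsFactors = FALSE),
      span = c(min(start), max(start) + 80L)), class = "GenomicCluster")
  }
  out
}

#' Write a synthetic dataset to pipeline input files
#'
#' Emits the generator's output in the pipeline's own input formats so the
#' file-based path is exercised end to end: mRNA TSV (linear intensities),
#' miRNA TSV (log2), metadata TSV, clusters BED6+1 and a ground-truth JSON.
#'
#' @param dataset a `SyntheticDataset`.
#' @param dir output directory (created if needed).
#' @return named character vector of the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "SyntheticDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(mrna = file.path(dir, "mrna.tsv"),
             mirna = file.path(dir, "mirna.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             clusters = file.path(dir, "clusters.bed"),
             truth = file.path(dir, "truth.json"))
  write_expression_table(dataset$mrna, paths["mrna"])
  write_expression_table(dataset$mirna, paths["mirna"])
  data.table::fwrite(as.data.frame(dataset$metadata)[
    c("sample_id", "grade", "histotype")], paths["metadata"], sep = "\t")
  bed <- do.call(rbind, lapply(dataset$clusters, function(cl)
    data.frame(chrom = cl$chromosome, start = cl$members$start,
               end = cl$members$end, name = cl$members$member_id,
               score = 0L, strand = "+", cluster = cl$cluster_name)))
  if (is.null(bed)) bed <- data.frame()
  utils::write.table(bed, paths["clusters"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  truth <- dataset$truth
  truth$spec <- truth$spec[setdiff(names(truth$spec),
                                   c("class_design", "clusters"))]
  jsonlite::write_json(truth, paths["truth"], digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  paths
}

#' Match recovered factors to planted factors
#'
#' Finds the assignment of recovered loading columns to planted columns
#' maximizing total absolute Tucker congruence (cosine similarity), with
#' exhaustive search over permutations when the counts are equal and
#' small, greedy matching otherwise (surplus recovered factors are left
#' unmatched).
#'
#' @param recovered,planted loading matrices over the same samples.
#' @return list with `permutation` (recovered column matched to each
#'   planted factor), `signs`, `congruence` (per planted factor, absolute).
#' @export
match_factors <- function(recovered, planted) {
  if (nrow(recovered) != nrow(planted))
    stop("sample dimension mismatch between recovered and planted loadings")
  nr <- ncol(recovered); np <- ncol(planted)
  if (nr < np) stop("fewer recovered factors than planted factors")
  unit <- function(M) sweep(M, 2, sqrt(colSums(M^2)), `/`)
  C <- t(unit(planted)) %*% unit(recovered)          # np x nr, signed
  if (nr == np && np <= 7) {
    perms <- permutations(np)
    scores <- vapply(perms, function(p)
      sum(abs(C[cbind(seq_len(np), p)])), numeric(1))
    perm <- perms[[which.max(scores)]]
  } else {
    perm <- integer(np)
    left <- seq_len(nr)
    for (i in order(-apply(abs(C), 1, max))) {
      j <- left[which.max(abs(C[i, left]))]
      perm[i] <- j
      left <- setdiff(left, j)
    }
  }
  cong <- abs(C[cbind(seq_len(np), perm)])
  signs <- sign(C[cbind(seq_len(np), perm)])
  signs[signs == 0] <- 1
  list(permutation = perm, signs = signs, congruence = cong)
}

permutations <- function(k) {
  if (k == 1) return(list(1L))
  unlist(lapply(seq_len(k), function(i)
    lapply(permutations(k - 1), function(p)
      c(i, ifelse(p >= i, p + 1L, p)))), recursive = FALSE)
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Preprocesses (log2, fold-change filter, normalization), fits the factor
#' model and selects factor-associated genes — the same path a real
#' dataset takes.
#'
#' The generator emits values already on the joint analysis scale, so the
#' default runs without row re-normalization (`mode = "none"`); the
#' min-max modes are available for measuring their effect (see the methods
#' vignette: on low-noise model-exact data, forcing every row onto a unit
#' range erases the score magnitudes the two-sigma selection relies on).
#'
#' @param dataset a `SyntheticDataset`.
#' @param l factor count (default: the planted count).
#' @param mode normalization mode (default `"none"`).
#' @param fold_change filter threshold.
#' @param multiplier score-selection band width.
#' @return list with `model` (`FactorModel`), `gene_sets`
#'   (per-factor `FactorGeneSet`), `joint` (preprocessed matrix),
#'   `log` (preprocessing row counts).
#' @export
run_pipeline <- function(dataset, l = NULL, mode = "none",
                         fold_change = 2.5, multiplier = 2) {
  if (is.null(l)) l <- max(dataset$truth$spec$n_factors, 1)
  prep <- preprocess_pipeline(dataset$mrna, dataset$mirna,
                              fold_change = fold_change, mode = mode)
  model <- fit_factor_model(prep$matrix, l = l)
  list(model = model,
       gene_sets = select_factor_genes(model$scores, multiplier),
       joint = prep$matrix, log = prep$log)
}

#' Evaluate how well the pipeline recovered the planted structure
#'
#' Matches recovered factors to the planted loadings and reports, per
#' planted factor: the Tucker congruence, and precision/recall of the
#' two-sigma gene selection against the planted signal genes. Adds the
#' cluster-enrichment table for the factor(s) carrying planted clusters
#' and the leave-one-out LDA confusion for each designed contrast on its
#' matched factor.
#'
#' @param dataset a `SyntheticDataset`.
#' @param output result of [run_pipeline()] on it.
#' @return list with `congruence`, `selection` (data.frame of
#'   precision/recall per factor), `cluster_enrichment` (data.frame or
#'   NULL), `lda` (per-contrast list of `ConfusionTable`s).
#' @export
evaluate_recovery <- function(dataset, output) {
  truth <- dataset$truth
  l <- ncol(truth$loadings)
  mt <- match_factors(output$model$loadings, truth$loadings)
  sel <- NULL
  if (l > 0) {
    sel <- do.call(rbind, lapply(seq_len(l), function(f) {
      gs <- output$gene_sets[[mt$permutation[f]]]
      got <- c(names(gs$positive_set), names(gs$negative_set))
      want <- intersect(truth$signal_ids[[f]],
                        feature_ids(output$joint))     # survive the filter
      tp <- length(intersect(got, want))
      data.frame(factor = f, matched = mt$permutation[f],
                 n_selected = length(got), n_planted = length(want),
                 precision = if (length(got)) tp / length(got) else NA,
                 recall = if (length(want)) tp / length(want) else NA)
    }))
  }
  enr <- NULL
  if (length(truth$cluster_factor)) {
    f <- unique(truth$cluster_factor)
    stopifnot(length(f) == 1)                          # default design
    gs <- output$gene_sets[[mt$permutation[f]]]
    got <- c(names(gs$positive_set), names(gs$negative_set))
    background <- feature_ids(dataset$mirna)
    selected_mir <- intersect(got, background)
    enr <- cluster_enrichment(selected_mir, dataset$clusters, background)
  }
  lda <- list()
  cd <- truth$spec$class_design
  if (l > 0 && nrow(cd)) {
    dich <- attr(dataset$metadata, "dichotomies")
    for (r in seq_len(nrow(cd))) {
      nm <- cd$contrast[r]
      lda[[nm]] <- loo_lda_confusion(
        output$model$loadings,
        dich[[nm]][rownames(output$model$loadings)],
        subset = mt$permutation[cd$factor[r]], class_name = nm)
    }
  }
  list(congruence = mt$congruence, selection = sel,
       cluster_enrichment = enr, lda = lda)
}
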