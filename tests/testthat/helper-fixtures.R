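# Fixture builders and independent oracles shared across the suite.
# All fixtures are generated in code; nothing is read from disk except
# files the tests themselves write to tempdir().

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

random_expression <- function(n = 10, m = 4, kind = "mRNA",
                              scale = "log2", seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n * m, 8, 2), n, m,
              dimnames = list(sprintf("%s_%03d", tolower(kind), seq_len(n)),
                              sprintf("S%02d", seq_len(m))))
  expression_matrix(v, row_kinds = kind, scale = scale)
}

# metadata mirroring the 12-biopsy layout: 2 anaplastic (low), 6
# glioblastoma (high), 3 gliosarcoma (high), 1 oligodendroglioma (low)
brain_metadata_df <- function() {
  histo <- rep(c("anaplastic", "glioblastoma", "gliosarcoma",
                 "oligodendroglioma"), c(2, 6, 3, 1))
  data.frame(sample_id = sprintf("S%02d", 1:12),
             grade = ifelse(histo %in% c("glioblastoma", "gliosarcoma"),
                            "high", "low"),
             histotype = histo, stringsAsFactors = FALSE)
}

write_metadata_fixture <- function(df = brain_metadata_df()) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# BED6+1 fixture: two clusters of 4 and 3 miRNA loci
write_bed_fixture <- function() {
  path <- tempfile(fileext = ".bed")
  lines <- c(
    sprintf("chr13\t%d\t%d\tmirA%d\t0\t+\tclustA", 100 + 150 * (0:3),
            180 + 150 * (0:3), 1:4),
    sprintf("chrX\t%d\t%d\tmirB%d\t0\t+\tclustB", 500 + 150 * (0:2),
            580 + 150 * (0:2), 1:3))
  writeLines(lines, path)
  path
}

# --- independent oracles -------------------------------------------------

# two-sided Fisher p by direct summation of dhyper point masses
oracle_fisher <- function(m) {
  r1 <- m[1, 1] + m[1, 2]; r2 <- m[2, 1] + m[2, 2]; c1 <- m[1, 1] + m[2, 1]
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == r1 + r2) return(1)
  a <- max(0, c1 - r2):min(r1, c1)
  p <- stats::dhyper(a, r1, r2, c1)
  sum(p[p <= p[a == m[1, 1]] * (1 + 1e-7)])
}

# hypergeometric upper tail by a direct ratio of binomial coefficients
oracle_hyper_upper <- function(N, K, n, k) {
  i <- k:min(K, n)
  i <- i[i >= max(0, n - (N - K))]
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# leave-one-out LDA via per-fold MASS::lda (training-fold priors are the
# MASS default), the implementation convention this package follows
oracle_loo_lda <- function(X, y) {
  pred <- logical(nrow(X))
  for (i in seq_len(nrow(X))) {
    fit <- MASS::lda(X[-i, , drop = FALSE], grouping = y[-i])
    pred[i] <- as.logical(as.character(
      stats::predict(fit, X[i, , drop = FALSE])$class))
  }
  c(a = sum(y & pred), b = sum(y & !pred),
    c = sum(!y & pred), d = sum(!y & !pred))
}

expect_confusion <- function(t, a, b, c, d) {
  expect_identical(c(t$a, t$b, t$c, t$d), c(a, b, c, d))
}
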