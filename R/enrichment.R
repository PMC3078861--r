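#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items without
#' replacement from a population of `N` containing `K` marked items. Point
#' masses are computed from log binomial coefficients and summed directly,
#' which is exact to double precision at the population sizes this package
#' meets (tens to hundreds).
#'
#' @param N background (population) size.
#' @param K marked items in the background.
#' @param n number drawn (the selection size).
#' @param k observed marked items in the selection.
#' @param lower return the lower tail `P(X <= k)` instead (audit flag).
#' @return tail probability.
#' @export
hypergeom_upper_tail <- function(N, K, n, k, lower = FALSE) {
  stopifnot(N >= 0, K >= 0, n >= 0, k >= 0)
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k > min(K, n)) stop("k must not exceed min(K, n)")
  i <- max(0, n - (N - K)):min(K, n)               # support
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  if (lower) sum(exp(logp[i <= k])) else min(1, sum(exp(logp[i >= k])))
}

#' Bonferroni correction
#'
#' @param p raw p-value(s).
#' @param hypothesis_count number of hypotheses tested (>= 1).
#' @return `min(1, p * hypothesis_count)`, vectorized over `p`.
#' @export
bonferroni <- function(p, hypothesis_count) {
  stopifnot(hypothesis_count >= 1)
  pmin(1, p * hypothesis_count)
}

new_enrichment_result <- function(unit, N, K, n, k, p_raw, p_adj, method) {
  data.frame(unit = unit, N = N, K = K, n = n, k = k,
             p_raw = p_raw, p_adj = p_adj, method = method,
             stringsAsFactors = FALSE)
}

#' Genomic-cluster enrichment of selected miRNAs
#'
#' Tests whether factor-selected miRNAs are over-represented in each
#' genomic cluster, and in the union of all clusters, against the
#' background of all detected miRNAs. Cluster membership is intersected
#' with the background before counting (`K`); `n` is the selection size and
#' `k` the selected members. One upper-tail hypergeometric p-value per
#' emitted result, Bonferroni-corrected by the number of results emitted.
#'
#' @param selected character vector of selected miRNA ids (must be a
#'   subset of `background`).
#' @param clusters list of `GenomicCluster` objects (or named lists of
#'   member id vectors).
#' @param background character vector of all detected miRNA ids.
#' @return data.frame of `EnrichmentResult` rows: `unit, N, K, n, k,
#'   p_raw, p_adj, method`.
#' @export
cluster_enrichment <- function(selected, clusters, background) {
  offenders <- setdiff(selected, background)
  if (length(offenders))
    stop("selected ids not in the background: ",
         paste(offenders, collapse = ", "))
  members <- lapply(clusters, function(cl)
    if (inherits(cl, "GenomicCluster")) cl$member_ids else as.character(cl))
  if (is.null(names(members)) || !all(nzchar(names(members))))
    names(members) <- vapply(clusters, function(cl)
      if (inherits(cl, "GenomicCluster")) cl$cluster_name else NA_character_,
      character(1))
  members$union <- unique(unlist(members))
  N <- length(unique(background))
  n <- length(unique(selected))
  rows <- lapply(names(members), function(nm) {
    mem <- intersect(members[[nm]], background)
    k <- length(intersect(selected, mem))
    p <- hypergeom_upper_tail(N, length(mem), n, k)
    new_enrichment_result(nm, N, length(mem), n, k, p, NA_real_, "bonferroni")
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni(out$p_raw, nrow(out))
  out
}

#' Term over-representation of selected genes
#'
#' Upper-tail hypergeometric test per term of a gene-set collection, with
#' Benjamini-Hochberg (default) or Bonferroni adjustment; stands in for
#' web-service annotation tools so the statistics stay fully offline and
#' testable.
#'
#' @param selected selected gene ids (subset of `background`).
#' @param terms named list of gene-id sets (e.g. from [read_gmt()]).
#' @param background all gene ids in the tested universe.
#' @param method `"benjamini_hochberg"` or `"bonferroni"`.
#' @return data.frame of `EnrichmentResult` rows sorted by `p_adj`.
#' @export
term_overrepresentation <- function(selected, terms, background,
                                    method = c("benjamini_hochberg",
                                               "bonferroni")) {
  method <- match.arg(method)
  offenders <- setdiff(selected, background)
  if (length(offenders))
    stop("selected ids not in the background: ",
         paste(offenders, collapse = ", "))
  if (!length(terms))
    return(new_enrichment_result(character(0), integer(0), integer(0),
                                 integer(0), integer(0), numeric(0),
                                 numeric(0), character(0)))
  N <- length(unique(background))
  n <- length(unique(selected))
  rows <- lapply(names(terms), function(nm) {
    mem <- intersect(unique(terms[[nm]]), background)
    k <- length(intersect(selected, mem))
    p <- hypergeom_upper_tail(N, length(mem), n, k)
    new_enrichment_result(nm, N, length(mem), n, k, p, NA_real_, method)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (method == "bonferroni")
    bonferroni(out$p_raw, nrow(out))
  else
    stats::p.adjust(out$p_raw, method = "BH")
  out[order(out$p_adj, out$p_raw), , drop = FALSE]
}

#' Indirect functional annotation of miRNAs via their targets
#'
#' Relational join: each selected miRNA is linked to its (experimentally
#' validated) target genes and each target to its functional terms. No
#' statistic is attached — target lists are typically too short for a
#' meaningful p-value. miRNAs without any known target are kept with an
#' empty target field.
#'
#' @param selected_mirnas miRNA ids to annotate.
#' @param target_map data.frame with columns `mirna`, `target`
#'   (see [read_target_map()]).
#' @param terms named list of gene sets; a target's terms are all set names
#'   containing it.
#' @return data.frame with columns `mirna`, `target`, `terms`
#'   (semicolon-joined; empty string when none).
#' @export
indirect_annotation <- function(selected_mirnas, target_map, terms) {
  if (!length(selected_mirnas))
    return(data.frame(mirna = character(0), target = character(0),
                      terms = character(0), stringsAsFactors = FALSE))
  gene_terms <- function(g) {
    hit <- vapply(terms, function(set) g %in% set, logical(1))
    paste(names(terms)[hit], collapse = ";")
  }
  rows <- lapply(selected_mirnas, function(mir) {
    tg <- target_map$target[target_map$mirna == mir]
    if (!length(tg))
      return(data.frame(mirna = mir, target = "", terms = "",
                        stringsAsFactors = FALSE))
    data.frame(mirna = mir, target = tg,
               terms = vapply(tg, gene_terms, character(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
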