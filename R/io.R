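#' Read an expression table (TSV or CSV)
#'
#' Expects a delimited text file with feature identifiers in the first
#' column and a header row of sample identifiers. All rows are assigned the
#' same molecule kind and scale. Rows containing missing values are dropped
#' with a message reporting the count.
#'
#' @param path file path; the delimiter (tab or comma) is auto-detected.
#' @param kind `"mRNA"` or `"miRNA"`.
#' @param scale `"linear"` (e.g. raw microarray intensities) or `"log2"`
#'   (e.g. real-time PCR output).
#' @return an [expression_matrix()] with row order preserved.
#' @export
read_expression_table <- function(path, kind = c("mRNA", "miRNA"),
                                  scale = c("linear", "log2")) {
  kind <- match.arg(kind)
  scale <- match.arg(scale)
  check_rectangular(path)
  dt <- tryCatch(
    data.table::fread(path, header = TRUE, sep = "auto", fill = FALSE,
                      colClasses = list(character = 1), data.table = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(dt) < 2) stop("expression table needs >= 1 sample column")
  ids <- dt[[1]]
  if (anyDuplicated(ids))
    stop("duplicate feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- dt[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) &
                     !is.na(vals[[j]]))[1]
      stop(sprintf("non-numeric value in row '%s', column '%s'",
                   ids[if (is.na(bad)) 1 else bad], names(vals)[j]))
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  miss <- rowSums(is.na(m)) > 0
  if (any(miss)) {
    message(sum(miss), " row(s) with missing values dropped")
    m <- m[!miss, , drop = FALSE]
  }
  expression_matrix(m, row_kinds = kind, scale = scale)
}

#' Write an expression table as TSV
#'
#' Inverse of [read_expression_table()]: full double precision is kept so a
#' write/read round trip reproduces the matrix exactly.
#'
#' @param mat an `ExpressionMatrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(mat, path) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  # 17 significant digits round-trips IEEE doubles exactly through text
  txt <- apply(mat$values, 2, function(x) formatC(x, digits = 17,
                                                  format = "g"))
  if (!is.matrix(txt)) txt <- matrix(txt, nrow = nrow(mat$values))
  df <- data.frame(feature_id = rownames(mat$values), txt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("feature_id", colnames(mat$values))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# every data row must have as many fields as the header
check_rectangular <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  nf <- utils::count.fields(path, sep = sep, quote = "\"",
                            comment.char = "")
  bad <- which(nf != nf[1])
  if (length(bad))
    stop("row ", bad[1] - 1L, " has ", nf[bad[1]], " field(s), expected ",
         nf[1])
  invisible(TRUE)
}

HISTOTYPES <- c("anaplastic", "glioblastoma", "gliosarcoma", "oligodendroglioma")

#' Read sample metadata
#'
#' Reads a delimited table with columns `sample_id`, `grade` (high/low) and
#' `histotype` (anaplastic, glioblastoma, gliosarcoma, oligodendroglioma),
#' and derives the four dichotomous contrasts used for discriminant
#' analysis: high/low grade and each histotype versus its complement.
#'
#' @param path file path (TSV or CSV).
#' @return a `SampleMetadata` object: a data.frame with the three input
#'   columns plus an attribute `"dichotomies"` holding named logical vectors.
#' @export
read_sample_metadata <- function(path) {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  for (col in c("sample_id", "grade", "histotype"))
    if (!col %in% names(df)) stop("metadata is missing column '", col, "'")
  df$sample_id <- as.character(df$sample_id)
  df$grade <- tolower(as.character(df$grade))
  df$histotype <- tolower(as.character(df$histotype))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!all(df$grade %in% c("high", "low")))
    stop("unknown grade value(s): ",
         paste(setdiff(df$grade, c("high", "low")), collapse = ", "))
  if (!all(df$histotype %in% HISTOTYPES))
    stop("unknown histotype value(s): ",
         paste(setdiff(df$histotype, HISTOTYPES), collapse = ", "))
  sample_metadata(df)
}

#' Construct sample metadata from a data.frame
#'
#' @param df data.frame with columns `sample_id`, `grade`, `histotype`.
#' @return a `SampleMetadata` (see [read_sample_metadata()]).
#' @export
sample_metadata <- function(df) {
  stopifnot(all(c("sample_id", "grade", "histotype") %in% names(df)))
  dich <- list(
    grade        = df$grade == "high",
    anaplastic   = df$histotype == "anaplastic",
    glioblastoma = df$histotype == "glioblastoma",
    gliosarcoma  = df$histotype == "gliosarcoma")
  dich <- lapply(dich, function(v) stats::setNames(v, df$sample_id))
  structure(df, dichotomies = dich,
            class = c("SampleMetadata", "data.frame"))
}

#' Dichotomous contrasts defined by sample metadata
#'
#' Returns the named logical label vectors (TRUE = member of the class) for
#' each contrast that actually partitions the samples into two non-empty
#' groups. Degenerate contrasts are dropped with a warning.
#'
#' @param meta a `SampleMetadata`.
#' @param samples optional character vector: restrict/reorder to these
#'   sample ids (error if any is missing from the metadata).
#' @return named list of logical vectors.
#' @export
dichotomies <- function(meta, samples = NULL) {
  d <- attr(meta, "dichotomies")
  if (!is.null(samples)) {
    missing <- setdiff(samples, meta$sample_id)
    if (length(missing))
      stop("samples absent from metadata: ", paste(missing, collapse = ", "))
    d <- lapply(d, function(v) v[samples])
  }
  ok <- vapply(d, function(v) any(v) && !all(v), logical(1))
  if (!all(ok))
    warning("contrast(s) with an empty class skipped: ",
            paste(names(d)[!ok], collapse = ", "))
  d[ok]
}

#' Read genomic miRNA clusters from BED or GFF3
#'
#' Groups miRNA loci into genomic clusters (e.g. polycistronic transcripts
#' such as miR-17-92). The format is chosen by file extension
#' (`.bed` vs `.gff`/`.gff3`). For BED input a seventh column must carry the
#' cluster name (BED6+1); the `name` column carries the miRNA identifier.
#' For GFF3 the attribute named by `cluster_key` carries the cluster and
#' `ID` (or `Name`) the miRNA. Intervals are normalized to the package's
#' internal 0-based half-open convention (GFF3's 1-based inclusive
#' coordinates are converted on read).
#'
#' @param path BED6+1 or GFF3 file.
#' @param cluster_key GFF3 attribute holding the cluster name
#'   (default `"cluster"`); ignored for BED.
#' @return list of `GenomicCluster` objects, each a list with
#'   `cluster_name`, `chromosome`, `member_ids`, `members` (data.frame of
#'   per-member 0-based half-open intervals) and `span` (c(start, end)).
#' @export
read_mirna_clusters <- function(path, cluster_key = "cluster") {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "BED",
                              extraCols = c(cluster = "character"))
    members <- as.character(gr$name)
    clusters <- as.character(gr$cluster)
  } else if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "GFF3")
    md <- GenomicRanges::mcols(gr)
    if (!cluster_key %in% names(md))
      stop("GFF3 attribute '", cluster_key, "' not found")
    clusters <- as.character(md[[cluster_key]])
    members <- if ("ID" %in% names(md) && !anyNA(md$ID))
      as.character(md$ID) else as.character(md$Name)
  } else stop("unrecognized cluster file extension: ", ext)
  # internal convention: 0-based half-open
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  if (any(start0 >= end0))
    stop("malformed interval (start >= end) for: ",
         paste(members[start0 >= end0], collapse = ", "))
  if (anyNA(clusters) || anyNA(members))
    stop("every feature needs a member id and a cluster tag")
  by_member <- split(clusters, members)
  multi <- names(by_member)[vapply(by_member, function(x)
    length(unique(x)) > 1, logical(1))]
  if (length(multi))
    warning("member(s) listed in more than one cluster (kept in all): ",
            paste(multi, collapse = ", "))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  out <- lapply(unique(clusters), function(cl) {
    i <- which(clusters == cl)
    if (anyDuplicated(members[i]))
      stop("duplicate member within cluster ", cl)
    if (length(unique(chrom[i])) > 1)
      stop("cluster ", cl, " spans multiple chromosomes")
    structure(list(cluster_name = cl,
                   chromosome = chrom[i][1],
                   member_ids = members[i],
                   members = data.frame(member_id = members[i],
                                        start = start0[i], end = end0[i],
                                        stringsAsFactors = FALSE),
                   span = c(min(start0[i]), max(end0[i]))),
              class = "GenomicCluster")
  })
  names(out) <- unique(clusters)
  out
}

#' @export
print.GenomicCluster <- function(x, ...) {
  cat(sprintf("GenomicCluster %s (%s:%d-%d): %d member(s)\n", x$cluster_name,
              x$chromosome, x$span[1], x$span[2], length(x$member_ids)))
  invisible(x)
}

#' Read a gene-set collection in GMT format
#'
#' GMT: one set per line, tab-separated `term<TAB>description<TAB>gene...`.
#' Duplicate genes within a set are collapsed; empty sets are an error.
#'
#' @param path GMT file.
#' @return named list of character vectors, with a `"descriptions"`
#'   attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(ids)) stop("duplicate term id(s) in GMT")
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  if (any(lengths(sets) == 0))
    stop("empty gene set(s): ",
         paste(ids[lengths(sets) == 0], collapse = ", "))
  names(sets) <- ids
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, function(p)
      if (length(p) >= 2) p[[2]] else "", character(1)), ids)
  sets
}

#' Read a miRNA-to-target map
#'
#' Two-column delimited table: miRNA id, target gene id (e.g. an export of
#' experimentally validated interactions).
#'
#' @param path TSV/CSV file with a header.
#' @return data.frame with columns `mirna`, `target`.
#' @export
read_target_map <- function(path) {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(df) < 2) stop("target map needs two columns: miRNA, target gene")
  out <- data.frame(mirna = as.character(df[[1]]),
                    target = as.character(df[[2]]),
                    stringsAsFactors = FALSE)
  unique(out)
}
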