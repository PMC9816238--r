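## Core container: a complete (site x sample) grid of read counts held as
## three integer matrices (ref/alt/other), mirroring the assay-matrix layout
## of SummarizedExperiment-style containers. The grid is complete by
## construction: a (site, sample) pair with no reads is stored as (0,0,0),
## never omitted, so failed-call counting is a pure downstream operation.

#' Construct a site identifier
#'
#' Builds the canonical `"chrom:pos:ref:alt"` key used as the row name of
#' the count matrices in a [study_table()].
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @param ref Reference allele (single base).
#' @param alt Alternative allele (single base or `"*"`).
#' @return Character vector of site identifiers.
#' @export
site_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

validate_sites <- function(sites) {
  stopifnot(is.data.frame(sites))
  required <- c("chrom", "pos", "ref", "alt")
  missing <- setdiff(required, names(sites))
  if (length(missing) > 0L) {
    stop("site table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(sites$pos < 1L)) {
    stop("positions are 1-based; found pos < 1")
  }
  if (!all(sites$ref %in% .BASES)) {
    stop("ref alleles must be one of A, C, G, T")
  }
  ok_alt <- sites$alt %in% c(.BASES, .SPANNING_DELETION)
  if (!all(ok_alt)) {
    stop("alt alleles must be A, C, G, T or '*'")
  }
  if (any(sites$ref == sites$alt)) {
    stop("ref and alt alleles must differ")
  }
  ids <- site_id(sites$chrom, sites$pos, sites$ref, sites$alt)
  if (anyDuplicated(ids)) {
    stop("duplicate site records: ", ids[duplicated(ids)][1L])
  }
  invisible(ids)
}

validate_samples <- function(samples) {
  stopifnot(is.data.frame(samples))
  required <- c("sample_id", "matrix", "condition", "time_days")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0L) {
    stop("sample table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in sample metadata")
  }
  key <- paste(samples$matrix, samples$condition, samples$time_days)
  if (anyDuplicated(key)) {
    stop("(matrix, condition, time_days) combinations must be unique")
  }
  if (any(samples$time_days < 0L)) {
    stop("time_days must be non-negative")
  }
  invisible(samples$sample_id)
}

#' Assemble a study table of per-site, per-sample read counts
#'
#' The central data container: an ordered collection of biallelic variant
#' sites, a sample sheet (one sample per matrix/condition/time-point
#' combination), and three aligned integer count matrices giving, for every
#' (site, sample) pair, the number of reads supporting the reference allele,
#' the alternative allele, and any other allele. Absence of coverage is
#' encoded explicitly as a (0, 0, 0) observation.
#'
#' @param sites Data frame with columns `chrom`, `pos` (1-based), `ref`
#'   (single base) and `alt` (single base or `"*"` for a spanning deletion).
#' @param samples Data frame with columns `sample_id`, `matrix` (e.g.
#'   `"blood"`, `"saliva"`), `condition` (e.g. `"dry"`, `"humid"`, `"none"`)
#'   and `time_days` (non-negative integer storage time; day 0 is the truth
#'   reference).
#' @param ref_reads,alt_reads,other_reads Integer matrices, sites x samples,
#'   in the row/column order of `sites` and `samples`.
#' @return An object of class `study_table`.
#' @export
study_table <- function(sites, samples, ref_reads, alt_reads, other_reads) {
  ids <- validate_sites(sites)
  validate_samples(samples)
  n_sites <- nrow(sites)
  n_samples <- nrow(samples)
  for (m in list(ref_reads, alt_reads, other_reads)) {
    if (!is.matrix(m) || nrow(m) != n_sites || ncol(m) != n_samples) {
      stop("count matrices must be sites x samples")
    }
    if (any(m < 0L) || any(m != round(m))) {
      stop("read counts must be non-negative integers")
    }
  }
  ord <- genomic_order(sites)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  dress <- function(m) {
    m <- m[ord, , drop = FALSE]
    storage.mode(m) <- "integer"
    dimnames(m) <- list(ids[ord], samples$sample_id)
    m
  }
  structure(
    list(
      sites = sites,
      samples = samples,
      ref_reads = dress(ref_reads),
      alt_reads = dress(alt_reads),
      other_reads = dress(other_reads)
    ),
    class = "study_table"
  )
}

## Genomic sort order: chromosome (lexicographic), then position, then alt
## allele so decomposed multi-allelic records stay adjacent.
genomic_order <- function(sites) {
  order(sites$chrom, sites$pos, sites$alt, method = "radix")
}

#' @export
print.study_table <- function(x, ...) {
  cat(
    "study_table:", nrow(x$sites), "sites x", nrow(x$samples), "samples\n"
  )
  cat("  matrices:", paste(unique(x$samples$matrix), collapse = ", "), "\n")
  cat("  conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  cat("  time points (days):",
      paste(sort(unique(x$samples$time_days)), collapse = ", "), "\n")
  invisible(x)
}

#' Total read depth per observation
#'
#' @param table A [study_table()].
#' @return Integer matrix of ref + alt + other reads, sites x samples.
#' @export
total_reads <- function(table) {
  table$ref_reads + table$alt_reads + table$other_reads
}

#' @export
as.data.frame.study_table <- function(x, ...) {
  n_sites <- nrow(x$sites)
  n_samples <- nrow(x$samples)
  data.frame(
    chrom = rep(x$sites$chrom, times = n_samples),
    pos = rep(x$sites$pos, times = n_samples),
    ref = rep(x$sites$ref, times = n_samples),
    alt = rep(x$sites$alt, times = n_samples),
    sample_id = rep(x$samples$sample_id, each = n_sites),
    ref_reads = as.integer(x$ref_reads),
    alt_reads = as.integer(x$alt_reads),
    other_reads = as.integer(x$other_reads),
    stringsAsFactors = FALSE
  )
}

#' Build a study table from a long counts data frame
#'
#' Inverse of [as.data.frame.study_table()]: takes one row per (site,
#' sample) observation and pivots to the matrix layout. Every site must be
#' observed in every sample exactly once.
#'
#' @param counts Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `sample_id`, `ref_reads`, `alt_reads`, `other_reads`.
#' @param samples Sample metadata data frame (see [study_table()]).
#' @return A [study_table()].
#' @export
study_table_from_long <- function(counts, samples) {
  validate_samples(samples)
  sites <- unique(counts[, c("chrom", "pos", "ref", "alt")])
  sites <- sites[genomic_order(sites), , drop = FALSE]
  rownames(sites) <- NULL
  ids <- site_id(sites$chrom, sites$pos, sites$ref, sites$alt)
  row_key <- site_id(counts$chrom, counts$pos, counts$ref, counts$alt)
  i <- match(row_key, ids)
  j <- match(counts$sample_id, samples$sample_id)
  if (anyNA(j)) {
    stop(
      "sample_id not in sample metadata: ",
      paste(unique(counts$sample_id[is.na(j)]), collapse = ", ")
    )
  }
  idx <- cbind(i, j)
  if (anyDuplicated(idx)) {
    d <- idx[duplicated(idx), , drop = FALSE][1L, ]
    stop(
      "duplicate observation for site ", ids[d[1L]],
      " sample ", samples$sample_id[d[2L]]
    )
  }
  if (nrow(counts) != nrow(sites) * nrow(samples)) {
    stop(
      "incomplete grid: expected ", nrow(sites) * nrow(samples),
      " observations, got ", nrow(counts),
      " (every site must be observed in every sample; use (0,0,0) rows ",
      "for absent coverage)"
    )
  }
  blank <- matrix(0L, nrow(sites), nrow(samples))
  fill <- function(v) {
    m <- blank
    m[idx] <- as.integer(v)
    m
  }
  study_table(
    sites, samples,
    ref_reads = fill(counts$ref_reads),
    alt_reads = fill(counts$alt_reads),
    other_reads = fill(counts$other_reads)
  )
}
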