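## Flat-file interfaces: the TSV counts table, the sample sheet, and
## multi-sample VCF input (GATK-style AD/DP genotype fields, parsed through
## vcfR). All writers are deterministic: fixed column order, genomic sort
## order, LF line endings, no floating-point columns.

.COUNTS_COLUMNS <- c(
  "chrom", "pos", "ref", "alt", "sample_id",
  "ref_reads", "alt_reads", "other_reads"
)

#' Write a counts table to TSV
#'
#' One row per (site, sample) observation, sorted by (chrom, pos, alt,
#' sample_id). Output is byte-deterministic: the same table always produces
#' an identical file.
#'
#' @param table A [study_table()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_counts_table <- function(table, path) {
  stopifnot(inherits(table, "study_table"))
  long <- as.data.frame(table)
  ord <- order(long$chrom, long$pos, long$alt, long$sample_id,
               method = "radix")
  long <- long[ord, .COUNTS_COLUMNS]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(.COUNTS_COLUMNS, collapse = "\t"), con)
  if (nrow(long) > 0L) {
    writeLines(do.call(paste, c(unname(as.list(long)), sep = "\t")), con)
  }
  invisible(path)
}

#' Read a counts table from TSV
#'
#' Reads the tab-separated counts format written by [write_counts_table()]
#' and validates every row: 1-based positions, canonical alleles (`"*"`
#' accepted as a spanning deletion), non-negative integer counts, no
#' duplicate (site, sample) observations, complete site x sample grid.
#'
#' @param path Path to the counts TSV.
#' @param samples Sample metadata data frame; when `NULL`, a minimal sheet
#'   is derived by parsing sample identifiers of the form
#'   `<matrix>_<condition>_d<days>`.
#' @return A [study_table()].
#' @export
read_counts_table <- function(path, samples = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty counts file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, .COUNTS_COLUMNS)) {
    stop(
      "counts table header must be: ",
      paste(.COUNTS_COLUMNS, collapse = ", ")
    )
  }
  body <- lines[-1L]
  if (length(body) == 0L) {
    counts <- data.frame(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), sample_id = character(), ref_reads = integer(),
      alt_reads = integer(), other_reads = integer(),
      stringsAsFactors = FALSE
    )
  } else {
    fields <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != length(.COUNTS_COLUMNS))
    if (length(bad) > 0L) {
      stop("malformed row at line ", bad[1L] + 1L, " of ", path)
    }
    m <- matrix(unlist(fields), ncol = length(.COUNTS_COLUMNS), byrow = TRUE)
    to_int <- function(col, name) {
      v <- suppressWarnings(as.integer(m[, col]))
      bad <- which(is.na(v) | m[, col] != as.character(v))
      if (length(bad) > 0L) {
        stop(
          "malformed ", name, " at line ", bad[1L] + 1L, " of ", path
        )
      }
      v
    }
    counts <- data.frame(
      chrom = m[, 1L],
      pos = to_int(2L, "pos"),
      ref = m[, 3L],
      alt = m[, 4L],
      sample_id = m[, 5L],
      ref_reads = to_int(6L, "ref_reads"),
      alt_reads = to_int(7L, "alt_reads"),
      other_reads = to_int(8L, "other_reads"),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(samples)) {
    samples <- infer_sample_meta(unique(counts$sample_id))
  }
  study_table_from_long(counts, samples)
}

## Fallback sample sheet from "<matrix>_<condition>_d<days>" identifiers.
infer_sample_meta <- function(sample_ids) {
  parts <- strsplit(sample_ids, "_", fixed = TRUE)
  ok <- lengths(parts) == 3L & grepl("^d[0-9]+$", vapply(parts, `[`, "", 3L))
  if (!all(ok)) {
    stop(
      "cannot infer sample metadata from sample_id '",
      sample_ids[!ok][1L],
      "'; pass a sample sheet (sample_id, matrix, condition, time_days)"
    )
  }
  data.frame(
    sample_id = sample_ids,
    matrix = vapply(parts, `[`, "", 1L),
    condition = vapply(parts, `[`, "", 2L),
    time_days = as.integer(sub("^d", "", vapply(parts, `[`, "", 3L))),
    stringsAsFactors = FALSE
  )
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `matrix`, `condition`,
#'   `time_days`.
#' @return Validated sample metadata data frame.
#' @export
read_sample_meta <- function(path) {
  samples <- read.table(
    path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    colClasses = c(
      sample_id = "character", matrix = "character",
      condition = "character", time_days = "integer"
    )
  )
  validate_samples(samples)
  samples
}

#' Write a sample sheet
#'
#' @param samples Sample metadata data frame.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_sample_meta <- function(samples, path) {
  validate_samples(samples)
  write_tsv(samples[, c("sample_id", "matrix", "condition", "time_days")],
            path)
}

## Deterministic TSV writer used by all report outputs.
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0L) {
    cols <- lapply(df, function(x) {
      if (is.double(x)) format(x, trim = TRUE, digits = 15L) else as.character(x)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Read a multi-sample VCF into a study table
#'
#' Parses a GATK-style multi-sample VCF with per-genotype `AD` (allelic
#' depth) and `DP` (total depth) fields. Multi-allelic records are
#' decomposed into one biallelic record per alternative allele; depth on the
#' remaining alternatives, plus any uninformative depth (`DP` exceeding the
#' sum of `AD`), is carried in `other_reads`. Records whose alleles are not
#' single canonical bases (or the spanning-deletion allele `"*"`) are
#' skipped and counted in the `skipped_records` attribute. A genotype with a
#' missing `AD` field is accepted only at zero depth, where it encodes
#' absence of coverage as a (0, 0, 0) observation.
#'
#' @param path Path to the VCF (plain or bgzipped).
#' @param samples Sample metadata data frame; every VCF sample name must
#'   appear in it.
#' @return A [study_table()] with attribute `skipped_records` (count of
#'   non-SNV alternative alleles skipped).
#' @export
read_vcf <- function(path, samples) {
  validate_samples(samples)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  vcf_samples <- colnames(v@gt)[-1L]
  unknown <- setdiff(vcf_samples, samples$sample_id)
  if (length(unknown) > 0L) {
    stop(
      "VCF sample(s) missing from sample metadata: ",
      paste(unknown, collapse = ", ")
    )
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  dp_chr <- vcfR::extract.gt(v, element = "DP")
  dp <- suppressWarnings(matrix(as.integer(dp_chr), nrow = nrow(ad)))
  n_rec <- nrow(fix)
  n_samp <- length(vcf_samples)
  skipped <- 0L
  rows <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    ref <- fix[r, "REF"]
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1L]]
    if (!ref %in% .BASES) {
      skipped <- skipped + length(alts)
      next
    }
    keep <- alts %in% c(.BASES, .SPANNING_DELETION)
    skipped <- skipped + sum(!keep)
    if (!any(keep)) next
    ## per-sample allele depth vectors (ref, alt1, alt2, ...)
    ad_r <- ad[r, vcf_samples]
    dp_r <- dp[r, ]
    dp_r[is.na(dp_r)] <- 0L
    ad_mat <- matrix(0L, nrow = n_samp, ncol = 1L + length(alts))
    for (s in seq_len(n_samp)) {
      field <- ad_r[[s]]
      if (is.na(field) || field == ".") {
        if (dp_r[s] > 0L) {
          stop(
            "missing AD field at ", fix[r, "CHROM"], ":", fix[r, "POS"],
            " sample ", vcf_samples[s], " with non-zero depth"
          )
        }
        next
      }
      vals <- suppressWarnings(
        as.integer(strsplit(field, ",", fixed = TRUE)[[1L]])
      )
      vals[is.na(vals)] <- 0L
      if (length(vals) != ncol(ad_mat)) {
        stop(
          "AD field with wrong allele count at ",
          fix[r, "CHROM"], ":", fix[r, "POS"], " sample ", vcf_samples[s]
        )
      }
      ad_mat[s, ] <- vals
    }
    ## uninformative reads: DP beyond the sum of allele depths
    slack <- pmax(dp_r - rowSums(ad_mat), 0L)
    alt_idx <- which(keep)
    rec_rows <- vector("list", length(alt_idx))
    for (k in seq_along(alt_idx)) {
      a <- alt_idx[k]
      alt_depth <- ad_mat[, 1L + a]
      sibling <- rowSums(ad_mat[, -c(1L, 1L + a), drop = FALSE])
      rec_rows[[k]] <- data.frame(
        chrom = unname(fix[r, "CHROM"]),
        pos = as.integer(fix[r, "POS"]),
        ref = unname(ref),
        alt = alts[a],
        sample_id = vcf_samples,
        ref_reads = ad_mat[, 1L],
        alt_reads = alt_depth,
        other_reads = sibling + slack,
        stringsAsFactors = FALSE
      )
    }
    rows[[r]] <- do.call(rbind, rec_rows)
  }
  counts <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(counts) || nrow(counts) == 0L) {
    stop("no usable SNV records in ", path)
  }
  used <- samples[samples$sample_id %in% vcf_samples, , drop = FALSE]
  out <- study_table_from_long(counts, used)
  attr(out, "skipped_records") <- skipped
  out
}

#' Write a study table as a multi-sample VCF
#'
#' Emits a minimal VCFv4.2 file with `GT:AD:DP` genotype fields. `AD`
#' carries the ref and alt read counts; `other_reads` is folded into `DP`
#' as uninformative depth, so [read_vcf()] reproduces the table exactly.
#' `GT` is informational only, derived from the default band caller; `./.`
#' marks zero-coverage genotypes. Output bytes are deterministic.
#'
#' @param table A [study_table()].
#' @param path Output VCF path.
#' @param config [calling_config()] used for the informational `GT` field.
#' @return Invisibly, the path.
#' @export
write_vcf <- function(table, path, config = calling_config()) {
  stopifnot(inherits(table, "study_table"))
  sites <- table$sites
  total <- total_reads(table)
  gt_code <- c("0/0" = "0/0", "0/1" = "0/1", "1/1" = "1/1", "FAILED" = "./.")
  calls <- call_study(table, config)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=snvdrift",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0('##FORMAT=<ID=AD,Number=R,Type=Integer,',
           'Description="Allelic depths for the ref and alt alleles">'),
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(
      c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
        "FORMAT", table$samples$sample_id),
      collapse = "\t"
    )
  )
  n_sites <- nrow(sites)
  gt_block <- matrix(
    paste0(
      gt_code[as.character(calls$call)], ":",
      table$ref_reads, ",", table$alt_reads, ":",
      total
    ),
    nrow = n_sites
  )
  body <- paste(
    sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".", ".", ".",
    "GT:AD:DP",
    apply(gt_block, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
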