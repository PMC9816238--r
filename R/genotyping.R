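## PRV computation and genotype allocation. The PRV (percentage of reads of
## the variant allele) is 100 * alt_reads / total_reads, with total_reads
## counting all detected alleles (ref + alt + other). Genotypes are
## allocated by a deterministic PRV band caller: 0/0 below the lower band,
## 1/1 above the upper band (with a symmetric minimum-read guard), 0/1 in
## between, FAILED at zero coverage. The literal mapping 0% -> 0/0,
## 100% -> 1/1, in between -> 0/1 is the limiting case of the band caller
## (bands at 0/100, minimum evidence of one read); the default bands
## tolerate sequencing error, which would otherwise turn any single
## miscalled read into a heterozygous call.

#' Genotype-calling configuration
#'
#' @param het_band_low PRV (percentage points) below which an observation is
#'   called homozygous reference. Default 5.
#' @param het_band_high PRV above which an observation is called homozygous
#'   alternative. Default 95.
#' @param min_alt_reads_for_het Minimum number of alternative-allele reads
#'   required before an observation can leave 0/0 (and, symmetrically, the
#'   maximum number of reference reads tolerated by a 1/1 call). Default 2,
#'   so a single stray read is treated as sequencing error.
#' @param coverage_floor Observations with `total_reads` strictly below this
#'   are FAILED. Default 1: exactly zero coverage fails, matching the
#'   definition of a failed genotype call as a site with no coverage.
#' @return A list of class `calling_config`.
#' @export
calling_config <- function(het_band_low = 5,
                           het_band_high = 95,
                           min_alt_reads_for_het = 2L,
                           coverage_floor = 1L) {
  stopifnot(
    het_band_low > 0, het_band_low < het_band_high, het_band_high < 100,
    min_alt_reads_for_het >= 1L, coverage_floor >= 1L
  )
  structure(
    list(
      het_band_low = het_band_low,
      het_band_high = het_band_high,
      min_alt_reads_for_het = as.integer(min_alt_reads_for_het),
      coverage_floor = as.integer(coverage_floor)
    ),
    class = "calling_config"
  )
}

#' Percentage of reads of the variant allele (PRV)
#'
#' `PRV = 100 * alt_reads / (ref_reads + alt_reads + other_reads)`. The
#' denominator counts reads of all detected alleles. Undefined at zero
#' total depth; callers must branch on FAILED genotypes first.
#'
#' @param ref_reads,alt_reads,other_reads Non-negative integer vectors.
#' @return Numeric vector of percentages in \[0, 100\].
#' @export
compute_prv <- function(ref_reads, alt_reads, other_reads = 0L) {
  total <- ref_reads + alt_reads + other_reads
  if (any(total == 0L)) {
    stop("PRV is undefined at zero total depth")
  }
  100 * alt_reads / total
}

#' Allocate genotype calls from read counts
#'
#' Vectorised band caller. Rules, applied in order per observation:
#' FAILED when `total_reads < coverage_floor`; homozygous reference when
#' `PRV < het_band_low` or `alt_reads < min_alt_reads_for_het`; homozygous
#' alternative when `PRV > het_band_high` and
#' `ref_reads < min_alt_reads_for_het`; heterozygous otherwise.
#'
#' @inheritParams compute_prv
#' @param config A [calling_config()].
#' @return Factor with levels [genotype_levels()].
#' @export
allocate_genotype <- function(ref_reads, alt_reads, other_reads = 0L,
                              config = calling_config()) {
  n <- max(length(ref_reads), length(alt_reads), length(other_reads))
  ref_reads <- rep_len(ref_reads, n)
  alt_reads <- rep_len(alt_reads, n)
  other_reads <- rep_len(other_reads, n)
  total <- ref_reads + alt_reads + other_reads
  prv <- ifelse(total > 0L, 100 * alt_reads / total, NA_real_)
  out <- rep("0/1", n)
  hom_alt <- !is.na(prv) &
    prv > config$het_band_high &
    ref_reads < config$min_alt_reads_for_het
  out[hom_alt] <- "1/1"
  hom_ref <- !is.na(prv) &
    (prv < config$het_band_low | alt_reads < config$min_alt_reads_for_het)
  out[hom_ref] <- "0/0"
  out[total < config$coverage_floor] <- "FAILED"
  factor(out, levels = .GT_LEVELS)
}

#' Call genotypes for every observation of a study table
#'
#' @param table A [study_table()].
#' @param config A [calling_config()].
#' @return An object of class `study_calls`: the site and sample tables of
#'   the input plus two aligned sites x samples matrices, `call` (character,
#'   one of [genotype_levels()]) and `prv` (numeric, `NA` where the call is
#'   FAILED), and the configuration used.
#' @export
call_study <- function(table, config = calling_config()) {
  stopifnot(inherits(table, "study_table"))
  gt <- allocate_genotype(
    as.integer(table$ref_reads),
    as.integer(table$alt_reads),
    as.integer(table$other_reads),
    config
  )
  total <- total_reads(table)
  prv <- ifelse(total > 0L, 100 * table$alt_reads / total, NA_real_)
  call <- matrix(as.character(gt), nrow = nrow(table$sites),
                 dimnames = dimnames(table$ref_reads))
  prv <- matrix(prv, nrow = nrow(table$sites),
                dimnames = dimnames(table$ref_reads))
  prv[call == "FAILED"] <- NA_real_
  structure(
    list(
      sites = table$sites,
      samples = table$samples,
      call = call,
      prv = prv,
      config = config
    ),
    class = "study_calls"
  )
}

#' @export
print.study_calls <- function(x, ...) {
  tab <- table(factor(x$call, levels = .GT_LEVELS))
  cat("study_calls:", nrow(x$sites), "sites x", nrow(x$samples), "samples\n")
  cat("  calls:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}
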