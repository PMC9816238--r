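# In-code fixtures shared across the suite. Everything is generated at test
# time; nothing binary is stored.

# Two-sample, three-site handcrafted table.
tiny_table <- function() {
  sites <- data.frame(
    chrom = "chr1",
    pos = c(100L, 200L, 300L),
    ref = c("C", "G", "A"),
    alt = c("T", "A", "C"),
    stringsAsFactors = FALSE
  )
  samples <- data.frame(
    sample_id = c("blood_none_d0", "blood_none_d21"),
    matrix = "blood",
    condition = "none",
    time_days = c(0L, 21L),
    stringsAsFactors = FALSE
  )
  study_table(
    sites, samples,
    ref_reads = matrix(c(30L, 15L, 29L, 0L, 1L, 0L), 3L, 2L),
    alt_reads = matrix(c(0L, 15L, 1L, 30L, 29L, 0L), 3L, 2L),
    other_reads = matrix(0L, 3L, 2L)
  )
}

# One-series sample sheet at the follow-up-study time points.
series_samples <- function(matrix = "blood", condition = "dry",
                           times = c(0L, 22L, 92L)) {
  data.frame(
    sample_id = paste0(matrix, "_", condition, "_d", times),
    matrix = matrix,
    condition = condition,
    time_days = times,
    stringsAsFactors = FALSE
  )
}

# A study table built from an explicit long data frame of counts.
table_from_rows <- function(rows, samples) {
  study_table_from_long(rows, samples)
}

# Handcrafted multi-sample VCF exercising AD/DP parsing, multi-allelic
# decomposition, missing genotypes and symbolic-allele skipping.
write_fixture_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    paste(c("chr1", "100", ".", "A", "T", ".", ".", ".", "GT:AD:DP",
            "0/1:18,17:35", "0/0:30,0:30"), collapse = "\t"),
    paste(c("chr1", "200", ".", "C", "T,G", ".", ".", ".", "GT:AD:DP",
            "1/2:10,5,5:20", "./.:.:0"), collapse = "\t"),
    paste(c("chr1", "300", ".", "G", "<DEL>", ".", ".", ".", "GT:AD:DP",
            "0/1:12,3:15", "0/0:20,0:20"), collapse = "\t"),
    paste(c("chr1", "400", ".", "G", "*", ".", ".", ".", "GT:AD:DP",
            "0/1:8,2:10", "0/0:9,0:12"), collapse = "\t")
  )
  writeLines(lines, path)
  path
}

fixture_vcf_samples <- function() {
  data.frame(
    sample_id = c("s1", "s2"),
    matrix = "blood",
    condition = "none",
    time_days = c(0L, 21L),
    stringsAsFactors = FALSE
  )
}

# Single-series simulation design for fast unit tests.
small_design <- function(n_sites = 1000L, seed = 20220911L, ...) {
  sim_design(
    n_sites = n_sites,
    series = data.frame(matrix = "blood", condition = "dry",
                        stringsAsFactors = FALSE),
    seed = seed,
    ...
  )
}
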