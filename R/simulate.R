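## Forward simulator of the data-generating process the analysis assumes:
## a donor truth genotype per site, time-dependent hydrolytic deamination
## converting template molecules (C read as T, G as A on the covered
## strand), exponential mean-coverage decay plus a site-dropout process
## producing zero-coverage (failed) calls, a small per-read sequencing
## error background, spanning-deletion accumulation, and planted "ideal"
## marker and homozygote-switch sites shared across matrices and
## conditions.
##
## Damage acts on the per-read conversion probability, not on the genotype
## state, so intermediate PRVs arise naturally: at a deamination-eligible
## site with true alternative-allele fraction g (0, 1/2 or 1), the template
## alt fraction at storage time t is
##     f(t) = g + (1 - g) * d(t),   d(t) = 1 - exp(-lambda * m * t),
## with lambda the per-day site conversion rate and m the humid multiplier.
## Sequencing error mixes alleles symmetrically at rate e per read:
##     p_alt = f (1 - e) + (1 - f) e / 3.

#' Hydrolytic damage model
#'
#' Rates are per day. Defaults are deamination-dominant, chosen to
#' reproduce the qualitative directions of storage damage (a majority of
#' G>A / C>T changes among changed sites, failed-call growth with time,
#' stronger decay under humid storage) at desk scale.
#'
#' @param deam_rate Per-day conversion rate of template C (or G on the
#'   covered strand) at damage-prone sites. Default 0.005.
#' @param marker_rate Elevated conversion rate at planted marker sites,
#'   producing a gradual PRV rise (about 20 percent at day 22, 60 percent
#'   at day 92). Default 0.01.
#' @param switch_rate Conversion rate at planted homozygote-switch sites,
#'   high enough to traverse 0/0 through 0/1 to 1/1 within the study
#'   window. Default 0.06.
#' @param cov_decay_rate Exponential decay rate of mean coverage. Default
#'   0.002.
#' @param dropout_rate Per-day rate of complete site dropout (fragmentation
#'   or damage in the flanking sequence leaving the position with no
#'   coverage at all); drives failed genotype calls. Default 5e-5.
#' @param humid_multiplier Factor >= 1 applied to all damage and decay
#'   rates under humid storage. Default 1.5.
#' @param seq_error_rate Per-read, per-site miscall probability. Default
#'   0.001.
#' @param spandel_rate Per-day rate at which reads over a spanning-deletion
#'   site convert to deletion-supporting evidence. Default 0.003.
#' @return A list of class `damage_model`.
#' @export
damage_model <- function(deam_rate = 0.005,
                         marker_rate = 0.01,
                         switch_rate = 0.06,
                         cov_decay_rate = 0.002,
                         dropout_rate = 5e-5,
                         humid_multiplier = 1.5,
                         seq_error_rate = 0.001,
                         spandel_rate = 0.003) {
  stopifnot(
    deam_rate >= 0, marker_rate >= 0, switch_rate >= 0,
    cov_decay_rate >= 0, dropout_rate >= 0,
    humid_multiplier >= 1, seq_error_rate >= 0, seq_error_rate < 0.01,
    spandel_rate >= 0
  )
  structure(
    list(
      deam_rate = deam_rate,
      marker_rate = marker_rate,
      switch_rate = switch_rate,
      cov_decay_rate = cov_decay_rate,
      dropout_rate = dropout_rate,
      humid_multiplier = humid_multiplier,
      seq_error_rate = seq_error_rate,
      spandel_rate = spandel_rate
    ),
    class = "damage_model"
  )
}

#' Simulation design
#'
#' Study layout: sites, site roles, day-0 genotype frequencies, coverage,
#' time points and (matrix, condition) series. Defaults mirror a storage
#' study sequenced at 30x with samples taken at 0, 22 and 92 days in blood
#' and saliva under dry and humid conditions. Role fractions are allocated
#' by quota (exact counts, largest-remainder rounding).
#'
#' @param n_sites Number of variant sites.
#' @param role_fractions Named fractions (summing to 1) over the site roles
#'   `null` (background only), `damage_prone` (deamination-susceptible at
#'   `deam_rate`), `planted_marker` and `planted_switch`. Planted roles are
#'   always assigned deamination-eligible (C>T or G>A) sites with a 0/0
#'   day-0 genotype.
#' @param spandel_fraction Fraction of sites (taken from the null quota)
#'   carried as spanning-deletion records (`alt = "*"`). Default 0.01.
#' @param genotype_freqs Day-0 genotype frequencies for null and
#'   damage-prone sites, in the order 0/0, 0/1, 1/1.
#' @param mean_coverage Expected depth at day 0. Default 30.
#' @param time_points Storage times in days, starting at 0.
#' @param series Data frame with columns `matrix` and `condition`.
#' @param saliva_prestore_days Effective pre-storage time (days) added to
#'   saliva series, modelling extracellular DNA already damaged at
#'   collection. Default 0 (off).
#' @param seed Master seed; all randomness derives from it.
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(n_sites = 10000L,
                       role_fractions = c(null = 0.85, damage_prone = 0.12,
                                          planted_marker = 0.02,
                                          planted_switch = 0.01),
                       spandel_fraction = 0.01,
                       genotype_freqs = c(0.70, 0.20, 0.10),
                       mean_coverage = 30,
                       time_points = c(0L, 22L, 92L),
                       series = default_series(),
                       saliva_prestore_days = 0,
                       seed = 1L) {
  roles <- c("null", "damage_prone", "planted_marker", "planted_switch")
  if (!all(names(role_fractions) %in% roles)) {
    stop("unknown role in role_fractions")
  }
  full <- setNames(numeric(4L), roles)
  full[names(role_fractions)] <- role_fractions
  if (abs(sum(full) - 1) > 1e-8) stop("role fractions must sum to 1")
  if (spandel_fraction > full[["null"]]) {
    stop("spandel_fraction cannot exceed the null fraction")
  }
  stopifnot(
    n_sites >= 1L, abs(sum(genotype_freqs) - 1) < 1e-8,
    mean_coverage > 0, time_points[1L] == 0L,
    !is.unsorted(time_points, strictly = TRUE),
    saliva_prestore_days >= 0
  )
  validate_series <- unique(series[, c("matrix", "condition")])
  if (nrow(validate_series) != nrow(series)) stop("duplicate series")
  structure(
    list(
      n_sites = as.integer(n_sites),
      role_fractions = full,
      spandel_fraction = spandel_fraction,
      genotype_freqs = genotype_freqs,
      mean_coverage = mean_coverage,
      time_points = as.integer(time_points),
      series = series,
      saliva_prestore_days = saliva_prestore_days,
      seed = as.integer(seed)
    ),
    class = "sim_design"
  )
}

#' Default study series
#'
#' @return Data frame of the four (matrix, condition) series: blood and
#'   saliva, each stored dry and humid.
#' @export
default_series <- function() {
  data.frame(
    matrix = rep(c("blood", "saliva"), each = 2L),
    condition = rep(c("dry", "humid"), times = 2L),
    stringsAsFactors = FALSE
  )
}

## Quota allocation with largest-remainder rounding; returns integer counts
## summing to n.
quota_counts <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0L) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

#' Simulate donor truth sites
#'
#' Draws the site panel: positions, ref/alt alleles, true day-0 genotypes
#' and damage roles. Null sites have reference alleles uniform over
#' A, C, G, T and a uniformly chosen different alternative allele; all
#' deamination-susceptible roles (damage-prone and planted) are C>T or G>A
#' sites. Planted roles are forced to a 0/0 truth genotype so their PRV
#' starts at zero; spanning-deletion sites (carved from the null quota)
#' are 0/0 sites with `alt = "*"`. Reproducible from the design seed.
#'
#' @param design A [sim_design()].
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `genotype`, `role`.
#' @export
simulate_truth <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  n <- design$n_sites
  counts <- quota_counts(n, design$role_fractions)
  names(counts) <- names(design$role_fractions)
  n_spandel <- quota_counts(n, c(design$spandel_fraction,
                                 1 - design$spandel_fraction))[1L]
  roles <- sample(rep(names(counts), counts))
  spandel <- rep(FALSE, n)
  null_idx <- which(roles == "null")
  if (n_spandel > 0L) {
    spandel[null_idx[seq_len(min(n_spandel, length(null_idx)))]] <- TRUE
  }
  ref <- character(n)
  alt <- character(n)
  eligible <- roles != "null"
  ref[eligible] <- sample(c("C", "G"), sum(eligible), replace = TRUE)
  alt[eligible] <- ifelse(ref[eligible] == "C", "T", "A")
  n_null <- sum(!eligible)
  ref[!eligible] <- sample(.BASES, n_null, replace = TRUE)
  alt[!eligible] <- vapply(
    ref[!eligible],
    function(r) sample(setdiff(.BASES, r), 1L),
    ""
  )
  alt[spandel] <- .SPANNING_DELETION
  genotype <- sample(c("0/0", "0/1", "1/1"), n, replace = TRUE,
                     prob = design$genotype_freqs)
  genotype[roles %in% c("planted_marker", "planted_switch")] <- "0/0"
  genotype[spandel] <- "0/0"
  data.frame(
    chrom = "chr1",
    pos = seq_len(n) * 100L,
    ref = ref,
    alt = alt,
    genotype = genotype,
    role = roles,
    stringsAsFactors = FALSE
  )
}

## Site-specific per-day conversion rate implied by role.
role_rates <- function(roles, model) {
  rate <- numeric(length(roles))
  rate[roles == "damage_prone"] <- model$deam_rate
  rate[roles == "planted_marker"] <- model$marker_rate
  rate[roles == "planted_switch"] <- model$switch_rate
  rate
}

## Deterministic sub-seed per (sample, draw stage): draws are generated in
## site order within one vectorised call per stage, so enlarging the site
## panel appends draws without perturbing existing sites.
substream_seed <- function(seed, sample_index, stage) {
  (seed + 7919L * sample_index + 101L * stage) %% 2147483629L
}

#' Simulate read counts under the damage model
#'
#' For every site, series and time point t (with humid multiplier m and,
#' for saliva series, the optional pre-storage offset added to t):
#' a site drops out completely with probability `1 - exp(-dropout_rate m t)`
#' (no coverage, a failed call); otherwise depth is Poisson with mean
#' `mean_coverage * exp(-cov_decay_rate m t)`; the template alt fraction is
#' `g + (1 - g) (1 - exp(-lambda m t))` at deamination-susceptible sites
#' (g the true alt fraction: 0, 1/2 or 1) and `g` elsewhere; sequencing
#' error mixes alleles symmetrically at `seq_error_rate` per read; alt and
#' other read counts are binomial draws from the resulting per-read
#' probabilities. Spanning-deletion sites accumulate deletion-supporting
#' reads at rate `spandel_rate` instead.
#'
#' @param truth Output of [simulate_truth()].
#' @param design The [sim_design()].
#' @param model A [damage_model()].
#' @return A [study_table()]; sample identifiers are
#'   `<matrix>_<condition>_d<time>`.
#' @export
simulate_counts <- function(truth, design, model = damage_model()) {
  stopifnot(inherits(design, "sim_design"), inherits(model, "damage_model"))
  n <- nrow(truth)
  samples <- expand.grid(
    time_days = design$time_points,
    idx = seq_len(nrow(design$series)),
    stringsAsFactors = FALSE
  )
  samples <- data.frame(
    sample_id = paste0(
      design$series$matrix[samples$idx], "_",
      design$series$condition[samples$idx], "_d", samples$time_days
    ),
    matrix = design$series$matrix[samples$idx],
    condition = design$series$condition[samples$idx],
    time_days = as.integer(samples$time_days),
    stringsAsFactors = FALSE
  )
  g <- c("0/0" = 0, "0/1" = 0.5, "1/1" = 1)[truth$genotype]
  lambda <- role_rates(truth$role, model)
  is_spandel <- truth$alt == .SPANNING_DELETION
  e <- model$seq_error_rate
  ref_m <- matrix(0L, n, nrow(samples))
  alt_m <- matrix(0L, n, nrow(samples))
  oth_m <- matrix(0L, n, nrow(samples))
  for (s in seq_len(nrow(samples))) {
    m <- if (samples$condition[s] == "humid") model$humid_multiplier else 1
    t_eff <- samples$time_days[s] +
      if (samples$matrix[s] == "saliva") design$saliva_prestore_days else 0
    set.seed(substream_seed(design$seed, s, 1L))
    dropped <- runif(n) < 1 - exp(-model$dropout_rate * m * t_eff)
    set.seed(substream_seed(design$seed, s, 2L))
    depth <- rpois(n, design$mean_coverage *
                     exp(-model$cov_decay_rate * m * t_eff))
    depth[dropped] <- 0L
    d_t <- 1 - exp(-lambda * m * t_eff)
    f <- g + (1 - g) * d_t
    p_alt <- f * (1 - e) + (1 - f) * e / 3
    p_other <- 2 * e / 3
    if (any(is_spandel)) {
      f_del <- 1 - exp(-model$spandel_rate * m * t_eff)
      p_alt[is_spandel] <- f_del
      p_other_del <- (1 - f_del) * e
      p_other <- rep_len(p_other, n)
      p_other[is_spandel] <- p_other_del
    } else {
      p_other <- rep_len(p_other, n)
    }
    set.seed(substream_seed(design$seed, s, 3L))
    alt_reads <- rbinom(n, depth, p_alt)
    set.seed(substream_seed(design$seed, s, 4L))
    rem <- depth - alt_reads
    other_reads <- rbinom(n, rem, pmin(p_other / pmax(1 - p_alt, 1e-12), 1))
    ref_m[, s] <- rem - other_reads
    alt_m[, s] <- alt_reads
    oth_m[, s] <- other_reads
  }
  study_table(
    sites = truth[, c("chrom", "pos", "ref", "alt")],
    samples = samples,
    ref_reads = ref_m,
    alt_reads = alt_m,
    other_reads = oth_m
  )
}

#' Simulate a complete study
#'
#' Convenience wrapper: [simulate_truth()] followed by
#' [simulate_counts()].
#'
#' @inheritParams simulate_counts
#' @return List with `truth` and `table`.
#' @export
simulate_study <- function(design = sim_design(), model = damage_model()) {
  truth <- simulate_truth(design)
  list(truth = truth, table = simulate_counts(truth, design, model))
}

#' Estimate the deamination rate from homozygous-reference trajectories
#'
#' At a damage-prone 0/0 site the expected PRV at time t is
#' `100 * (1 - exp(-lambda t))`, so the rate is recovered per stored time
#' point as `lambda_hat = -log(1 - mean_PRV(t) / 100) / t`, averaged over
#' stored time points. Observations without coverage are excluded. The
#' estimate assumes the supplied samples experienced no rate multiplier
#' (use dry-condition series, or divide by the humid multiplier yourself).
#'
#' @param table A [study_table()] of damage-prone 0/0 sites (e.g. a
#'   simulated table restricted to that role).
#' @param sample_ids Samples to use; default: all samples with
#'   `time_days > 0`.
#' @return The estimated per-day conversion rate.
#' @export
estimate_deam_rate <- function(table, sample_ids = NULL) {
  stopifnot(inherits(table, "study_table"))
  if (is.null(sample_ids)) {
    sample_ids <- table$samples$sample_id[table$samples$time_days > 0L]
  }
  if (length(sample_ids) == 0L) stop("no stored-time samples supplied")
  times <- table$samples$time_days[match(sample_ids, table$samples$sample_id)]
  if (anyNA(times) || any(times <= 0L)) {
    stop("sample_ids must name stored (time > 0) samples of the table")
  }
  total <- total_reads(table)[, sample_ids, drop = FALSE]
  prv <- 100 * table$alt_reads[, sample_ids, drop = FALSE] /
    ifelse(total > 0L, total, NA_integer_)
  mean_prv <- colMeans(prv, na.rm = TRUE)
  if (any(mean_prv >= 100)) {
    stop("mean PRV at or above 100 percent: rate is unidentifiable")
  }
  mean(-log(1 - mean_prv / 100) / times)
}

#' Write a simulated study as VCF plus truth sidecar
#'
#' Writes the table with [write_vcf()] and the planted truth (site, role,
#' true genotype) as a TSV sidecar at `<path>.truth.tsv`. Reading the VCF
#' back with [read_vcf()] reproduces the study table exactly; output bytes
#' are deterministic.
#'
#' @param table A simulated [study_table()].
#' @param truth The matching [simulate_truth()] output.
#' @param path Output VCF path.
#' @return Invisibly, the path.
#' @export
write_simulated_vcf <- function(table, truth, path) {
  write_vcf(table, path)
  ord <- genomic_order(truth)
  write_tsv(
    truth[ord, c("chrom", "pos", "ref", "alt", "genotype", "role")],
    paste0(path, ".truth.tsv")
  )
  invisible(path)
}
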