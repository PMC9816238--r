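## Stepwise candidate-marker nomination for time-since-deposition (TsD)
## estimation: restrict to the deamination-type base changes (G>A, C>T),
## require a homozygous day-0 genotype, enforce a minimum read-count
## threshold at every observation of the site, and keep only sites whose
## PRV drifts gradually in the same direction in every required series.

#' Marker filter configuration
#'
#' @param min_total_reads Read-count threshold applied to every sample of
#'   every retained series at a site. Default 10, the threshold used to
#'   eliminate changes explicable by sequencing error.
#' @param depth_mode `"total"` applies the threshold to total depth (the
#'   default interpretation); `"alt"` applies it to variant-allele reads
#'   instead.
#' @param allowed_changes Character vector of `"ref>alt"` substitutions to
#'   retain. Default `c("C>T", "G>A")`, the deamination signature.
#' @param require_day0_homozygous Keep only sites whose day-0 call is 0/0
#'   or 1/1 in every retained series. Default `TRUE`.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_total_reads = 10L,
                          depth_mode = c("total", "alt"),
                          allowed_changes = c("C>T", "G>A"),
                          require_day0_homozygous = TRUE) {
  depth_mode <- match.arg(depth_mode)
  stopifnot(min_total_reads >= 1L)
  structure(
    list(
      min_total_reads = as.integer(min_total_reads),
      depth_mode = depth_mode,
      allowed_changes = allowed_changes,
      require_day0_homozygous = isTRUE(require_day0_homozygous)
    ),
    class = "filter_config"
  )
}

#' Sites that changed between day 0 and storage
#'
#' A site is changed when, in any series, its genotype call at a stored
#' time point differs from the day-0 call (both calls non-FAILED). With a
#' numeric `prv_tol`, PRV drift beyond that many percentage points relative
#' to day 0 also counts as a change even when the call is unchanged; the
#' default (`NULL`) counts call changes only, so that read-sampling noise
#' at heterozygous sites does not register as change. Sites whose only
#' difference from day 0 is loss of coverage are reported separately as
#' failed-onset sites, never as changed sites.
#'
#' @param calls A `study_calls` object from [call_study()].
#' @param prv_tol Optional PRV drift tolerance (percentage points).
#' @return List with data frames `changed` and `failed_only` (site rows),
#'   plus `n_changed` / `n_failed_only`.
#' @export
changed_sites <- function(calls, prv_tol = NULL) {
  stopifnot(inherits(calls, "study_calls"))
  series <- study_series(calls$samples)
  n <- nrow(calls$sites)
  changed <- rep(FALSE, n)
  failed <- rep(FALSE, n)
  for (i in seq_len(nrow(series))) {
    ids <- series_sample_ids(calls$samples, series$matrix[i],
                             series$condition[i])
    day0 <- calls$call[, ids[1L]]
    later <- calls$call[, ids[-1L], drop = FALSE]
    ok0 <- day0 != "FAILED"
    call_change <- ok0 & rowSums(later != day0 & later != "FAILED") > 0L
    if (!is.null(prv_tol)) {
      prv0 <- calls$prv[, ids[1L]]
      drift <- abs(calls$prv[, ids[-1L], drop = FALSE] - prv0) > prv_tol
      call_change <- call_change |
        (ok0 & rowSums(drift, na.rm = TRUE) > 0L)
    }
    changed <- changed | call_change
    failed <- failed | (ok0 & rowSums(later == "FAILED") > 0L)
  }
  failed_only <- failed & !changed
  list(
    changed = calls$sites[changed, , drop = FALSE],
    failed_only = calls$sites[failed_only, , drop = FALSE],
    n_changed = sum(changed),
    n_failed_only = sum(failed_only)
  )
}

#' Apply the stepwise marker filters
#'
#' Gates, in order: (1) substitution spectrum — the site's `ref>alt` pair
#' must be in `allowed_changes`; (2) day-0 genotype — homozygous in every
#' retained series when required; (3) read-count threshold — every
#' observation of the site, in every sample of every retained series, must
#' reach `min_total_reads` (inclusive). Attrition at each gate is reported.
#'
#' @param table The [study_table()] of raw counts.
#' @param calls The matching `study_calls` object.
#' @param sites Data frame of candidate input sites (subset of
#'   `table$sites`, e.g. the changed sites); defaults to all sites.
#' @param config A [filter_config()].
#' @param series Data frame of series to consider (columns `matrix`,
#'   `condition`); defaults to all.
#' @return List with `sites` (survivors, genomic order) and `attrition`
#'   (data frame: stage, n_in, n_removed, n_out).
#' @export
apply_filters <- function(table, calls, sites = NULL,
                          config = filter_config(), series = NULL) {
  stopifnot(inherits(table, "study_table"), inherits(calls, "study_calls"))
  if (is.null(sites)) sites <- table$sites
  if (is.null(series)) series <- study_series(table$samples)
  ids <- site_id(sites$chrom, sites$pos, sites$ref, sites$alt)
  sample_ids <- unlist(lapply(seq_len(nrow(series)), function(i) {
    series_sample_ids(table$samples, series$matrix[i], series$condition[i])
  }))
  day0_ids <- vapply(seq_len(nrow(series)), function(i) {
    series_sample_ids(table$samples, series$matrix[i], series$condition[i])[1L]
  }, "")
  attrition <- data.frame(
    stage = character(), n_in = integer(), n_removed = integer(),
    n_out = integer(), stringsAsFactors = FALSE
  )
  gate <- function(keep, stage, current) {
    attrition[nrow(attrition) + 1L, ] <<- list(
      stage, length(current), sum(!keep), sum(keep)
    )
    current[keep]
  }

  current <- ids
  change <- paste(sites$ref, sites$alt, sep = ">")
  names(change) <- ids
  current <- gate(change[current] %in% config$allowed_changes,
                  "spectrum", current)

  if (config$require_day0_homozygous) {
    hom <- matrix(
      calls$call[current, day0_ids, drop = FALSE] %in% c("0/0", "1/1"),
      nrow = length(current)
    )
    current <- gate(rowSums(hom) == length(day0_ids), "day0_homozygous",
                    current)
  }

  depth <- if (config$depth_mode == "total") {
    total_reads(table)
  } else {
    table$alt_reads
  }
  deep <- matrix(
    depth[current, sample_ids, drop = FALSE] >= config$min_total_reads,
    nrow = length(current)
  )
  current <- gate(rowSums(deep) == length(sample_ids), "read_threshold",
                  current)

  keep_rows <- match(current, ids)
  out <- sites[keep_rows, , drop = FALSE]
  out <- out[genomic_order(out), , drop = FALSE]
  rownames(out) <- NULL
  list(sites = out, attrition = attrition)
}

#' Select cross-series concordant candidate markers
#'
#' A site becomes a candidate marker when its PRV trajectory is gradual
#' (per [is_gradual()]) with the same direction in every required series.
#' Sites with a FAILED call in any required series carry undefined PRVs and
#' are skipped (counted in `n_skipped_failed`).
#'
#' @param calls A `study_calls` object.
#' @param sites Data frame of sites to consider (typically the survivors of
#'   [apply_filters()]).
#' @param config A [monotone_config()].
#' @param series Data frame of required series (columns `matrix`,
#'   `condition`); defaults to all series of the study.
#' @return List with `markers` — a data frame sorted by genomic position
#'   with site columns, `direction`, `day0_genotype`, and one
#'   `prv_<matrix>_<condition>_d<t>` column per series sample — and
#'   `n_skipped_failed`.
#' @export
select_candidates <- function(calls, sites, config = monotone_config(),
                              series = NULL) {
  stopifnot(inherits(calls, "study_calls"))
  if (is.null(series)) series <- study_series(calls$samples)
  sites <- sites[genomic_order(sites), , drop = FALSE]
  ids <- site_id(sites$chrom, sites$pos, sites$ref, sites$alt)
  n <- length(ids)
  dir_mat <- matrix(NA_character_, nrow = n, ncol = nrow(series))
  prv_cols <- list()
  any_failed <- rep(FALSE, n)
  for (i in seq_len(nrow(series))) {
    sids <- series_sample_ids(calls$samples, series$matrix[i],
                              series$condition[i])
    prv <- calls$prv[ids, sids, drop = FALSE]
    any_failed <- any_failed | rowSums(is.na(prv)) > 0L
    dir_mat[, i] <- gradual_direction(prv, config)
    times <- calls$samples$time_days[match(sids, calls$samples$sample_id)]
    colnames(prv) <- paste0(
      "prv_", series$matrix[i], "_", series$condition[i], "_d", times
    )
    prv_cols[[i]] <- prv
  }
  eligible <- !any_failed
  concordant <- eligible &
    rowSums(is.na(dir_mat)) == 0L &
    apply(dir_mat, 1L, function(d) length(unique(d)) == 1L)
  concordant[is.na(concordant)] <- FALSE
  day0_first <- series_sample_ids(calls$samples, series$matrix[1L],
                                  series$condition[1L])[1L]
  markers <- data.frame(
    sites[concordant, , drop = FALSE],
    direction = dir_mat[concordant, 1L],
    day0_genotype = calls$call[ids[concordant], day0_first],
    stringsAsFactors = FALSE
  )
  for (prv in prv_cols) {
    markers <- cbind(
      markers,
      as.data.frame(round(prv[concordant, , drop = FALSE], 4L))
    )
  }
  rownames(markers) <- NULL
  list(markers = markers, n_skipped_failed = sum(any_failed))
}

#' Homozygote-switch sites
#'
#' Sites whose genotype traverses from one homozygote through the
#' heterozygote to the opposite homozygote across the three time points of
#' a series, plus the sites shared between series (the cross-condition
#' intersection).
#'
#' @param trajectories Output of [classify_trajectories()].
#' @return List with `per_series` (site, matrix, condition, direction) and
#'   `shared` (sites switching in more than one series, with the number of
#'   series and the direction).
#' @export
homozygote_switches <- function(trajectories) {
  sw <- trajectories[
    trajectories$label %in% c("HOM_SWITCH_UP", "HOM_SWITCH_DOWN"), ,
    drop = FALSE
  ]
  per_series <- data.frame(
    sw[, c("chrom", "pos", "ref", "alt", "matrix", "condition")],
    direction = ifelse(sw$label == "HOM_SWITCH_UP", "up", "down"),
    stringsAsFactors = FALSE
  )
  rownames(per_series) <- NULL
  if (nrow(per_series) == 0L) {
    shared <- data.frame(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), direction = character(), n_series = integer(),
      stringsAsFactors = FALSE
    )
  } else {
    key <- site_id(per_series$chrom, per_series$pos, per_series$ref,
                   per_series$alt)
    tab <- table(key)
    multi <- names(tab)[tab > 1L]
    idx <- match(multi, key)
    shared <- data.frame(
      per_series[idx, c("chrom", "pos", "ref", "alt", "direction")],
      n_series = as.integer(tab[multi]),
      stringsAsFactors = FALSE
    )
    shared <- shared[genomic_order(shared), , drop = FALSE]
    rownames(shared) <- NULL
  }
  list(per_series = per_series, shared = shared)
}
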