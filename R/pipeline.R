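## End-to-end orchestration, mirroring the stepwise analysis narrative:
## (1) genotype allocation and distribution tables, (2) failed-call counts,
## (3) homozygote switches, (4) base-change spectra of changed sites,
## (5) deamination-focused filtering with the read-count threshold,
## (6) gradual-PRV candidate markers concordant across series, plus a
## statistics summary and a machine-readable run manifest. Every number in
## the written reports comes from a table in the returned bundle.

#' Pipeline configuration
#'
#' @param calling A [calling_config()].
#' @param monotone A [monotone_config()].
#' @param filters A [filter_config()].
#' @param required_series Data frame (`matrix`, `condition`) of series a
#'   candidate marker must hold in; `NULL` means all series present.
#' @param prv_tol Optional PRV drift tolerance for [changed_sites()]
#'   (percentage points); `NULL` counts genotype-call changes only.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic; the seed matters when the input table was simulated).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(calling = calling_config(),
                            monotone = monotone_config(),
                            filters = filter_config(),
                            required_series = NULL,
                            prv_tol = NULL,
                            seed = NULL) {
  structure(
    list(
      calling = calling,
      monotone = monotone,
      filters = filters,
      required_series = required_series,
      prv_tol = prv_tol,
      seed = seed
    ),
    class = "pipeline_config"
  )
}

#' Run the full degradation-SNV analysis
#'
#' @param table A [study_table()] (from [read_vcf()],
#'   [read_counts_table()] or [simulate_counts()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every bundle table is
#'   written as a TSV plus a JSON manifest, deterministically (identical
#'   inputs give byte-identical files).
#' @return A list bundle: `calls`, `genotype_distribution`,
#'   `failed_calls`, `trajectory_classes` (counts per series and label),
#'   `trajectories`, `homozygote_switches`, `changed`, `spectra`
#'   (per-series spectrum of changed sites), `attrition`, `candidates`,
#'   `stats`, `manifest`.
#' @export
run_pipeline <- function(table, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(table, "study_table"))
  series <- study_series(table$samples)
  required <- if (is.null(config$required_series)) series else
    config$required_series

  calls <- call_study(table, config$calling)

  ## genotype distribution per sample (the genotypes-over-time table)
  dist <- do.call(rbind, lapply(seq_len(nrow(calls$samples)), function(j) {
    tab <- base::table(factor(calls$call[, j], levels = .GT_LEVELS))
    cbind(
      calls$samples[j, , drop = FALSE],
      as.data.frame(as.list(setNames(as.integer(tab), c(
        "hom_ref", "het", "hom_alt", "failed"
      ))))
    )
  }))
  rownames(dist) <- NULL

  failed <- count_failed_calls(calls)

  trajectories <- classify_trajectories(calls, series)
  class_counts <- as.data.frame(
    base::table(
      matrix = trajectories$matrix,
      condition = trajectories$condition,
      label = factor(trajectories$label, levels = .TRAJECTORY_LEVELS)
    ),
    stringsAsFactors = FALSE
  )
  names(class_counts)[names(class_counts) == "Freq"] <- "count"
  class_counts <- class_counts[
    order(class_counts$matrix, class_counts$condition, class_counts$label), ]
  rownames(class_counts) <- NULL

  switches <- homozygote_switches(trajectories)

  changed <- changed_sites(calls, prv_tol = config$prv_tol)

  ## spectrum of changed sites, per series the site changed in
  spectra <- do.call(rbind, lapply(seq_len(nrow(series)), function(i) {
    sub <- trajectories[
      trajectories$matrix == series$matrix[i] &
        trajectories$condition == series$condition[i] &
        !trajectories$label %in% c("STABLE", "FAILED_ONSET"), , drop = FALSE]
    sp <- spectrum_counts(sub)
    cbind(
      matrix = series$matrix[i], condition = series$condition[i], sp,
      stringsAsFactors = FALSE
    )
  }))
  rownames(spectra) <- NULL

  filtered <- apply_filters(
    table, calls, sites = changed$changed,
    config = config$filters, series = required
  )

  selected <- select_candidates(
    calls, filtered$sites, config = config$monotone, series = required
  )

  stats <- pipeline_stats(calls, trajectories, selected$markers, required)

  manifest <- list(
    package = "snvdrift",
    version = as.character(packageVersion("snvdrift")),
    seed = config$seed,
    n_sites = nrow(table$sites),
    n_samples = nrow(table$samples),
    calling = unclass(config$calling),
    monotone = unclass(config$monotone),
    filters = unclass(config$filters),
    prv_tol = config$prv_tol,
    n_changed = changed$n_changed,
    n_failed_only = changed$n_failed_only,
    n_candidates = nrow(selected$markers),
    excluded_day0_failed = as.list(attr(trajectories, "excluded_day0_failed"))
  )

  bundle <- list(
    calls = calls,
    genotype_distribution = dist,
    failed_calls = failed,
    trajectory_classes = class_counts,
    trajectories = trajectories,
    homozygote_switches = switches,
    changed = changed,
    spectra = spectra,
    attrition = filtered$attrition,
    candidates = selected$markers,
    stats = stats,
    manifest = manifest
  )
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

## Statistics summary: one-way ANOVA of candidate PRVs across time points
## and a rank-sum comparison of the two latest stored times, pooled over
## candidate sites per series; plus, when both matrices are present, a
## Pearson chi-squared comparison of spanning-deletion versus substitution
## changes between matrices. All p-values unadjusted.
pipeline_stats <- function(calls, trajectories, markers, series) {
  rows <- list()
  for (i in seq_len(nrow(series))) {
    sids <- series_sample_ids(calls$samples, series$matrix[i],
                              series$condition[i])
    times <- calls$samples$time_days[match(sids, calls$samples$sample_id)]
    cols <- paste0("prv_", series$matrix[i], "_", series$condition[i],
                   "_d", times)
    if (nrow(markers) < 2L || !all(cols %in% names(markers))) next
    groups <- lapply(seq_along(cols), function(j) markers[[cols[j]]])
    names(groups) <- paste0("d", times)
    fit <- tryCatch(prv_anova(groups), error = function(e) NULL)
    if (!is.null(fit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = paste0("candidate PRV by time (", series$matrix[i],
                            ", ", series$condition[i], ")"),
        test = "one-way ANOVA",
        statistic = fit$F, p.value = fit$p.value,
        n = sum(fit$n), stringsAsFactors = FALSE
      )
    }
    k <- length(cols)
    mw <- tryCatch(
      prv_rank_test(markers[[cols[k - 1L]]], markers[[cols[k]]]),
      error = function(e) NULL
    )
    if (!is.null(mw)) {
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = paste0("candidate PRV d", times[k - 1L], " vs d",
                            times[k], " (", series$matrix[i], ", ",
                            series$condition[i], ")"),
        test = "Mann-Whitney U",
        statistic = mw$U, p.value = mw$p.value,
        n = sum(mw$n), stringsAsFactors = FALSE
      )
    }
  }
  matrices <- unique(series$matrix)
  if (length(matrices) == 2L) {
    tab <- vapply(matrices, function(m) {
      sub <- trajectories[
        trajectories$matrix == m &
          !trajectories$label %in% c("STABLE", "FAILED_ONSET"), ,
        drop = FALSE]
      spandel <- sum(sub$alt == .SPANNING_DELETION)
      c(spandel = spandel, substitution = nrow(sub) - spandel)
    }, c(spandel = 0, substitution = 0))
    chi <- tryCatch(counts_chisq(t(tab)), error = function(e) NULL)
    if (!is.null(chi)) {
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = paste0(
          "spanning-deletion share of changes, ",
          paste(matrices, collapse = " vs ")
        ),
        test = "Pearson chi-squared",
        statistic = chi$statistic, p.value = chi$p.value,
        n = sum(tab), stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(
      comparison = character(), test = character(), statistic = numeric(),
      p.value = numeric(), n = integer(), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Deterministic TSV + JSON serialisation of a report bundle.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(name) file.path(out_dir, name)
  write_tsv(bundle$genotype_distribution, p("genotype_distribution.tsv"))
  write_tsv(bundle$failed_calls, p("failed_calls.tsv"))
  write_tsv(bundle$trajectory_classes, p("trajectory_classes.tsv"))
  write_tsv(bundle$homozygote_switches$per_series,
            p("homozygote_switches.tsv"))
  write_tsv(bundle$homozygote_switches$shared,
            p("homozygote_switches_shared.tsv"))
  write_tsv(bundle$changed$changed, p("changed_sites.tsv"))
  write_tsv(bundle$changed$failed_only, p("failed_onset_sites.tsv"))
  write_tsv(bundle$spectra, p("spectra.tsv"))
  write_tsv(bundle$attrition, p("filter_attrition.tsv"))
  write_tsv(bundle$candidates, p("candidate_markers.tsv"))
  write_tsv(bundle$stats, p("stats_summary.tsv"))
  jsonlite::write_json(
    bundle$manifest, p("manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA
  )
  invisible(out_dir)
}
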