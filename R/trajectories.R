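## Per-site temporal behaviour within one (matrix, condition) series: the
## day-0 sample is the truth reference; later samples are compared against
## it. Trajectory labels partition all sites with a non-FAILED day-0 call.

.TRAJECTORY_LEVELS <- c(
  "STABLE", "GAIN_HET", "LOSS_HET", "RESOLVE_TO_HOM",
  "HOM_SWITCH_UP", "HOM_SWITCH_DOWN", "FAILED_ONSET", "OTHER"
)

#' Trajectory class labels
#'
#' @return Character vector of the trajectory class vocabulary: `STABLE`
#'   (first and last calls identical), `GAIN_HET` (0/0 to 0/1), `LOSS_HET`
#'   (1/1 to 0/1), `RESOLVE_TO_HOM` (0/1 to either homozygote),
#'   `HOM_SWITCH_UP` (the exact 0/0, 0/1, 1/1 three-step pattern),
#'   `HOM_SWITCH_DOWN` (1/1, 0/1, 0/0), `FAILED_ONSET` (coverage lost at
#'   any later time point) and `OTHER`.
#' @export
trajectory_levels <- function() .TRAJECTORY_LEVELS

#' Classify one call trajectory
#'
#' Labels an ordered vector of genotype calls (day 0 first). A FAILED call
#' at any later time point pre-empts every other label (`FAILED_ONSET`);
#' the two exact homozygote-switch patterns over three time points are
#' recognised next; otherwise the (first, last) call pair decides, and any
#' remaining pattern (e.g. a direct 0/0 to 1/1 jump without the
#' intermediate heterozygote) is `OTHER`. A trajectory whose day-0 call is
#' FAILED has no truth reference and is an error here; study-level
#' classification excludes such sites with a count.
#'
#' @param calls Character vector (length >= 2) of [genotype_levels()],
#'   ordered by time with day 0 first.
#' @return A single trajectory label.
#' @export
classify_trajectory <- function(calls) {
  calls <- as.character(calls)
  if (length(calls) < 2L) stop("a trajectory needs at least two time points")
  if (!all(calls %in% .GT_LEVELS)) stop("unknown genotype call")
  if (calls[1L] == "FAILED") {
    stop("day-0 call is FAILED: no truth reference for this site")
  }
  classify_call_matrix(matrix(calls, nrow = 1L))[1L]
}

## Vectorised classifier over a sites x time-points call matrix.
classify_call_matrix <- function(call_mat) {
  k <- ncol(call_mat)
  first <- call_mat[, 1L]
  last <- call_mat[, k]
  out <- rep("OTHER", nrow(call_mat))
  out[first == last] <- "STABLE"
  out[first == "0/0" & last == "0/1"] <- "GAIN_HET"
  out[first == "1/1" & last == "0/1"] <- "LOSS_HET"
  out[first == "0/1" & last %in% c("0/0", "1/1")] <- "RESOLVE_TO_HOM"
  if (k == 3L) {
    mid <- call_mat[, 2L]
    out[first == "0/0" & mid == "0/1" & last == "1/1"] <- "HOM_SWITCH_UP"
    out[first == "1/1" & mid == "0/1" & last == "0/0"] <- "HOM_SWITCH_DOWN"
  }
  later_failed <- rowSums(call_mat[, -1L, drop = FALSE] == "FAILED") > 0L
  out[later_failed] <- "FAILED_ONSET"
  out[first == "FAILED"] <- NA_character_
  out
}

## Sample identifiers of one series, ordered by storage time.
series_sample_ids <- function(samples, matrix, condition) {
  rows <- samples[samples$matrix == matrix & samples$condition == condition, ,
                  drop = FALSE]
  if (nrow(rows) < 2L) {
    stop("series (", matrix, ", ", condition, ") has fewer than 2 time points")
  }
  rows <- rows[order(rows$time_days), , drop = FALSE]
  if (rows$time_days[1L] != 0L) {
    stop("series (", matrix, ", ", condition, ") lacks a day-0 sample")
  }
  rows$sample_id
}

#' Enumerate the (matrix, condition) series of a sample sheet
#'
#' @param samples Sample metadata data frame.
#' @return Data frame with columns `matrix` and `condition`, one row per
#'   series.
#' @export
study_series <- function(samples) {
  s <- unique(samples[, c("matrix", "condition")])
  s <- s[order(s$matrix, s$condition), , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' Classify every site trajectory of a called study
#'
#' Applies [classify_trajectory()] to every site in every (matrix,
#' condition) series. Sites whose day-0 call is FAILED carry no truth
#' reference; they are excluded and counted in the `excluded_day0_failed`
#' attribute (a named count per series).
#'
#' @param calls A `study_calls` object from [call_study()].
#' @param series Optional data frame of series to classify (columns
#'   `matrix`, `condition`); defaults to all series present.
#' @return Data frame with one row per (site, series): site columns,
#'   `matrix`, `condition`, `label`, and the per-time-point calls and PRVs
#'   as list-independent columns `call_d<t>` / `prv_d<t>`.
#' @export
classify_trajectories <- function(calls, series = NULL) {
  stopifnot(inherits(calls, "study_calls"))
  if (is.null(series)) series <- study_series(calls$samples)
  out <- vector("list", nrow(series))
  excluded <- integer(nrow(series))
  names(excluded) <- paste(series$matrix, series$condition, sep = "/")
  for (i in seq_len(nrow(series))) {
    ids <- series_sample_ids(calls$samples, series$matrix[i],
                             series$condition[i])
    cm <- calls$call[, ids, drop = FALSE]
    labels <- classify_call_matrix(cm)
    keep <- !is.na(labels)
    excluded[i] <- sum(!keep)
    times <- calls$samples$time_days[match(ids, calls$samples$sample_id)]
    df <- data.frame(
      calls$sites[keep, , drop = FALSE],
      matrix = series$matrix[i],
      condition = series$condition[i],
      label = labels[keep],
      stringsAsFactors = FALSE
    )
    for (j in seq_along(ids)) {
      df[[paste0("call_d", times[j])]] <- cm[keep, j]
      df[[paste0("prv_d", times[j])]] <- calls$prv[keep, ids[j]]
    }
    out[[i]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "excluded_day0_failed") <- excluded
  res
}

#' Count failed genotype calls per sample
#'
#' A failed call is a (site, sample) observation with no sequencing
#' coverage.
#'
#' @param calls A `study_calls` object.
#' @return The sample sheet with an extra `n_failed` column.
#' @export
count_failed_calls <- function(calls) {
  stopifnot(inherits(calls, "study_calls"))
  out <- calls$samples
  out$n_failed <- as.integer(colSums(calls$call == "FAILED"))
  out
}

#' Genotype transition counts between two time points
#'
#' Cross-tabulates day-0 calls against calls at a later time point over the
#' same site set, in the spirit of a genotype-distribution-over-time table.
#'
#' @param day0_calls,later_calls Vectors of [genotype_levels()] over the
#'   same sites, in the same order (names, when present, must agree).
#' @return A 4 x 4 integer matrix; rows are day-0 genotypes, columns the
#'   later genotypes; entries sum to the number of sites.
#' @export
genotype_transition_counts <- function(day0_calls, later_calls) {
  if (length(day0_calls) != length(later_calls)) {
    stop("site sets differ between the two time points")
  }
  if (!is.null(names(day0_calls)) && !is.null(names(later_calls)) &&
      !identical(names(day0_calls), names(later_calls))) {
    stop("site sets differ between the two time points")
  }
  tab <- table(
    day0 = factor(as.character(day0_calls), levels = .GT_LEVELS),
    later = factor(as.character(later_calls), levels = .GT_LEVELS)
  )
  m <- matrix(as.integer(tab), 4L, 4L, dimnames = dimnames(tab))
  m
}

#' Classify the base change of a variant site
#'
#' Deterministic mapping of the (ref, alt) pair, on the reference strand:
#' G>A and C>T are type 2 transitions (the deamination signature), A>G and
#' T>C type 1 transitions, `"*"` a spanning deletion, and every other base
#' pair a transversion.
#'
#' @param ref,alt Allele vectors.
#' @return Factor with levels `TYPE1_TRANSITION`, `TYPE2_TRANSITION`,
#'   `TRANSVERSION`, `SPANNING_DELETION`.
#' @export
classify_base_change <- function(ref, alt) {
  out <- rep("TRANSVERSION", length(ref))
  out[(ref == "G" & alt == "A") | (ref == "C" & alt == "T")] <-
    "TYPE2_TRANSITION"
  out[(ref == "A" & alt == "G") | (ref == "T" & alt == "C")] <-
    "TYPE1_TRANSITION"
  out[alt == .SPANNING_DELETION] <- "SPANNING_DELETION"
  factor(out, levels = .BASE_CHANGE_LEVELS)
}

#' Base-change spectrum of a site set
#'
#' Counts sites per substitution category: the 12 ordered single-base
#' substitutions plus the spanning deletion. Strands are not folded by
#' default (G>A and C>T are reported separately); `fold_strands = TRUE`
#' aggregates each substitution with its reverse complement (the
#' "or vice versa" grouping), halving the table to 6 substitution classes.
#'
#' @param sites Data frame with `ref` and `alt` columns.
#' @param fold_strands Aggregate reverse-complement pairs. Default `FALSE`.
#' @return Data frame with columns `change`, `class`, `count`; counts sum
#'   to `nrow(sites)`.
#' @export
spectrum_counts <- function(sites, fold_strands = FALSE) {
  pairs <- expand.grid(ref = .BASES, alt = .BASES, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  pairs <- pairs[order(pairs$ref, pairs$alt), ]
  levels_chr <- c(paste(pairs$ref, pairs$alt, sep = ">"), .SPANNING_DELETION)
  obs <- ifelse(
    sites$alt == .SPANNING_DELETION,
    .SPANNING_DELETION,
    paste(sites$ref, sites$alt, sep = ">")
  )
  counts <- table(factor(obs, levels = levels_chr))
  out <- data.frame(
    change = levels_chr,
    class = as.character(classify_base_change(
      c(pairs$ref, "N"), c(pairs$alt, .SPANNING_DELETION)
    )),
    count = as.integer(counts),
    stringsAsFactors = FALSE
  )
  if (fold_strands) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    fold_key <- vapply(seq_len(nrow(out)), function(i) {
      ch <- out$change[i]
      if (ch == .SPANNING_DELETION) return(ch)
      r <- substr(ch, 1L, 1L)
      a <- substr(ch, 3L, 3L)
      rc <- paste(comp[[r]], comp[[a]], sep = ">")
      paste(sort(c(ch, rc)), collapse = "/")
    }, "")
    agg <- tapply(out$count, fold_key, sum)
    cls <- tapply(out$class, fold_key, `[`, 1L)
    out <- data.frame(
      change = names(agg),
      class = as.character(cls),
      count = as.integer(agg),
      stringsAsFactors = FALSE
    )
    out <- out[order(out$class, out$change), ]
    rownames(out) <- NULL
  }
  out
}

#' Monotone-drift configuration
#'
#' Formalises a "gradual" PRV change as tolerance-bounded monotonicity plus
#' a minimum total excursion.
#'
#' @param direction `"increasing"`, `"decreasing"` or `"either"`.
#' @param min_total_delta Minimum absolute PRV difference (percentage
#'   points) between the last and first time point. Default 20.
#' @param per_step_tolerance Maximum backsliding (percentage points)
#'   allowed per step against the trend. Default 2.
#' @return A list of class `monotone_config`.
#' @export
monotone_config <- function(direction = c("either", "increasing", "decreasing"),
                            min_total_delta = 20,
                            per_step_tolerance = 2) {
  direction <- match.arg(direction)
  stopifnot(min_total_delta > 0, per_step_tolerance >= 0)
  structure(
    list(
      direction = direction,
      min_total_delta = min_total_delta,
      per_step_tolerance = per_step_tolerance
    ),
    class = "monotone_config"
  )
}

## Vectorised gradual-drift test over a sites x time-points PRV matrix.
## Returns "increasing", "decreasing" or NA per row; rows containing NA
## PRVs yield NA.
gradual_direction <- function(prv_mat, config = monotone_config()) {
  k <- ncol(prv_mat)
  steps <- prv_mat[, -1L, drop = FALSE] - prv_mat[, -k, drop = FALSE]
  total <- prv_mat[, k] - prv_mat[, 1L]
  tol <- config$per_step_tolerance
  inc <- rowSums(steps < -tol) == 0L & total >= config$min_total_delta
  dec <- rowSums(steps > tol) == 0L & -total >= config$min_total_delta
  if (config$direction == "increasing") dec <- dec & FALSE
  if (config$direction == "decreasing") inc <- inc & FALSE
  ifelse(inc, "increasing", ifelse(dec, "decreasing", NA_character_))
}

#' Test a PRV trajectory for gradual monotone drift
#'
#' A trajectory is gradual when its PRVs are monotone in the stated
#' direction — allowing `per_step_tolerance` percentage points of
#' backsliding per step — and the total excursion `|last - first|` reaches
#' `min_total_delta`. All PRVs must be defined (no FAILED calls).
#'
#' @param prvs Numeric vector of PRVs ordered by time, day 0 first.
#' @param config A [monotone_config()].
#' @return List with elements `gradual` (logical) and `direction`
#'   (`"increasing"`, `"decreasing"`, or `NA` when not gradual).
#' @export
is_gradual <- function(prvs, config = monotone_config()) {
  if (anyNA(prvs)) {
    stop("undefined PRV in trajectory: gradual drift requires full coverage")
  }
  if (length(prvs) < 2L) stop("a trajectory needs at least two time points")
  dir <- gradual_direction(matrix(prvs, nrow = 1L), config)[1L]
  list(gradual = !is.na(dir), direction = dir)
}
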