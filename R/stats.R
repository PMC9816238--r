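## Statistical comparisons used in the reporting layer: rank-sum comparison
## of PRV between storage times, one-way analysis of variance of PRV across
## time points, and a Pearson contingency test for spanning-deletion
## proportions. All p-values are reported unadjusted; an optional
## Benjamini-Hochberg step is available to callers via stats::p.adjust but
## is never applied implicitly.

#' Mann-Whitney U test on two PRV samples
#'
#' Rank-sum comparison with midrank ties. Small tie-free samples use exact
#' enumeration of rank assignments; larger or tied samples use the normal
#' approximation with tie correction (the standard behaviour of
#' [stats::wilcox.test()], which provides the computation).
#'
#' @param x,y Non-empty numeric vectors of PRVs.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` (default) chooses exact for tie-free samples with fewer than 50
#'   observations each.
#' @return List with `U` (the U statistic for `x` versus `y`), `p.value`,
#'   `n` (the two sample sizes) and `method`.
#' @export
prv_rank_test <- function(x, y, alternative = "two.sided", exact = NULL) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty")
  }
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = FALSE)
  )
  list(
    U = unname(res$statistic),
    p.value = res$p.value,
    n = c(length(x), length(y)),
    method = res$method
  )
}

#' One-way analysis of variance of PRV across groups
#'
#' Classical fixed-effects one-way ANOVA: F is the ratio of the
#' between-group to the within-group mean square, with the p-value from
#' the F distribution (computed by [stats::oneway.test()] with equal
#' variances assumed, i.e. the textbook decomposition).
#'
#' @param groups Named list of numeric PRV vectors, one per group (e.g. one
#'   per storage time point); at least two groups, total n greater than the
#'   number of groups.
#' @return List with `F`, `p.value`, `df` (between, within) and `n` per
#'   group.
#' @export
prv_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("ANOVA needs at least two groups")
  }
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stop("every group must be non-empty")
  values <- unlist(groups, use.names = FALSE)
  if (length(values) <= length(groups)) {
    stop("total n must exceed the number of groups")
  }
  g <- factor(rep(seq_along(groups), sizes))
  grand <- mean(values)
  ssb <- sum(sizes * (vapply(groups, mean, 0) - grand)^2)
  ssw <- sum((values - rep(vapply(groups, mean, 0), sizes))^2)
  if (ssb == 0 && ssw == 0) {
    stop("degenerate input: zero between- and within-group variance")
  }
  res <- oneway.test(values ~ g, var.equal = TRUE)
  list(
    F = unname(res$statistic),
    p.value = res$p.value,
    df = unname(res$parameter),
    n = unname(sizes)
  )
}

#' Pearson chi-squared test on a contingency table of counts
#'
#' Pearson's chi-squared without continuity correction by default; a
#' correction flag is available for 2 x 2 tables. All expected cell counts
#' must be positive (no zero marginal).
#'
#' @param counts Matrix of non-negative counts, at least 2 x 2.
#' @param correct Apply the Yates continuity correction (2 x 2 only).
#'   Default `FALSE`.
#' @return List with `statistic`, `p.value` and `df`.
#' @export
counts_chisq <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("contingency table must be at least 2 x 2")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal: every row and column must have observations")
  }
  res <- suppressWarnings(chisq.test(counts, correct = correct))
  list(
    statistic = unname(res$statistic),
    p.value = res$p.value,
    df = unname(res$parameter)
  )
}
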