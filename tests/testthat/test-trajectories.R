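# Independent brute-force labelling of a call triple, written directly from
# the class definitions; the classifier must agree on all 64 cases.
oracle_label <- function(c1, c2, c3) {
  if (c1 == "FAILED") return(NA_character_)
  if (c2 == "FAILED" || c3 == "FAILED") return("FAILED_ONSET")
  if (c1 == "0/0" && c2 == "0/1" && c3 == "1/1") return("HOM_SWITCH_UP")
  if (c1 == "1/1" && c2 == "0/1" && c3 == "0/0") return("HOM_SWITCH_DOWN")
  if (c1 == c3) return("STABLE")
  if (c1 == "0/0" && c3 == "0/1") return("GAIN_HET")
  if (c1 == "1/1" && c3 == "0/1") return("LOSS_HET")
  if (c1 == "0/1" && c3 %in% c("0/0", "1/1")) return("RESOLVE_TO_HOM")
  "OTHER"
}

test_that("classifier matches the exhaustive 64-triple oracle", {
  lv <- genotype_levels()
  grid <- expand.grid(c1 = lv, c2 = lv, c3 = lv, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    expected <- oracle_label(grid$c1[i], grid$c2[i], grid$c3[i])
    calls <- unlist(grid[i, ])
    if (is.na(expected)) {
      expect_error(classify_trajectory(calls), "truth reference")
    } else {
      expect_equal(classify_trajectory(calls), expected,
                   info = paste(calls, collapse = " "))
    }
  }
})

test_that("named trajectory examples classify as documented", {
  expect_equal(classify_trajectory(c("0/0", "0/1", "1/1")), "HOM_SWITCH_UP")
  expect_equal(classify_trajectory(c("1/1", "0/1", "0/0")), "HOM_SWITCH_DOWN")
  expect_equal(classify_trajectory(c("0/0", "0/0", "0/0")), "STABLE")
  expect_equal(classify_trajectory(c("0/0", "FAILED", "0/0")), "FAILED_ONSET")
  expect_equal(classify_trajectory(c("0/0", "0/1", "0/1")), "GAIN_HET")
  # a direct homozygote jump without the intermediate het is OTHER
  expect_equal(classify_trajectory(c("0/0", "0/0", "1/1")), "OTHER")
})

test_that("trajectory classes partition sites with a usable day-0 call", {
  design <- small_design(n_sites = 800L)
  s <- simulate_study(design)
  calls <- call_study(s$table)
  tr <- classify_trajectories(calls)
  excluded <- attr(tr, "excluded_day0_failed")
  expect_equal(nrow(tr) + sum(excluded), nrow(s$table$sites))
  expect_true(all(tr$label %in% trajectory_levels()))
})

test_that("failed-call counts are zero without failures and exact with them", {
  samples <- series_samples(times = c(0L, 22L))
  n <- 10L
  sites <- data.frame(chrom = "chr1", pos = 1:n * 10L, ref = "C", alt = "T",
                      stringsAsFactors = FALSE)
  ref <- matrix(20L, n, 2L)
  ref[1:3, 2L] <- 0L
  tab <- study_table(sites, samples, ref, matrix(0L, n, 2L),
                     matrix(0L, n, 2L))
  fc <- count_failed_calls(call_study(tab))
  expect_equal(fc$n_failed, c(0L, 3L))
})

test_that("genotype transition matrix conserves sites", {
  set.seed(33)
  lv <- genotype_levels()
  day0 <- sample(lv, 100L, replace = TRUE)
  later <- sample(lv, 100L, replace = TRUE)
  m <- genotype_transition_counts(day0, later)
  expect_equal(sum(m), 100L)
  expect_equal(unname(rowSums(m)),
               as.integer(table(factor(day0, levels = lv))))

  # identical vectors give a diagonal matrix
  d <- genotype_transition_counts(day0, day0)
  expect_equal(sum(diag(d)), 100L)

  # a single uniform transition fills one off-diagonal cell
  u <- genotype_transition_counts(rep("0/0", 5L), rep("0/1", 5L))
  expect_equal(u["0/0", "0/1"], 5L)
  expect_equal(sum(u), 5L)

  expect_error(genotype_transition_counts(day0, later[-1]), "site sets")
})

test_that("base changes map to their substitution classes", {
  expect_equal(as.character(classify_base_change("C", "T")),
               "TYPE2_TRANSITION")
  expect_equal(as.character(classify_base_change("G", "A")),
               "TYPE2_TRANSITION")
  expect_equal(as.character(classify_base_change("A", "G")),
               "TYPE1_TRANSITION")
  expect_equal(as.character(classify_base_change("T", "C")),
               "TYPE1_TRANSITION")
  expect_equal(as.character(classify_base_change("C", "G")), "TRANSVERSION")
  expect_equal(as.character(classify_base_change("G", "*")),
               "SPANNING_DELETION")
  # the twelve substitutions split 2/2/8 across transition/transversion
  pairs <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- classify_base_change(pairs$ref, pairs$alt)
  expect_equal(as.integer(table(cls)),
               c(2L, 2L, 8L, 0L))
})

test_that("spectrum counts sum to input and respect strand complementation", {
  set.seed(44)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 300L, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  alt[1:10] <- "*"
  sites <- data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
  sp <- spectrum_counts(sites)
  expect_equal(sum(sp$count), 300L)

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flipped <- data.frame(
    ref = ifelse(alt == "*", comp[ref], comp[ref]),
    alt = ifelse(alt == "*", "*", comp[alt]),
    stringsAsFactors = FALSE
  )
  sp2 <- spectrum_counts(flipped)
  # complementation swaps the two deamination-signature substitutions
  get <- function(s, ch) s$count[s$change == ch]
  expect_equal(get(sp, "G>A"), get(sp2, "C>T"))
  expect_equal(get(sp, "C>T"), get(sp2, "G>A"))
  # class totals are strand-symmetric
  agg <- function(s) tapply(s$count, s$class, sum)
  expect_equal(agg(sp), agg(sp2))

  # folding strands halves the substitution table and conserves counts
  folded <- spectrum_counts(sites, fold_strands = TRUE)
  expect_equal(sum(folded$count), 300L)
  expect_equal(get(folded, "C>T/G>A"), get(sp, "C>T") + get(sp, "G>A"))

  expect_equal(sum(spectrum_counts(sites[0, ])$count), 0L)
})

test_that("gradual-drift detection follows the monotone band rules", {
  cfg <- monotone_config(direction = "increasing")
  expect_true(is_gradual(c(0, 20, 98), cfg)$gradual)
  expect_equal(is_gradual(c(0, 20, 98), cfg)$direction, "increasing")
  expect_false(is_gradual(c(0, 50, 30), cfg)$gradual)
  expect_false(is_gradual(c(10, 10, 10), monotone_config())$gradual)
  # per-step tolerance permits bounded backsliding
  expect_true(is_gradual(c(0, 30, 28.5, 60), monotone_config())$gradual)
  expect_false(is_gradual(c(0, 30, 25, 60), monotone_config())$gradual)
  # decreasing drift carries its direction
  res <- is_gradual(c(90, 60, 10), monotone_config())
  expect_true(res$gradual)
  expect_equal(res$direction, "decreasing")
  expect_error(is_gradual(c(0, NA, 50), cfg), "undefined PRV")
})

test_that("zero tolerance and vanishing delta reduce to strict monotonicity", {
  cfg <- monotone_config(direction = "increasing", min_total_delta = 1e-9,
                         per_step_tolerance = 0)
  set.seed(55)
  for (i in 1:200) {
    p <- round(runif(3, 0, 100), 1)
    strict <- all(diff(p) >= 0) && p[3] > p[1]
    expect_equal(is_gradual(p, cfg)$gradual, strict,
                 info = paste(p, collapse = " "))
  }
})
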