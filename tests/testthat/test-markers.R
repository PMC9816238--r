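# A deterministic three-site, one-series table for filter examples.
filter_fixture <- function(depth_200 = 30L) {
  samples <- series_samples()
  # pos 100: C>T rising to het; pos 200: C>T with adjustable depth at d92;
  # pos 300: A>C transversion rising to het
  rows <- data.frame(
    chrom = "chr1",
    pos = rep(c(100L, 200L, 300L), each = 3L),
    ref = rep(c("C", "C", "A"), each = 3L),
    alt = rep(c("T", "T", "C"), each = 3L),
    sample_id = rep(samples$sample_id, times = 3L),
    ref_reads = c(30L, 24L, 12L, 30L, 24L, depth_200 - round(depth_200 * 0.6),
                  30L, 24L, 12L),
    alt_reads = c(0L, 6L, 18L, 0L, 6L, round(depth_200 * 0.6),
                  0L, 6L, 18L),
    other_reads = 0L,
    stringsAsFactors = FALSE
  )
  study_table_from_long(rows, samples)
}

test_that("changed sites are call differences from day 0", {
  tab <- filter_fixture()
  calls <- call_study(tab)
  ch <- changed_sites(calls)
  expect_equal(ch$n_changed, 3L)
  expect_equal(ch$n_failed_only, 0L)

  # identical calls at all times: nothing changes
  samples <- series_samples()
  n <- 5L
  sites <- data.frame(chrom = "chr1", pos = 1:n * 10L, ref = "C", alt = "T",
                      stringsAsFactors = FALSE)
  stable <- study_table(sites, samples, matrix(20L, n, 3L),
                        matrix(20L, n, 3L), matrix(0L, n, 3L))
  expect_equal(changed_sites(call_study(stable))$n_changed, 0L)

  # a site failing at day 92 only is failed-onset, not changed
  ref <- matrix(20L, n, 3L)
  ref[2L, 3L] <- 0L
  alt <- matrix(20L, n, 3L)
  alt[2L, 3L] <- 0L
  failing <- study_table(sites, samples, ref, alt, matrix(0L, n, 3L))
  ch2 <- changed_sites(call_study(failing))
  expect_equal(ch2$n_changed, 0L)
  expect_equal(ch2$n_failed_only, 1L)
  expect_equal(ch2$failed_only$pos, 20L)
})

test_that("optional PRV drift tolerance flags call-stable drifting sites", {
  samples <- series_samples()
  sites <- data.frame(chrom = "chr1", pos = 10L, ref = "C", alt = "T",
                      stringsAsFactors = FALSE)
  # het throughout, but PRV drifts 50 -> 50 -> 80
  tab <- study_table(
    sites, samples,
    ref_reads = matrix(c(15L, 15L, 6L), 1L),
    alt_reads = matrix(c(15L, 15L, 24L), 1L),
    other_reads = matrix(0L, 1L, 3L)
  )
  calls <- call_study(tab)
  expect_equal(changed_sites(calls)$n_changed, 0L)
  expect_equal(changed_sites(calls, prv_tol = 5)$n_changed, 1L)
})

test_that("stepwise filters gate in order with conservative attrition", {
  tab <- filter_fixture(depth_200 = 9L)
  calls <- call_study(tab)
  res <- apply_filters(tab, calls, config = filter_config())
  at <- res$attrition
  expect_equal(at$stage, c("spectrum", "day0_homozygous", "read_threshold"))
  # A>C transversion removed by the spectrum gate
  expect_equal(at$n_removed[at$stage == "spectrum"], 1L)
  # one sample at 9 reads: below the 10-read threshold
  expect_equal(at$n_removed[at$stage == "read_threshold"], 1L)
  expect_equal(res$sites$pos, 100L)
  # conservation at every gate
  expect_true(all(at$n_in - at$n_removed == at$n_out))
  expect_equal(at$n_in[-1L], at$n_out[-3L])

  # exactly 10 reads everywhere is retained (inclusive threshold)
  tab10 <- filter_fixture(depth_200 = 10L)
  res10 <- apply_filters(tab10, call_study(tab10), config = filter_config())
  expect_setequal(res10$sites$pos, c(100L, 200L))
})

test_that("relaxing the read threshold never shrinks the surviving set", {
  design <- small_design(n_sites = 600L)
  s <- simulate_study(design)
  calls <- call_study(s$table)
  prev <- -1L
  for (thr in c(25L, 20L, 15L, 10L, 5L, 1L)) {
    res <- apply_filters(s$table, calls,
                         config = filter_config(min_total_reads = thr))
    expect_gte(nrow(res$sites), prev)
    prev <- nrow(res$sites)
  }
})

test_that("candidate selection requires concordant gradual drift", {
  # two series; site A rises in both, site B rises in one and falls in the
  # other, site C rises in one series only (flat elsewhere)
  samples <- rbind(series_samples("blood", "dry"),
                   series_samples("saliva", "dry"))
  sites <- data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L),
    ref = "C", alt = "T", stringsAsFactors = FALSE
  )
  alt <- rbind(
    c(0L, 6L, 18L, 0L, 5L, 20L),    # A: up in both
    c(0L, 6L, 18L, 24L, 18L, 3L),   # B: up in blood, down in saliva
    c(0L, 6L, 18L, 0L, 0L, 0L)      # C: up in blood only
  )
  tab <- study_table(sites, samples,
                     ref_reads = 30L - alt, alt_reads = alt,
                     other_reads = matrix(0L, 3L, 6L))
  calls <- call_study(tab)
  sel <- select_candidates(calls, sites)
  expect_equal(sel$markers$pos, 100L)
  expect_equal(sel$markers$direction, "increasing")
  expect_equal(as.character(sel$markers$day0_genotype), "0/0")
  expect_true(all(c("prv_blood_dry_d0", "prv_saliva_dry_d92") %in%
                    names(sel$markers)))

  # selection is invariant under permuting the input site order
  sel2 <- select_candidates(calls, sites[c(3, 1, 2), ])
  expect_equal(sel2$markers, sel$markers)
})

test_that("planted markers are recovered and null sites are not selected", {
  design <- sim_design(n_sites = 2000L, seed = 90210L)
  s <- simulate_study(design)
  calls <- call_study(s$table)
  ch <- changed_sites(calls)
  filt <- apply_filters(s$table, calls, sites = ch$changed)
  sel <- select_candidates(calls, filt$sites)
  truth_key <- site_id(s$truth$chrom, s$truth$pos, s$truth$ref, s$truth$alt)
  marker_key <- site_id(sel$markers$chrom, sel$markers$pos,
                        sel$markers$ref, sel$markers$alt)
  planted <- truth_key[s$truth$role == "planted_marker"]
  nulls <- truth_key[s$truth$role == "null"]
  expect_gte(mean(planted %in% marker_key), 0.9)
  expect_lte(mean(nulls %in% marker_key), 0.05)
  # all selected planted markers rise, as simulated
  expect_true(all(sel$markers$direction[marker_key %in% planted] ==
                    "increasing"))
})

test_that("homozygote switches are listed per series with their overlap", {
  samples <- rbind(series_samples("blood", "dry"),
                   series_samples("blood", "humid"))
  sites <- data.frame(
    chrom = "chr1", pos = c(100L, 200L), ref = "C", alt = "T",
    stringsAsFactors = FALSE
  )
  # pos 100 switches up in both conditions; pos 200 only in dry
  alt <- rbind(
    c(0L, 15L, 30L, 0L, 15L, 30L),
    c(0L, 15L, 30L, 0L, 0L, 0L)
  )
  tab <- study_table(sites, samples, ref_reads = 30L - alt, alt_reads = alt,
                     other_reads = matrix(0L, 2L, 6L))
  tr <- classify_trajectories(call_study(tab))
  sw <- homozygote_switches(tr)
  expect_equal(nrow(sw$per_series), 3L)
  expect_true(all(sw$per_series$direction == "up"))
  expect_equal(sw$shared$pos, 100L)
  expect_equal(sw$shared$n_series, 2L)

  empty <- homozygote_switches(tr[tr$label == "STABLE", ])
  expect_equal(nrow(empty$per_series), 0L)
  expect_equal(nrow(empty$shared), 0L)
})
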