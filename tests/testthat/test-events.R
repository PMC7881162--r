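test_that("every significance threshold is inclusive at its boundary", {
  # exactly at every quoted bound: kept
  at_bound <- make_events(1, p_value = 0.05, inclusion_reads = 1L,
                          exclusion_reads = 9L, psi_treated = 0.2,
                          psi_control = 0.1)
  expect_equal(nrow(filter_significant(at_bound)), 1)

  # total reads 9 < 10: removed despite a large dPSI
  low_total <- make_events(1, p_value = 0.05, inclusion_reads = 5L,
                           exclusion_reads = 4L, psi_treated = 0.9,
                           psi_control = 0.4)
  expect_equal(nrow(filter_significant(low_total)), 0)

  # exclusion events (dPSI < 0) are kept by the absolute-value rule
  excl <- make_events(1, psi_treated = 0.2, psi_control = 0.8)
  expect_equal(nrow(filter_significant(excl)), 1)

  # filtering is idempotent and yields a subset
  tbl <- random_events(500, seed = 21)
  once <- filter_significant(tbl)
  expect_equal(filter_significant(once), once)
  expect_true(all(once$event_id %in% tbl$event_id))
})

test_that("reciprocal overlap follows the 95% both-ways rule", {
  a <- list(chrom = "chr1", start = 100, end = 200, strand = "+")
  b <- list(chrom = "chr1", start = 101, end = 201, strand = "+")
  ro <- reciprocal_overlap(a, b)
  expect_equal(c(ro$frac_a, ro$frac_b), c(0.99, 0.99))
  expect_true(ro$match)

  half <- reciprocal_overlap(a, list(chrom = "chr1", start = 150, end = 250,
                                     strand = "+"))
  expect_equal(c(half$frac_a, half$frac_b), c(0.5, 0.5))
  expect_false(half$match)

  # same coordinates, opposite strand: never the same event
  flip <- reciprocal_overlap(a, list(chrom = "chr1", start = 100, end = 200,
                                     strand = "-"))
  expect_false(flip$match)

  # match decision is symmetric
  long_b <- list(chrom = "chr1", start = 95, end = 210, strand = "+")
  expect_equal(reciprocal_overlap(a, long_b)$match,
               reciprocal_overlap(long_b, a)$match)

  expect_error(reciprocal_overlap(a, list(chrom = "chr1", start = 5, end = 5,
                                          strand = "+")),
               "zero-length", class = "gliosplice_validation_error")
})

test_that("consolidation recovers planted events and is order-invariant", {
  sim <- sim_ase_tables(600, 3, 0.05, seed = 13)
  filtered <- lapply(sim$tables, filter_significant)
  common <- consolidate_events(filtered)
  expect_setequal(common$event_id, sim$truth$shared_significant_event_ids)
  expect_equal(attr(common, "n_events"), 30L)

  # reversing sample order returns the same matched groups
  rev_common <- consolidate_events(rev(filtered))
  expect_setequal(rev_common$event_id, common$event_id)

  # per-sample dPSI columns are attached for every sample
  expect_true(all(c("dpsi_sample1", "dpsi_sample2", "dpsi_sample3")
                  %in% names(common)))
  expect_true(all(abs(common$dpsi_sample2) >= 0.10))

  # adding a sample can only shrink the common set
  common2 <- consolidate_events(filtered[1:2])
  expect_true(all(common$event_id %in% common2$event_id))

  # disjoint coordinates consolidate to nothing
  a <- make_events(3)
  b <- make_events(3, start = 50000L + 1000L * (0:2),
                   end = 50100L + 1000L * (0:2))
  expect_equal(nrow(consolidate_events(list(a, b))), 0)
})

test_that("impact classification applies frame arithmetic and stop scan", {
  tx <- toy_transcripts()
  # length 100: frameshift
  ce100 <- make_events(1, start = 100L, end = 200L)
  expect_equal(classify_impact(ce100, tx)$call, "disruptive_frameshift")
  expect_equal(classify_impact(ce100, tx)$basis, "length_mod3")

  # length 99, no sequence: in-frame preserving
  ce99 <- make_events(1, start = 100L, end = 199L)
  expect_equal(classify_impact(ce99, tx)$call, "in_frame_preserving")

  # no transcript on that chromosome: unknown
  far <- make_events(1, chrom = "chr9")
  call <- classify_impact(far, tx)
  expect_equal(call$call, "unknown")
  expect_equal(call$basis, "no_transcript_match")

  # RI of 51 nt carrying an in-frame TAA: disruptive via stop codon
  genome <- c(chr1 = paste(rep("C", 1000), collapse = ""))
  substr(genome["chr1"], 151, 153) <- "TAA"  # event offset 30, phase 0
  ri_tx <- tibble::tibble(
    transcript_id = "tx_ri", gene = "G1", chrom = "chr1", strand = "+",
    exon_start = 0, exon_end = 300, is_canonical = FALSE, coding_start = 99)
  ri <- make_events(1, event_class = "RI", start = 120L, end = 171L)
  got <- classify_impact(ri, ri_tx, genome = genome)
  expect_equal(got$call, "disruptive_frameshift")
  expect_equal(got$basis, "stop_codon")

  # same RI without the stop codon is in-frame preserving
  clean <- c(chr1 = paste(rep("C", 1000), collapse = ""))
  expect_equal(classify_impact(ri, ri_tx, genome = clean)$call,
               "in_frame_preserving")

  expect_error(
    classify_impact(ce100, dplyr::mutate(tx, exon_end = exon_start)),
    "malformed", class = "gliosplice_validation_error")
})

test_that("direction-disruption test matches exact enumeration", {
  perfect <- tibble::tibble(
    delta_psi = c(rep(0.5, 10), rep(-0.5, 10)),
    call = c(rep("disruptive_frameshift", 10), rep("in_frame_preserving", 10)))
  res <- direction_disruption_test(perfect)
  # all-diagonal 2x2: two-sided p is 2 / C(20, 10)
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)

  balanced <- tibble::tibble(
    delta_psi = rep(c(0.3, 0.3, -0.3, -0.3), 5),
    call = rep(c("disruptive_frameshift", "in_frame_preserving"), 10))
  expect_equal(direction_disruption_test(balanced)$p_value, 1)

  # zero margin: degenerate table, p = 1 with a warning
  one_sided <- tibble::tibble(delta_psi = rep(0.4, 6),
                              call = rep(c("disruptive_frameshift",
                                           "in_frame_preserving"), 3))
  expect_warning(deg <- direction_disruption_test(one_sided), "degenerate")
  expect_equal(deg$p_value, 1)

  expect_error(direction_disruption_test(
    tibble::tibble(delta_psi = 0.1, call = "unknown")),
    "unknown", class = "gliosplice_validation_error")
})

test_that("direction-disruption test controls type I error under the null", {
  set.seed(31)
  rej <- vapply(1:100, function(i) {
    ev <- tibble::tibble(
      delta_psi = sample(c(-0.3, 0.3), 60, TRUE),
      call = sample(c("disruptive_frameshift", "in_frame_preserving"), 60, TRUE))
    direction_disruption_test(ev)$p_value <= 0.05
  }, logical(1))
  # discrete Fisher p-values are conservative; rejection rate stays near or
  # below the nominal level
  expect_lte(mean(rej), 0.08)
})
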