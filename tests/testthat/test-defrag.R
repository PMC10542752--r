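test_that("consecutive collinear fragments merge into one copy", {
  hits <- make_hits(
    make_hit(start = 0L, end = 400L, cons_start = 1L, cons_end = 400L,
             cons_left = 400L, run_id = 1L, K = 4),
    make_hit(start = 450L, end = 860L, cons_start = 390L, cons_end = 800L,
             cons_left = 0L, run_id = 2L, K = 6)
  )
  cp <- merge_fragments(hits)
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$n_fragments, 2L)
  expect_equal(cp$start, 0L)
  expect_equal(cp$end, 860L)
  # consensus union spans 1-800 of an 800 bp consensus
  expect_equal(cp$cons_cov_bp, 800L)
  expect_equal(cp$cons_span_frac, 1)
  # merged length excludes the inter-fragment gap
  expect_equal(cp$merged_len, 810L)
})

test_that("distant fragments with different run ids stay separate", {
  hits <- make_hits(
    make_hit(start = 0L, end = 400L, cons_start = 1L, cons_end = 400L,
             cons_left = 400L, run_id = 1L),
    make_hit(start = 10400L, end = 10800L, cons_start = 390L,
             cons_end = 800L, cons_left = 0L, run_id = 2L)
  )
  expect_equal(nrow(merge_fragments(hits)), 2L)
})

test_that("a shared run id rejoins fragments across a nested insertion", {
  hits <- make_hits(
    make_hit(start = 0L, end = 500L, family = "old", cons_start = 1L,
             cons_end = 500L, cons_left = 700L, run_id = 1L, K = 15),
    make_hit(start = 500L, end = 700L, family = "young",
             class_family = "SINE/tRNA", cons_start = 1L, cons_end = 200L,
             cons_left = 0L, run_id = 2L, K = 1),
    make_hit(start = 700L, end = 1400L, family = "old", cons_start = 501L,
             cons_end = 1200L, cons_left = 0L, run_id = 1L, K = 15)
  )
  cp <- merge_fragments(hits)
  expect_equal(nrow(cp), 2L)
  old <- cp[cp$family == "old", ]
  expect_equal(old$n_fragments, 2L)
  expect_equal(old$merged_len, 1200L)
  expect_equal(cp$n_fragments[cp$family == "young"], 1L)
})

test_that("unsorted hit input is rejected", {
  hits <- dplyr::bind_rows(
    make_hit(start = 500L, end = 600L),
    make_hit(start = 0L, end = 100L)
  )
  expect_error(merge_fragments(hits), "sorted")
})

test_that("minus-strand collinearity mirrors the plus-strand rule", {
  # genomic left-to-right fragments of a minus-strand copy descend in
  # consensus coordinates
  hits <- make_hits(
    make_hit(start = 0L, end = 400L, strand = "-", cons_start = 401L,
             cons_end = 800L, cons_left = 0L, run_id = 1L, K = 5),
    make_hit(start = 450L, end = 850L, strand = "-", cons_start = 1L,
             cons_end = 410L, cons_left = 390L, run_id = 2L, K = 5)
  )
  expect_equal(nrow(merge_fragments(hits)), 1L)
  # ascending consensus coordinates on "-" must NOT merge (beyond tolerance)
  hits2 <- make_hits(
    make_hit(start = 0L, end = 400L, strand = "-", cons_start = 1L,
             cons_end = 400L, cons_left = 400L, run_id = 1L, K = 5),
    make_hit(start = 450L, end = 850L, strand = "-", cons_start = 401L,
             cons_end = 800L, cons_left = 0L, run_id = 2L, K = 5)
  )
  expect_equal(nrow(merge_fragments(hits2)), 2L)
})

test_that("every hit lands in exactly one pre-filter copy", {
  for (seed in 1:5) {
    sim <- plant_genome(small_sim_config(seed = seed), sequence = FALSE)
    cp <- merge_fragments(sim$hits)
    n_frag <- sum(cp$n_fragments)
    expect_equal(n_frag, nrow(sim$hits))
    # fragment bp is conserved by merging
    expect_equal(sum(cp$merged_len), sum(sim$hits$end - sim$hits$start))
  }
})

test_that("planted copies are recovered with their exact fragment sets", {
  sim <- plant_genome(small_sim_config(seed = 99), sequence = FALSE)
  cp <- merge_fragments(sim$hits)
  cp <- assemble_ltr(cp)
  tr <- sim$truth
  m <- dplyr::inner_join(
    cp[, c("chrom", "start", "end", "n_fragments")],
    tr[, c("chrom", "start", "end", "n_fragments")],
    by = c("chrom", "start"), suffix = c("", "_true"))
  expect_equal(nrow(m), nrow(tr))
  expect_true(all(m$end == m$end_true))
  expect_true(all(m$n_fragments == m$n_fragments_true))
})

test_that("LTR-internal-LTR triplets fuse into full elements", {
  mk <- function(start, end, family, strand = "+", id) {
    make_copy(start = start, end = end, family = family, class = "LTR",
              strand = strand, copy_id = id)
  }
  copies <- dplyr::bind_rows(
    mk(0L, 300L, "ERVX_LTR", id = "a"),
    mk(350L, 4350L, "ERVX_I", id = "b"),
    mk(4400L, 4700L, "ERVX_LTR", id = "c")
  )
  out <- assemble_ltr(copies)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 0L)
  expect_equal(out$end, 4700L)
  expect_equal(out$family, "ERVX")
  expect_equal(out$n_fragments, 3L)

  # the same pattern on the minus strand fuses identically
  minus <- dplyr::bind_rows(
    mk(0L, 300L, "ERVX_LTR", "-", "a"),
    mk(350L, 4350L, "ERVX_I", "-", "b"),
    mk(4400L, 4700L, "ERVX_LTR", "-", "c")
  )
  out_minus <- assemble_ltr(minus)
  expect_equal(out_minus$start, out$start)
  expect_equal(out_minus$end, out$end)
  expect_equal(out_minus$family, out$family)

  # a solo LTR with nothing nearby stays as it is
  solo <- mk(0L, 300L, "ERVX_LTR", id = "a")
  expect_equal(assemble_ltr(solo)$family, "ERVX_LTR")
  # mixed strands must not fuse
  mixed <- dplyr::bind_rows(
    mk(0L, 300L, "ERVX_LTR", "+", "a"),
    mk(350L, 4350L, "ERVX_I", "-", "b"),
    mk(4400L, 4700L, "ERVX_LTR", "+", "c")
  )
  expect_equal(nrow(assemble_ltr(mixed)), 3L)
})

test_that("the 80-80-80 filter enforces all three boundaries", {
  p <- merge_params()
  short <- make_copy(merged_len = 79L, K = 5, cons_span_frac = 0.9)
  diverged <- make_copy(end = 5000L, merged_len = 5000L, K = 20,
                        cons_span_frac = 0.9)
  boundary <- make_copy(merged_len = 80L, K = 19.99, cons_span_frac = 0.80)
  low_span <- make_copy(merged_len = 500L, K = 5, cons_span_frac = 0.79)
  unclass <- make_copy(merged_len = 500L, K = 5, cons_span_frac = 0.9,
                       class = "Unclassified")
  all_cp <- dplyr::bind_rows(short, diverged, boundary, low_span, unclass)
  kept <- filter_808080(all_cp, p)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$merged_len, 80L)
  # non-strict mode drops only length and identity offenders
  kept2 <- filter_808080(all_cp, merge_params(strict = FALSE))
  expect_equal(nrow(kept2), 2L)
})

test_that("annotation summaries count copies, bp and genome share", {
  empty <- annotation_summary(empty_copies_test(), 1e6)
  expect_equal(sum(empty$n), 0L)
  expect_equal(sum(empty$total_bp), 0L)
  one <- annotation_summary(make_copy(end = 5000L, merged_len = 5000L), 1e6)
  expect_equal(one$pct_genome[one$class == "Total"], 0.5)
  # filtering never increases any per-class count or coverage
  sim <- plant_genome(small_sim_config(seed = 5), sequence = FALSE)
  cp_raw <- classify_copies(assemble_ltr(merge_fragments(sim$hits)))
  cp_fin <- filter_808080(cp_raw)
  g <- sum(sim$chrom_sizes$length)
  s_raw <- annotation_summary(cp_raw, g)
  s_fin <- annotation_summary(cp_fin, g)
  j <- dplyr::left_join(s_fin, s_raw, by = "class", suffix = c("_f", "_r"))
  expect_true(all(j$n_f <= j$n_r))
  expect_true(all(j$total_bp_f <= j$total_bp_r))
})
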