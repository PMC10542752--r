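test_that("evolve_copy respects its boundary behaviours", {
  cons <- random_dna_test(600)
  ev0 <- evolve_copy(cons, 0)
  expect_identical(ev0$sequence, cons)
  expect_error(evolve_copy(cons, 55), "out of range")
  expect_error(evolve_copy(random_dna_test(40), 5), "shorter")
  # kappa -> infinity leaves only transitions
  set.seed(5)
  ev <- evolve_copy(random_dna_test(2000), 10, kappa = 1e9)
  expect_equal(ev$counts$tv_raw, 0L)
  expect_gt(ev$counts$ts_raw, 0L)
})

test_that("the evolver is calibrated to the CpG-adjusted estimator", {
  set.seed(11)
  cons <- random_dna_test(2000, 0.45)
  K_hat <- replicate(100, {
    ev <- evolve_copy(cons, 10)
    kimura2(count_substitutions(ev$sequence, ev$consensus))
  })
  expect_lt(abs(mean(K_hat) - 10), 0.5)
  # calibration holds with CpG hypermutability switched off as well
  K_flat <- replicate(100, {
    ev <- evolve_copy(cons, 10, cpg_multiplier = 1)
    kimura2(count_substitutions(ev$sequence, ev$consensus))
  })
  expect_lt(abs(mean(K_flat) - 10), 0.5)
})

test_that("age classes are almost always recovered for 500+ bp copies", {
  set.seed(12)
  cons <- random_dna_test(600, 0.45)
  hits <- vapply(rep(c(2, 12), each = 100), function(K_true) {
    ev <- evolve_copy(cons, K_true)
    K_hat <- kimura2(count_substitutions(ev$sequence, ev$consensus))
    classify_age(K_hat) == classify_age(K_true)
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("a zero-copy configuration yields empty tables, not errors", {
  cfg <- sim_config(seed = 1,
                    chrom_lengths = c(chr1 = 1e5),
                    sex_chroms = character(0),
                    copy_spec = default_copy_spec()[0, ])
  sim <- plant_genome(cfg)
  expect_equal(nrow(sim$hits), 0L)
  expect_equal(nrow(sim$truth), 0L)
  d <- withr::local_tempdir()
  write_rm_out(sim$hits, file.path(d, "x.out"))
  expect_equal(nrow(parse_rm_out(file.path(d, "x.out"))), 0L)
  w <- make_windows(sim$chrom_sizes, 5e4)
  ft <- feature_table(w, empty_copies_test(), sequence = sim$genome)
  expect_true(all(ft$te_cov_all == 0))
})

test_that("the same seed reproduces byte-identical outputs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  plant_genome(small_sim_config(seed = 6), dir = d1)
  plant_genome(small_sim_config(seed = 6), dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("emitted hit tables reproduce the planted truth exactly", {
  sim <- plant_genome(small_sim_config(seed = 31), dir = withr::local_tempdir())
  hits <- parse_rm_out(sim$paths$out)
  expect_equal(as.data.frame(hits), as.data.frame(sim$hits),
               tolerance = 1e-12)
  # every truth fragment appears as a hit with matching run_id grouping
  tr_frag <- tidyr::unnest(sim$truth[, c("copy_id", "fragments")],
                           "fragments")
  key_hits <- paste(hits$chrom, hits$start, hits$end)
  key_tr <- paste(tr_frag$chrom, tr_frag$start, tr_frag$end)
  expect_setequal(key_tr, key_hits)
  # planted bp equals the summary of the parsed output (no filtering)
  s <- annotation_summary(hits, sum(sim$chrom_sizes$length))
  expect_equal(s$total_bp[s$class == "Total"], sum(sim$truth$planted_bp))
})

test_that("an overfull copy request is refused", {
  cfg <- sim_config(seed = 1, chrom_lengths = c(chr1 = 2e4),
                    sex_chroms = character(0))
  expect_error(plant_genome(cfg, sequence = FALSE), "overfull")
})

test_that("planted coupling coefficients document expected signs", {
  zero <- sim_config(coupling = list(te_recent = 0, te_ancient = 0,
                                     gene = 0, cpg = 0, rec = 0, gc = 0))
  expect_true(all(plant_correlations(zero)$expected_sign == "none"))
  neg <- sim_config(coupling = list(te_recent = 1, te_ancient = 1,
                                    gene = 0, cpg = 0, rec = -1, gc = 0))
  pc <- plant_correlations(neg)
  expect_equal(
    pc$expected_sign[pc$te_category == "all" & pc$feature == "rec_rate"],
    "-")
  # a recent-only coupling separates the age classes
  rec_only <- sim_config(coupling = list(te_recent = -1, te_ancient = 0,
                                         gene = 0, cpg = 0, rec = 1, gc = 0))
  pc2 <- plant_correlations(rec_only)
  expect_equal(
    pc2$expected_sign[pc2$te_category == "recent" & pc2$feature == "rec_rate"],
    "-")
  expect_equal(
    pc2$expected_sign[pc2$te_category == "ancient" & pc2$feature == "rec_rate"],
    "none")
})

test_that("window-level simulation plants recoverable rank dependences", {
  set.seed(20)
  cpl <- list(te_recent = -1.5, te_ancient = 0, gene = 0, cpg = 0,
              rec = 1.5, gc = 0)
  ft <- simulate_window_features(500, coupling = cpl)
  pk <- partial_kendall(ft, "te_cov_recent", "rec_rate",
                        c("gene_cov", "cpg_cov", "gc"))
  expect_lt(pk$tau_partial, 0)
  expect_lt(pk$p_raw, 0.01)
})
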