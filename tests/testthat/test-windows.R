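test_that("window tiling keeps and flags trailing partial windows", {
  sizes <- tibble::tibble(chrom = "chr1", length = 5e5, is_autosome = TRUE)
  w <- make_windows(sizes, 2e5)
  expect_equal(w$start, c(0L, 200000L, 400000L))
  expect_equal(w$end, c(200000L, 400000L, 500000L))
  expect_equal(w$is_partial, c(FALSE, FALSE, TRUE))
  # a chromosome shorter than the width is a single partial window
  short <- make_windows(tibble::tibble(chrom = "c", length = 5e4), 2e5)
  expect_equal(nrow(short), 1L)
  expect_true(short$is_partial)
  # an exact multiple leaves no partial window
  exact <- make_windows(tibble::tibble(chrom = "c", length = 4e5), 2e5)
  expect_equal(nrow(exact), 2L)
  expect_false(any(exact$is_partial))
  expect_error(make_windows(sizes, 0), "width")
})

test_that("coverage counts union bp, clipped at window edges", {
  w <- make_windows(tibble::tibble(chrom = "chr1", length = 4e5), 2e5)
  iv <- tibble::tibble(chrom = "chr1", start = 10000L, end = 30000L)
  expect_equal(coverage_pct(w, iv), c(10, 0))
  # overlapping intervals count once
  iv2 <- tibble::tibble(chrom = "chr1", start = c(0L, 500L),
                        end = c(1000L, 1500L))
  expect_equal(coverage_pct(w, iv2)[1], 100 * 1500 / 2e5)
  # an interval spanning the boundary contributes its clip to each side
  iv3 <- tibble::tibble(chrom = "chr1", start = 190000L, end = 210000L)
  expect_equal(coverage_pct(w, iv3), c(5, 5))
  # invariant to ordering and to splitting an interval in two
  iv4 <- tibble::tibble(chrom = "chr1", start = c(210000L, 190000L),
                        end = c(220000L, 210000L))
  iv5 <- tibble::tibble(chrom = "chr1",
                        start = c(190000L, 200000L, 210000L),
                        end = c(200000L, 210000L, 220000L))
  expect_equal(coverage_pct(w, iv4), coverage_pct(w, iv5))
})

test_that("GC content excludes ambiguous bases from the denominator", {
  w <- tibble::tibble(chrom = "chr1", start = 0L, end = 8L)
  expect_equal(gc_pct(w, c(chr1 = "GGCCGGCC")), 100)
  expect_equal(gc_pct(w, c(chr1 = "ATGCATGC")), 50)
  expect_equal(gc_pct(w, c(chr1 = "ATGCNNNN")), 50)
  expect_true(is.na(gc_pct(w, c(chr1 = "NNNNNNNN"))))
})

test_that("window recombination rate is the overlap-weighted mean", {
  w <- tibble::tibble(chrom = "chr1", start = 0L, end = 200000L)
  map <- tibble::tibble(chrom = "chr1", start = c(0L, 50000L),
                        end = c(50000L, 200000L), value = c(1, 3))
  expect_equal(rec_rate_window(w, map), 2.5)
  whole <- tibble::tibble(chrom = "chr1", start = 0L, end = 200000L,
                          value = 4.6e-9)
  expect_equal(rec_rate_window(w, whole), 4.6e-9)
  off <- tibble::tibble(chrom = "chr2", start = 0L, end = 100L, value = 1)
  expect_true(is.na(rec_rate_window(w, off)))
})

test_that("the feature table matches an independent interval oracle", {
  sim <- plant_genome(small_sim_config(seed = 13))
  ann <- annotate_genome(sim$hits, sim$blocks)
  w <- make_windows(sim$chrom_sizes, 5e4)
  ft <- feature_table(w, ann$copies, genes = sim$genes, cpg = sim$cpg,
                      recmap = sim$recmap, sequence = sim$genome)
  # brute-force union oracle over per-bp masks
  oracle_cov <- function(iv, win) {
    mask <- logical(win$end - win$start)
    iv <- iv[iv$chrom == win$chrom & iv$end > win$start & iv$start < win$end, ]
    for (i in seq_len(nrow(iv))) {
      a <- max(iv$start[i], win$start) - win$start + 1L
      b <- min(iv$end[i], win$end) - win$start
      mask[a:b] <- TRUE
    }
    100 * sum(mask) / length(mask)
  }
  iv_all <- copies_to_intervals_test(ann$copies)
  idx <- c(1, 3, nrow(ft))
  for (i in idx) {
    expect_equal(ft$te_cov_all[i], oracle_cov(iv_all, ft[i, ]),
                 tolerance = 1e-12)
  }
  # with disjoint age classes, recent + ancient coverage = total coverage
  expect_equal(ft$te_cov_recent + ft$te_cov_ancient, ft$te_cov_all,
               tolerance = 1e-9)
  # per-type coverages never exceed the total
  for (cl in c("LTR", "LINE", "SINE", "DNA")) {
    expect_true(all(ft[[paste0("te_cov_", cl)]] <= ft$te_cov_all + 1e-9))
  }
  expect_true(all(ft$gc >= 0 & ft$gc <= 100, na.rm = TRUE))
  expect_true(all(ft$rec_rate > 0, na.rm = TRUE))
  # chromosome name mismatches are reported
  bad <- ann$copies
  bad$chrom <- "chrX"
  expect_error(feature_table(w, bad), "chrX")
})

test_that("windows with no annotation report zero coverage", {
  sizes <- tibble::tibble(chrom = "chr1", length = 2e5)
  w <- make_windows(sizes, 2e5)
  ft <- feature_table(w, empty_copies_test(),
                     sequence = c(chr1 = random_dna_test(2e5)))
  expect_equal(ft$te_cov_all, 0)
  expect_equal(ft$te_cov_recent, 0)
  expect_false(is.na(ft$gc))
})
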