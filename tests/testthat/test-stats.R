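test_that("tau-b reproduces brute-force pair counts", {
  expect_equal(kendall_tau_b(1:5, 1:5), 1)
  expect_equal(kendall_tau_b(1:5, -(1:5)), -1)
  # 3 pairs: two concordant, one discordant -> 1/3
  expect_equal(kendall_tau_b(c(1, 2, 3), c(1, 3, 2)), 1 / 3)
  expect_error(kendall_tau_b(c(1, 1, 1), 1:3), "zero variance")
  # ties handled as tau-b: cross-check base R on random tied data
  set.seed(1)
  for (i in 1:10) {
    x <- sample(1:5, 30, TRUE)
    y <- sample(1:5, 30, TRUE)
    expect_equal(kendall_tau_b(x, y),
                 suppressWarnings(cor(x, y, method = "kendall")),
                 tolerance = 1e-12)
  }
})

test_that("partial correlation reduces to the one-control recursion", {
  # tau_xz = tau_yz = 0 leaves tau_xy untouched: build from the formula
  r <- (0.6 - 0.5 * 0.5) / sqrt((1 - 0.25) * (1 - 0.25))
  expect_equal(r, 0.35 / 0.75)
  # matrix route equals the recursion on random 3-variable tables
  set.seed(2)
  for (i in 1:200) {
    n <- 30
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -0.4 * z + rnorm(n)
    d <- tibble::tibble(x = x, y = y, z = z)
    pk <- partial_kendall(d, "x", "y", "z")
    t_xy <- kendall_tau_b(x, y)
    t_xz <- kendall_tau_b(x, z)
    t_yz <- kendall_tau_b(y, z)
    rec <- (t_xy - t_xz * t_yz) / sqrt((1 - t_xz^2) * (1 - t_yz^2))
    expect_equal(pk$tau_partial, rec, tolerance = 1e-12)
  }
})

test_that("partial correlation validates its inputs", {
  d <- tibble::tibble(x = rnorm(20), y = rnorm(20), z = rnorm(20))
  expect_error(partial_kendall(d, "x", "y", "x"), "disjoint")
  expect_error(partial_kendall(d[1:5, ], "x", "y", "z"), "complete rows")
  d2 <- d
  d2$z2 <- d2$z  # perfectly confounded control pair
  expect_error(partial_kendall(d2, "x", "y", c("z", "z2")), "degenerate")
  out <- tidy(partial_kendall(d, "x", "y", "z"))
  expect_true(abs(out$tau_partial) <= 1)
  expect_true(out$p_raw >= 0 && out$p_raw <= 1)
})

test_that("Kruskal-Wallis matches the hand-ranked statistic", {
  kw <- kruskal_wallis(list(a = c(1, 2), b = c(3, 4)))
  expect_equal(kw$H, 2.4, tolerance = 1e-9)
  expect_equal(kw$df, 1)
  expect_error(kruskal_wallis(list(a = numeric(0), b = 1:3)), "empty group")
  expect_error(kruskal_wallis(list(a = c(2, 2), b = c(2, 2))), "tied")
  # permuting groups leaves H unchanged
  g1 <- list(a = rnorm(10), b = rnorm(12), c = rnorm(8))
  expect_equal(kruskal_wallis(g1)$H, kruskal_wallis(rev(g1))$H)
  # invariant under strictly monotone transforms of the pooled values
  g2 <- lapply(g1, function(v) exp(v))
  expect_equal(kruskal_wallis(g1)$H, kruskal_wallis(g2)$H, tolerance = 1e-12)
})

test_that("Bonferroni caps the adjusted p at 1", {
  expect_equal(bonferroni(0.02, 3), 0.06)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(0.3, 1), 0.3)
  expect_error(bonferroni(1.2, 2), "outside")
})

test_that("chromosomes split at 20 Mb with the boundary counted macro", {
  expect_equal(chrom_class(c(19999999, 20000001, 20000000)),
               c("micro", "macro", "macro"))
  expect_error(chrom_class(0), "length")
})

test_that("relative coverage is a per-chromosome union percentage", {
  sizes <- tibble::tibble(chrom = c("chr1", "chr2"),
                          length = c(1e7, 25e6))
  cp <- dplyr::bind_rows(
    make_copy(chrom = "chr1", start = 0L, end = 1000000L,
              merged_len = 1000000L),
    make_copy(chrom = "chr1", start = 500000L, end = 1200000L,
              merged_len = 700000L, copy_id = "cp2")
  )
  rc <- relative_coverage(cp, sizes)
  expect_equal(rc$rel_cov[rc$chrom == "chr1"], 100 * 1.2e6 / 1e7)
  expect_equal(rc$rel_cov[rc$chrom == "chr2"], 0)
  expect_equal(rc$chrom_class, c("micro", "macro"))
  expect_error(relative_coverage(
    make_copy(chrom = "chrX"), sizes), "unknown")
  # all-classes coverage is at least every single-class coverage
  sim <- plant_genome(small_sim_config(seed = 4), sequence = FALSE)
  cp2 <- classify_copies(merge_fragments(sim$hits))
  rc_all <- relative_coverage(cp2, sim$chrom_sizes)
  rc_cl <- relative_coverage(cp2, sim$chrom_sizes, by = "class")
  j <- dplyr::left_join(rc_cl, rc_all, by = "chrom",
                        suffix = c("_cl", "_all"))
  expect_true(all(j$rel_cov_cl <= j$rel_cov_all + 1e-9))
})

test_that("coverage-length regression handles boundaries and recovers signs", {
  const <- tibble::tibble(length = c(1e6, 2e6, 3e6, 4e6), rel_cov = 5)
  fit <- coverage_length_regression(const)
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  expect_gt(fit$p, 0.99)
  coll <- tibble::tibble(length = seq(1e6, 5e6, by = 1e6),
                         rel_cov = 10^(seq(0.1, 0.5, by = 0.1)))
  fit2 <- coverage_length_regression(coll)
  expect_gt(fit2$slope, 0)
  expect_lt(fit2$p, 1e-6)
  expect_warning(coverage_length_regression(
    tibble::tibble(length = c(1e6, 2e6, 3e6, 4e6),
                   rel_cov = c(0, 1, 2, 3))), "zero coverage")
  # planted slope sign recovered across seeded replicates
  set.seed(3)
  hits <- replicate(100, {
    len <- runif(30, 1e6, 5e7)
    rc <- 10^(0.02 * len / 1e6 + rnorm(30, sd = 0.3))
    sign(coverage_length_regression(
      tibble::tibble(length = len, rel_cov = rc))$slope) == 1
  })
  expect_gte(mean(hits), 0.95)
})

test_that("the correlation report applies per-feature Bonferroni families", {
  set.seed(9)
  ft <- simulate_window_features(300)
  ft$is_autosome <- TRUE
  ft$is_partial <- FALSE
  rep <- te_feature_correlations(ft)
  expect_equal(nrow(rep), 12L)  # 3 categories x 4 features
  expect_true(all(rep$p_adj >= rep$p_raw))
  expect_true(all(rep$p_adj <= 1))
  expect_equal(rep$p_adj, pmin(1, 3 * rep$p_raw))
  # each correlation controls for the other three features
  expect_true(all(vapply(strsplit(rep$controls, ","), length,
                         integer(1)) == 3L))
})
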