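test_that("substitution counting applies the CpG weighting rules", {
  # identical sequences: nothing to count
  c0 <- count_substitutions("ACGT", "ACGT")
  expect_equal(c0$ts_adj, 0)
  expect_equal(c0$tv_raw, 0)
  expect_equal(c0$n_sites, 4L)
  # one transition at a CpG column counts 1/10
  c1 <- count_substitutions("ATGT", "ACGT")
  expect_equal(c1$ts_raw, 1L)
  expect_equal(c1$ts_adj, 0.1)
  expect_equal(c1$tv_raw, 0L)
  # both columns of one CpG transitioned count exactly 1 in total
  c2 <- count_substitutions("ATAT", "ACGT")
  expect_equal(c2$ts_raw, 2L)
  expect_equal(c2$ts_adj, 1.0)
  # without adjustment, raw transitions are used
  expect_equal(count_substitutions("ATAT", "ACGT", cpg_adjust = FALSE)$ts_adj, 2L)
  # gaps and ambiguous bases are excluded from usable sites
  c3 <- count_substitutions("AC-GN", "AC-GT")
  expect_equal(c3$n_sites, 3L)
  expect_error(count_substitutions("--", "--"), "empty alignment")
})

test_that("kimura2 matches the closed form and respects its domain", {
  expect_equal(kimura2(0, 0), 0)
  expect_equal(kimura2(0.1, 0.05), 17.02, tolerance = 5e-4)
  expect_error(kimura2(0.5, 0.25), "saturated")
  # monotone increasing in P and Q on the domain
  grid <- expand.grid(P = seq(0, 0.2, by = 0.04), Q = seq(0, 0.2, by = 0.04))
  K <- kimura2(grid$P, grid$Q)
  for (q in unique(grid$Q)) {
    expect_true(all(diff(K[grid$Q == q][order(grid$P[grid$Q == q])]) > 0))
  }
  for (p in unique(grid$P)) {
    expect_true(all(diff(K[grid$P == p][order(grid$Q[grid$P == p])]) > 0))
  }
})

test_that("with no CpG context, K equals the textbook K2P distance", {
  # cross-check against ape's K80 distance on random gapless pairs
  set.seed(42)
  for (i in 1:10) {
    n <- 600L
    cons <- paste(sample(c("A", "T"), n, TRUE), collapse = "")  # no CG possible
    q <- strsplit(cons, "")[[1]]
    mut <- sample(n, 60)
    q[mut] <- vapply(q[mut], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, "")
    query <- paste(q, collapse = "")
    counts <- count_substitutions(query, cons)
    expect_equal(counts$ts_adj, counts$ts_raw)
    K_ours <- kimura2(counts)
    m <- ape::as.DNAbin(matrix(c(strsplit(tolower(query), "")[[1]],
                                 strsplit(tolower(cons), "")[[1]]),
                               nrow = 2, byrow = TRUE))
    K_ape <- 100 * as.numeric(ape::dist.dna(m, model = "K80"))
    expect_equal(K_ours, K_ape, tolerance = 1e-9)
  }
})

test_that("per-copy divergence is the length-weighted fragment mean", {
  expect_equal(copy_kimura(5, 100), 5)
  expect_equal(copy_kimura(c(2, 6), c(100, 300)), 5)
  expect_equal(copy_kimura(c(2, 6), c(100, 100)), 4)
  expect_error(copy_kimura(numeric(0), numeric(0)), "no fragments")
})

test_that("divergence converts linearly to age with T = K / (2 mu)", {
  m <- age_model()
  expect_equal(age_mya(0, m), 0)
  expect_equal(age_mya(7, m), 15.2, tolerance = 0.005)
  expect_lte(age_mya(7, m), 16)  # the recent threshold stays below ~16 My
  expect_equal(age_mya(14, m), 2 * age_mya(7, m))
})

test_that("age classification is boundary-inclusive at the threshold", {
  m <- age_model()
  expect_equal(classify_age(7, m), "recent")
  expect_equal(classify_age(7.000001, m), "ancient")
  expect_equal(classify_age(0, m), "recent")
})

test_that("the divergence estimator is calibrated on simulated copies", {
  # copies >= 1000 bp evolved to a known K_true; the CpG-adjusted estimate
  # should be unbiased to within half a divergence unit
  set.seed(7)
  cons <- random_dna_test(1500, 0.45)
  for (K_true in c(5, 15)) {
    K_hat <- replicate(60, {
      ev <- evolve_copy(cons, K_true)
      kimura2(count_substitutions(ev$sequence, ev$consensus))
    })
    expect_lt(abs(mean(K_hat) - K_true), 0.5)
  }
})

test_that("align_divergence appends counts and K per block", {
  sim <- plant_genome(small_sim_config(seed = 2), sequence = FALSE)
  div <- align_divergence(sim$blocks)
  expect_true(all(c("n_sites", "ts_adj", "P", "Q", "K") %in% names(div)))
  expect_equal(nrow(div), nrow(sim$blocks))
  expect_true(all(div$K >= 0))
  expect_true(all(div$ts_adj <= div$ts_raw + 1e-12))
  expect_true(all(div$P + div$Q <= 1))
})
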