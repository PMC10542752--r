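# Shared fixture builders. All fixtures are generated in code.

# a hit tibble row with sensible defaults, internal (0-based) coordinates
make_hit <- function(chrom = "chr1", start = 0L, end = 100L, strand = "+",
                     family = "famA", class_family = "LINE/CR1",
                     score = 200L, pct_div = 5, cons_start = 1L,
                     cons_end = end - start, cons_left = 0L, run_id = 1L,
                     star = FALSE, K = NULL) {
  h <- tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    strand = strand, family = family, class_family = class_family,
    class = te_class_label(class_family), score = as.integer(score),
    pct_div = pct_div, pct_del = 0, pct_ins = 0,
    cons_start = as.integer(cons_start), cons_end = as.integer(cons_end),
    cons_left = as.integer(cons_left), run_id = as.integer(run_id),
    star = star
  )
  if (!is.null(K)) h$K <- K
  h
}

make_hits <- function(...) {
  h <- dplyr::bind_rows(...)
  dplyr::arrange(h, chrom, start)
}

# minimal copy tibble for filter/summary tests
make_copy <- function(chrom = "chr1", start = 0L, end = 1000L,
                      strand = "+", family = "famA", class = "LINE",
                      merged_len = end - start, cons_span_frac = 0.9,
                      K = 5, age_class = "unset", n_fragments = 1L,
                      copy_id = "cp000001") {
  tibble::tibble(
    copy_id = copy_id, chrom = chrom, start = as.integer(start),
    end = as.integer(end), strand = strand, family = family, class = class,
    n_fragments = as.integer(n_fragments),
    merged_len = as.integer(merged_len),
    cons_cov_bp = as.integer(round(cons_span_frac * merged_len)),
    cons_len = as.integer(merged_len),
    cons_span_frac = cons_span_frac, K = K, age_mya = NA_real_,
    age_class = age_class,
    fragments = list(tibble::tibble(start = as.integer(start),
                                    end = as.integer(end),
                                    run_id = 1L, K = K,
                                    w = as.integer(end - start)))
  )
}

empty_copies_test <- function() make_copy()[0, ]

copies_to_intervals_test <- function(copies) {
  n_fr <- vapply(copies$fragments, nrow, integer(1))
  fr <- dplyr::bind_rows(copies$fragments)
  tibble::tibble(chrom = rep(copies$chrom, n_fr), start = fr$start,
                 end = fr$end)
}

random_dna_test <- function(n, gc = 0.42) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# small, fast simulation configuration for repeated-seed tests
small_sim_config <- function(seed = 1, ...) {
  sim_config(
    seed = seed,
    chrom_lengths = c(chr1 = 150000, chr2 = 100000),
    sex_chroms = character(0),
    copy_spec = tibble::tibble(
      family = c("ERVK_sim", "CR1_sim", "L2_sim", "hAT_sim"),
      n = c(5L, 8L, 5L, 4L),
      k_dist = c("normal", "uniform", "uniform", "uniform"),
      k1 = c(1, 5, 8, 5),
      k2 = c(0.5, 25, 25, 15)
    ),
    nesting_prob = 0.4,
    ...
  )
}
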