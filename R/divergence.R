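# CpG-adjusted Kimura 2-parameter divergence, insertion-age conversion and
# recent/ancient classification.

#' Age model: mutation rate and recent/ancient divergence threshold
#'
#' Holds the neutral substitution rate used to convert divergence into an
#' insertion age and the divergence cut-off separating recent from ancient
#' copies. The defaults are the collared-flycatcher rate of 2.3e-9
#' substitutions per site per year and a threshold of K <= 7 percent, which
#' corresponds to a maximum insertion age of roughly 15 million years
#' (see [age_mya()]).
#'
#' @param mu Substitutions per site per year; must be > 0.
#' @param recent_threshold_K Percent divergence at or below which a copy is
#'   classified as a recent insertion; in `[0, 100]`.
#' @return A list with class `"age_model"`.
#' @examples
#' age_mya(7, age_model())  # ~15.2 My
#' @export
age_model <- function(mu = 2.3e-9, recent_threshold_K = 7) {
  if (!is.numeric(mu) || mu <= 0) stopf("mu must be > 0")
  if (recent_threshold_K < 0 || recent_threshold_K > 100) {
    stopf("recent_threshold_K must be in [0, 100]")
  }
  structure(list(mu = mu, recent_threshold_K = recent_threshold_K),
            class = "age_model")
}

#' Count substitutions in a copy-versus-consensus alignment
#'
#' Classifies every alignment column as match, transition (A<->G, C<->T),
#' transversion, gap or ambiguous. Gap and ambiguous (non-ACGT) columns are
#' excluded from the usable site count. With `cpg_adjust = TRUE`
#' transitions in CpG context are down-weighted: a single transition at a
#' column belonging to a consensus `CG` dinucleotide counts 1/10, and when
#' both columns of one consensus CpG are transitions the pair contributes
#' exactly 1 transition in total. Transversions are never reweighted.
#'
#' @param query_seq,cons_seq Aligned sequences of equal length (`-` gaps).
#' @param cpg_adjust Apply the CpG down-weighting (default `TRUE`); with
#'   `FALSE`, `ts_adj` equals `ts_raw` and `K` from [kimura2()] is the
#'   textbook K2P distance.
#' @return One-row tibble: `n_sites`, `ts_raw`, `tv_raw`, `ts_adj`
#'   (possibly fractional), `P = ts_adj / n_sites`, `Q = tv_raw / n_sites`.
#' @examples
#' count_substitutions("ATGT", "ACGT")  # CpG transition: ts_adj = 0.1
#' @export
count_substitutions <- function(query_seq, cons_seq, cpg_adjust = TRUE) {
  q <- strsplit(toupper(query_seq), "")[[1]]
  s <- strsplit(toupper(cons_seq), "")[[1]]
  if (length(q) != length(s)) {
    stopf("aligned sequences differ in length (%d vs %d)", length(q), length(s))
  }
  acgt <- c("A", "C", "G", "T")
  valid <- q %in% acgt & s %in% acgt
  n_sites <- sum(valid)
  if (n_sites == 0L) stopf("empty alignment: no usable columns")
  mism <- valid & q != s
  purine <- c("A", "G")
  is_ts <- mism & ((q %in% purine) == (s %in% purine))
  is_tv <- mism & !is_ts
  ts_raw <- sum(is_ts)
  tv_raw <- sum(is_tv)
  if (!cpg_adjust) {
    ts_adj <- ts_raw
  } else {
    pairs <- cpg_pairs(s)
    in_pair <- rep(FALSE, length(s))
    if (nrow(pairs) > 0L) in_pair[c(pairs$c_col, pairs$g_col)] <- TRUE
    ts_adj <- sum(is_ts & !in_pair)
    if (nrow(pairs) > 0L) {
      tc <- is_ts[pairs$c_col]
      tg <- is_ts[pairs$g_col]
      ts_adj <- ts_adj + sum(ifelse(tc & tg, 1, (tc + tg) * 0.1))
    }
  }
  tibble(n_sites = n_sites, ts_raw = ts_raw, tv_raw = tv_raw,
         ts_adj = ts_adj, P = ts_adj / n_sites, Q = tv_raw / n_sites)
}

# Aligned column indices (c_col, g_col) of each CG dinucleotide in the
# ungapped consensus. CG occurrences cannot overlap, so pairing is unique.
cpg_pairs <- function(cons_cols) {
  non_gap <- which(cons_cols != "-")
  bases <- cons_cols[non_gap]
  if (length(bases) < 2L) return(tibble(c_col = integer(), g_col = integer()))
  is_cg <- which(bases[-length(bases)] == "C" & bases[-1] == "G")
  tibble(c_col = non_gap[is_cg], g_col = non_gap[is_cg + 1L])
}

#' Kimura 2-parameter distance (percent)
#'
#' `K = 100 * (-1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q))` where `P` and `Q`
#' are the transition and transversion proportions. Outside the domain
#' (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) the distance is undefined
#' (saturated) and an error is raised.
#'
#' @param P Transition proportion, or a tibble from
#'   [count_substitutions()] holding `P` and `Q` columns.
#' @param Q Transversion proportion (ignored when `P` is a tibble).
#' @return Percent divergence, vectorised over `P`/`Q`.
#' @examples
#' kimura2(0.1, 0.05)  # 17.02
#' @export
kimura2 <- function(P, Q = NULL) {
  if (is.data.frame(P)) {
    Q <- P$Q
    P <- P$P
  }
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  if (any(a <= 0 | b <= 0)) stopf("saturated divergence: log argument <= 0")
  100 * (-0.5 * log(a) - 0.25 * log(b))
}

#' Length-weighted per-copy divergence
#'
#' The divergence of a merged copy is the mean of its fragment divergences
#' weighted by aligned fragment length.
#'
#' @param K Fragment divergences (percent).
#' @param len Aligned fragment lengths (bp), all > 0.
#' @return Scalar weighted mean.
#' @export
copy_kimura <- function(K, len) {
  if (length(K) == 0L) stopf("copy_kimura: no fragments")
  if (length(K) != length(len)) stopf("K and len differ in length")
  if (any(len <= 0)) stopf("fragment lengths must be > 0")
  sum(K * len) / sum(len)
}

#' Convert percent divergence to insertion age in million years
#'
#' `T = (K / 100) / (2 mu) / 1e6`: divergence accumulates on the copy
#' lineage since insertion at rate `mu` relative to a consensus that proxies
#' the ancestral sequence, so the per-site distance grows at `2 mu` per
#' year. At the default rate, K = 7 maps to about 15.2 My.
#'
#' @param K Percent divergence (>= 0), vectorised.
#' @param model An [age_model()].
#' @return Age in million years.
#' @export
age_mya <- function(K, model = age_model()) {
  (K / 100) / (2 * model$mu) / 1e6
}

#' Classify copies as recent or ancient insertions
#'
#' A copy is recent when its divergence is at or below the model threshold
#' (boundary inclusive), ancient otherwise.
#'
#' @param K Percent divergence, vectorised.
#' @param model An [age_model()].
#' @return Character vector over `{"recent", "ancient"}`.
#' @export
classify_age <- function(K, model = age_model()) {
  ifelse(K <= model$recent_threshold_K, "recent", "ancient")
}

#' Per-block divergence for a table of alignment blocks
#'
#' Runs [count_substitutions()] and [kimura2()] over every alignment block,
#' appending the substitution counts, the usable aligned length and `K`.
#'
#' @param blocks Alignment tibble from [parse_rm_align()].
#' @param cpg_adjust Apply the CpG adjustment (default `TRUE`).
#' @return `blocks` with columns `n_sites`, `ts_raw`, `tv_raw`, `ts_adj`,
#'   `P`, `Q`, `K` added.
#' @export
align_divergence <- function(blocks, cpg_adjust = TRUE) {
  counts <- purrr::map2(blocks$query_seq, blocks$cons_seq,
                        count_substitutions, cpg_adjust = cpg_adjust)
  counts <- dplyr::bind_rows(counts)
  counts$K <- kimura2(counts)
  dplyr::bind_cols(blocks, counts)
}
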