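# Merging RepeatMasker hit fragments into TE copies, LTR structure
# assembly, and the 80-80-80 retention filter.

#' Merge and filter parameters
#'
#' Holds the defragmentation gap parameters and the three thresholds of the
#' 80-80-80 rule: a retained copy must be at least `min_len` bp long
#' (default 80), at least 80% identical to its consensus -- expressed as a
#' divergence ceiling, copies with `K >= min_identity_K` (default 20) are
#' removed -- and cover at least `min_cons_span` (default 0.80) of the
#' consensus length.
#'
#' @param max_gap Maximum genomic gap (bp) between consecutive fragments of
#'   one copy (default 2500).
#' @param cons_overlap_tol Allowed backtrack (bp) of consensus coordinates
#'   between consecutive fragments (default 15).
#' @param min_len Minimum merged copy length in bp.
#' @param min_identity_K Copies with divergence at or above this percent
#'   are filtered out.
#' @param min_cons_span Minimum fraction of the consensus covered by the
#'   union of fragment consensus intervals.
#' @param strict Apply all three criteria; with `FALSE` the consensus-span
#'   criterion is skipped and only length and identity are enforced.
#' @return A list with class `"merge_params"`.
#' @export
merge_params <- function(max_gap = 2500, cons_overlap_tol = 15, min_len = 80,
                         min_identity_K = 20, min_cons_span = 0.80,
                         strict = TRUE) {
  vals <- c(max_gap, cons_overlap_tol, min_len, min_identity_K, min_cons_span)
  if (any(vals < 0)) stopf("merge_params: thresholds must be >= 0")
  structure(list(max_gap = max_gap, cons_overlap_tol = cons_overlap_tol,
                 min_len = min_len, min_identity_K = min_identity_K,
                 min_cons_span = min_cons_span, strict = isTRUE(strict)),
            class = "merge_params")
}

#' Merge RepeatMasker hit fragments into TE copies
#'
#' Deterministic greedy left-to-right merge. Two hits join the same copy
#' when (a) they share a `run_id` on the same chromosome, or (b) they share
#' family, chromosome and strand, the genomic gap to the copy's last
#' fragment is at most `max_gap`, and the consensus coordinates continue
#' collinearly for the strand (the next fragment's `cons_start` may
#' backtrack at most `cons_overlap_tol` bp below the previous `cons_end` on
#' `+`; mirrored on `-`). When several open copies could absorb a hit the
#' one with the nearest genomic end wins. Every hit ends up in exactly one
#' copy.
#'
#' Per-fragment divergence is taken from a `K` column when present (e.g.
#' after joining [align_divergence()] output) and from `pct_div` otherwise;
#' the copy divergence is the length-weighted mean ([copy_kimura()]),
#' weighted by `n_sites` when available, else by genomic fragment length.
#'
#' @param hits Hit tibble from [parse_rm_out()], sorted by
#'   (`chrom`, `start`); unsorted input is an error.
#' @param params A [merge_params()].
#' @param model Optional [age_model()]; when supplied, `age_mya` and
#'   `age_class` are filled in (see [classify_copies()]).
#' @return A copy tibble: `copy_id`, `chrom`, `start`, `end` (0-based
#'   half-open envelope), `strand`, `family`, `class`, `n_fragments`,
#'   `merged_len` (summed fragment bp, gaps excluded), `cons_cov_bp`,
#'   `cons_len`, `cons_span_frac`, `K`, `age_mya`, `age_class`, and a
#'   `fragments` list column of per-fragment intervals.
#' @export
merge_fragments <- function(hits, params = merge_params(), model = NULL) {
  if (nrow(hits) == 0L) return(empty_copies())
  ord <- order(hits$chrom, hits$start, method = "radix")
  if (!identical(ord, seq_len(nrow(hits)))) {
    stopf("merge_fragments: hits must be sorted by (chrom, start)")
  }
  frag_K <- if ("K" %in% names(hits)) hits$K else hits$pct_div
  frag_w <- if ("n_sites" %in% names(hits)) hits$n_sites else hits$end - hits$start

  assign_to <- integer(nrow(hits))
  # open-copy bookkeeping (grown as vectors; modest n per genome)
  cp_chrom <- character(0); cp_strand <- character(0); cp_family <- character(0)
  cp_end <- integer(0); cp_last_cs <- integer(0); cp_last_ce <- integer(0)
  cp_run_ids <- list()
  n_cp <- 0L
  for (i in seq_len(nrow(hits))) {
    h_chrom <- hits$chrom[[i]]; h_start <- hits$start[[i]]
    h_strand <- hits$strand[[i]]; h_family <- hits$family[[i]]
    cand <- integer(0)
    if (n_cp > 0L) {
      same_chrom <- cp_chrom == h_chrom
      rule_a <- same_chrom &
        vapply(cp_run_ids, function(r) hits$run_id[[i]] %in% r, logical(1))
      gap <- h_start - cp_end
      collinear <- if (h_strand == "+") {
        hits$cons_start[[i]] >= cp_last_ce - params$cons_overlap_tol
      } else {
        hits$cons_end[[i]] <= cp_last_cs + params$cons_overlap_tol
      }
      rule_b <- same_chrom & cp_strand == h_strand & cp_family == h_family &
        gap <= params$max_gap & collinear
      cand <- which(rule_a | rule_b)
    }
    if (length(cand) == 0L) {
      n_cp <- n_cp + 1L
      cp_chrom[n_cp] <- h_chrom; cp_strand[n_cp] <- h_strand
      cp_family[n_cp] <- h_family; cp_end[n_cp] <- hits$end[[i]]
      cp_last_cs[n_cp] <- hits$cons_start[[i]]
      cp_last_ce[n_cp] <- hits$cons_end[[i]]
      cp_run_ids[[n_cp]] <- hits$run_id[[i]]
      assign_to[[i]] <- n_cp
    } else {
      j <- cand[[which.max(cp_end[cand])]]  # nearest genomic end wins
      if (hits$start[[i]] < cp_end[[j]] ) {
        # overlapping fragment absorbed into the same copy
        warnf("merge_fragments: overlapping fragments merged at %s:%d",
              h_chrom, h_start)
      }
      cp_end[[j]] <- max(cp_end[[j]], hits$end[[i]])
      cp_last_cs[[j]] <- hits$cons_start[[i]]
      cp_last_ce[[j]] <- hits$cons_end[[i]]
      cp_run_ids[[j]] <- unique(c(cp_run_ids[[j]], hits$run_id[[i]]))
      assign_to[[i]] <- j
    }
  }

  copies <- lapply(seq_len(n_cp), function(j) {
    idx <- which(assign_to == j)
    fr <- hits[idx, ]
    cons_len <- max(fr$cons_end + fr$cons_left)
    cons_cov <- interval_union_bp(fr$cons_start - 1L, fr$cons_end)
    tibble(
      chrom = fr$chrom[[1]], start = min(fr$start), end = max(fr$end),
      strand = fr$strand[[1]], family = fr$family[[1]],
      class = fr$class[[1]], n_fragments = length(idx),
      merged_len = sum(fr$end - fr$start),
      cons_cov_bp = cons_cov, cons_len = cons_len,
      cons_span_frac = min(cons_cov / cons_len, 1),
      K = copy_kimura(frag_K[idx], frag_w[idx]),
      fragments = list(tibble(start = fr$start, end = fr$end,
                              run_id = fr$run_id, K = frag_K[idx],
                              w = frag_w[idx]))
    )
  })
  copies <- dplyr::bind_rows(copies)
  copies <- dplyr::arrange(copies, .data$chrom, .data$start, .data$family)
  copies$copy_id <- sprintf("cp%06d", seq_len(nrow(copies)))
  copies$age_mya <- NA_real_
  copies$age_class <- "unset"
  copies <- copies[, copy_cols()]
  if (!is.null(model)) copies <- classify_copies(copies, model)
  copies
}

copy_cols <- function() {
  c("copy_id", "chrom", "start", "end", "strand", "family", "class",
    "n_fragments", "merged_len", "cons_cov_bp", "cons_len",
    "cons_span_frac", "K", "age_mya", "age_class", "fragments")
}

empty_copies <- function() {
  tibble(
    copy_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), family = character(),
    class = character(), n_fragments = integer(), merged_len = integer(),
    cons_cov_bp = integer(), cons_len = integer(), cons_span_frac = double(),
    K = double(), age_mya = double(), age_class = character(),
    fragments = list()
  )
}

#' Fill in insertion age and recent/ancient class for merged copies
#'
#' @param copies Copy tibble from [merge_fragments()].
#' @param model An [age_model()].
#' @return `copies` with `age_mya` and `age_class` set from the copy `K`.
#' @export
classify_copies <- function(copies, model = age_model()) {
  copies$age_mya <- age_mya(copies$K, model)
  copies$age_class <- classify_age(copies$K, model)
  copies
}

#' Assemble LTR retrotransposon structures from adjacent copies
#'
#' The consensus library names LTR parts by a shared stem: `X_LTR` (the
#' long terminal repeat) and `X_I` (the internal sequence). Adjacent copies
#' matching the pattern LTR-internal-LTR with one stem, on one strand, with
#' genomic gaps at most `max_gap`, are fused into one full-element copy
#' named by the stem. Scanning is leftmost-first; unpaired (solo) LTRs are
#' left untouched. The fused consensus span is the summed covered bp of the
#' three parts over the full element length (two LTRs plus internal).
#'
#' @param copies Copy tibble from [merge_fragments()].
#' @param library Consensus library tibble from [read_fasta_library()]
#'   (used for part lengths via `cons_len` already carried on copies).
#' @param params A [merge_params()].
#' @return Copy tibble with fused LTR elements replacing their parts.
#' @export
assemble_ltr <- function(copies, library = NULL, params = merge_params()) {
  if (nrow(copies) == 0L) return(copies)
  stem_of <- function(fam) sub("_(LTR|I)$", "", fam)
  role_of <- function(fam) ifelse(endsWith(fam, "_LTR"), "ltr",
                                  ifelse(endsWith(fam, "_I"), "internal", "none"))
  copies <- dplyr::arrange(copies, .data$chrom, .data$start, .data$family)
  role <- role_of(copies$family)
  stem <- stem_of(copies$family)
  used <- rep(FALSE, nrow(copies))
  fused <- list()
  ord <- order(copies$chrom, copies$start, method = "radix")
  for (ii in seq_along(ord)) {
    i <- ord[[ii]]
    if (used[[i]] || role[[i]] != "ltr" || ii >= length(ord) - 1L) next
    # look ahead for internal then ltr of the same stem/strand within max_gap
    rest <- ord[(ii + 1L):length(ord)]
    rest <- rest[!used[rest] & copies$chrom[rest] == copies$chrom[[i]] &
                   copies$strand[rest] == copies$strand[[i]] &
                   stem[rest] == stem[[i]]]
    if (length(rest) < 2L) next
    j <- rest[[1]]; k <- rest[[2]]
    ok <- role[[j]] == "internal" && role[[k]] == "ltr" &&
      (copies$start[[j]] - copies$end[[i]]) <= params$max_gap &&
      (copies$start[[j]] - copies$end[[i]]) >= 0 &&
      (copies$start[[k]] - copies$end[[j]]) <= params$max_gap &&
      (copies$start[[k]] - copies$end[[j]]) >= 0
    if (!ok) next
    used[c(i, j, k)] <- TRUE
    parts <- copies[c(i, j, k), ]
    full_len <- 2L * parts$cons_len[[1]] + parts$cons_len[[2]]
    w <- vapply(parts$fragments, function(f) sum(f$w), numeric(1))
    fused[[length(fused) + 1L]] <- tibble(
      copy_id = parts$copy_id[[1]],
      chrom = parts$chrom[[1]], start = parts$start[[1]],
      end = parts$end[[3]], strand = parts$strand[[1]],
      family = stem[[i]], class = "LTR",
      n_fragments = sum(parts$n_fragments),
      merged_len = sum(parts$merged_len),
      cons_cov_bp = sum(parts$cons_cov_bp),
      cons_len = full_len,
      cons_span_frac = min(sum(parts$cons_cov_bp) / full_len, 1),
      K = copy_kimura(parts$K, w),
      age_mya = NA_real_, age_class = "unset",
      fragments = list(dplyr::bind_rows(parts$fragments))
    )
  }
  out <- dplyr::bind_rows(c(list(copies[!used, ]), fused))
  dplyr::arrange(out, .data$chrom, .data$start, .data$family)
}

#' Apply the 80-80-80 retention rule
#'
#' A copy is retained when `merged_len >= min_len`, `K < min_identity_K`,
#' and (in strict mode) `cons_span_frac >= min_cons_span`. Unclassified
#' copies are always removed: the curated annotation keeps only the four
#' recognised TE types.
#'
#' @param copies Copy tibble with `K` and `cons_span_frac` filled in.
#' @param params A [merge_params()].
#' @return The retained subset of `copies`.
#' @export
filter_808080 <- function(copies, params = merge_params()) {
  keep <- copies$merged_len >= params$min_len &
    copies$K < params$min_identity_K &
    copies$class != "Unclassified"
  if (params$strict) keep <- keep & copies$cons_span_frac >= params$min_cons_span
  copies[keep, ]
}

#' Summarise an annotation by repeat type
#'
#' Per repeat type and overall: number of copies (or fragments), summed
#' length in bp and the percentage of the genome covered. Works on a copy
#' tibble (summing `merged_len`, i.e. fragment-union bp rather than
#' envelope bp) or on a raw hit tibble (summing `end - start`).
#'
#' @param x Copy or hit tibble with a `class` column.
#' @param genome_len Assembly length in bp (> 0).
#' @return Tibble `class`, `n`, `total_bp`, `pct_genome`, with a final
#'   `"Total"` row.
#' @export
annotation_summary <- function(x, genome_len) {
  if (genome_len <= 0) stopf("genome_len must be > 0")
  len <- if ("merged_len" %in% names(x)) x$merged_len else x$end - x$start
  d <- tibble(class = x$class, len = len)
  per <- d |>
    dplyr::group_by(class = factor(.data$class, levels = te_classes)) |>
    dplyr::summarise(n = dplyr::n(), total_bp = sum(.data$len),
                     .groups = "drop") |>
    dplyr::mutate(class = as.character(.data$class))
  total <- tibble(class = "Total", n = nrow(d), total_bp = sum(d$len))
  out <- dplyr::bind_rows(per, total)
  out$pct_genome <- 100 * out$total_bp / genome_len
  out
}
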