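# Fixed-width genome windows and the per-window feature table: TE coverage
# (overall, per type, per age class), gene coverage, GC content, CpG-island
# coverage and distance-weighted recombination rate.

#' Tile chromosomes into non-overlapping windows
#'
#' @param chrom_sizes Tibble `chrom`, `length`, optionally `is_autosome`
#'   (see [read_chrom_sizes()]).
#' @param w Window width in bp (default 200 kb); must be > 0.
#' @return Tibble `chrom`, `start`, `end` (0-based half-open), `width`,
#'   `is_partial` (trailing window shorter than `w`), `is_autosome`.
#' @export
make_windows <- function(chrom_sizes, w = 200000L) {
  if (w <= 0) stopf("window width must be > 0")
  if (!"is_autosome" %in% names(chrom_sizes)) chrom_sizes$is_autosome <- TRUE
  purrr::pmap(chrom_sizes[, c("chrom", "length", "is_autosome")],
              function(chrom, length, is_autosome) {
    starts <- seq(0, length - 1, by = w)
    ends <- pmin(starts + w, length)
    tibble(chrom = chrom, start = as.integer(starts), end = as.integer(ends),
           width = as.integer(ends - starts),
           is_partial = (ends - starts) < w, is_autosome = is_autosome)
  }) |> dplyr::bind_rows()
}

#' Percent of each window covered by a set of intervals
#'
#' Overlapping intervals are counted once (union), and intervals crossing a
#' window edge contribute only their clipped bp to that window.
#'
#' @param windows Window tibble from [make_windows()].
#' @param intervals Tibble `chrom`, `start`, `end`, 0-based half-open.
#' @return Numeric vector, one percentage per window row.
#' @export
coverage_pct <- function(windows, intervals) {
  bp <- window_overlap_bp(windows, intervals)
  100 * bp / (windows$end - windows$start)
}

# union-overlap bp of `intervals` within each window row
window_overlap_bp <- function(windows, intervals) {
  out <- numeric(nrow(windows))
  if (is.null(intervals) || nrow(intervals) == 0L) return(out)
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    iv <- intervals[intervals$chrom == ch, ]
    if (nrow(iv) == 0L) next
    ir <- IRanges::reduce(IRanges::IRanges(iv$start + 1L, iv$end))
    wr <- IRanges::IRanges(windows$start[wi] + 1L, windows$end[wi])
    ov <- IRanges::findOverlaps(wr, ir)
    if (length(ov) == 0L) next
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    clip <- pmin(IRanges::end(ir)[s], IRanges::end(wr)[q]) -
      pmax(IRanges::start(ir)[s], IRanges::start(wr)[q]) + 1L
    sums <- tapply(clip, q, sum)
    out[wi[as.integer(names(sums))]] <- as.numeric(sums)
  }
  out
}

#' GC content of each window
#'
#' `100 * (G + C) / (A + C + G + T)` over the window's sequence slice;
#' ambiguous bases (N and other IUPAC codes) are excluded from the
#' denominator. A window with no unambiguous base gets `NA`.
#'
#' @param windows Window tibble.
#' @param sequence Named [Biostrings::DNAStringSet] (or named character
#'   vector) of chromosome sequences.
#' @return Numeric vector of percentages, one per window row.
#' @export
gc_pct <- function(windows, sequence) {
  if (!methods::is(sequence, "DNAStringSet")) {
    sequence <- Biostrings::DNAStringSet(sequence)
  }
  out <- rep(NA_real_, nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    if (!ch %in% names(sequence)) next
    v <- Biostrings::Views(sequence[[ch]],
                           start = windows$start[wi] + 1L,
                           end = windows$end[wi])
    freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    denom <- rowSums(freq)
    gc <- rowSums(freq[, c("C", "G"), drop = FALSE])
    out[wi] <- ifelse(denom == 0, NA_real_, 100 * gc / denom)
  }
  out
}

#' Distance-weighted mean recombination rate per window
#'
#' The window rate is the mean of the map-interval rates weighted by the
#' bp each interval contributes inside the window; windows with no map
#' overlap get `NA`.
#'
#' @param windows Window tibble.
#' @param map Interval track `chrom`, `start`, `end`, `value` (per-bp rate)
#'   as returned by `read_tracks(..., format = "tsv")`.
#' @return Numeric vector of rates, one per window row.
#' @export
rec_rate_window <- function(windows, map) {
  out <- rep(NA_real_, nrow(windows))
  if (is.null(map) || nrow(map) == 0L) return(out)
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    iv <- map[map$chrom == ch, ]
    if (nrow(iv) == 0L) next
    ir <- IRanges::IRanges(iv$start + 1L, iv$end)
    wr <- IRanges::IRanges(windows$start[wi] + 1L, windows$end[wi])
    ov <- IRanges::findOverlaps(wr, ir)
    if (length(ov) == 0L) next
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    clip <- pmin(IRanges::end(ir)[s], IRanges::end(wr)[q]) -
      pmax(IRanges::start(ir)[s], IRanges::start(wr)[q]) + 1L
    wsum <- tapply(clip * iv$value[s], q, sum)
    bsum <- tapply(clip, q, sum)
    out[wi[as.integer(names(wsum))]] <- as.numeric(wsum) / as.numeric(bsum)
  }
  out
}

# flatten copies to genomic intervals; coverage uses fragment unions, not
# the copy envelope, so bp of nested foreign TEs is not double-counted
copies_to_intervals <- function(copies, use_fragments = TRUE) {
  if (nrow(copies) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  class = character(), age_class = character()))
  }
  if (use_fragments && "fragments" %in% names(copies)) {
    n_fr <- vapply(copies$fragments, nrow, integer(1))
    fr <- dplyr::bind_rows(copies$fragments)
    tibble(chrom = rep(copies$chrom, n_fr), start = fr$start, end = fr$end,
           class = rep(copies$class, n_fr),
           age_class = rep(copies$age_class, n_fr))
  } else {
    tibble(chrom = copies$chrom, start = copies$start, end = copies$end,
           class = copies$class, age_class = copies$age_class)
  }
}

#' Assemble the windowed genome-feature table
#'
#' Fills every window metric: TE coverage overall, per repeat type and per
#' age class (recent/ancient copy sets are disjoint), gene coverage,
#' CpG-island coverage, GC content and the distance-weighted recombination
#' rate. TE coverage is computed from fragment unions so the bp of nested
#' foreign copies is not counted twice.
#'
#' @param windows Window tibble from [make_windows()].
#' @param copies Copy tibble with `age_class` filled in
#'   ([classify_copies()]).
#' @param genes,cpg Interval tracks (`chrom`, `start`, `end`) or `NULL`.
#' @param recmap Recombination map track with `value`, or `NULL`.
#' @param sequence Chromosome sequences for GC content, or `NULL`.
#' @return The window tibble with columns `te_cov_all`, `te_cov_LTR`,
#'   `te_cov_LINE`, `te_cov_SINE`, `te_cov_DNA`, `te_cov_recent`,
#'   `te_cov_ancient`, `gene_cov`, `cpg_cov`, `gc`, `rec_rate` appended.
#' @export
feature_table <- function(windows, copies, genes = NULL, cpg = NULL,
                          recmap = NULL, sequence = NULL) {
  iv <- copies_to_intervals(copies)
  offenders <- setdiff(unique(iv$chrom), unique(windows$chrom))
  if (length(offenders) > 0L) {
    stopf("feature_table: copies on chromosomes absent from the windows: %s",
          paste(offenders, collapse = ", "))
  }
  out <- windows
  out$te_cov_all <- coverage_pct(windows, iv)
  for (cl in c("LTR", "LINE", "SINE", "DNA")) {
    out[[paste0("te_cov_", cl)]] <-
      coverage_pct(windows, iv[iv$class == cl, ])
  }
  out$te_cov_recent <- coverage_pct(windows, iv[iv$age_class == "recent", ])
  out$te_cov_ancient <- coverage_pct(windows, iv[iv$age_class == "ancient", ])
  out$gene_cov <- if (is.null(genes)) NA_real_ else coverage_pct(windows, genes)
  out$cpg_cov <- if (is.null(cpg)) NA_real_ else coverage_pct(windows, cpg)
  out$gc <- if (is.null(sequence)) NA_real_ else gc_pct(windows, sequence)
  out$rec_rate <- rec_rate_window(windows, recmap)
  out
}
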