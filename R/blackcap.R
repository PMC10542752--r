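# Published per-type summary of the blackcap (Sylvia atricapilla) genome
# TE annotation, shipped as reference data. These printed totals support
# the share/fraction arithmetic without access to the assembly itself.

#' Blackcap TE annotation summary (reference data)
#'
#' Per repeat type: fragment count and bp of the raw RepeatMasker
#' annotation of the blackcap genome, and copy count and bp of the curated
#' (merged and 80-80-80 filtered) annotation. The curated annotation drops
#' all Unclassified repeats (NA in the final columns).
#'
#' @return Tibble `class`, `copies_raw`, `bp_raw`, `copies_final`,
#'   `bp_final`.
#' @export
blackcap_te_summary <- function() {
  readr::read_tsv(system.file("extdata", "blackcap_te_summary.tsv",
                              package = "tescape"),
                  col_types = "ciiii", progress = FALSE)
}

#' Blackcap recent-insertion and genome-total reference values
#'
#' Companion key-value table to [blackcap_te_summary()]: the number and bp
#' of recent TE copies (average divergence K <= 7), the percentage of LTR
#' copies and of LTR coverage attributed to recent insertions, and the
#' genome-wide totals and percentages of the raw and curated annotations.
#'
#' @return Named numeric vector.
#' @export
blackcap_recent_stats <- function() {
  d <- readr::read_tsv(system.file("extdata",
                                   "blackcap_recent_insertions.tsv",
                                   package = "tescape"),
                       col_types = "cd", progress = FALSE)
  setNames(d$value, d$key)
}

#' Per-type shares of an annotation summary
#'
#' Expresses each repeat type's copy count and total bp as a percentage of
#' the summed counts and bp over the classified types.
#'
#' @param counts Tibble with `class`, `n` and `total_bp` columns (e.g.
#'   from [annotation_summary()], minus its `Total` row, or the reference
#'   columns of [blackcap_te_summary()]).
#' @return `counts` with `share_copies` and `share_bp` (percent) added.
#' @export
class_shares <- function(counts) {
  keep <- !is.na(counts$n) & !is.na(counts$total_bp)
  counts$share_copies <- ifelse(keep, 100 * counts$n / sum(counts$n[keep]),
                                NA_real_)
  counts$share_bp <- ifelse(keep,
                            100 * counts$total_bp / sum(counts$total_bp[keep]),
                            NA_real_)
  counts
}
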