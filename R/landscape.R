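# Divergence-binned repeat landscapes: genome coverage as a function of
# Kimura substitution level, a proxy for TE activity through time.

#' Build a divergence-binned repeat landscape
#'
#' Accrues each item's length to the divergence bin `floor(K / bin_width)`.
#' In `"raw"` mode the items are RepeatMasker fragments with per-fragment
#' divergence; in `"final"` mode they are curated copies with per-copy
#' divergence -- the binning itself is identical, the mode is recorded on
#' the result. Bins from 0 up to `k_max` are always emitted, including
#' empty ones, for every group present.
#'
#' @param items Tibble with columns `group` (repeat type or family), `K`
#'   (percent divergence, >= 0) and `length_bp` (> = 0; negative lengths are
#'   an error). For convenience a hit or copy tibble can be passed: `class`
#'   is used as `group` and `merged_len` (copies) or `end - start` (hits)
#'   as `length_bp`, with `K` taken from the `K` column (falling back to
#'   `pct_div` for raw hits).
#' @param genome_len Assembly length in bp.
#' @param mode `"raw"` (per-fragment) or `"final"` (per-copy); annotation
#'   only.
#' @param bin_width Divergence bin width in percent (default 1).
#' @param k_max Largest bin lower edge emitted (default 50).
#' @param model [age_model()] used for the secondary age axis.
#' @return Tibble `group`, `bin_lo`, `bp`, `pct_genome`, `age_mya_lo`,
#'   `mode`. Within each group, `sum(pct_genome)` equals the group's total
#'   genome coverage.
#' @export
build_landscape <- function(items, genome_len, mode = c("final", "raw"),
                            bin_width = 1, k_max = 50,
                            model = age_model()) {
  mode <- match.arg(mode)
  if (genome_len <= 0) stopf("genome_len must be > 0")
  if (!"group" %in% names(items)) {
    items <- tibble(
      group = items$class,
      K = if ("K" %in% names(items)) items$K else items$pct_div,
      length_bp = if ("merged_len" %in% names(items)) items$merged_len
                  else items$end - items$start
    )
  }
  if (any(items$length_bp < 0)) stopf("negative length in landscape items")
  if (any(items$K < 0)) stopf("negative divergence in landscape items")
  bins <- seq(0, k_max, by = bin_width)
  acc <- items |>
    dplyr::mutate(bin_lo = pmin(floor(.data$K / bin_width) * bin_width,
                                k_max)) |>
    dplyr::group_by(.data$group, .data$bin_lo) |>
    dplyr::summarise(bp = sum(.data$length_bp), .groups = "drop")
  grid <- tidyr::expand_grid(group = unique(items$group), bin_lo = bins)
  out <- dplyr::left_join(grid, acc, by = c("group", "bin_lo")) |>
    dplyr::mutate(bp = dplyr::coalesce(.data$bp, 0),
                  pct_genome = 100 * .data$bp / genome_len,
                  age_mya_lo = age_mya(.data$bin_lo, model),
                  mode = mode) |>
    dplyr::arrange(.data$group, .data$bin_lo)
  out
}

#' Share of a group's coverage at low divergence
#'
#' Percentage of a group's landscape bp sitting in bins with lower edge at
#' most `K_max`; quantifies a recent activity burst (e.g. the elevated LTR
#' coverage at substitution level <= 2).
#'
#' @param bins Landscape tibble for a single group (see
#'   [build_landscape()]).
#' @param K_max Divergence ceiling in percent.
#' @return Percent of the group's total bp, 0 when the group is empty.
#' @export
recent_burst_stat <- function(bins, K_max) {
  total <- sum(bins$bp)
  if (total == 0) return(0)
  100 * sum(bins$bp[bins$bin_lo <= K_max]) / total
}

#' Plot a repeat landscape as stacked divergence bins
#'
#' @param landscape Tibble from [build_landscape()].
#' @param model [age_model()] for the secondary age axis.
#' @return A ggplot object: stacked bars of percent genome per divergence
#'   bin, coloured by group, with an insertion-age axis on top.
#' @export
plot_landscape <- function(landscape, model = age_model()) {
  ggplot2::ggplot(landscape,
                  ggplot2::aes(x = .data$bin_lo, y = .data$pct_genome,
                               fill = .data$group)) +
    ggplot2::geom_col(width = 1, position = "stack") +
    ggplot2::scale_x_continuous(
      name = "Kimura substitution level (CpG adjusted, %)",
      sec.axis = ggplot2::sec_axis(~ age_mya(.x, model),
                                   name = "age (million years)")
    ) +
    ggplot2::labs(y = "% of genome", fill = "repeat type") +
    ggplot2::theme_minimal()
}
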