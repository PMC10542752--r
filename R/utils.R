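# Internal helpers shared across modules.

#' Map a RepeatMasker class/family string to a canonical repeat type
#'
#' The text before the first `/` (with any trailing `?`) decides the label:
#' strings starting `LTR` map to `"LTR"`, `LINE` to `"LINE"`, `SINE` to
#' `"SINE"`, `DNA` or `RC` to `"DNA"`; anything else (including `Unknown`,
#' `Simple_repeat`, satellites) becomes `"Unclassified"`.
#'
#' @param class_family Character vector of `class/family` strings as found in
#'   RepeatMasker output (e.g. `"LTR/ERVK"`, `"LINE/CR1"`, `"DNA?"`).
#' @return Character vector over `{"LTR","LINE","SINE","DNA","Unclassified"}`.
#' @examples
#' te_class_label(c("LTR/ERVK", "LINE/CR1", "RC/Helitron", "Unknown"))
#' @export
te_class_label <- function(class_family) {
  head_part <- sub("[/?].*$", "", class_family)
  head_part <- sub("\\?$", "", head_part)
  dplyr::case_when(
    startsWith(head_part, "LTR") ~ "LTR",
    startsWith(head_part, "LINE") ~ "LINE",
    startsWith(head_part, "SINE") ~ "SINE",
    head_part %in% c("DNA", "RC") | startsWith(head_part, "DNA") ~ "DNA",
    TRUE ~ "Unclassified"
  )
}

te_classes <- c("SINE", "LINE", "LTR", "DNA", "Unclassified")

# bp of overlap between the union of [starts, ends) and the window [ws, we).
# Coordinates 0-based half-open.
interval_union_overlap <- function(starts, ends, ws, we) {
  keep <- ends > ws & starts < we
  if (!any(keep)) return(0L)
  s <- pmax(starts[keep], ws)
  e <- pmin(ends[keep], we)
  ir <- IRanges::reduce(IRanges::IRanges(start = s + 1L, end = e))
  sum(IRanges::width(ir))
}

# Total bp in the union of [starts, ends), 0-based half-open.
interval_union_bp <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  sum(IRanges::width(ir))
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))
warnf <- function(fmt, ...) warn(sprintf(fmt, ...))
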