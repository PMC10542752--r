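# Readers and writers for every external format the pipeline touches.
#
# Coordinate conventions: all tibbles inside the package are 0-based
# half-open; each reader/writer converts at the boundary and nowhere else.
# RepeatMasker ".out"/".align" and GFF3 are 1-based inclusive on disk; BED
# and the recombination-map TSV are 0-based half-open on disk.

# ---- RepeatMasker .out ------------------------------------------------------

rm_out_header <- c(
  "   SW   perc perc perc  query     position in query         matching  repeat         position in repeat",
  "score   div. del. ins.  sequence  begin  end       (left)   repeat    class/family   begin  end  (left)   ID",
  ""
)

empty_hits <- function() {
  tibble(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), family = character(), class_family = character(),
    class = character(), score = integer(), pct_div = double(),
    pct_del = double(), pct_ins = double(), cons_start = integer(),
    cons_end = integer(), cons_left = integer(), run_id = integer(),
    star = logical()
  )
}

strip_paren <- function(x) suppressWarnings(as.integer(sub("^\\((.*)\\)$", "\\1", x)))

# One body row. Canonical layout, 15 whitespace-separated fields plus an
# optional trailing "*":
#   score div del ins chrom begin end (left) strand family class/family
#   c1 c2 c3 ID [*]
# where the consensus triple (c1,c2,c3) is "begin end (left)" on "+" and
# "(left) end begin" on "C".
parse_rm_out_row <- function(line, line_no) {
  f <- strsplit(trimws(line), "\\s+")[[1]]
  star <- length(f) == 16L && f[[16]] == "*"
  if (!(length(f) == 15L || star)) {
    stopf(".out line %d: expected 15 fields (plus optional '*'), found %d",
          line_no, length(f))
  }
  strand_sym <- f[[9]]
  if (!strand_sym %in% c("+", "C")) {
    stopf(".out line %d: unknown strand symbol '%s'", line_no, strand_sym)
  }
  if (strand_sym == "+") {
    cons_start <- suppressWarnings(as.integer(f[[12]]))
    cons_end <- suppressWarnings(as.integer(f[[13]]))
    cons_left <- strip_paren(f[[14]])
  } else {
    cons_left <- strip_paren(f[[12]])
    cons_end <- suppressWarnings(as.integer(f[[13]]))
    cons_start <- suppressWarnings(as.integer(f[[14]]))
  }
  out <- tibble(
    chrom = f[[5]],
    start = suppressWarnings(as.integer(f[[6]])) - 1L,
    end = suppressWarnings(as.integer(f[[7]])),
    strand = if (strand_sym == "+") "+" else "-",
    family = f[[10]],
    class_family = f[[11]],
    class = te_class_label(f[[11]]),
    score = suppressWarnings(as.integer(f[[1]])),
    pct_div = suppressWarnings(as.numeric(f[[2]])),
    pct_del = suppressWarnings(as.numeric(f[[3]])),
    pct_ins = suppressWarnings(as.numeric(f[[4]])),
    cons_start = cons_start, cons_end = cons_end, cons_left = cons_left,
    run_id = suppressWarnings(as.integer(f[[15]])),
    star = star
  )
  bad <- c("start", "end", "score", "pct_div", "pct_del", "pct_ins",
           "cons_start", "cons_end", "cons_left", "run_id")
  if (anyNA(out[bad])) stopf(".out line %d: malformed numeric field", line_no)
  if (out$start >= out$end) stopf(".out line %d: start >= end", line_no)
  if (out$cons_start > out$cons_end) {
    stopf(".out line %d: consensus start > end after normalisation", line_no)
  }
  out
}

#' Read a RepeatMasker-style hit table (".out" dialect)
#'
#' Parses the whitespace-separated body after the three header lines. Minus
#' strand is encoded `C` on disk and is normalised to `-`; for `C` rows the
#' consensus coordinates appear in the order `(left) end begin` and are
#' reordered so that `cons_start <= cons_end`. Rows flagged `*` (hit
#' overlapping a higher-scoring hit) are retained and marked in the `star`
#' column so they can be excluded downstream if desired.
#'
#' @param path Path to a `.out` file.
#' @return A tibble with one row per masked fragment: `chrom`, `start`,
#'   `end` (0-based half-open), `strand` (`+`/`-`), `family`, `class_family`
#'   (the raw class/family string), `class` (see [te_class_label()]),
#'   `score`, `pct_div`, `pct_del`, `pct_ins`, `cons_start`, `cons_end`,
#'   `cons_left` (1-based consensus positions and bp remaining), `run_id`,
#'   `star`.
#' @seealso [write_rm_out()], [parse_rm_align()]
#' @export
parse_rm_out <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) < 3L) stopf("truncated .out file: %s", path)
  body <- lines[-(1:3)]
  body_idx <- which(nzchar(trimws(body)))
  if (length(body_idx) == 0L) return(empty_hits())
  dplyr::bind_rows(lapply(body_idx, function(i) {
    parse_rm_out_row(body[[i]], line_no = i + 3L)
  }))
}

#' Write a hit table in the RepeatMasker ".out" dialect
#'
#' Inverse of [parse_rm_out()]: emits three header lines then one row per
#' hit, converting back to 1-based inclusive coordinates and the `C` minus
#' strand encoding (consensus triple reordered accordingly). The genomic
#' `(left)` column is reconstructed from `chrom_sizes` when given, else 0.
#'
#' @param hits Hit tibble as returned by [parse_rm_out()].
#' @param path Output path.
#' @param chrom_sizes Optional tibble `chrom`, `length` used to fill the
#'   genomic `(left)` column.
#' @export
write_rm_out <- function(hits, path, chrom_sizes = NULL) {
  readr::write_lines(c(rm_out_header, format_rm_out_rows(hits, chrom_sizes)),
                     path)
}

format_rm_out_rows <- function(hits, chrom_sizes = NULL) {
  if (nrow(hits) == 0L) return(character(0))
  left <- rep(0L, nrow(hits))
  if (!is.null(chrom_sizes)) {
    len <- chrom_sizes$length[match(hits$chrom, chrom_sizes$chrom)]
    left <- ifelse(is.na(len), 0L, as.integer(len) - hits$end)
  }
  plus <- hits$strand == "+"
  c1 <- ifelse(plus, as.character(hits$cons_start),
               sprintf("(%d)", hits$cons_left))
  c3 <- ifelse(plus, sprintf("(%d)", hits$cons_left),
               as.character(hits$cons_start))
  paste(
    hits$score, sprintf("%.2f", hits$pct_div), sprintf("%.2f", hits$pct_del),
    sprintf("%.2f", hits$pct_ins), hits$chrom, hits$start + 1L, hits$end,
    sprintf("(%d)", left), ifelse(plus, "+", "C"), hits$family,
    hits$class_family, c1, hits$cons_end, c3, hits$run_id,
    ifelse(hits$star, "*", "")
  ) |> trimws()
}

# ---- RepeatMasker .align ----------------------------------------------------

#' Read pairwise copy-versus-consensus alignments (".align" dialect)
#'
#' Each block consists of a header line in the same 15-field layout as a
#' `.out` row, followed by interleaved pairs of sequence lines
#' (`<chrom> <pos> <chunk> <pos>` above `<family> <pos> <chunk> <pos>`),
#' and a blank line terminating the block. Chunks are concatenated to
#' reconstruct the full aligned query and consensus strings; `-` is the gap
#' character. A per-column CpG mask is computed from the block's ungapped
#' consensus: a column is CpG context when its consensus base is the C or
#' the G of a `CG` dinucleotide (gap columns are never CpG context).
#'
#' @param path Path to a `.align` file.
#' @param consensus_library Optional consensus library tibble (see
#'   [read_fasta_library()]); when supplied, a block whose consensus name is
#'   absent from the library is an error.
#' @return A tibble with one row per alignment block: the `.out` columns of
#'   the header plus `query_seq`, `cons_seq` (aligned strings of equal
#'   length) and `cpg_mask` (list column of per-column logicals).
#' @seealso [write_rm_align()], [count_substitutions()]
#' @export
parse_rm_align <- function(path, consensus_library = NULL) {
  lines <- readr::read_lines(path)
  is_blank <- !nzchar(trimws(lines))
  starts <- which(!is_blank & c(TRUE, is_blank[-length(is_blank)]))
  blocks <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    i <- starts[[b]]
    j <- i
    while (j < length(lines) && !is_blank[[j + 1L]]) j <- j + 1L
    blocks[[b]] <- parse_align_block(lines[i:j], first_line = i)
  }
  out <- dplyr::bind_rows(blocks)
  if (nrow(out) == 0L) {
    out <- empty_hits()
    out$query_seq <- character()
    out$cons_seq <- character()
    out$cpg_mask <- list()
    return(out)
  }
  if (!is.null(consensus_library)) {
    unknown <- setdiff(unique(out$family), consensus_library$name)
    if (length(unknown) > 0L) {
      stopf("alignment blocks reference consensus sequences absent from the library: %s",
            paste(unknown, collapse = ", "))
    }
  }
  out
}

parse_align_block <- function(block_lines, first_line) {
  hdr <- parse_rm_out_row(block_lines[[1]], line_no = first_line)
  seq_lines <- block_lines[-1]
  if (length(seq_lines) == 0L || length(seq_lines) %% 2L != 0L) {
    stopf(".align block at line %d: expected interleaved query/consensus line pairs",
          first_line)
  }
  q_chunks <- character(0)
  c_chunks <- character(0)
  for (k in seq(1L, length(seq_lines), by = 2L)) {
    qf <- strsplit(trimws(seq_lines[[k]]), "\\s+")[[1]]
    cf <- strsplit(trimws(seq_lines[[k + 1L]]), "\\s+")[[1]]
    if (length(qf) != 4L || length(cf) != 4L) {
      stopf(".align block at line %d: malformed sequence line", first_line + k)
    }
    if (nchar(qf[[3]]) != nchar(cf[[3]])) {
      stopf(".align block at line %d: length mismatch between interleaved lines (%d vs %d)",
            first_line + k, nchar(qf[[3]]), nchar(cf[[3]]))
    }
    q_chunks <- c(q_chunks, qf[[3]])
    c_chunks <- c(c_chunks, cf[[3]])
  }
  hdr$query_seq <- toupper(paste(q_chunks, collapse = ""))
  hdr$cons_seq <- toupper(paste(c_chunks, collapse = ""))
  ungapped_cons <- gsub("-", "", hdr$cons_seq, fixed = TRUE)
  span <- hdr$cons_end - hdr$cons_start + 1L
  if (nchar(ungapped_cons) != span) {
    stopf(".align block at line %d: ungapped consensus length %d does not match declared span %d",
          first_line, nchar(ungapped_cons), span)
  }
  hdr$cpg_mask <- list(cpg_mask_from_alignment(hdr$cons_seq))
  hdr
}

#' Compute the per-column CpG mask of an aligned consensus string
#'
#' A column is CpG context when its (non-gap) consensus base is the C or
#' the G of a `CG` dinucleotide in the ungapped consensus sequence.
#'
#' @param cons_aligned Aligned consensus string (`-` gaps allowed).
#' @return Logical vector, one entry per alignment column.
#' @export
cpg_mask_from_alignment <- function(cons_aligned) {
  cols <- strsplit(toupper(cons_aligned), "")[[1]]
  non_gap <- cols != "-"
  bases <- cols[non_gap]
  m <- rep(FALSE, length(bases))
  if (length(bases) >= 2L) {
    is_cg <- bases[-length(bases)] == "C" & bases[-1] == "G"
    m[which(is_cg)] <- TRUE
    m[which(is_cg) + 1L] <- TRUE
  }
  mask <- rep(FALSE, length(cols))
  mask[non_gap] <- m
  mask
}

#' Write alignment blocks in the ".align" dialect
#'
#' Inverse of [parse_rm_align()]; sequences are wrapped into interleaved
#' 60-column line pairs.
#'
#' @param blocks Alignment tibble as returned by [parse_rm_align()].
#' @param path Output path.
#' @param chrom_sizes Optional tibble `chrom`, `length` for the genomic
#'   `(left)` field of block headers.
#' @export
write_rm_align <- function(blocks, path, chrom_sizes = NULL) {
  out <- character(0)
  width <- 60L
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    hdr <- format_rm_out_rows(
      b[, setdiff(names(b), c("query_seq", "cons_seq", "cpg_mask"))],
      chrom_sizes = chrom_sizes
    )
    q <- b$query_seq
    cs <- b$cons_seq
    n <- nchar(q)
    qpos <- b$start + 1L
    cpos <- if (b$strand == "+") b$cons_start else b$cons_end
    lines <- character(0)
    for (off in seq(1L, n, by = width)) {
      to <- min(off + width - 1L, n)
      qc <- substr(q, off, to)
      cc <- substr(cs, off, to)
      qlen <- nchar(gsub("-", "", qc, fixed = TRUE))
      clen <- nchar(gsub("-", "", cc, fixed = TRUE))
      qend <- qpos + max(qlen - 1L, 0L)
      cend <- if (b$strand == "+") cpos + max(clen - 1L, 0L) else cpos - max(clen - 1L, 0L)
      lines <- c(lines,
                 sprintf("%-12s %8d %s %8d", b$chrom, qpos, qc, qend),
                 sprintf("%-12s %8d %s %8d", b$family, cpos, cc, cend))
      qpos <- qpos + qlen
      cpos <- if (b$strand == "+") cpos + clen else cpos - clen
    }
    out <- c(out, hdr, lines, "")
  }
  readr::write_lines(out, path)
}

# ---- interval tracks --------------------------------------------------------

#' Read an interval track (BED, GFF3 genes, or a recombination-map TSV)
#'
#' All formats are normalised to 0-based half-open coordinates and sorted
#' within chromosome. BED input is used as-is; from GFF3 only features of
#' type `gene` are kept (1-based inclusive converted at the boundary); the
#' TSV map has columns `chrom`, `start`, `end`, `rate` (already half-open)
#' and its rate is carried in `value`.
#'
#' @param path Input path.
#' @param format One of `"bed"`, `"gff3"`, `"tsv"`.
#' @param chrom_sizes Optional tibble `chrom`, `length`; when supplied,
#'   intervals on unknown chromosomes are an error.
#' @return Tibble `chrom`, `start`, `end`, `value` (NA where the format has
#'   no value column), sorted by (`chrom`, `start`).
#' @export
read_tracks <- function(path, format = c("bed", "gff3", "tsv"),
                        chrom_sizes = NULL) {
  format <- match.arg(format)
  if (format == "bed") {
    d <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                         col_types = "cii", comment = "#", progress = FALSE)
    d$value <- NA_real_
  } else if (format == "gff3") {
    d <- readr::read_tsv(
      path,
      col_names = c("seqid", "source", "type", "start", "end", "score",
                    "strand", "phase", "attributes"),
      col_types = "ccciicccc", comment = "#", progress = FALSE
    )
    d <- d[d$type == "gene", ]
    d <- tibble(chrom = d$seqid, start = d$start - 1L, end = d$end,
                value = NA_real_)
  } else {
    d <- readr::read_tsv(path, col_types = "ciid", progress = FALSE)
    names(d)[1:4] <- c("chrom", "start", "end", "value")
  }
  if (any(d$start >= d$end)) {
    stopf("%s: %d interval(s) with start >= end", path, sum(d$start >= d$end))
  }
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(d$chrom), chrom_sizes$chrom)
    if (length(unknown) > 0L) {
      stopf("%s: unknown chromosome name(s): %s", path,
            paste(unknown, collapse = ", "))
    }
  }
  d <- dplyr::arrange(d, .data$chrom, .data$start)
  as_tibble(d[, c("chrom", "start", "end", "value")])
}

#' Read a chromosome-size table
#'
#' Two or three tab-separated columns: `chrom`, `length`, and optionally
#' `is_autosome` (logical / 0-1). Without the metadata column, chromosomes
#' named `Z`/`W` (with or without a `chr` prefix) are labelled as sex
#' chromosomes and everything else as autosomal.
#'
#' @param path Input path.
#' @return Tibble `chrom`, `length`, `is_autosome`.
#' @export
read_chrom_sizes <- function(path) {
  d <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                       progress = FALSE)
  names(d)[1:2] <- c("chrom", "length")
  d$length <- as.numeric(d$length)
  if (ncol(d) >= 3L) {
    d$is_autosome <- as.logical(d[[3]])
  } else {
    d$is_autosome <- !toupper(sub("^chr", "", d$chrom)) %in% c("Z", "W")
  }
  as_tibble(d[, c("chrom", "length", "is_autosome")])
}

write_bed <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "start", "end")], path,
                   col_names = FALSE, progress = FALSE)
}

write_recmap <- function(track, path) {
  d <- track[, c("chrom", "start", "end", "value")]
  names(d)[4] <- "rate"
  readr::write_tsv(d, path, progress = FALSE)
}

write_genes_gff3 <- function(track, path, source = "tescape") {
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tgene\t%d\t%d\t.\t+\t.\tID=gene%05d",
                     track$chrom, source, track$start + 1L, track$end,
                     seq_len(nrow(track))))
  readr::write_lines(lines, path)
}

# ---- consensus library FASTA ------------------------------------------------

#' Read a TE consensus library from FASTA
#'
#' Record names follow the RepeatMasker convention `name#class/family`.
#' LTR retrotransposon parts are recognised by name suffix: `*_LTR` is the
#' long terminal repeat and `*_I` the internal sequence of the element with
#' the shared stem; other records get `ltr_role = "none"`.
#'
#' @param path FASTA path.
#' @return Tibble `name`, `class_family`, `class`, `length`, `sequence`,
#'   `ltr_role` (`"ltr_part"`, `"internal_part"` or `"none"`).
#' @export
read_fasta_library <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  full <- names(seqs)
  name <- sub("#.*$", "", full)
  class_family <- ifelse(grepl("#", full), sub("^[^#]*#", "", full), "Unknown")
  if (anyDuplicated(name)) stopf("duplicate consensus names in %s", path)
  tibble(
    name = name,
    class_family = class_family,
    class = te_class_label(class_family),
    length = Biostrings::width(seqs),
    sequence = as.character(seqs),
    ltr_role = dplyr::case_when(
      endsWith(name, "_LTR") ~ "ltr_part",
      endsWith(name, "_I") ~ "internal_part",
      TRUE ~ "none"
    )
  )
}

write_fasta_library <- function(library, path) {
  seqs <- Biostrings::DNAStringSet(setNames(
    library$sequence, paste0(library$name, "#", library$class_family)
  ))
  Biostrings::writeXStringSet(seqs, path, width = 70L)
}

# ---- final annotation GFF3 --------------------------------------------------

#' Write the curated TE annotation as GFF3
#'
#' One `dispersed_repeat` feature per TE copy, 1-based inclusive
#' coordinates, deterministically ordered by (`chrom`, `start`, `family`).
#' Attributes carry `ID`, `Name` (family), `class`, `kimura` (2 decimals),
#' `age_class` and `n_fragments`.
#'
#' @param copies Copy tibble as produced by [merge_fragments()] /
#'   [filter_808080()] with `K` and `age_class` filled in.
#' @param path Output path.
#' @seealso [read_annotation_gff3()]
#' @export
write_annotation_gff3 <- function(copies, path) {
  copies <- dplyr::arrange(copies, .data$chrom, .data$start, .data$family)
  attrs <- sprintf(
    "ID=%s;Name=%s;class=%s;kimura=%.2f;age_class=%s;n_fragments=%d",
    copies$copy_id, copies$family, copies$class, copies$K,
    copies$age_class, copies$n_fragments
  )
  lines <- c("##gff-version 3",
             sprintf("%s\ttescape\tdispersed_repeat\t%d\t%d\t.\t%s\t.\t%s",
                     copies$chrom, copies$start + 1L, copies$end,
                     copies$strand, attrs))
  readr::write_lines(lines, path)
}

#' Read a curated TE annotation written by [write_annotation_gff3()]
#'
#' @param path GFF3 path.
#' @return Tibble `copy_id`, `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `family`, `class`, `K`, `age_class`, `n_fragments`.
#' @export
read_annotation_gff3 <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(copy_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  family = character(), class = character(), K = double(),
                  age_class = character(), n_fragments = integer()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0(key, "=[^;]*"), attrs))
    sub(paste0(key, "="), "", m)
  }
  attrs <- vapply(f, `[[`, "", 9L)
  tibble(
    copy_id = get_attr(attrs, "ID"),
    chrom = vapply(f, `[[`, "", 1L),
    start = as.integer(vapply(f, `[[`, "", 4L)) - 1L,
    end = as.integer(vapply(f, `[[`, "", 5L)),
    strand = vapply(f, `[[`, "", 7L),
    family = get_attr(attrs, "Name"),
    class = get_attr(attrs, "class"),
    K = as.numeric(get_attr(attrs, "kimura")),
    age_class = get_attr(attrs, "age_class"),
    n_fragments = as.integer(get_attr(attrs, "n_fragments"))
  )
}
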