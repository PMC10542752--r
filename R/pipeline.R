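# End-to-end orchestration: parse -> divergence -> merge -> LTR assembly ->
# 80-80-80 filter -> landscape -> windows -> statistics, with per-stage
# on-disk artifacts.

#' Join alignment-based divergence onto a hit table and build curated copies
#'
#' Per-fragment divergence comes from the alignment blocks
#' ([align_divergence()]), joined to hits by coordinates and family; hits
#' without an alignment block fall back to their `pct_div` and blocks
#' without a matching hit are reported with a warning (they still carry
#' their own coordinates). Fragments are then merged into copies, LTR
#' structures assembled, ages classified, and the 80-80-80 filter applied.
#'
#' @param hits Hit tibble from [parse_rm_out()].
#' @param blocks Alignment tibble from [parse_rm_align()], or `NULL` to
#'   use `pct_div` throughout.
#' @param params A [merge_params()].
#' @param model An [age_model()].
#' @param cpg_adjust Apply the CpG adjustment to alignment divergences.
#' @return List: `hits` (with `K`/`n_sites` columns), `copies_raw`
#'   (pre-filter merged copies) and `copies` (the curated annotation).
#' @export
annotate_genome <- function(hits, blocks = NULL, params = merge_params(),
                            model = age_model(), cpg_adjust = TRUE) {
  if (!is.null(blocks) && nrow(blocks) > 0L) {
    div <- align_divergence(blocks, cpg_adjust = cpg_adjust)
    key <- c("chrom", "start", "end", "family", "run_id")
    joined <- dplyr::left_join(hits, div[, c(key, "K", "n_sites")], by = key)
    missing <- sum(is.na(joined$K))
    if (missing > 0L) {
      warnf("%d hit(s) without alignment block; using their pct_div", missing)
      joined$K[is.na(joined$K)] <- joined$pct_div[is.na(joined$K)]
      joined$n_sites[is.na(joined$n_sites)] <-
        (joined$end - joined$start)[is.na(joined$n_sites)]
    }
    orphan <- nrow(dplyr::anti_join(div[, key], hits[, key], by = key))
    if (orphan > 0L) {
      warnf("%d alignment block(s) without a matching hit row", orphan)
    }
    hits <- joined
  }
  copies_raw <- merge_fragments(hits, params)
  copies_raw <- assemble_ltr(copies_raw, params = params)
  copies_raw <- classify_copies(copies_raw, model)
  copies <- filter_808080(copies_raw, params)
  list(hits = hits, copies_raw = copies_raw, copies = copies)
}

#' Export the per-copy divergence table
#'
#' @param copies Copy tibble with ages classified.
#' @return Tibble `copy_id`, `chrom`, `start`, `end`, `family`, `class`,
#'   `n_fragments`, `K`, `age_mya`, `age_class`.
#' @export
copy_divergence_table <- function(copies) {
  copies[, c("copy_id", "chrom", "start", "end", "family", "class",
             "n_fragments", "K", "age_mya", "age_class")]
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the whole analysis end to end
#'
#' Simulates (or reads) the inputs, builds the curated TE annotation,
#' and writes the report bundle to `out_dir`: the annotation GFF3, raw and
#' final per-type summaries, raw and final repeat landscapes (TSV), the
#' per-copy divergence table, the windowed feature table, the TE-feature
#' partial-correlation report, macro/micro Kruskal-Wallis comparisons with
#' the coverage-versus-length regression, and a manifest stamping the seed
#' and a configuration hash. Every output is a pure function of the inputs
#' and the configuration: re-running with the same configuration gives
#' identical files.
#'
#' @param input Either a [sim_config()] (the genome is simulated) or a
#'   named list of file paths: `out`, `align`, `library`, `genome`,
#'   `sizes`, `genes`, `cpg`, `recmap`.
#' @param out_dir Output directory, created if needed.
#' @param params A [merge_params()].
#' @param model An [age_model()].
#' @param w Window width in bp.
#' @param write_plot Also write `landscape.png`.
#' @return Invisibly, a list with every intermediate table and the output
#'   paths.
#' @export
run_all <- function(input = sim_config(), out_dir, params = merge_params(),
                    model = age_model(), w = 200000L, write_plot = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (inherits(input, "sim_config")) {
    sim <- run_stage("simulate", plant_genome(input))
    hits <- sim$hits; blocks <- sim$blocks
    chrom_sizes <- sim$chrom_sizes; genome <- sim$genome
    genes <- sim$genes; cpg <- sim$cpg; recmap <- sim$recmap
    seed <- input$seed
  } else {
    sim <- NULL
    hits <- run_stage("parse", parse_rm_out(input$out))
    lib <- if (!is.null(input$library)) read_fasta_library(input$library)
    blocks <- if (!is.null(input$align)) {
      run_stage("parse", parse_rm_align(input$align, lib))
    }
    chrom_sizes <- run_stage("parse", read_chrom_sizes(input$sizes))
    genome <- if (!is.null(input$genome)) {
      g <- Biostrings::readDNAStringSet(input$genome)
      names(g) <- sub("\\s.*$", "", names(g))
      g
    }
    genes <- if (!is.null(input$genes)) {
      read_tracks(input$genes, "gff3", chrom_sizes)
    }
    cpg <- if (!is.null(input$cpg)) read_tracks(input$cpg, "bed", chrom_sizes)
    recmap <- if (!is.null(input$recmap)) {
      read_tracks(input$recmap, "tsv", chrom_sizes)
    }
    seed <- NA_integer_
  }
  genome_len <- sum(chrom_sizes$length)

  ann <- run_stage("annotate", annotate_genome(hits, blocks, params, model))

  summary_raw <- run_stage("summarise", annotation_summary(ann$hits, genome_len))
  summary_final <- run_stage("summarise", annotation_summary(ann$copies, genome_len))
  summary_raw$mode <- "raw"; summary_final$mode <- "final"

  land_raw <- run_stage("landscape",
                        build_landscape(ann$hits, genome_len, mode = "raw",
                                        model = model))
  land_final <- run_stage("landscape",
                          build_landscape(ann$copies, genome_len,
                                          mode = "final", model = model))

  windows <- run_stage("windows", make_windows(chrom_sizes, w))
  feat <- run_stage("windows",
                    feature_table(windows, ann$copies, genes = genes,
                                  cpg = cpg, recmap = recmap,
                                  sequence = genome))

  cors <- run_stage("correlate", tryCatch(
    te_feature_correlations(feat),
    error = function(e) {
      warnf("correlation report skipped: %s", conditionMessage(e))
      NULL
    }))

  relcov <- run_stage("chromosomes", relative_coverage(ann$copies, chrom_sizes))
  macro_micro <- run_stage("chromosomes", tryCatch({
    sp <- split(relcov$rel_cov, relcov$chrom_class)
    tidy(kruskal_wallis(sp))
  }, error = function(e) {
    warnf("macro/micro comparison skipped: %s", conditionMessage(e))
    NULL
  }))
  reg <- run_stage("chromosomes", tryCatch(
    tidy(coverage_length_regression(relcov)),
    error = function(e) NULL))

  # ---- write the bundle ----
  paths <- list(
    annotation = file.path(out_dir, "annotation.gff3"),
    summary = file.path(out_dir, "summary.tsv"),
    landscape = file.path(out_dir, "landscape.tsv"),
    divergence = file.path(out_dir, "copy_divergence.tsv"),
    features = file.path(out_dir, "feature_table.tsv"),
    correlations = file.path(out_dir, "correlations.tsv"),
    chromosomes = file.path(out_dir, "chromosome_stats.tsv"),
    manifest = file.path(out_dir, "manifest.tsv")
  )
  write_annotation_gff3(ann$copies, paths$annotation)
  readr::write_tsv(dplyr::bind_rows(summary_raw, summary_final),
                   paths$summary, progress = FALSE)
  readr::write_tsv(dplyr::bind_rows(land_raw, land_final), paths$landscape,
                   progress = FALSE)
  readr::write_tsv(copy_divergence_table(ann$copies), paths$divergence,
                   progress = FALSE)
  readr::write_tsv(feat, paths$features, progress = FALSE)
  if (!is.null(cors)) readr::write_tsv(cors, paths$correlations, progress = FALSE)
  chrom_stats <- relcov
  readr::write_tsv(chrom_stats, paths$chromosomes, progress = FALSE)
  manifest <- tibble(
    key = c("seed", "config_hash", "window_width", "mu",
            "recent_threshold_K", "max_gap", "min_len", "min_identity_K",
            "min_cons_span"),
    value = as.character(c(seed, rlang::hash(list(input, params, model, w)),
                           w, model$mu, model$recent_threshold_K,
                           params$max_gap, params$min_len,
                           params$min_identity_K, params$min_cons_span))
  )
  readr::write_tsv(manifest, paths$manifest, progress = FALSE)
  if (write_plot) {
    p <- plot_landscape(land_final, model)
    ggplot2::ggsave(file.path(out_dir, "landscape.png"), p,
                    width = 8, height = 4, dpi = 150)
    paths$plot <- file.path(out_dir, "landscape.png")
  }

  invisible(list(
    sim = sim, hits = ann$hits, copies_raw = ann$copies_raw,
    copies = ann$copies, summary = dplyr::bind_rows(summary_raw, summary_final),
    landscape = dplyr::bind_rows(land_raw, land_final), features = feat,
    correlations = cors, relative_coverage = relcov,
    macro_micro = macro_micro, regression = reg, paths = paths
  ))
}
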