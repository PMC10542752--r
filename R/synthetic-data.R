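# Synthetic genomes with planted TE copies at known divergence, plus
# coupled gene/CpG/recombination tracks, so the whole pipeline is testable
# with no external data.

#' Simulation configuration
#'
#' Defines a small genome with planted TE copies. Defaults emulate an
#' avian-like repeat landscape scaled down to test size: a recent
#' ERVK-like LTR burst (divergence centred near K = 1), a second, older
#' LTR family, two broadly aged LINE families, plus minor SINE, DNA and
#' unclassifiable components. Copy placement, gene density, CpG-island
#' density, GC background and recombination rate are all monotone links of
#' one smoothed latent field, with per-track coupling coefficients, so rank
#' associations of known sign are planted between TE coverage and every
#' feature track.
#'
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param sex_chroms Names in `chrom_lengths` labelled non-autosomal.
#' @param gc_background Background GC fraction.
#' @param copy_spec Tibble `family`, `n`, `k_dist` (`"normal"` or
#'   `"uniform"`), `k1`, `k2` giving per-family copy counts and the
#'   divergence distribution of `K_true` (normal: mean/sd, truncated to
#'   `[0.05, 40]`; uniform: min/max).
#' @param kappa Transition/transversion rate ratio.
#' @param cpg_multiplier CpG-context transition rate multiplier.
#' @param solo_ltr_prob Probability that an LTR-family copy is a solo LTR
#'   rather than a full LTR-internal-LTR element.
#' @param truncation_prob Probability that a LINE copy is 5'-truncated;
#'   the retained 3' fraction is uniform on `[0.2, 1]`.
#' @param nesting_prob Probability that an eligible host copy (single-part
#'   LINE/DNA of >= 600 bp) receives a nested young insertion that splits
#'   it into two fragments sharing the host `run_id`.
#' @param coupling Named list of link strengths between the latent field
#'   and the tracks: `te_recent`, `te_ancient` (placement intensity of
#'   recent/ancient copies), `gene`, `cpg`, `rec`, `gc`.
#' @param field_res Latent-field tile size in bp.
#' @return A list with class `"sim_config"`.
#' @export
sim_config <- function(
    seed = 1,
    chrom_lengths = c(chr1 = 4e5, chr2 = 3e5, chr3 = 2e5, chrZ = 1e5),
    sex_chroms = "chrZ",
    gc_background = 0.42,
    copy_spec = default_copy_spec(),
    kappa = 2.0,
    cpg_multiplier = 10,
    solo_ltr_prob = 0.3,
    truncation_prob = 0.5,
    nesting_prob = 0.15,
    coupling = list(te_recent = -1, te_ancient = -0.5, gene = 1, cpg = 0.8,
                    rec = 1, gc = 0.5),
    field_res = 20000) {
  probs <- c(solo_ltr_prob, truncation_prob, nesting_prob)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (any(chrom_lengths <= 0)) stopf("chromosome lengths must be > 0")
  structure(list(
    seed = as.integer(seed), chrom_lengths = chrom_lengths,
    sex_chroms = sex_chroms, gc_background = gc_background,
    copy_spec = copy_spec, kappa = kappa, cpg_multiplier = cpg_multiplier,
    solo_ltr_prob = solo_ltr_prob, truncation_prob = truncation_prob,
    nesting_prob = nesting_prob, coupling = coupling, field_res = field_res
  ), class = "sim_config")
}

#' Default per-family copy specification
#'
#' @return Tibble `family`, `n`, `k_dist`, `k1`, `k2`; see [sim_config()].
#' @export
default_copy_spec <- function() {
  tibble(
    family = c("ERVK_sim", "LTRX_sim", "CR1_sim", "L2_sim", "SINE1_sim",
               "hAT_sim", "Unk_sim"),
    n = c(15L, 10L, 20L, 15L, 8L, 8L, 4L),
    k_dist = c("normal", "normal", "uniform", "uniform", "uniform",
               "uniform", "uniform"),
    k1 = c(1, 12, 5, 8, 8, 5, 10),
    k2 = c(0.5, 4, 25, 25, 20, 15, 20)
  )
}

sim_family_table <- function() {
  tibble(
    family = c("ERVK_sim", "LTRX_sim", "CR1_sim", "L2_sim", "SINE1_sim",
               "hAT_sim", "Unk_sim"),
    class_family = c("LTR/ERVK", "LTR/ERV1", "LINE/CR1", "LINE/L2",
                     "SINE/tRNA", "DNA/hAT", "Unknown"),
    is_ltr = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    ltr_len = c(300L, 250L, NA, NA, NA, NA, NA),
    int_len = c(1500L, 1200L, NA, NA, NA, NA, NA),
    cons_len = c(NA, NA, 2000L, 1500L, 200L, 800L, 400L)
  )
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Build the synthetic consensus library for a configuration
#'
#' Consensus sequences are random at the background GC; LTR families get a
#' `*_LTR` and a `*_I` part sharing the family stem. Deterministic given
#' the configuration seed (called inside [plant_genome()]).
#'
#' @param config A [sim_config()].
#' @return Consensus library tibble as from [read_fasta_library()].
#' @export
make_library <- function(config = sim_config()) {
  fams <- sim_family_table()
  wanted <- config$copy_spec$family
  # nested guests are drawn from the short SINE family even when it has no
  # top-level copies of its own
  if (config$nesting_prob > 0) wanted <- union(wanted, "SINE1_sim")
  fams <- fams[fams$family %in% wanted, ]
  recs <- list()
  for (i in seq_len(nrow(fams))) {
    f <- fams[i, ]
    if (f$is_ltr) {
      recs[[length(recs) + 1L]] <- tibble(
        name = paste0(f$family, "_LTR"), class_family = f$class_family,
        class = te_class_label(f$class_family), length = f$ltr_len,
        sequence = random_dna(f$ltr_len, config$gc_background),
        ltr_role = "ltr_part")
      recs[[length(recs) + 1L]] <- tibble(
        name = paste0(f$family, "_I"), class_family = f$class_family,
        class = te_class_label(f$class_family), length = f$int_len,
        sequence = random_dna(f$int_len, config$gc_background),
        ltr_role = "internal_part")
    } else {
      recs[[length(recs) + 1L]] <- tibble(
        name = f$family, class_family = f$class_family,
        class = te_class_label(f$class_family), length = f$cons_len,
        sequence = random_dna(f$cons_len, config$gc_background),
        ltr_role = "none")
    }
  }
  dplyr::bind_rows(recs)
}

#' Evolve a TE copy away from its consensus to a target divergence
#'
#' Per-site categorical substitution sampling with transition:transversion
#' odds `kappa`:1 (the two transversions equally likely) and the
#' CpG-context transition rate multiplied by `cpg_multiplier` (capped so a
#' site's substitution probability stays below 1). The overall rate is
#' calibrated numerically so that the expected CpG-adjusted Kimura
#' divergence of the resulting alignment equals `K_true` (the planted
#' divergence is on the same scale the estimator reports). The returned
#' alignment is gapless.
#'
#' @param consensus Consensus nucleotide string (>= 50 bp).
#' @param K_true Target percent divergence in `[0, 50)`.
#' @param kappa Transition/transversion rate ratio.
#' @param cpg_multiplier CpG transition multiplier.
#' @return List: `sequence` (evolved copy), `consensus` (the input; the
#'   pair is the gapless truth alignment) and `counts`, the realized
#'   substitution tallies (`n_sites`, `ts_raw`, `tv_raw`).
#' @export
evolve_copy <- function(consensus, K_true, kappa = 2, cpg_multiplier = 10) {
  L <- nchar(consensus)
  if (L < 50L) stopf("consensus shorter than 50 bp")
  if (K_true < 0 || K_true >= 50) stopf("K_true out of range [0, 50)")
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (K_true == 0) {
    return(list(sequence = consensus, consensus = consensus,
                counts = tibble(n_sites = L, ts_raw = 0L, tv_raw = 0L)))
  }
  pairs <- cpg_pairs(bases)
  n_cpg <- 2L * nrow(pairs)
  is_cpg <- rep(FALSE, L)
  if (nrow(pairs) > 0L) is_cpg[c(pairs$c_col, pairs$g_col)] <- TRUE

  # expected CpG-adjusted K as a function of the overall rate scale s
  expected_K <- function(s) {
    q_tv <- s / (kappa + 1)
    q_ts <- s * kappa / (kappa + 1)
    q_ts_c <- pmin(cpg_multiplier * q_ts, 0.95 - q_tv)
    p <- q_ts_c
    e_pair <- 0.1 * 2 * p * (1 - p) + p^2   # per CpG pair, after adjustment
    ts_adj <- (L - n_cpg) * q_ts + nrow(pairs) * e_pair
    tv <- L * q_tv
    P <- ts_adj / L; Q <- tv / L
    if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(Inf)
    100 * (-0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q))
  }
  s <- uniroot(function(s) expected_K(s) - K_true,
               lower = 1e-8, upper = 0.6, extendInt = "no",
               tol = 1e-10)$root
  q_tv <- s / (kappa + 1)
  q_ts <- s * kappa / (kappa + 1)
  q_ts_site <- ifelse(is_cpg, pmin(cpg_multiplier * q_ts, 0.95 - q_tv), q_ts)

  u <- runif(L)
  ts_mut <- u < q_ts_site
  tv_mut <- !ts_mut & u < q_ts_site + q_tv
  which_tv <- runif(L) < 0.5
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map1 <- c(A = "C", G = "C", C = "A", T = "A")
  tv_map2 <- c(A = "T", G = "T", C = "G", T = "G")
  out <- bases
  out[ts_mut] <- ts_map[bases[ts_mut]]
  out[tv_mut & which_tv] <- tv_map1[bases[tv_mut & which_tv]]
  out[tv_mut & !which_tv] <- tv_map2[bases[tv_mut & !which_tv]]
  list(sequence = paste(out, collapse = ""), consensus = consensus,
       counts = tibble(n_sites = L, ts_raw = sum(ts_mut),
                       tv_raw = sum(tv_mut)))
}

# smoothed latent field over n tiles (moving average of white noise)
latent_field <- function(n, smooth = 5L) {
  raw <- rnorm(n + smooth - 1L)
  as.numeric(stats::filter(raw, rep(1 / smooth, smooth), sides = 1))[smooth:(n + smooth - 1L)]
}

sample_k_true <- function(spec_row) {
  if (spec_row$k_dist == "normal") {
    k <- rnorm(1, spec_row$k1, spec_row$k2)
  } else {
    k <- runif(1, spec_row$k1, spec_row$k2)
  }
  min(max(k, 0.05), 40)
}

#' Plant a synthetic genome with TE copies of known divergence
#'
#' Generates background sequence tile by tile (GC modulated by the latent
#' field through the `gc` coupling), evolves each planted copy to its drawn
#' `K_true` with [evolve_copy()], places copies at positions drawn from the
#' field-weighted intensity of their age class, optionally 5'-truncates
#' LINEs, splits nested hosts into fragments sharing a `run_id`, and emits
#' the RepeatMasker-dialect hit and alignment tables plus gene, CpG-island
#' and recombination tracks coupled to the same field.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, all external files are
#'   written there (`genome.fa`, `hits.out`, `hits.align`, `library.fa`,
#'   `genes.gff3`, `cpg.bed`, `recmap.tsv`, `chrom.sizes`, `truth.tsv`).
#' @param sequence Build the background genome sequence (default `TRUE`);
#'   with `FALSE` only the tables are generated (`genome` is `NULL`),
#'   which is considerably faster when the sequence is not needed.
#' @return A list: `config`, `library`, `chrom_sizes`, `genome`
#'   ([Biostrings::DNAStringSet]), `hits` (truth `.out` tibble, sorted),
#'   `blocks` (truth `.align` tibble), `truth` (per planted copy: family,
#'   class, strand, envelope, `K_true`, realized counts, fragment count,
#'   nesting flag), `genes`, `cpg`, `recmap` (interval tracks), `field`
#'   (per-tile latent field), and `paths` when `dir` was given.
#' @export
plant_genome <- function(config = sim_config(), dir = NULL, sequence = TRUE) {
  set.seed(config$seed)
  lib <- make_library(config)
  fams <- sim_family_table()
  chroms <- config$chrom_lengths
  genome_len <- sum(chroms)
  res <- config$field_res
  cpl <- config$coupling

  # latent field per chromosome
  field <- purrr::imap(as.list(chroms), function(len, ch) {
    n <- ceiling(len / res)
    tibble(chrom = ch, tile = seq_len(n) - 1L,
           start = (seq_len(n) - 1L) * res,
           end = pmin(seq_len(n) * res, len),
           f = latent_field(n))
  }) |> dplyr::bind_rows()

  # ---- plan elements ----
  run_counter <- 0L
  next_run <- function() { run_counter <<- run_counter + 1L; run_counter }
  elements <- list()
  for (i in seq_len(nrow(config$copy_spec))) {
    spec <- config$copy_spec[i, ]
    fam <- fams[fams$family == spec$family, ]
    if (nrow(fam) == 0L) stopf("unknown family in copy_spec: %s", spec$family)
    for (k in seq_len(spec$n)) {
      K_true <- sample_k_true(spec)
      strand <- sample(c("+", "-"), 1)
      if (fam$is_ltr) {
        solo <- runif(1) < config$solo_ltr_prob
        part_names <- if (solo) paste0(fam$family, "_LTR") else
          paste0(fam$family, c("_LTR", "_I", "_LTR"))
        parts <- lapply(part_names, function(nm) {
          cons <- lib$sequence[lib$name == nm]
          ev <- evolve_copy(cons, K_true, config$kappa, config$cpg_multiplier)
          list(name = nm, class_family = fam$class_family,
               cons_len = nchar(cons), cons_start0 = 0L,
               seq = ev$sequence, cons = cons, counts = ev$counts,
               run_id = next_run())
        })
      } else {
        cons_full <- lib$sequence[lib$name == fam$family]
        cons_len <- nchar(cons_full)
        cons_start0 <- 0L
        if (fam$class_family %in% c("LINE/CR1", "LINE/L2") &&
            runif(1) < config$truncation_prob) {
          retained <- max(80L, as.integer(round(runif(1, 0.2, 1) * cons_len)))
          cons_start0 <- cons_len - retained
        }
        cons <- substr(cons_full, cons_start0 + 1L, cons_len)
        ev <- evolve_copy(cons, K_true, config$kappa, config$cpg_multiplier)
        parts <- list(list(name = fam$family, class_family = fam$class_family,
                           cons_len = cons_len, cons_start0 = cons_start0,
                           seq = ev$sequence, cons = cons, counts = ev$counts,
                           run_id = next_run()))
      }
      elements[[length(elements) + 1L]] <- list(
        family = fam$family, class_family = fam$class_family,
        class = te_class_label(fam$class_family), strand = strand,
        K_true = K_true, parts = parts, nested_in = NA_integer_
      )
    }
  }

  # ---- nesting: young insertions split eligible hosts ----
  n_elem <- length(elements)
  host_ok <- vapply(elements, function(e) {
    length(e$parts) == 1L && e$class %in% c("LINE", "DNA") &&
      nchar(e$parts[[1]]$seq) >= 600L
  }, logical(1))
  nest_plan <- integer(0)  # host index per nested element
  if (n_elem > 0L) {
    for (h in which(host_ok)) {
      if (runif(1) < config$nesting_prob) {
        fam <- fams[fams$family == "SINE1_sim", ]
        if (nrow(fam) == 0L) next
        K_true <- min(max(abs(rnorm(1, 1, 0.5)), 0.05), 6.9)
        cons <- lib$sequence[lib$name == fam$family]
        ev <- evolve_copy(cons, K_true, config$kappa, config$cpg_multiplier)
        elements[[length(elements) + 1L]] <- list(
          family = fam$family, class_family = fam$class_family,
          class = te_class_label(fam$class_family),
          strand = sample(c("+", "-"), 1), K_true = K_true,
          parts = list(list(name = fam$family,
                            class_family = fam$class_family,
                            cons_len = nchar(cons), cons_start0 = 0L,
                            seq = ev$sequence, cons = cons,
                            counts = ev$counts, run_id = next_run())),
          nested_in = h)
        nest_plan <- c(nest_plan, h)
      }
    }
  }

  # ---- lay out regions (a top-level element plus any nested guest) ----
  regions <- list()
  for (e_idx in seq_along(elements)) {
    e <- elements[[e_idx]]
    if (!is.na(e$nested_in)) next
    frags <- list()   # per fragment: part ref, region offsets, part offsets
    offset <- 0L
    part_layout <- list()
    for (p_idx in seq_along(e$parts)) {
      plen <- nchar(e$parts[[p_idx]]$seq)
      part_layout[[p_idx]] <- list(p_idx = p_idx, region_start = offset,
                                   plen = plen, splits = integer(0))
      offset <- offset + plen
    }
    guests <- which(vapply(elements, function(x) {
      !is.na(x$nested_in) && x$nested_in == e_idx
    }, logical(1)))
    region <- list(e_idx = e_idx, part_layout = part_layout,
                   guests = guests, K_place = e$K_true)
    regions[[length(regions) + 1L]] <- region
  }

  # assemble each region's genome-oriented sequence and fragment table
  region_data <- lapply(regions, function(rg) {
    e <- elements[[rg$e_idx]]
    pieces <- character(0)
    frag_rows <- list()
    pos <- 0L
    for (pl in rg$part_layout) {
      part <- e$parts[[pl$p_idx]]
      g <- if (e$strand == "+") part$seq else revcomp(part$seq)
      splits <- integer(0)
      guest_here <- rg$guests  # nested guests split the (single) part
      if (length(guest_here) > 0L && length(rg$part_layout) == 1L) {
        splits <- sort(vapply(guest_here, function(gi) {
          as.integer(round(runif(1, 100, pl$plen - 100)))
        }, integer(1)))
      }
      bounds <- unique(c(0L, splits, pl$plen))
      for (b in seq_len(length(bounds) - 1L)) {
        a <- bounds[[b]]; z <- bounds[[b + 1L]]
        pieces <- c(pieces, substr(g, a + 1L, z))
        frag_rows[[length(frag_rows) + 1L]] <- list(
          e_idx = rg$e_idx, p_idx = pl$p_idx, region_start = pos,
          region_end = pos + (z - a), part_a = a, part_b = z)
        pos <- pos + (z - a)
        if (b < length(bounds) - 1L) {
          gi <- guest_here[[b]]
          gpart <- elements[[gi]]$parts[[1]]
          gseq <- if (elements[[gi]]$strand == "+") gpart$seq else revcomp(gpart$seq)
          pieces <- c(pieces, gseq)
          frag_rows[[length(frag_rows) + 1L]] <- list(
            e_idx = gi, p_idx = 1L, region_start = pos,
            region_end = pos + nchar(gseq), part_a = 0L,
            part_b = nchar(gseq))
          pos <- pos + nchar(gseq)
        }
      }
    }
    list(seq = paste(pieces, collapse = ""), len = pos, frags = frag_rows,
         K_place = rg$K_place)
  })

  total_te_bp <- sum(vapply(region_data, `[[`, numeric(1), "len"))
  if (total_te_bp > 0.8 * genome_len) stopf("overfull genome: requested copy bp exceeds 80%% of the genome")

  # ---- place regions: chromosome by length, tile by age-class weight ----
  model <- age_model()
  occ_s <- lapply(names(chroms), function(ch) numeric(0))
  names(occ_s) <- names(chroms)
  occ_e <- occ_s
  placements <- vector("list", length(region_data))
  if (length(region_data) > 0L) {
    for (r in seq_along(region_data)) {
      rd <- region_data[[r]]
      w_age <- if (rd$K_place <= model$recent_threshold_K) cpl$te_recent else cpl$te_ancient
      placed <- FALSE
      for (try in seq_len(300L)) {
        ch <- sample(names(chroms), 1, prob = chroms / genome_len)
        if (chroms[[ch]] < rd$len + 2L) next
        tiles <- field[field$chrom == ch, ]
        wt <- exp(w_age * tiles$f)
        t_row <- tiles[sample.int(nrow(tiles), 1, prob = wt), ]
        lo <- t_row$start
        hi <- min(t_row$end, chroms[[ch]] - rd$len)
        if (hi <= lo) next
        s <- as.integer(floor(runif(1, lo, hi)))
        if (any(occ_e[[ch]] > s & occ_s[[ch]] < s + rd$len)) next
        occ_s[[ch]] <- c(occ_s[[ch]], s)
        occ_e[[ch]] <- c(occ_e[[ch]], s + rd$len)
        placements[[r]] <- list(chrom = ch, start = s)
        placed <- TRUE
        break
      }
      if (!placed) stopf("could not place copy %d: genome too full", r)
    }
  }

  # ---- background sequence with GC coupled to the field ----
  if (sequence || !is.null(dir)) {
    genome <- lapply(names(chroms), function(ch) {
      tiles <- field[field$chrom == ch, ]
      p_gc <- stats::plogis(stats::qlogis(config$gc_background) + cpl$gc * tiles$f)
      paste(vapply(seq_len(nrow(tiles)), function(i) {
        random_dna(tiles$end[[i]] - tiles$start[[i]], p_gc[[i]])
      }, character(1)), collapse = "")
    })
    names(genome) <- names(chroms)
    # overwrite planted intervals with the evolved element sequence
    for (r in seq_along(region_data)) {
      pl <- placements[[r]]
      rd <- region_data[[r]]
      g <- genome[[pl$chrom]]
      substr(g, pl$start + 1L, pl$start + rd$len) <- rd$seq
      genome[[pl$chrom]] <- g
    }
  } else {
    genome <- NULL
  }

  # ---- emit hit and alignment tables plus the truth ----
  hit_rows <- list()
  block_rows <- list()
  elem_frag_iv <- vector("list", length(elements))
  for (r in seq_along(region_data)) {
    pl <- placements[[r]]
    rd <- region_data[[r]]
    for (fr in rd$frags) {
      e <- elements[[fr$e_idx]]
      part <- e$parts[[fr$p_idx]]
      plen <- nchar(part$seq)
      a <- fr$part_a; b <- fr$part_b
      if (e$strand == "+") {
        ps <- a; pe <- b
      } else {
        ps <- plen - b; pe <- plen - a
      }
      cons_s <- part$cons_start0 + ps + 1L
      cons_e <- part$cons_start0 + pe
      q_str <- substr(part$seq, ps + 1L, pe)
      c_str <- substr(part$cons, ps + 1L, pe)
      mism <- mapply(function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]),
                     q_str, c_str)
      gstart <- pl$start + fr$region_start
      gend <- pl$start + fr$region_end
      row <- tibble(
        chrom = pl$chrom, start = gstart, end = gend, strand = e$strand,
        family = part$name, class_family = part$class_family,
        class = te_class_label(part$class_family),
        score = as.integer((gend - gstart) * 2L),
        pct_div = round(100 * as.numeric(mism) / (gend - gstart), 2),
        pct_del = 0, pct_ins = 0,
        cons_start = cons_s, cons_end = cons_e,
        cons_left = part$cons_len - cons_e,
        run_id = part$run_id, star = FALSE
      )
      hit_rows[[length(hit_rows) + 1L]] <- row
      blk <- row
      blk$query_seq <- q_str
      blk$cons_seq <- c_str
      blk$cpg_mask <- list(cpg_mask_from_alignment(c_str))
      block_rows[[length(block_rows) + 1L]] <- blk
      elem_frag_iv[[fr$e_idx]] <- dplyr::bind_rows(
        elem_frag_iv[[fr$e_idx]],
        tibble(chrom = pl$chrom, start = gstart, end = gend))
    }
  }
  hits <- dplyr::bind_rows(hit_rows)
  blocks <- dplyr::bind_rows(block_rows)
  if (nrow(hits) == 0L) {
    hits <- empty_hits()
    blocks <- empty_hits()
    blocks$query_seq <- character(0)
    blocks$cons_seq <- character(0)
    blocks$cpg_mask <- list()
  } else {
    ord <- order(hits$chrom, hits$start, method = "radix")
    hits <- hits[ord, ]
    ord_b <- order(blocks$chrom, blocks$start, method = "radix")
    blocks <- blocks[ord_b, ]
  }

  truth <- purrr::imap(elements, function(e, e_idx) {
    iv <- elem_frag_iv[[e_idx]]
    if (is.null(iv)) return(NULL)
    counts <- dplyr::bind_rows(lapply(e$parts, `[[`, "counts"))
    tibble(
      copy_id = sprintf("true%05d", e_idx),
      chrom = iv$chrom[[1]], start = min(iv$start), end = max(iv$end),
      strand = e$strand, family = e$family, class = e$class,
      K_true = e$K_true, n_fragments = nrow(iv),
      planted_bp = sum(iv$end - iv$start),
      n_sites = sum(counts$n_sites), ts_raw = sum(counts$ts_raw),
      tv_raw = sum(counts$tv_raw),
      is_nested = !is.na(e$nested_in),
      run_ids = paste(vapply(e$parts, function(p) p$run_id, integer(1)),
                      collapse = ","),
      fragments = list(iv)
    )
  }) |> dplyr::bind_rows()

  # ---- feature tracks coupled to the field ----
  tracks <- sim_feature_tracks(field, cpl)
  chrom_sizes <- tibble(chrom = names(chroms),
                        length = as.numeric(unname(chroms)),
                        is_autosome = !names(chroms) %in% config$sex_chroms)
  genome_set <- if (is.null(genome)) NULL else
    Biostrings::DNAStringSet(unlist(genome))

  out <- list(config = config, library = lib, chrom_sizes = chrom_sizes,
              genome = genome_set, hits = hits, blocks = blocks,
              truth = truth, genes = tracks$genes, cpg = tracks$cpg,
              recmap = tracks$recmap, field = field)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      genome = file.path(dir, "genome.fa"), out = file.path(dir, "hits.out"),
      align = file.path(dir, "hits.align"),
      library = file.path(dir, "library.fa"),
      genes = file.path(dir, "genes.gff3"), cpg = file.path(dir, "cpg.bed"),
      recmap = file.path(dir, "recmap.tsv"),
      sizes = file.path(dir, "chrom.sizes"),
      truth = file.path(dir, "truth.tsv")
    )
    Biostrings::writeXStringSet(genome_set, paths$genome, width = 70L)
    write_rm_out(hits, paths$out, chrom_sizes = chrom_sizes)
    write_rm_align(blocks, paths$align, chrom_sizes = chrom_sizes)
    write_fasta_library(lib, paths$library)
    write_genes_gff3(tracks$genes, paths$genes)
    write_bed(tracks$cpg, paths$cpg)
    write_recmap(tracks$recmap, paths$recmap)
    sz <- chrom_sizes
    sz$is_autosome <- as.integer(sz$is_autosome)
    readr::write_tsv(sz, paths$sizes, col_names = FALSE, progress = FALSE)
    readr::write_tsv(truth[, setdiff(names(truth), "fragments")],
                     paths$truth, progress = FALSE)
    out$paths <- paths
  }
  out
}

# gene, CpG-island and recombination tracks as monotone links of the field
sim_feature_tracks <- function(field, cpl) {
  genes <- list(); cpg <- list(); recmap <- list()
  for (i in seq_len(nrow(field))) {
    t <- field[i, ]
    tl <- t$end - t$start
    gene_frac <- 0.4 * stats::plogis(cpl$gene * t$f)
    gene_len <- as.integer(round(gene_frac * tl))
    if (gene_len >= 50L) {
      off <- as.integer(floor(runif(1, 0, tl - gene_len)))
      genes[[length(genes) + 1L]] <- tibble(
        chrom = t$chrom, start = t$start + off, end = t$start + off + gene_len,
        value = NA_real_)
    }
    cpg_frac <- 0.05 * stats::plogis(cpl$cpg * t$f)
    cpg_len <- as.integer(round(cpg_frac * tl))
    if (cpg_len >= 20L) {
      off <- as.integer(floor(runif(1, 0, tl - cpg_len)))
      cpg[[length(cpg) + 1L]] <- tibble(
        chrom = t$chrom, start = t$start + off, end = t$start + off + cpg_len,
        value = NA_real_)
    }
    recmap[[length(recmap) + 1L]] <- tibble(
      chrom = t$chrom, start = t$start, end = t$end,
      value = 4.6e-9 * exp(cpl$rec * t$f))
  }
  list(genes = dplyr::bind_rows(genes), cpg = dplyr::bind_rows(cpg),
       recmap = dplyr::bind_rows(recmap))
}

#' Expected sign of every planted TE-feature rank association
#'
#' Reads the coupling coefficients of a configuration and reports, for each
#' TE age category and each feature track, the sign of the rank association
#' the simulation plants (the product of the TE-placement coupling and the
#' feature coupling; zero coupling on either side yields `"none"`).
#'
#' @param config A [sim_config()].
#' @return Tibble `te_category`, `feature`, `expected_sign`
#'   (`"+"`, `"-"` or `"none"`).
#' @export
plant_correlations <- function(config = sim_config()) {
  cpl <- config$coupling
  te_coef <- c(recent = cpl$te_recent, ancient = cpl$te_ancient,
               all = cpl$te_recent + cpl$te_ancient)
  feat_coef <- c(gene_cov = cpl$gene, cpg_cov = cpl$cpg,
                 rec_rate = cpl$rec, gc = cpl$gc)
  tidyr::expand_grid(te_category = names(te_coef),
                     feature = names(feat_coef)) |>
    dplyr::mutate(
      product = te_coef[.data$te_category] * feat_coef[.data$feature],
      expected_sign = dplyr::case_when(
        .data$product > 0 ~ "+",
        .data$product < 0 ~ "-",
        TRUE ~ "none"
      )
    ) |>
    dplyr::select(-"product")
}

#' Simulate window-level features with planted rank dependences
#'
#' A lightweight window-scale counterpart of [plant_genome()]: one smoothed
#' latent field over `n` windows, each metric a monotone link of the field
#' (per its coupling coefficient) plus independent Gaussian noise, then
#' squashed to a coverage-like scale. Metrics with zero coupling are pure
#' noise. Used to study the statistical battery at a controlled sample
#' size.
#'
#' @param n Number of windows.
#' @param coupling Coupling list as in [sim_config()].
#' @param noise_sd Independent noise standard deviation.
#' @param smooth Moving-average span of the latent field.
#' @return Tibble with `te_cov_all`, `te_cov_recent`, `te_cov_ancient`,
#'   `gene_cov`, `cpg_cov`, `gc`, `rec_rate` over `n` windows.
#' @export
simulate_window_features <- function(n = 500,
                                     coupling = list(te_recent = -1,
                                                     te_ancient = -0.5,
                                                     gene = 1, cpg = 0.8,
                                                     rec = 1, gc = 0.5),
                                     noise_sd = 1, smooth = 5L) {
  f <- latent_field(n, smooth)
  link <- function(coef, scale = 100) {
    scale * stats::plogis(coef * f + rnorm(n, sd = noise_sd))
  }
  rec_raw <- coupling$rec * f + rnorm(n, sd = noise_sd)
  tibble(
    te_cov_recent = link(coupling$te_recent),
    te_cov_ancient = link(coupling$te_ancient),
    te_cov_all = 100 * stats::plogis(
      (coupling$te_recent + coupling$te_ancient) / 2 * f +
        rnorm(n, sd = noise_sd)),
    gene_cov = link(coupling$gene),
    cpg_cov = link(coupling$cpg, scale = 10),
    gc = 30 + link(coupling$gc, scale = 30),
    rec_rate = 4.6e-9 * exp(rec_raw)
  )
}
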