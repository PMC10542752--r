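# The statistical battery: Kendall tau-b, partial Kendall correlation with
# a normal-approximation test and Bonferroni correction, Kruskal-Wallis
# comparisons, macro/micro chromosome classification, relative coverage and
# coverage-versus-length regression.

#' Kendall's tau-b rank correlation
#'
#' `tau_b = (C - D) / sqrt((n0 - n1)(n0 - n2))` with `C`/`D` the concordant
#' and discordant pair counts, `n0 = n(n-1)/2` and `n1`, `n2` the tie
#' corrections in `x` and `y`.
#'
#' @param x,y Numeric vectors of equal length (>= 2), finite values.
#' @return The correlation in `[-1, 1]`.
#' @export
kendall_tau_b <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stopf("x and y differ in length")
  if (n < 2L) stopf("need at least 2 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("non-finite values")
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  S <- sum(dx * dy) / 2
  n0 <- n * (n - 1) / 2
  tie_corr <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  n1 <- tie_corr(x)
  n2 <- tie_corr(y)
  if (n0 == n1 || n0 == n2) stopf("zero variance: all values tied")
  S / sqrt((n0 - n1) * (n0 - n2))
}

#' Partial Kendall rank correlation
#'
#' Computes the pairwise tau-b matrix over `{x, y}` and the controls,
#' inverts it, and reads the partial correlation off the inverse:
#' `tau_xy.controls = -M[x,y] / sqrt(M[x,x] M[y,y])`. With a single control
#' `z` this reduces to the textbook recursion
#' `(tau_xy - tau_xz tau_yz) / sqrt((1 - tau_xz^2)(1 - tau_yz^2))`.
#' The two-sided p-value uses the normal approximation
#' `z = tau / sqrt(2 (2(n - g) + 5) / (9 (n - g)(n - g - 1)))` with
#' `g` the number of controls.
#'
#' Rows with a missing value in any used column are dropped (complete-case)
#' before computing the correlations.
#'
#' @param data Data frame of window metrics.
#' @param x,y Column names of the two variables of interest.
#' @param controls Character vector of control column names, disjoint from
#'   `x`/`y`.
#' @return An object of class `"partial_kendall"`; see
#'   [tidy.partial_kendall()].
#' @export
partial_kendall <- function(data, x, y, controls = character(0)) {
  if (any(controls %in% c(x, y))) stopf("controls must be disjoint from x and y")
  vars <- c(x, y, controls)
  d <- data[, vars, drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n < 10L) stopf("partial_kendall: fewer than 10 complete rows (n = %d)", n)
  k <- length(vars)
  tau <- diag(1, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      tau[i, j] <- tau[j, i] <- kendall_tau_b(d[[i]], d[[j]])
    }
  }
  inv <- tryCatch(solve(tau), error = function(e) NULL)
  if (is.null(inv)) stopf("degenerate control set: singular tau matrix")
  tp <- -inv[1, 2] / sqrt(inv[1, 1] * inv[2, 2])
  g <- length(controls)
  se <- sqrt(2 * (2 * (n - g) + 5) / (9 * (n - g) * (n - g - 1)))
  z <- tp / se
  structure(list(x_name = x, y_name = y, controls = controls, n = n,
                 tau_partial = tp, z_stat = z,
                 p_raw = 2 * pnorm(-abs(z)), p_adj = NA_real_),
            class = "partial_kendall")
}

#' @export
print.partial_kendall <- function(x, ...) {
  cat(sprintf(
    "Partial Kendall correlation: %s ~ %s | %s\n  n = %d, tau = %.4f, z = %.2f, p = %.3g\n",
    x$x_name, x$y_name,
    if (length(x$controls)) paste(x$controls, collapse = ", ") else "(none)",
    x$n, x$tau_partial, x$z_stat, x$p_raw))
  invisible(x)
}

#' Tidy a partial Kendall correlation
#'
#' @param x A `"partial_kendall"` object.
#' @param ... Unused.
#' @return One-row tibble: `x_name`, `y_name`, `controls`, `n`,
#'   `tau_partial`, `z_stat`, `p_raw`, `p_adj`.
#' @export
tidy.partial_kendall <- function(x, ...) {
  tibble(x_name = x$x_name, y_name = x$y_name,
         controls = paste(x$controls, collapse = ","), n = x$n,
         tau_partial = x$tau_partial, z_stat = x$z_stat,
         p_raw = x$p_raw, p_adj = x$p_adj)
}

#' Kruskal-Wallis rank-sum comparison of groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square upper-tail p-value on
#' `k - 1` degrees of freedom (delegated to [stats::kruskal.test()] after
#' validation). All values identical across groups leaves the tie
#' correction undefined and is an error, as is any empty group.
#'
#' @param groups Named list of numeric vectors, one per group (>= 2
#'   groups, total N >= 3).
#' @return An object of class `"kw_test"`; see [tidy.kw_test()].
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stopf("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stopf("empty group")
  if (sum(sizes) < 3L) stopf("need total N >= 3")
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1L) stopf("all values tied")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  g <- factor(rep(names(groups), sizes), levels = names(groups))
  kt <- stats::kruskal.test(pooled, g)
  structure(list(groups = names(groups), n_i = as.integer(sizes),
                 H = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value),
            class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.3g (groups: %s)\n",
              x$H, x$df, x$p, paste(x$groups, collapse = ", ")))
  invisible(x)
}

#' Tidy a Kruskal-Wallis comparison
#'
#' @param x A `"kw_test"` object.
#' @param ... Unused.
#' @return One-row tibble `H`, `df`, `p_value`, `n`, `groups`.
#' @export
tidy.kw_test <- function(x, ...) {
  tibble(H = x$H, df = x$df, p_value = x$p,
         n = sum(x$n_i), groups = paste(x$groups, collapse = ","))
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m p)` where `m` is the size of the declared test family
#' (for the windowed correlation report: the TE categories tested per
#' genomic feature).
#'
#' @param p Raw p-values in `[0, 1]`.
#' @param m Family size (>= 1).
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p, m) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values outside [0, 1]")
  if (m < 1) stopf("family size m must be >= 1")
  pmin(1, m * p)
}

#' Macro/micro chromosome classification
#'
#' Microchromosomes are strictly shorter than 20 Mb; chromosomes of
#' exactly 20 Mb are macro (documented tie-break).
#'
#' @param length_bp Chromosome lengths in bp (> 0), vectorised.
#' @return Character vector over `{"macro", "micro"}`.
#' @export
chrom_class <- function(length_bp) {
  if (any(length_bp <= 0)) stopf("chromosome length must be > 0")
  ifelse(length_bp < 2e7, "micro", "macro")
}

#' Relative TE coverage per chromosome
#'
#' Percentage of each chromosome covered by the union of the selected
#' copies' fragments, overall or split by repeat type. Chromosomes with no
#' copies report 0.
#'
#' @param copies Copy tibble.
#' @param chrom_sizes Tibble `chrom`, `length` covering every chromosome
#'   that carries copies (unknown chromosomes are an error).
#' @param by `"all"` for one value per chromosome or `"class"` for one per
#'   chromosome and repeat type.
#' @return Tibble `chrom`, `length`, `chrom_class`, (`class`,) `rel_cov`.
#' @export
relative_coverage <- function(copies, chrom_sizes, by = c("all", "class")) {
  by <- match.arg(by)
  iv <- copies_to_intervals(copies)
  unknown <- setdiff(unique(iv$chrom), chrom_sizes$chrom)
  if (length(unknown) > 0L) {
    stopf("copies on unknown chromosome(s): %s", paste(unknown, collapse = ", "))
  }
  base <- tibble(chrom = chrom_sizes$chrom, length = chrom_sizes$length,
                 chrom_class = chrom_class(chrom_sizes$length))
  cov_for <- function(sub) {
    vapply(seq_len(nrow(base)), function(i) {
      s <- sub[sub$chrom == base$chrom[[i]], ]
      100 * interval_union_bp(s$start, s$end) / base$length[[i]]
    }, numeric(1))
  }
  if (by == "all") {
    base$rel_cov <- cov_for(iv)
    return(base)
  }
  purrr::map(c("LTR", "LINE", "SINE", "DNA"), function(cl) {
    out <- base
    out$class <- cl
    out$rel_cov <- cov_for(iv[iv$class == cl, ])
    out
  }) |> dplyr::bind_rows()
}

#' Regression of relative TE coverage on chromosome length
#'
#' Ordinary least squares of `log10(rel_cov)` on chromosome length, with a
#' two-sided t-test on the slope. Chromosomes with zero coverage cannot be
#' log-transformed and are dropped with a warning.
#'
#' @param per_chrom Tibble with `length` and `rel_cov` columns, e.g. from
#'   [relative_coverage()]; at least 3 usable chromosomes.
#' @return An object of class `"cov_len_reg"` with `slope`, `p`, `n` and
#'   the underlying `lm` fit; see [tidy.cov_len_reg()].
#' @export
coverage_length_regression <- function(per_chrom) {
  drop <- per_chrom$rel_cov <= 0
  if (any(drop)) {
    warnf("dropping %d chromosome(s) with zero coverage", sum(drop))
    per_chrom <- per_chrom[!drop, ]
  }
  if (nrow(per_chrom) < 3L) stopf("need at least 3 chromosomes with coverage")
  fit <- suppressWarnings(lm(log10(rel_cov) ~ length, data = per_chrom))
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  p <- sm$coefficients[2, 4]
  if (!is.finite(p)) {
    # zero residual variance: exactly constant response (slope 0) gives the
    # null boundary p = 1, an exact non-constant fit the opposite boundary
    p <- if (abs(slope) < 1e-12) 1 else 0
  }
  structure(list(slope = slope, p = p, r_squared = sm$r.squared,
                 n = nrow(per_chrom), fit = fit),
            class = "cov_len_reg")
}

#' @export
print.cov_len_reg <- function(x, ...) {
  cat(sprintf("log10(coverage) ~ length: slope = %.3g, p = %.3g, n = %d\n",
              x$slope, x$p, x$n))
  invisible(x)
}

#' Tidy a coverage-versus-length regression
#'
#' @param x A `"cov_len_reg"` object.
#' @param ... Unused.
#' @return One-row tibble `slope`, `p_value`, `r_squared`, `n`.
#' @export
tidy.cov_len_reg <- function(x, ...) {
  tibble(slope = x$slope, p_value = x$p, r_squared = x$r_squared, n = x$n)
}

#' @rdname tidy.cov_len_reg
#' @export
glance.cov_len_reg <- function(x, ...) tidy(x, ...)

#' Windowed TE-versus-feature correlation report
#'
#' For every TE category (all / ancient / recent by default) and every
#' genomic feature, computes the partial Kendall correlation between the
#' category's window coverage and the feature, controlling for the other
#' features. A Bonferroni correction is applied per feature, with family
#' size equal to the number of TE categories tested against it. Partial
#' windows and non-autosomal windows are excluded by default.
#'
#' @param table Feature table from [feature_table()].
#' @param te_cols Named character vector mapping category labels to TE
#'   coverage columns.
#' @param feature_cols Named character vector mapping feature labels to
#'   feature columns.
#' @param autosomes_only Drop non-autosomal windows (default `TRUE`).
#' @param include_partial Keep trailing partial windows (default `FALSE`).
#' @return Tibble with one row per (category, feature): `te_category`,
#'   `feature`, `controls`, `n`, `tau_partial`, `z_stat`, `p_raw`, `p_adj`.
#' @export
te_feature_correlations <- function(
    table,
    te_cols = c(all = "te_cov_all", ancient = "te_cov_ancient",
                recent = "te_cov_recent"),
    feature_cols = c(GC = "gc", CpG = "cpg_cov", Gene = "gene_cov",
                     Rec.rate = "rec_rate"),
    autosomes_only = TRUE, include_partial = FALSE) {
  d <- table
  if (autosomes_only && "is_autosome" %in% names(d)) d <- d[d$is_autosome, ]
  if (!include_partial && "is_partial" %in% names(d)) d <- d[!d$is_partial, ]
  rows <- purrr::imap(feature_cols, function(fcol, flab) {
    purrr::imap(te_cols, function(tcol, tlab) {
      ctrl <- setdiff(unname(feature_cols), fcol)
      r <- tidy(partial_kendall(d, tcol, fcol, ctrl))
      tibble(te_category = tlab, feature = flab, controls = r$controls,
             n = r$n, tau_partial = r$tau_partial, z_stat = r$z_stat,
             p_raw = r$p_raw)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  rows |>
    dplyr::group_by(.data$feature) |>
    dplyr::mutate(p_adj = bonferroni(.data$p_raw, dplyr::n())) |>
    dplyr::ungroup()
}
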