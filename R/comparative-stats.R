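# Cross-species statistics: pg <-> Mbp conversion, C-value aggregation,
# normality-gated Mann-Whitney order comparisons, percentile reports,
# Spearman genome-size correlates and BUSCO completeness arithmetic.

# 1 pg of DNA corresponds to 978 Mbp (Dolezel et al. conversion).
MBP_PER_PG <- 978

#' Convert haploid DNA content between picograms and megabase pairs
#'
#' Uses the standard conversion 1 pg = 978 Mbp.  The two functions are
#' exact inverses to machine precision.
#'
#' @param c_value_pg,mbp Non-negative numeric vectors.
#' @return Numeric vector in the target unit.
#' @export
pg_to_mbp <- function(c_value_pg) {
  if (any(c_value_pg < 0)) stop("C-value must be non-negative")
  c_value_pg * MBP_PER_PG
}

#' @rdname pg_to_mbp
#' @export
mbp_to_pg <- function(mbp) {
  if (any(mbp < 0)) stop("genome size must be non-negative")
  mbp / MBP_PER_PG
}

#' Average duplicate C-value entries per species
#'
#' Databases often carry several measurements per species; this collapses
#' them to the arithmetic mean, carrying the taxonomy through.  Conflicting
#' order (or family) labels for one species are an error naming the
#' species.
#'
#' @param records Data frame from [read_cvalue_table()].
#' @return One row per species with columns `species`, `order`, `family`,
#'   `c_value_pg` (the mean) and `n_entries`.
#' @export
species_mean_cvalues <- function(records) {
  sp <- split(seq_len(nrow(records)), records$species)
  one <- function(i) {
    ord <- unique(records$order[i])
    if (length(ord) > 1L)
      stop("conflicting order labels for species ", records$species[i[1]],
           ": ", paste(ord, collapse = ", "))
    fam <- unique(records$family[i])
    fam <- fam[!is.na(fam)]
    if (length(fam) > 1L)
      stop("conflicting family labels for species ", records$species[i[1]])
    data.frame(species = records$species[i[1]], order = ord,
               family = if (length(fam)) fam else NA_character_,
               c_value_pg = mean(records$c_value_pg[i]),
               n_entries = length(i), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(sp, one))
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test for two independent samples
#'
#' U counts the pairs (i, j) with x_i > y_j, plus half the tied pairs.  The
#' p-value is exact (full enumeration of rank splits) when n1 * n2 <= 400
#' and there are no ties, and otherwise uses the normal approximation with
#' tie and continuity corrections.
#'
#' @param x,y Non-empty numeric vectors.
#' @param alternative Only `"two.sided"` is offered, matching the
#'   order-comparison use.
#' @return Object of class `mann_whitney_result` with `u_statistic` (U of
#'   `x`), `p_value`, `method` (`"exact"` or `"normal_approx"`), `n1`,
#'   `n2`.
#' @export
mann_whitney <- function(x, y, alternative = "two.sided") {
  alternative <- match.arg(alternative, "two.sided")
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  if (anyNA(x) || anyNA(y)) stop("samples contain NA")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) * length(y) <= 400
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = TRUE))
  structure(list(u_statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 method = if (exact) "exact" else "normal_approx",
                 n1 = length(x), n2 = length(y),
                 alternative = alternative),
            class = "mann_whitney_result")
}

#' @export
print.mann_whitney_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n1 = %d, n2 = %d), p = %.4g [%s]\n",
              x$u_statistic, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' Returns TRUE when the sample should be treated as non-normal (Shapiro-
#' Wilk p below `alpha`), routing downstream comparisons to the
#' non-parametric path.  Samples too small or constant cannot be tested and
#' gate to TRUE with a warning.  Samples beyond the test's n = 5000 limit
#' are reduced to 5000 evenly spaced order statistics.
#'
#' @param values Numeric vector.
#' @param alpha Significance level of the gate.
#' @return Logical: TRUE means use the non-parametric test.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3L || length(unique(values)) == 1L) {
    warning("cannot test normality (n < 3 or constant sample); gating to non-parametric")
    return(TRUE)
  }
  if (length(values) > 5000L) {
    values <- sort(values)[round(seq(1L, length(values), length.out = 5000L))]
  }
  stats::shapiro.test(values)$p.value < alpha
}

significance_stars <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 1e-2, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' Compare a focal order's C-values against every other order
#'
#' For each non-focal order with enough species, tests the per-species
#' C-values of the focal order against that order (Mann-Whitney by default;
#' Welch's t as an option) and labels significance on the conventional star
#' ladder (0.05 / 0.01 / 0.001 / 0.0001).  P-values are reported
#' unadjusted; set `adjust = "holm"` for a Holm correction.
#'
#' @param records Per-species C-values (one row per species, e.g. from
#'   [species_mean_cvalues()]): columns `species`, `order`, `c_value_pg`.
#' @param focal_order Name of the reference order; must have at least
#'   `min_species` species.
#' @param test `"mannwhitney"` or `"welch"`.
#' @param min_species Minimum species per order to include a comparison.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Data frame of class `order_comparison`: one row per comparison
#'   with per-order means (pg), the test statistic, p-value, method and
#'   significance label.
#' @export
compare_focal_order <- function(records, focal_order,
                                test = c("mannwhitney", "welch"),
                                min_species = 2L, adjust = c("none", "holm")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  focal <- records$c_value_pg[records$order == focal_order]
  if (length(focal) == 0L) stop("focal order not present: ", focal_order)
  if (length(focal) < min_species)
    stop("focal order has fewer than ", min_species, " species")
  others <- setdiff(unique(records$order), focal_order)
  rows <- list()
  for (ord in others) {
    v <- records$c_value_pg[records$order == ord]
    if (length(v) < min_species) next
    if (test == "mannwhitney") {
      r <- mann_whitney(focal, v)
      stat <- r$u_statistic; p <- r$p_value; meth <- paste0("mannwhitney_", r$method)
    } else {
      tt <- stats::t.test(focal, v)
      stat <- unname(tt$statistic); p <- tt$p.value; meth <- "welch_t"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      focal_order = focal_order, other_order = ord,
      n_focal = length(focal), n_other = length(v),
      focal_mean_pg = mean(focal), other_mean_pg = mean(v),
      statistic = stat, p_value = p, method = meth,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no other order has at least ", min_species, " species")
  if (adjust == "holm") out$p_value <- stats::p.adjust(out$p_value, "holm")
  out$significance <- significance_stars(out$p_value)
  rownames(out) <- NULL
  class(out) <- c("order_comparison", "data.frame")
  out
}

#' Global and per-order C-value percentile report
#'
#' Computes global percentile cutoffs over the per-species values, each
#' order's share of species at or below each lower-tail cutoff (e.g. "16.3%
#' of the order's species fall in the 5th-percentile range"), and, for an
#' optionally named order, the within-order percentile values.
#'
#' @param records Per-species C-values: columns `species`, `order`,
#'   `c_value_pg`; at least 10 species overall.
#' @param qs Percentile probabilities (default 5th, 10th, 90th).
#' @param focal_order Optional order for the within-order percentiles.
#' @return Object of class `percentile_report`: `cutoffs` (named numeric),
#'   `shares` (data frame: order, n_species, then share of species at or
#'   below each lower cutoff, in percent), and `focal` (within-order
#'   percentiles, when requested).
#' @export
order_percentile_report <- function(records, qs = c(0.05, 0.10, 0.90),
                                    focal_order = NULL) {
  if (nrow(records) < 10L) stop("at least 10 species are required")
  v <- records$c_value_pg
  cutoffs <- stats::setNames(quantile_linear(v, qs), qs)
  lower <- qs[qs < 0.5]
  orders <- unique(records$order)
  shares <- data.frame(order = orders,
                       n_species = vapply(orders, function(o) sum(records$order == o), 0L),
                       stringsAsFactors = FALSE)
  for (q in lower) {
    cut <- cutoffs[[as.character(q)]]
    shares[[paste0("pct_at_or_below_q", q * 100)]] <-
      vapply(orders, function(o) {
        vo <- v[records$order == o]
        100 * mean(vo <= cut)
      }, 0)
  }
  focal <- NULL
  if (!is.null(focal_order)) {
    vf <- v[records$order == focal_order]
    if (length(vf) == 0L) stop("focal order not present: ", focal_order)
    focal <- list(order = focal_order, n_species = length(vf),
                  percentiles = stats::setNames(quantile_linear(vf, qs), qs))
  }
  structure(list(cutoffs = cutoffs, shares = shares, focal = focal),
            class = "percentile_report")
}

#' @export
print.percentile_report <- function(x, ...) {
  cat("Global C-value percentile cutoffs (pg):\n")
  print(round(x$cutoffs, 4))
  cat("Per-order shares (%):\n")
  print(x$shares, row.names = FALSE)
  if (!is.null(x$focal)) {
    cat(sprintf("Within-order percentiles for %s (n = %d):\n",
                x$focal$order, x$focal$n_species))
    print(round(x$focal$percentiles, 4))
  }
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked data, with a two-sided p-value
#' from the t approximation on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, at least 3, neither
#'   constant.
#' @return Object of class `spearman_result` with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("inputs contain NA")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("constant vector: correlation undefined")
  rho <- stats::cor(x, y, method = "spearman")
  n <- length(x)
  p <- if (abs(rho) >= 1) 0
       else 2 * stats::pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), df = n - 2)
  structure(list(rho = rho, p_value = p, n = n), class = "spearman_result")
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (n = %d), p = %.4g\n", x$rho, x$n, x$p_value))
  invisible(x)
}

#' Genome-size correlates across species
#'
#' Spearman correlations of genome size against TE content (%), total
#' intron bp and total exon bp, across species.
#'
#' @param stats_df One row per species with columns `genome_size_bp`,
#'   `te_pct`, `total_intron_bp`, `total_exon_bp`.
#' @return Data frame with one row per pair: `pair`, `rho`, `p_value`,
#'   `n`.
#' @export
genome_correlates <- function(stats_df) {
  if (nrow(stats_df) < 3L) stop("need at least 3 species")
  pairs <- c(te_pct = "te_pct", total_intron_bp = "total_intron_bp",
             total_exon_bp = "total_exon_bp")
  rows <- lapply(names(pairs), function(nm) {
    r <- spearman_cor(stats_df$genome_size_bp, stats_df[[pairs[[nm]]]])
    data.frame(pair = paste0("genome_size_vs_", nm), rho = r$rho,
               p_value = r$p_value, n = r$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' BUSCO completeness percentage
#'
#' 100 * identified / total, reported to one decimal place.
#'
#' @param counts A [busco_counts()] object.
#' @return Percentage (one decimal).
#' @examples
#' busco_percent(busco_counts(identified = 3459, total = 3652))
#' @export
busco_percent <- function(counts) {
  stopifnot(inherits(counts, "busco_counts"))
  round(100 * counts$identified / counts$total, 1)
}
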