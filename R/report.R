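# Cross-species report assembly: joins per-species feature-size tables and
# repeat summaries into one comparison table with a correlation footer.

#' Assemble the cross-species comparison report
#'
#' Joins per-species feature-size tables (and optionally repeat summaries
#' and genome sizes) into one row per species with gene counts, median/IQR
#' and tail quantiles of the size distributions, TE content and size
#' totals.  When at least three species carry genome size plus TE and size
#' totals, Spearman genome-size correlates are appended as a footer block.
#' Columns without an input stay `NA` (written as `.` by
#' [write_species_report()]).
#'
#' @param feature_tables List of [feature_size_table()] objects, one per
#'   species; species labels must be unique.
#' @param repeat_summaries Optional list of [repeat_summary()] objects;
#'   matched to species by `species_label`.
#' @param genome_sizes Optional named numeric vector of genome sizes (bp)
#'   by species label; defaults to the matching repeat summary's genome
#'   size.
#' @return Object of class `species_report`: `table` (one row per species)
#'   and `correlations` (data frame from [genome_correlates()], or NULL).
#' @export
assemble_report <- function(feature_tables, repeat_summaries = NULL,
                            genome_sizes = NULL) {
  if (length(feature_tables) == 0L) stop("no feature tables supplied")
  labels <- vapply(feature_tables, function(x) x$species_label, "")
  if (anyDuplicated(labels))
    stop("duplicate species label: ", labels[duplicated(labels)][1])
  rep_by <- list()
  for (rs in repeat_summaries %||% list()) rep_by[[rs$species_label]] <- rs

  one <- function(ft) {
    sp <- ft$species_label
    qs <- function(v, p) if (length(v) >= 2L) quantile_linear(v, p) else NA_real_
    med <- function(v) if (length(v)) stats::median(v) else NA_real_
    iqr <- function(v) if (length(v) >= 2L) {
      q <- quantile_linear(v, c(0.25, 0.75)); q[2] - q[1]
    } else NA_real_
    rs <- rep_by[[sp]]
    gsize <- if (!is.null(genome_sizes) && sp %in% names(genome_sizes))
      genome_sizes[[sp]] else if (!is.null(rs)) rs$genome_size_bp else NA_real_
    data.frame(
      species = sp,
      genome_size_bp = gsize,
      gene_count = ft$gene_count,
      gene_median = med(ft$gene_sizes), gene_iqr = iqr(ft$gene_sizes),
      exon_median = med(ft$exon_sizes), exon_iqr = iqr(ft$exon_sizes),
      intron_median = med(ft$intron_sizes), intron_iqr = iqr(ft$intron_sizes),
      exon_q01 = qs(ft$exon_sizes, 0.01), exon_q80 = qs(ft$exon_sizes, 0.80),
      exon_q99 = qs(ft$exon_sizes, 0.99),
      intron_q01 = qs(ft$intron_sizes, 0.01),
      intron_q80 = qs(ft$intron_sizes, 0.80),
      intron_q99 = qs(ft$intron_sizes, 0.99),
      te_pct = if (!is.null(rs)) rs$te_pct_genome else NA_real_,
      total_exon_bp = ft$total_exon_bp,
      total_intron_bp = ft$total_intron_bp,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, lapply(feature_tables, one))
  rownames(tab) <- NULL
  complete <- !is.na(tab$genome_size_bp) & !is.na(tab$te_pct)
  correlations <- NULL
  if (sum(complete) >= 3L) {
    correlations <- genome_correlates(tab[complete, ])
  }
  structure(list(table = tab, correlations = correlations),
            class = "species_report")
}

#' @export
print.species_report <- function(x, ...) {
  cat(sprintf("species_report: %d species\n", nrow(x$table)))
  print(x$table, row.names = FALSE, digits = 4)
  if (!is.null(x$correlations)) {
    cat("Genome-size correlates (Spearman):\n")
    print(x$correlations, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write a species report as TSV
#'
#' One row per species with `.` for missing values; the correlation footer
#' is appended as comment lines (`# correlation<TAB>pair<TAB>rho...`).
#'
#' @param report A `species_report` from [assemble_report()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_species_report <- function(report, path) {
  stopifnot(inherits(report, "species_report"))
  write_tsv(report$table, path)
  if (!is.null(report$correlations)) {
    con <- file(path, open = "a", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(sprintf("# correlation\t%s\t%.6f\t%.6g\t%d",
                       report$correlations$pair, report$correlations$rho,
                       report$correlations$p_value, report$correlations$n),
               con)
  }
  invisible(path)
}
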