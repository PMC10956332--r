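# Repeat-element content summaries from RepeatMasker hits.

REPEAT_CLASSES <- c("DNA", "LINE", "SINE", "LTR", "Other")

#' Classify a RepeatMasker class/family string
#'
#' Prefix match on the class part (before `/`): `LINE*` -> LINE,
#' `SINE*` -> SINE, `LTR*` -> LTR, `DNA*` and `RC*` (rolling-circle
#' transposons) -> DNA; everything else (Simple_repeat, Low_complexity,
#' Satellite, Unknown, rRNA, ...) -> Other.
#'
#' @param repeat_class Character vector of class/family strings, e.g.
#'   `"LINE/L1"`.
#' @return Character vector over `{DNA, LINE, SINE, LTR, Other}`.
#' @export
classify_repeat <- function(repeat_class) {
  cls <- sub("/.*$", "", repeat_class)
  out <- rep("Other", length(cls))
  out[startsWith(cls, "LINE")] <- "LINE"
  out[startsWith(cls, "SINE")] <- "SINE"
  out[startsWith(cls, "LTR")] <- "LTR"
  out[startsWith(cls, "DNA") | startsWith(cls, "RC")] <- "DNA"
  out
}

# union length of a set of 1-based inclusive intervals
interval_union_bp <- function(start, end) {
  if (length(start) == 0L) return(0)
  r <- IRanges::reduce(IRanges::IRanges(start = start, end = end))
  sum(as.numeric(IRanges::width(r)))
}

#' Summarize repeat content per class
#'
#' Tallies masked base pairs per repeat class (hit length is
#' end - start + 1; RepeatMasker coordinates are 1-based inclusive) and the
#' derived percentages of the genome and of the repeat content.  In `raw`
#' mode hit lengths are summed as RepeatMasker's own tables do; in `merged`
#' mode per-class masked bp is the union length of that class's intervals
#' (per seqid), and the overall total is the genome-wide union of all
#' retained hits, so the total genome percentage cannot exceed 100.
#' `pct_of_repeats` is always normalized by the per-class sum, so it sums
#' to 100 whenever anything is masked.
#'
#' @param hits Data frame from [read_repeatmasker_out()].
#' @param genome_size_bp Positive genome size in bp.
#' @param overlap_mode `"raw"` (sum of hit lengths) or `"merged"`
#'   (interval union).
#' @param max_divergence Exclude hits more diverged from their consensus
#'   than this percentage (default 20); `NULL` disables the filter.
#' @param drop_overlapped Drop rows RepeatMasker marked `*` (overlapped by
#'   a higher-scoring hit)?  Default keeps them.
#' @param species_label Label carried into outputs.
#' @return Object of class `repeat_summary`: `per_class` data frame
#'   (class, masked_bp, pct_genome, pct_of_repeats), `total_masked_bp`,
#'   `total_pct_genome`, plus `te_masked_bp`/`te_pct_genome` for the four
#'   mobile classes combined (DNA + LINE + SINE + LTR), and bookkeeping on
#'   the filters applied.
#' @export
repeat_summary <- function(hits, genome_size_bp,
                           overlap_mode = c("raw", "merged"),
                           max_divergence = 20,
                           drop_overlapped = FALSE,
                           species_label = "genome") {
  overlap_mode <- match.arg(overlap_mode)
  if (length(genome_size_bp) != 1L || is.na(genome_size_bp) || genome_size_bp <= 0)
    stop("genome_size_bp must be a positive number")
  n_in <- nrow(hits)
  if (drop_overlapped) hits <- hits[!hits$overlapped, , drop = FALSE]
  if (!is.null(max_divergence))
    hits <- hits[hits$divergence_pct <= max_divergence, , drop = FALSE]
  cls <- classify_repeat(hits$repeat_class)

  masked <- stats::setNames(numeric(length(REPEAT_CLASSES)), REPEAT_CLASSES)
  for (k in REPEAT_CLASSES) {
    sel <- cls == k
    if (!any(sel)) next
    if (overlap_mode == "raw") {
      masked[k] <- sum(as.numeric(hits$query_end[sel] - hits$query_start[sel] + 1))
    } else {
      masked[k] <- sum(vapply(split(which(sel), hits$query_seq[sel]),
                              function(i) interval_union_bp(hits$query_start[i],
                                                            hits$query_end[i]),
                              0))
    }
  }
  class_sum <- sum(masked)
  total <- if (overlap_mode == "raw" || nrow(hits) == 0L) class_sum
           else sum(vapply(split(seq_len(nrow(hits)), hits$query_seq),
                           function(i) interval_union_bp(hits$query_start[i],
                                                         hits$query_end[i]),
                           0))
  per_class <- data.frame(
    class = REPEAT_CLASSES,
    masked_bp = as.numeric(masked),
    pct_genome = 100 * as.numeric(masked) / genome_size_bp,
    pct_of_repeats = if (class_sum > 0) 100 * as.numeric(masked) / class_sum
                     else rep(0, length(masked)),
    stringsAsFactors = FALSE)
  mobile <- sum(masked[c("DNA", "LINE", "SINE", "LTR")])
  structure(list(species_label = species_label,
                 genome_size_bp = genome_size_bp,
                 per_class = per_class,
                 total_masked_bp = total,
                 total_pct_genome = 100 * total / genome_size_bp,
                 te_masked_bp = mobile,
                 te_pct_genome = 100 * mobile / genome_size_bp,
                 overlap_mode = overlap_mode,
                 max_divergence = max_divergence,
                 n_hits_used = nrow(hits),
                 n_hits_excluded = n_in - nrow(hits)),
            class = "repeat_summary")
}

#' @export
print.repeat_summary <- function(x, ...) {
  cat(sprintf("repeat_summary for %s: %.0f bp genome, %s mode, %d hits used (%d excluded)\n",
              x$species_label, x$genome_size_bp, x$overlap_mode,
              x$n_hits_used, x$n_hits_excluded))
  print(x$per_class, row.names = FALSE)
  cat(sprintf("  total masked: %.0f bp (%.2f%% of genome); mobile elements: %.0f bp (%.2f%%)\n",
              x$total_masked_bp, x$total_pct_genome,
              x$te_masked_bp, x$te_pct_genome))
  invisible(x)
}
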