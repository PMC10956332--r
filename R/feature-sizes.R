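# Gene-model assembly and the coordinate-difference size procedure.
#
# Two size conventions are supported throughout:
#   "difference" -- literal coordinate differences: span = end - start,
#                   exon = end - start, intron = next.start - prev.end
#   "biological" -- base-pair lengths: +1 on spans/exons, -1 on introns
# The two differ by exactly 1 bp per feature.

size_convention <- function(convention) {
  match.arg(convention, c("difference", "biological"))
}

#' Assemble gene models from GFF3 records
#'
#' Builds the gene -> transcript -> exon hierarchy from parsed GFF3 records.
#' Exons with several `Parent` values contribute to each parent transcript;
#' a transcript with no exon children falls back to its CDS children;
#' transcripts whose parent gene is missing become single-transcript genes
#' with a synthesized gene id.  Exons are sorted by start coordinate
#' irrespective of strand.  Exons whose `Parent` matches no transcript, and
#' genes left with no transcripts, are counted and skipped, not fatal.
#'
#' @param records Data frame from [read_gff3()].
#' @param feature_config Named list mapping roles to GFF3 feature types:
#'   `gene`, `transcript`, `part` (exon), `part_fallback` (CDS).
#' @return An object of class `gene_models`: a list of gene models, each a
#'   list with `gene_id`, `seqid`, `start`, `end`, `strand` and
#'   `transcripts` (each with `transcript_id`, `gene_id`, `strand`, an
#'   `exons` two-column matrix sorted by start, and `overlapping_exons`
#'   flag).  QC counters are attached as the `counters` attribute.
#' @export
build_gene_models <- function(records,
                              feature_config = list(gene = "gene",
                                                    transcript = c("mRNA", "transcript"),
                                                    part = "exon",
                                                    part_fallback = "CDS")) {
  att <- records$attributes
  get_id <- function(a) if (!is.null(a[["ID"]])) a[["ID"]][1] else NA_character_
  ids <- vapply(att, get_id, "")
  parents <- lapply(att, function(a) a[["Parent"]] %||% character())
  type <- records$type

  g_idx <- which(type %in% feature_config$gene)
  t_idx <- which(type %in% feature_config$transcript)
  e_idx <- which(type %in% feature_config$part)
  c_idx <- which(type %in% (feature_config$part_fallback %||% character()))

  gene_ids <- ids[g_idx]
  tx_ids <- ids[t_idx]
  known_tx <- tx_ids[!is.na(tx_ids)]

  explode <- function(idxs) {
    p <- parents[idxs]
    n <- lengths(p)
    list(row = rep(idxs, n), parent = unlist(p, use.names = FALSE), n = n)
  }
  ex <- explode(e_idx)
  orphan_exons <- sum(!vapply(seq_along(e_idx), function(i) {
    any(parents[[e_idx[i]]] %in% known_tx)
  }, logical(1)))
  keep <- ex$parent %in% known_tx
  ex_by_tx <- split(ex$row[keep], ex$parent[keep])
  cd <- explode(c_idx)
  keepc <- cd$parent %in% known_tx
  cds_by_tx <- split(cd$row[keepc], cd$parent[keepc])

  starts <- records$start; ends <- records$end
  seqids <- records$seqid; strands <- records$strand

  n_overlap_flagged <- 0L
  n_empty_tx <- 0L
  make_tx <- function(j) {
    tid <- tx_ids[j]
    rows <- ex_by_tx[[tid]]
    if (is.null(rows) || length(rows) == 0L) rows <- cds_by_tx[[tid]]
    if (is.null(rows) || length(rows) == 0L) return(NULL)
    o <- order(starts[rows])
    s <- starts[rows][o]; e <- ends[rows][o]
    overl <- length(s) > 1L && any(s[-1L] <= e[-length(e)])
    list(transcript_id = tid, strand = strands[t_idx][match(j, seq_along(t_idx))],
         exons = cbind(start = s, end = e), overlapping_exons = overl)
  }

  tx_models <- vector("list", length(t_idx))
  for (j in seq_along(t_idx)) {
    tx <- make_tx(j)
    if (is.null(tx)) n_empty_tx <- n_empty_tx + 1L
    else {
      tx$strand <- strands[t_idx[j]]
      if (tx$overlapping_exons) n_overlap_flagged <- n_overlap_flagged + 1L
    }
    tx_models[[j]] <- tx
  }

  # attach transcripts to parent genes; orphans get synthesized genes
  genes <- list()
  gi <- stats::setNames(seq_along(g_idx), gene_ids)
  tx_lists <- vector("list", length(g_idx))
  orphan_genes <- list()
  for (j in seq_along(t_idx)) {
    tx <- tx_models[[j]]
    if (is.null(tx)) next
    par <- parents[[t_idx[j]]]
    par <- par[par %in% gene_ids]
    tx$gene_id <- if (length(par)) par[1] else paste0("gene-", tx$transcript_id)
    if (length(par)) {
      for (p in par) {
        k <- gi[[p]]
        tx$gene_id <- p
        tx_lists[[k]] <- c(tx_lists[[k]], list(tx))
      }
    } else {
      r <- t_idx[j]
      orphan_genes[[length(orphan_genes) + 1L]] <-
        list(gene_id = tx$gene_id, seqid = seqids[r], start = starts[r],
             end = ends[r], strand = strands[r], transcripts = list(tx))
    }
  }

  n_empty_genes <- 0L
  out <- list()
  for (k in seq_along(g_idx)) {
    if (is.null(tx_lists[[k]]) || length(tx_lists[[k]]) == 0L) {
      n_empty_genes <- n_empty_genes + 1L
      next
    }
    r <- g_idx[k]
    out[[length(out) + 1L]] <- list(gene_id = gene_ids[k], seqid = seqids[r],
                                    start = starts[r], end = ends[r],
                                    strand = strands[r],
                                    transcripts = tx_lists[[k]])
  }
  out <- c(out, orphan_genes)
  structure(out,
            counters = list(orphan_exons = orphan_exons,
                            empty_transcripts = n_empty_tx,
                            empty_genes = n_empty_genes,
                            overlapping_exon_transcripts = n_overlap_flagged,
                            orphan_transcripts = length(orphan_genes)),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  ct <- attr(x, "counters")
  ntx <- sum(vapply(x, function(g) length(g$transcripts), 0L))
  cat(sprintf("gene_models: %d genes, %d transcripts\n", length(x), ntx))
  cat(sprintf("  QC: %d orphan exons, %d empty transcripts, %d empty genes, %d transcripts with overlapping exons\n",
              ct$orphan_exons, ct$empty_transcripts, ct$empty_genes,
              ct$overlapping_exon_transcripts))
  invisible(x)
}

#' Gene locus span size
#'
#' Size of a gene model from its own record coordinates: the difference
#' between the final and initial base coordinate (`difference` convention), or
#' that difference plus one (`biological` base-pair length).
#'
#' @param gene A gene model from [build_gene_models()].
#' @param convention `"difference"` (end - start) or `"biological"`
#'   (end - start + 1).
#' @return An integer size.  Under the difference convention a zero-span gene
#'   yields 0; [feature_size_table()] drops and counts such values.
#' @export
gene_span_size <- function(gene, convention = "difference") {
  convention <- size_convention(convention)
  gene$end - gene$start + (convention == "biological")
}

#' Per-exon sizes of a transcript
#'
#' @param transcript A transcript model (element of a gene model's
#'   `transcripts` list).
#' @inheritParams gene_span_size
#' @return Integer vector of per-exon sizes in exon (start-coordinate)
#'   order.
#' @export
exon_sizes <- function(transcript, convention = "difference") {
  convention <- size_convention(convention)
  ex <- transcript$exons
  unname(ex[, "end"] - ex[, "start"] + (convention == "biological"))
}

#' Intron sizes inferred from exon gaps
#'
#' For k exons returns k - 1 values: the difference between the first base
#' coordinate of an exon and the last base coordinate of the preceding exon
#' (`difference` convention), minus one for the `biological` gap length.  Exons
#' are taken in ascending start order regardless of strand; sizes are
#' strand-symmetric.  Non-positive values (overlapping or bookended exons)
#' are returned as-is here and dropped with a counter by
#' [feature_size_table()].
#'
#' @inheritParams exon_sizes
#' @return Integer vector of length (number of exons - 1).
#' @export
intron_sizes <- function(transcript, convention = "difference") {
  convention <- size_convention(convention)
  ex <- transcript$exons
  k <- nrow(ex)
  if (k < 2L) return(integer())
  unname(ex[-1L, "start"] - ex[-k, "end"] - (convention == "biological"))
}

#' Pooled feature-size table for one species
#'
#' Applies the coordinate-difference size procedure over a collection of
#' gene models: one gene size per gene record, with exon and intron sizes
#' pooled across all transcripts of all genes (no canonical-transcript
#' selection; shared exons appear once per transcript).  Non-positive sizes
#' under the chosen convention are dropped and tallied.
#'
#' @param genes A `gene_models` object.
#' @param species_label Label carried into outputs.
#' @inheritParams gene_span_size
#' @return An object of class `feature_size_table` with fields
#'   `species_label`, `gene_sizes`, `exon_sizes`, `intron_sizes`,
#'   `gene_count`, `total_exon_bp`, `total_intron_bp`, `convention` and a
#'   `dropped` counter list.
#' @export
feature_size_table <- function(genes, species_label, convention = "difference") {
  convention <- size_convention(convention)
  gs <- vapply(genes, gene_span_size, 0L, convention = convention)
  ex_l <- vector("list", length(genes))
  in_l <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    txs <- genes[[i]]$transcripts
    ex_l[[i]] <- unlist(lapply(txs, exon_sizes, convention = convention),
                        use.names = FALSE)
    in_l[[i]] <- unlist(lapply(txs, intron_sizes, convention = convention),
                        use.names = FALSE)
  }
  es <- unlist(ex_l, use.names = FALSE) %||% integer()
  is <- unlist(in_l, use.names = FALSE) %||% integer()
  if (is.null(es)) es <- integer()
  if (is.null(is)) is <- integer()
  dropped <- list(gene = sum(gs <= 0L), exon = sum(es <= 0L),
                  intron = sum(is <= 0L))
  gs <- gs[gs > 0L]; es <- es[es > 0L]; is <- is[is > 0L]
  structure(list(species_label = species_label,
                 gene_sizes = as.integer(gs),
                 exon_sizes = as.integer(es),
                 intron_sizes = as.integer(is),
                 gene_count = length(gs),
                 total_exon_bp = sum(as.numeric(es)),
                 total_intron_bp = sum(as.numeric(is)),
                 convention = convention,
                 dropped = dropped),
            class = "feature_size_table")
}

#' @export
print.feature_size_table <- function(x, ...) {
  cat(sprintf("feature_size_table for %s (%s convention)\n",
              x$species_label, x$convention))
  cat(sprintf("  genes: %d (median size %s bp)\n", x$gene_count,
              if (x$gene_count) format(stats::median(x$gene_sizes)) else "-"))
  cat(sprintf("  exons: %d (total %.0f bp), introns: %d (total %.0f bp)\n",
              length(x$exon_sizes), x$total_exon_bp,
              length(x$intron_sizes), x$total_intron_bp))
  dr <- x$dropped
  if (dr$gene + dr$exon + dr$intron > 0)
    cat(sprintf("  dropped non-positive sizes: %d gene, %d exon, %d intron\n",
                dr$gene, dr$exon, dr$intron))
  invisible(x)
}

#' Long-format feature size export
#'
#' One row per measured feature, suitable for TSV export: columns
#' `species`, `gene_id`, `transcript_id`, `feature` (gene/exon/intron),
#' `ordinal`, `size_bp`, `convention`.  Unlike [feature_size_table()],
#' non-positive sizes are retained here so the export is lossless; filter on
#' `size_bp > 0` to match the pooled arrays.
#'
#' @inheritParams feature_size_table
#' @return A data frame.
#' @export
feature_size_frame <- function(genes, species_label, convention = "difference") {
  convention <- size_convention(convention)
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    parts <- list(data.frame(species = species_label, gene_id = g$gene_id,
                             transcript_id = NA_character_, feature = "gene",
                             ordinal = 1L,
                             size_bp = gene_span_size(g, convention),
                             stringsAsFactors = FALSE))
    for (tx in g$transcripts) {
      e <- exon_sizes(tx, convention)
      parts[[length(parts) + 1L]] <-
        data.frame(species = species_label, gene_id = g$gene_id,
                   transcript_id = tx$transcript_id, feature = "exon",
                   ordinal = seq_along(e), size_bp = e,
                   stringsAsFactors = FALSE)
      intr <- intron_sizes(tx, convention)
      if (length(intr))
        parts[[length(parts) + 1L]] <-
          data.frame(species = species_label, gene_id = g$gene_id,
                     transcript_id = tx$transcript_id, feature = "intron",
                     ordinal = seq_along(intr), size_bp = intr,
                     stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, parts)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(species = character(), gene_id = character(),
                      transcript_id = character(), feature = character(),
                      ordinal = integer(), size_bp = integer(),
                      stringsAsFactors = FALSE)
  out$convention <- rep(convention, nrow(out))
  rownames(out) <- NULL
  out
}
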