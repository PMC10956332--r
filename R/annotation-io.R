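#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a file atomically: stage in a sibling temp file, then rename.
atomic_write_lines <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) stop("cannot write to ", path)
  invisible(path)
}

# ---- GFF3 ------------------------------------------------------------------

# Percent-decode one attribute value (after comma-splitting, so encoded
# commas survive as literal characters).
decode_gff_value <- function(x) {
  vapply(x, utils::URLdecode, "", USE.NAMES = FALSE)
}

encode_gff_value <- function(x) {
  # '%' must be encoded first; then the GFF3 reserved characters.
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  x
}

parse_gff_attributes <- function(s) {
  if (is.na(s) || s == "." || !nzchar(s)) return(stats::setNames(list(), character()))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  eq <- regexpr("=", parts, fixed = TRUE)
  keys <- ifelse(eq > 0, substr(parts, 1L, eq - 1L), parts)
  vals <- ifelse(eq > 0, substr(parts, eq + 1L, nchar(parts)), "")
  out <- lapply(vals, function(v) decode_gff_value(strsplit(v, ",", fixed = TRUE)[[1]]))
  stats::setNames(out, keys)
}

#' Read a GFF3 annotation file
#'
#' Parses a GFF3 file into a data frame with one row per feature line.
#' Comment and directive lines (starting with `#`) are skipped.  Attribute
#' strings are parsed into named lists; multi-valued attributes such as
#' `Parent=a,b` become character vectors, and percent-encoded characters are
#' decoded.  Coordinates are kept in the native GFF3 convention: 1-based,
#' inclusive.
#'
#' @param path Path to a GFF3 file (plain or gzip-compressed).
#' @return A data frame with columns `seqid`, `source`, `type`, `start`,
#'   `end`, `score`, `strand`, `phase` and a list column `attributes`.
#' @examples
#' f <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\tsrc\tgene\t100\t400\t.\t+\t.\tID=g1"), f)
#' read_gff3(f)
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(seqid = character(), source = character(),
                      type = character(), start = integer(), end = integer(),
                      score = character(), strand = character(),
                      phase = character(),
                      attributes = I(list()), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfld <- lengths(fields)
  if (any(nfld != 9L)) {
    bad <- which(nfld != 9L)[1]
    stop(sprintf("GFF3 parse error at line %d: expected 9 tab-separated columns, got %d",
                 idx[bad], nfld[bad]))
  }
  m <- matrix(unlist(fields, use.names = FALSE), ncol = 9L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop(sprintf("GFF3 parse error at line %d: non-numeric coordinate", idx[bad]))
  }
  if (any(start < 1L)) {
    bad <- which(start < 1L)[1]
    stop(sprintf("GFF3 validation error at line %d: start < 1", idx[bad]))
  }
  if (any(end < start)) {
    bad <- which(end < start)[1]
    stop(sprintf("GFF3 validation error at line %d: end (%d) < start (%d)",
                 idx[bad], end[bad], start[bad]))
  }
  if (any(!nzchar(m[, 3L]))) {
    bad <- which(!nzchar(m[, 3L]))[1]
    stop(sprintf("GFF3 validation error at line %d: empty feature type", idx[bad]))
  }
  data.frame(seqid = m[, 1L], source = m[, 2L], type = m[, 3L],
             start = start, end = end, score = m[, 6L], strand = m[, 7L],
             phase = m[, 8L],
             attributes = I(lapply(m[, 9L], parse_gff_attributes)),
             stringsAsFactors = FALSE)
}

#' Write GFF3 records back to a file
#'
#' Inverse of [read_gff3()]: re-encodes reserved characters in attribute
#' values and joins multi-valued attributes with commas, so that
#' write-then-read round-trips coordinates and attributes exactly.
#'
#' @param records Data frame as returned by [read_gff3()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gff3 <- function(records, path) {
  att <- vapply(records$attributes, function(a) {
    if (length(a) == 0L) return(".")
    paste(vapply(seq_along(a), function(i) {
      paste0(names(a)[i], "=", paste(encode_gff_value(a[[i]]), collapse = ","))
    }, ""), collapse = ";")
  }, "")
  lines <- c("##gff-version 3",
             paste(records$seqid, records$source, records$type,
                   records$start, records$end, records$score,
                   records$strand, records$phase, att, sep = "\t"))
  atomic_write_lines(lines, path)
}

# ---- RepeatMasker .out -----------------------------------------------------

#' Read a RepeatMasker .out alignment table
#'
#' Parses the whitespace-delimited alignment table emitted by RepeatMasker.
#' Leading header lines (the two column-name lines and any blank lines) are
#' skipped.  Rows flagged with a trailing `*` (a hit overlapped by a
#' higher-scoring one) are retained and marked in the `overlapped` column so
#' that filtering remains a summary-time choice.
#'
#' @param path Path to a `.out` file.
#' @return A data frame with columns `query_seq`, `query_start`, `query_end`
#'   (1-based inclusive), `strand`, `repeat_name`, `repeat_class` (the
#'   class/family string, e.g. `"LINE/L1"`), `divergence_pct` and
#'   `overlapped`.
#' @export
read_repeatmasker_out <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  empty <- data.frame(query_seq = character(), query_start = integer(),
                      query_end = integer(), strand = character(),
                      repeat_name = character(), repeat_class = character(),
                      divergence_pct = numeric(), overlapped = logical(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  # header block: leading lines that do not start with a numeric score
  is_data <- grepl("^\\s*\\d", lines)
  first_data <- which(is_data)[1]
  if (is.na(first_data)) return(empty)
  idx <- seq(first_data, length(lines))
  idx <- idx[nzchar(trimws(lines[idx]))]
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  parse_row <- function(tk, lineno) {
    if (length(tk) < 14L)
      stop(sprintf(".out parse error at line %d: expected >= 14 fields, got %d",
                   lineno, length(tk)))
    qs <- suppressWarnings(as.integer(tk[6]))
    qe <- suppressWarnings(as.integer(tk[7]))
    dv <- suppressWarnings(as.numeric(tk[2]))
    if (is.na(qs) || is.na(qe))
      stop(sprintf(".out parse error at line %d: non-numeric query coordinate", lineno))
    if (is.na(dv) || dv < 0 || dv > 100)
      stop(sprintf(".out parse error at line %d: bad divergence value", lineno))
    if (qe < qs)
      stop(sprintf(".out validation error at line %d: query_end < query_start", lineno))
    list(query_seq = tk[5], query_start = qs, query_end = qe,
         strand = tk[9], repeat_name = tk[10], repeat_class = tk[11],
         divergence_pct = dv, overlapped = tk[length(tk)] == "*")
  }
  rows <- Map(parse_row, toks, idx)
  data.frame(
    query_seq = vapply(rows, `[[`, "", "query_seq"),
    query_start = vapply(rows, `[[`, 0L, "query_start"),
    query_end = vapply(rows, `[[`, 0L, "query_end"),
    strand = vapply(rows, `[[`, "", "strand"),
    repeat_name = vapply(rows, `[[`, "", "repeat_name"),
    repeat_class = vapply(rows, `[[`, "", "repeat_class"),
    divergence_pct = vapply(rows, `[[`, 0, "divergence_pct"),
    overlapped = vapply(rows, `[[`, FALSE, "overlapped"),
    stringsAsFactors = FALSE)
}

# ---- C-value tables --------------------------------------------------------

#' Read a species C-value table
#'
#' Reads a table of haploid DNA content (C-value, pg) per species, in the
#' layout of an Animal Genome Size Database export: columns `species`,
#' `order`, optional `family`, and `c_value_pg`.  The delimiter (tab or
#' comma) is sniffed from the header line.  Duplicate rows for one species
#' are preserved; averaging is a downstream step
#' ([species_mean_cvalues()]).
#'
#' @param path Path to a TSV or CSV file with a header row.
#' @return A data frame with columns `species`, `order`, `family` (NA when
#'   absent) and `c_value_pg`.
#' @export
read_cvalue_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  names(df) <- tolower(names(df))
  req <- c("species", "order", "c_value_pg")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("C-value table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (!is.numeric(df$c_value_pg))
    stop("C-value table schema error: c_value_pg is not numeric")
  if (any(is.na(df$c_value_pg) | df$c_value_pg <= 0)) {
    bad <- which(is.na(df$c_value_pg) | df$c_value_pg <= 0)[1]
    stop(sprintf("C-value validation error: non-positive C-value in row %d (%s)",
                 bad, df$species[bad]))
  }
  if (any(!nzchar(df$order)))
    stop("C-value validation error: empty order label")
  data.frame(species = as.character(df$species),
             order = as.character(df$order),
             family = if ("family" %in% names(df)) as.character(df$family) else NA_character_,
             c_value_pg = df$c_value_pg,
             stringsAsFactors = FALSE)
}

# ---- BUSCO -----------------------------------------------------------------

#' BUSCO ortholog counts
#'
#' Container for the counts reported by a BUSCO run: the number of complete
#' and fragmented orthologs, the number identified (complete + fragmented),
#' and the size of the reference set.  `identified` and `total` are
#' authoritative; if `complete + fragmented` disagrees with `identified`
#' (as printed tables sometimes do), a warning flags the inconsistency.
#'
#' @param identified Number of orthologs found (complete or fragmented).
#'   Defaults to `complete + fragmented` when those are given.
#' @param total Size of the ortholog reference set.
#' @param complete,fragmented Optional component counts.
#' @return An object of class `busco_counts`.
#' @seealso [busco_percent()]
#' @export
busco_counts <- function(identified = NULL, total, complete = NULL,
                         fragmented = NULL) {
  if (is.null(identified)) {
    if (is.null(complete) || is.null(fragmented))
      stop("give either `identified` or both `complete` and `fragmented`")
    identified <- complete + fragmented
  }
  identified <- as.integer(identified); total <- as.integer(total)
  if (total <= 0L) stop("total must be positive")
  if (identified < 0L) stop("identified must be non-negative")
  if (identified > total) stop("identified exceeds total")
  if (!is.null(complete) && !is.null(fragmented)) {
    if (complete < 0L || fragmented < 0L || complete + fragmented > total)
      stop("invalid complete/fragmented counts")
    if (complete + fragmented != identified)
      warning(sprintf("component counts inconsistent: %d + %d != %d; using `identified`",
                      complete, fragmented, identified))
  }
  structure(list(complete = if (is.null(complete)) NA_integer_ else as.integer(complete),
                 fragmented = if (is.null(fragmented)) NA_integer_ else as.integer(fragmented),
                 identified = identified, total = total),
            class = "busco_counts")
}

#' Parse a BUSCO short-summary file
#'
#' Extracts ortholog counts from the numbered lines of a
#' `short_summary*.txt` file ("Complete BUSCOs", "Fragmented BUSCOs",
#' "Total BUSCO groups searched").
#'
#' @param path Path to a BUSCO short summary text file.
#' @return A [busco_counts()] object.
#' @export
read_busco_summary <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  grab <- function(pattern) {
    hit <- grep(pattern, lines, value = TRUE)
    if (!length(hit)) return(NA_integer_)
    as.integer(sub("^\\D*(\\d+).*$", "\\1", hit[1]))
  }
  complete <- grab("Complete BUSCOs")
  fragmented <- grab("Fragmented BUSCOs")
  total <- grab("Total BUSCO groups searched")
  if (is.na(complete) || is.na(fragmented) || is.na(total))
    stop("could not locate BUSCO counts in ", path)
  busco_counts(complete = complete, fragmented = fragmented, total = total)
}

# ---- TSV -------------------------------------------------------------------

#' Write a table as TSV with '.' for missing values
#'
#' UTF-8, tab-delimited, header row first, missing values written as `.`.
#' The write is atomic (temp file + rename).  [read_genarch_tsv()] reads the
#' format back, restoring `.` to `NA`.
#'
#' @param table A data frame; all rows share the column set.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(table, path) {
  stopifnot(is.data.frame(table))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  utils::write.table(table, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".", fileEncoding = "UTF-8")
  if (!file.rename(tmp, path)) stop("cannot write to ", path)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_genarch_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", na.strings = ".",
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}
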