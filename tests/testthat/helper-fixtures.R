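# In-code fixtures shared across the suite.

toy_gff3_lines <- function() c(
  "##gff-version 3",
  "# a comment",
  "chr1\ttest\tgene\t100\t400\t.\t+\t.\tID=g1;Name=Gene%3B1",
  "chr1\ttest\tmRNA\t100\t400\t.\t+\t.\tID=t1;Parent=g1",
  "chr1\ttest\texon\t100\t200\t.\t+\t.\tID=t1.e1;Parent=t1",
  "chr1\ttest\texon\t301\t400\t.\t+\t.\tID=t1.e2;Parent=t1")

write_toy_gff3 <- function(lines = toy_gff3_lines()) {
  f <- tempfile(fileext = ".gff3")
  writeLines(lines, f)
  f
}

rm_out_header <- function() c(
  "   SW   perc perc perc  query      position in query    matching repeat",
  "score   div. del. ins.  sequence   begin end    (left)  repeat   class/family  begin end (left) ID",
  "")

rm_out_row <- function(score, div, query, qs, qe, strand, name, family, id,
                       star = FALSE) {
  paste0(sprintf("%5d %5.1f  0.0  0.0  %s %7d %7d (1000) %s  %s %s 1 %d (0) %d",
                 score, div, query, qs, qe, strand, name, family, qe - qs + 1, id),
         if (star) " *" else "")
}

write_toy_rmout <- function(rows) {
  f <- tempfile(fileext = ".out")
  writeLines(c(rm_out_header(), rows), f)
  f
}

write_cvalue_fixture <- function(text, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(text, f)
  f
}

# Build a transcript model directly (bypassing GFF3) for size-formula tests.
make_transcript <- function(exons, id = "t1", strand = "+") {
  list(transcript_id = id, gene_id = "g1", strand = strand,
       exons = cbind(start = exons[, 1], end = exons[, 2]),
       overlapping_exons = FALSE)
}

# Random k-exon transcript with positive exon and intron lengths.
random_transcript <- function(max_exons = 10L) {
  k <- sample.int(max_exons, 1L)
  elens <- sample.int(500L, k, replace = TRUE)
  ilens <- if (k > 1L) sample.int(2000L, k - 1L, replace = TRUE) else integer()
  s <- integer(k); e <- integer(k)
  pos <- sample.int(1000L, 1L)
  for (j in seq_len(k)) {
    s[j] <- pos
    e[j] <- pos + elens[j] - 1L
    pos <- e[j] + (if (j < k) ilens[j] else 0L) + 1L
  }
  make_transcript(cbind(s, e))
}
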