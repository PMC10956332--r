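test_that("gene models assemble the gene -> mRNA -> exon hierarchy", {
  rec <- read_gff3(write_toy_gff3())
  m <- build_gene_models(rec)
  expect_length(m, 1L)
  g <- m[[1]]
  expect_equal(g$gene_id, "g1")
  expect_equal(c(g$start, g$end), c(100L, 400L))
  expect_length(g$transcripts, 1L)
  expect_equal(nrow(g$transcripts[[1]]$exons), 2L)
})

test_that("CDS rows stand in for a transcript with no exon children", {
  f <- write_toy_gff3(c("##gff-version 3",
    "chr1\tt\tgene\t100\t400\t.\t+\t.\tID=g1",
    "chr1\tt\tmRNA\t100\t400\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tt\tCDS\t120\t200\t.\t+\t0\tID=c1;Parent=t1",
    "chr1\tt\tCDS\t301\t380\t.\t+\t0\tID=c2;Parent=t1"))
  m <- build_gene_models(read_gff3(f))
  ex <- m[[1]]$transcripts[[1]]$exons
  expect_equal(unname(ex[, "start"]), c(120L, 301L))
  expect_equal(unname(ex[, "end"]), c(200L, 380L))
})

test_that("multiple transcripts and orphan features are handled per contract", {
  f <- write_toy_gff3(c("##gff-version 3",
    "chr1\tt\tgene\t1\t1000\t.\t+\t.\tID=g1",
    "chr1\tt\tmRNA\t1\t1000\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tt\tmRNA\t1\t900\t.\t+\t.\tID=t2;Parent=g1",
    "chr1\tt\texon\t1\t100\t.\t+\t.\tParent=t1",
    "chr1\tt\texon\t1\t100\t.\t+\t.\tParent=t2",
    "chr1\tt\texon\t500\t900\t.\t+\t.\tParent=t2",
    "chr1\tt\texon\t500\t600\t.\t+\t.\tParent=missing",
    "chr1\tt\tmRNA\t2000\t3000\t.\t-\t.\tID=t3",
    "chr1\tt\texon\t2000\t3000\t.\t-\t.\tParent=t3",
    "chr1\tt\tgene\t5000\t6000\t.\t+\t.\tID=g_empty"))
  m <- build_gene_models(read_gff3(f))
  ct <- attr(m, "counters")
  # g1 with 2 transcripts + one synthesized gene for orphan transcript t3
  expect_length(m, 2L)
  expect_length(m[[1]]$transcripts, 2L)
  expect_equal(ct$orphan_exons, 1L)
  expect_equal(ct$empty_genes, 1L)
  expect_equal(ct$orphan_transcripts, 1L)
  orphan <- m[[2]]
  expect_equal(orphan$gene_id, "gene-t3")
  expect_length(orphan$transcripts, 1L)
})

test_that("exon with several Parent values contributes to each transcript", {
  f <- write_toy_gff3(c("##gff-version 3",
    "chr1\tt\tgene\t1\t500\t.\t+\t.\tID=g1",
    "chr1\tt\tmRNA\t1\t500\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tt\tmRNA\t1\t500\t.\t+\t.\tID=t2;Parent=g1",
    "chr1\tt\texon\t1\t100\t.\t+\t.\tParent=t1,t2"))
  m <- build_gene_models(read_gff3(f))
  expect_equal(vapply(m[[1]]$transcripts, function(t) nrow(t$exons), 0L),
               c(1L, 1L))
})

test_that("size formulas follow the coordinate-difference procedure", {
  g <- list(start = 100L, end = 400L)
  expect_equal(gene_span_size(g, "difference"), 300L)
  expect_equal(gene_span_size(g, "biological"), 301L)
  degenerate <- list(start = 5L, end = 5L)
  expect_equal(gene_span_size(degenerate, "difference"), 0L)
  expect_equal(gene_span_size(degenerate, "biological"), 1L)

  tx <- make_transcript(rbind(c(100, 200), c(301, 400)))
  expect_equal(exon_sizes(tx, "difference"), c(100, 99))
  expect_equal(exon_sizes(tx, "biological"), c(101, 100))
  expect_equal(intron_sizes(tx, "difference"), 101)
  expect_equal(intron_sizes(tx, "biological"), 100)

  single <- make_transcript(rbind(c(1, 50)))
  expect_equal(exon_sizes(single, "difference"), 49)
  expect_equal(intron_sizes(single, "difference"), integer())
})

test_that("feature_size_table pools features and satisfies the span identity", {
  rec <- read_gff3(write_toy_gff3())
  m <- build_gene_models(rec)
  ft <- feature_size_table(m, "toy", "difference")
  expect_equal(ft$gene_sizes, 300L)
  expect_equal(sort(ft$exon_sizes), c(99L, 100L))
  expect_equal(ft$intron_sizes, 101L)
  # 100 + 99 + 101 = 300
  expect_equal(sum(ft$exon_sizes) + sum(ft$intron_sizes), ft$gene_sizes)
  expect_equal(ft$gene_count, 1L)
  expect_equal(ft$total_exon_bp, 199)
  expect_equal(ft$total_intron_bp, 101)
})

test_that("two transcripts sharing a gene pool duplicated features", {
  f <- write_toy_gff3(c("##gff-version 3",
    "chr1\tt\tgene\t1\t400\t.\t+\t.\tID=g1",
    "chr1\tt\tmRNA\t1\t400\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tt\tmRNA\t1\t400\t.\t+\t.\tID=t2;Parent=g1",
    "chr1\tt\texon\t1\t100\t.\t+\t.\tParent=t1,t2",
    "chr1\tt\texon\t201\t400\t.\t+\t.\tParent=t1,t2"))
  ft <- feature_size_table(build_gene_models(read_gff3(f)), "toy")
  expect_length(ft$exon_sizes, 4L)
  expect_length(ft$intron_sizes, 2L)
})

test_that("empty gene collections give an empty table, not an error", {
  ft <- feature_size_table(structure(list(), class = "gene_models"), "none")
  expect_equal(ft$gene_count, 0L)
  expect_equal(ft$total_exon_bp, 0)
  expect_equal(ft$total_intron_bp, 0)
  expect_length(ft$gene_sizes, 0L)
})

test_that("span identity and intron counts hold on random transcripts", {
  set.seed(42)
  for (i in 1:200) {
    tx <- random_transcript()
    k <- nrow(tx$exons)
    span_diff <- unname(tx$exons[k, "end"] - tx$exons[1, "start"])
    span_bio <- span_diff + 1L
    e_p <- exon_sizes(tx, "difference"); i_p <- intron_sizes(tx, "difference")
    e_b <- exon_sizes(tx, "biological"); i_b <- intron_sizes(tx, "biological")
    expect_equal(sum(e_p) + sum(i_p), span_diff)
    expect_equal(sum(e_b) + sum(i_b), span_bio)
    expect_length(i_p, k - 1L)
    # convention switch: +1 per exon, -1 per intron
    expect_equal(e_b, e_p + 1L)
    if (k > 1L) expect_equal(i_b, i_p - 1L)
  }
})

test_that("long-format export is lossless and labelled", {
  rec <- read_gff3(write_toy_gff3())
  fr <- feature_size_frame(build_gene_models(rec), "toy", "difference")
  expect_equal(sort(unique(fr$feature)), c("exon", "gene", "intron"))
  expect_equal(fr$size_bp[fr$feature == "gene"], 300L)
  expect_true(all(fr$convention == "difference"))
  ft <- feature_table_from_frame(fr)
  expect_equal(ft$intron_sizes, 101L)
  expect_equal(ft$gene_count, 1L)
})
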