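# Synthetic-data generators with known ground truth: GFF3 annotations,
# RepeatMasker .out tables, and C-value tables.  One integer seed per spec
# drives a per-generator stream derived by a fixed offset, so adding a
# generator never perturbs the output of another.

derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}

# ---- annotations -----------------------------------------------------------

#' Specification for a synthetic genome annotation
#'
#' Describes the generating distributions of a synthetic gene -> mRNA ->
#' exon annotation: per-gene exon counts are uniform integers on
#' `exon_count`, and exon, intron and intergenic-gap lengths are log-normal
#' (natural-log parameters), drawn as reals and ceiled to integers of at
#' least 1 bp.  The defaults are stylized to the architecture of compact
#' teleost genomes: exon sizes tightly distributed around ~130 bp, intron
#' sizes right-skewed with a heavy tail (median 500 bp, sdlog 1.2).
#'
#' @param n_genes Number of genes (>= 1).
#' @param exon_count Length-2 integer range (min, max) or a single fixed
#'   count.
#' @param exon_size_meanlog,exon_size_sdlog Log-normal parameters of exon
#'   length (bp).
#' @param intron_size_meanlog,intron_size_sdlog Log-normal parameters of
#'   intron length (bp).
#' @param gap_meanlog,gap_sdlog Log-normal parameters of intergenic gaps.
#' @param n_seqids Number of sequences genes are distributed over.
#' @param seed Integer seed; identical specs generate byte-identical
#'   files.
#' @return Object of class `annotation_spec`.
#' @export
annotation_spec <- function(n_genes = 1000L,
                            exon_count = c(2L, 12L),
                            exon_size_meanlog = log(130), exon_size_sdlog = 0.5,
                            intron_size_meanlog = log(500), intron_size_sdlog = 1.2,
                            gap_meanlog = log(2000), gap_sdlog = 1.0,
                            n_seqids = 5L, seed = 1L) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (length(exon_count) == 1L) exon_count <- rep(exon_count, 2L)
  if (exon_count[1] < 1L || exon_count[2] < exon_count[1])
    stop("invalid exon_count range")
  if (exon_size_sdlog < 0 || intron_size_sdlog < 0 || gap_sdlog < 0)
    stop("sdlog parameters must be non-negative")
  if (n_seqids < 1L) stop("n_seqids must be >= 1")
  structure(list(n_genes = as.integer(n_genes),
                 exon_count = as.integer(exon_count),
                 exon_size_meanlog = exon_size_meanlog,
                 exon_size_sdlog = exon_size_sdlog,
                 intron_size_meanlog = intron_size_meanlog,
                 intron_size_sdlog = intron_size_sdlog,
                 gap_meanlog = gap_meanlog, gap_sdlog = gap_sdlog,
                 n_seqids = as.integer(n_seqids),
                 seed = as.integer(seed)),
            class = "annotation_spec")
}

draw_len <- function(n, meanlog, sdlog) {
  pmax(1, ceiling(stats::rlnorm(n, meanlog, sdlog)))
}

#' Generate a synthetic GFF3 annotation with ground truth
#'
#' Writes a well-formed, coordinate-sorted GFF3 file (gene -> mRNA -> exon,
#' 1-based inclusive, genes non-overlapping within a seqid) and returns the
#' drawn sizes as ground truth.  Ground-truth sizes are biological lengths
#' (bp), so running the size pipeline with the `biological` convention on
#' the file recovers them exactly.
#'
#' @param spec An [annotation_spec()].
#' @param gff_path Output GFF3 path.
#' @param truth_path Optional path for the ground-truth TSV.
#' @return Invisibly, a list with `gff_path` and `truth` (data frame:
#'   `gene_id`, `transcript_id`, `feature`, `ordinal`, `size_bp`).
#' @export
gen_annotation <- function(spec, gff_path, truth_path = NULL) {
  stopifnot(inherits(spec, "annotation_spec"))
  set.seed(derive_seed(spec$seed, 1L))
  n <- spec$n_genes
  rng <- seq(spec$exon_count[1], spec$exon_count[2])
  k <- if (length(rng) == 1L) rep(rng, n) else sample(rng, n, replace = TRUE)
  seqid_of <- rep(seq_len(spec$n_seqids), length.out = n)
  seqid_of <- sort(seqid_of)
  strands <- sample(c("+", "-"), n, replace = TRUE)

  lines <- vector("list", n)
  truth <- vector("list", n)
  cursor <- stats::setNames(rep(0L, spec$n_seqids), seq_len(spec$n_seqids))
  for (i in seq_len(n)) {
    ki <- k[i]
    elens <- draw_len(ki, spec$exon_size_meanlog, spec$exon_size_sdlog)
    ilens <- if (ki > 1L) draw_len(ki - 1L, spec$intron_size_meanlog,
                                   spec$intron_size_sdlog) else integer()
    gap <- draw_len(1L, spec$gap_meanlog, spec$gap_sdlog)
    sq <- seqid_of[i]
    gstart <- cursor[sq] + gap + 1
    es <- numeric(ki); ee <- numeric(ki)
    pos <- gstart
    for (j in seq_len(ki)) {
      es[j] <- pos
      ee[j] <- pos + elens[j] - 1
      pos <- ee[j] + (if (j < ki) ilens[j] else 0) + 1
    }
    gend <- ee[ki]
    cursor[sq] <- gend
    gid <- sprintf("gene%05d", i)
    tid <- sprintf("tx%05d", i)
    chrom <- sprintf("chrS%d", sq)
    st <- strands[i]
    gstart <- as.integer(gstart); gend <- as.integer(gend)
    es <- as.integer(es); ee <- as.integer(ee)
    lines[[i]] <- c(
      sprintf("%s\tgenarch_synth\tgene\t%d\t%d\t.\t%s\t.\tID=%s", chrom,
              gstart, gend, st, gid),
      sprintf("%s\tgenarch_synth\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              chrom, gstart, gend, st, tid, gid),
      sprintf("%s\tgenarch_synth\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
              chrom, es, ee, st, tid, seq_len(ki), tid))
    truth[[i]] <- data.frame(
      gene_id = gid, transcript_id = tid,
      feature = c("gene", rep("exon", ki), rep("intron", max(ki - 1L, 0L))),
      ordinal = c(1L, seq_len(ki), seq_len(max(ki - 1L, 0L))),
      size_bp = c(gend - gstart + 1, elens, ilens),
      stringsAsFactors = FALSE)
  }
  atomic_write_lines(c("##gff-version 3", unlist(lines, use.names = FALSE)),
                     gff_path)
  truth_df <- do.call(rbind, truth)
  rownames(truth_df) <- NULL
  if (!is.null(truth_path)) write_tsv(truth_df, truth_path)
  invisible(list(gff_path = gff_path, truth = truth_df))
}

# ---- repeats ---------------------------------------------------------------

#' Specification for a synthetic RepeatMasker table
#'
#' Target masked percentage per repeat class on a genome of a given size;
#' hits are placed without overlap so union and raw tallies agree, and
#' divergence values are drawn uniform on (0, 25) so a 20%-divergence
#' filter has something to remove.
#'
#' @param genome_size_bp Genome size in bp.
#' @param target_pct Named vector over a subset of
#'   `{DNA, LINE, SINE, LTR, Other}`: target percent of the genome to mask
#'   per class; must sum to at most 80.
#' @param mean_hit_len Mean hit length in bp.
#' @param seed Integer seed.
#' @return Object of class `repeat_spec`.
#' @export
repeat_spec <- function(genome_size_bp = 1000000L,
                        target_pct = c(DNA = 6, LINE = 5, SINE = 2, LTR = 3,
                                       Other = 4),
                        mean_hit_len = 400L, seed = 1L) {
  if (genome_size_bp <= 0) stop("genome_size_bp must be positive")
  if (is.null(names(target_pct)) || !all(names(target_pct) %in% REPEAT_CLASSES))
    stop("target_pct must be named over DNA/LINE/SINE/LTR/Other")
  if (any(target_pct < 0) || sum(target_pct) > 80)
    stop("target percentages must be non-negative and sum to <= 80")
  if (mean_hit_len < 10L) stop("mean_hit_len must be >= 10")
  structure(list(genome_size_bp = as.integer(genome_size_bp),
                 target_pct = target_pct,
                 mean_hit_len = as.integer(mean_hit_len),
                 seed = as.integer(seed)),
            class = "repeat_spec")
}

synth_family <- c(DNA = "DNA/hAT", LINE = "LINE/L1", SINE = "SINE/tRNA",
                  LTR = "LTR/Gypsy", Other = "Simple_repeat")

#' Generate a synthetic RepeatMasker .out file with ground truth
#'
#' Places non-overlapping hits per class until each class's masked bp is
#' within one mean hit length of its target.  Ground truth records the
#' per-class masked bp before and after a 20%-divergence filter.
#'
#' @param spec A [repeat_spec()].
#' @param out_path Output `.out` path.
#' @param truth_path Optional path for the ground-truth TSV.
#' @return Invisibly, a list with `out_path` and `truth` (data frame:
#'   `class`, `masked_bp`, `masked_bp_div20`, `n_hits`).
#' @export
gen_repeatmasker <- function(spec, out_path, truth_path = NULL) {
  stopifnot(inherits(spec, "repeat_spec"))
  set.seed(derive_seed(spec$seed, 2L))
  classes <- character(); lens <- integer()
  for (cl in names(spec$target_pct)) {
    target <- spec$genome_size_bp * spec$target_pct[[cl]] / 100
    got <- 0
    while (target - got > spec$mean_hit_len) {
      len <- max(10L, as.integer(round(stats::rlnorm(1, log(spec$mean_hit_len), 0.4))))
      len <- min(len, as.integer(round(target - got + spec$mean_hit_len)))
      classes <- c(classes, cl); lens <- c(lens, len)
      got <- got + len
    }
  }
  n <- length(classes)
  header <- c(
    "   SW   perc perc perc  query     position in query    matching  repeat         position in repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat    class/family   begin end  (left) ID",
    "")
  if (n == 0L) {
    atomic_write_lines(header, out_path)
    truth_df <- data.frame(class = REPEAT_CLASSES, masked_bp = 0,
                           masked_bp_div20 = 0, n_hits = 0L,
                           stringsAsFactors = FALSE)
    if (!is.null(truth_path)) write_tsv(truth_df, truth_path)
    return(invisible(list(out_path = out_path, truth = truth_df)))
  }
  free <- spec$genome_size_bp - sum(lens)
  if (free < n + 1L)
    stop("repeat targets unreachable on a genome of ", spec$genome_size_bp, " bp")
  ord <- sample.int(n)
  classes <- classes[ord]; lens <- lens[ord]
  gaps <- as.vector(stats::rmultinom(1, free, rep(1, n + 1L)))
  starts <- integer(n); pos <- 0L
  for (i in seq_len(n)) {
    starts[i] <- pos + gaps[i] + 1L
    pos <- starts[i] + lens[i] - 1L
  }
  ends <- starts + lens - 1L
  div <- round(stats::runif(n, 0, 25), 1)
  score <- sample(300:5000, n, replace = TRUE)
  fam <- synth_family[classes]
  rows <- sprintf("%5d %5.1f  0.0  0.0  %s %9d %9d (%d) %s  %-14s %-14s %5d %5d (0) %d",
                  score, div, "synth_genome", starts, ends,
                  spec$genome_size_bp - ends, sample(c("+", "C"), n, TRUE),
                  sub("/.*$", "-syn", paste0(fam)), fam,
                  1L, lens, seq_len(n))
  atomic_write_lines(c(header, rows), out_path)
  masked <- vapply(REPEAT_CLASSES, function(cl) sum(as.numeric(lens[classes == cl])), 0)
  masked20 <- vapply(REPEAT_CLASSES,
                     function(cl) sum(as.numeric(lens[classes == cl & div <= 20])), 0)
  truth_df <- data.frame(class = REPEAT_CLASSES, masked_bp = masked,
                         masked_bp_div20 = masked20,
                         n_hits = vapply(REPEAT_CLASSES,
                                         function(cl) sum(classes == cl), 0L),
                         stringsAsFactors = FALSE)
  rownames(truth_df) <- NULL
  if (!is.null(truth_path)) write_tsv(truth_df, truth_path)
  invisible(list(out_path = out_path, truth = truth_df))
}

# ---- C-values --------------------------------------------------------------

#' Specification for a synthetic C-value table
#'
#' Per order: number of species and the mean and standard deviation (pg)
#' of the species C-value distribution, drawn log-normal (moment-matched)
#' or normal (truncated at zero).  Each species may get several table rows
#' jittered around its value (jitter sd = sd_pg / 10, so `sd_pg = 0` gives
#' exact duplicates).
#'
#' @param orders Data frame with columns `order`, `n_species` (>= 2),
#'   `mean_pg` (> 0), `sd_pg` (>= 0) and optionally `distribution`
#'   (`"lognormal"`, the default, or `"normal"`).
#' @param duplicates_per_species Rows per species (>= 1).
#' @param seed Integer seed.
#' @return Object of class `cvalue_spec`.
#' @export
cvalue_spec <- function(orders, duplicates_per_species = 1L, seed = 1L) {
  stopifnot(is.data.frame(orders),
            all(c("order", "n_species", "mean_pg", "sd_pg") %in% names(orders)))
  if (!("distribution" %in% names(orders))) orders$distribution <- "lognormal"
  if (any(orders$n_species < 2L)) stop("each order needs n_species >= 2")
  if (any(orders$mean_pg <= 0)) stop("mean_pg must be positive")
  if (any(orders$sd_pg < 0)) stop("sd_pg must be non-negative")
  if (!all(orders$distribution %in% c("lognormal", "normal")))
    stop("distribution must be 'lognormal' or 'normal'")
  if (duplicates_per_species < 1L) stop("duplicates_per_species must be >= 1")
  structure(list(orders = orders,
                 duplicates_per_species = as.integer(duplicates_per_species),
                 seed = as.integer(seed)),
            class = "cvalue_spec")
}

#' Generate a synthetic C-value table with ground truth
#'
#' @param spec A [cvalue_spec()].
#' @param table_path Output TSV path (species, order, family, c_value_pg).
#' @param truth_path Optional path for the ground-truth TSV.
#' @return Invisibly, a list with `table_path`, `truth` (per-order spec
#'   mean and realized mean of species values) and `species` (the drawn
#'   per-species values).
#' @export
gen_cvalues <- function(spec, table_path, truth_path = NULL) {
  stopifnot(inherits(spec, "cvalue_spec"))
  set.seed(derive_seed(spec$seed, 3L))
  rows <- list(); sp_rows <- list(); truth <- list()
  for (r in seq_len(nrow(spec$orders))) {
    o <- spec$orders[r, ]
    vals <- if (o$sd_pg == 0) {
      rep(o$mean_pg, o$n_species)
    } else if (o$distribution == "lognormal") {
      s2 <- log(1 + (o$sd_pg / o$mean_pg)^2)
      stats::rlnorm(o$n_species, log(o$mean_pg) - s2 / 2, sqrt(s2))
    } else {
      v <- stats::rnorm(o$n_species, o$mean_pg, o$sd_pg)
      while (any(v <= 0)) v[v <= 0] <- stats::rnorm(sum(v <= 0), o$mean_pg, o$sd_pg)
      v
    }
    species <- sprintf("%s_sp%02d", o$order, seq_len(o$n_species))
    sp_rows[[r]] <- data.frame(species = species, order = o$order,
                               c_value_pg = vals, stringsAsFactors = FALSE)
    jit_sd <- o$sd_pg / 10
    dup <- spec$duplicates_per_species
    jit <- if (jit_sd > 0) stats::rnorm(o$n_species * dup, 0, jit_sd) else 0
    v_dup <- pmax(rep(vals, each = dup) + jit, 1e-6)
    rows[[r]] <- data.frame(species = rep(species, each = dup),
                            order = o$order,
                            family = paste0(o$order, "_fam"),
                            c_value_pg = round(v_dup, 4),
                            stringsAsFactors = FALSE)
    truth[[r]] <- data.frame(order = o$order, spec_mean_pg = o$mean_pg,
                             realized_mean_pg = mean(vals),
                             n_species = o$n_species, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  write_tsv(tab, table_path)
  truth_df <- do.call(rbind, truth)
  rownames(truth_df) <- NULL
  if (!is.null(truth_path)) write_tsv(truth_df, truth_path)
  invisible(list(table_path = table_path, truth = truth_df,
                 species = do.call(rbind, sp_rows)))
}
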