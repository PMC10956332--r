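# Brute-force pair-count U and enumeration p-value for tie-free samples.
oracle_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}
oracle_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  u_obs <- oracle_u(x, y)
  splits <- utils::combn(n1 + n2, n1)
  ranks <- rank(c(x, y))
  us <- apply(splits, 2, function(ix) sum(ranks[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

test_that("pg <-> Mbp conversion uses the 978 factor and round-trips", {
  expect_equal(pg_to_mbp(1.0), 978)
  expect_equal(pg_to_mbp(0), 0)
  expect_equal(pg_to_mbp(0.56), 547.68)
  v <- 10^seq(-3, 3, length.out = 50)
  expect_true(all(abs(mbp_to_pg(pg_to_mbp(v)) - v) < 1e-12))
  expect_error(pg_to_mbp(-1), "non-negative")
})

test_that("duplicate C-value entries average per species", {
  rec <- data.frame(species = c("x", "x", "y", "z", "z"),
                    order = c("A", "A", "A", "B", "B"),
                    family = NA_character_,
                    c_value_pg = c(0.5, 0.7, 1, 2, 2.2))
  m <- species_mean_cvalues(rec)
  expect_equal(nrow(m), 3L)
  expect_equal(m$c_value_pg[m$species == "x"], 0.6)
  expect_equal(m$c_value_pg[m$species == "y"], 1)

  bad <- transform(rec, order = c("A", "B", "A", "B", "B"))
  expect_error(species_mean_cvalues(bad), "conflicting order.*x")
})

test_that("Mann-Whitney exact mode matches enumeration on the worked example", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 1 / 3)

  # identical multisets: U = n1 n2 / 2 (all mass in ties)
  r2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$u_statistic, 4.5)
})

test_that("U equals the pair-count oracle and U + U' = n1 n2", {
  set.seed(14)
  for (i in 1:50) {
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    x <- sample(100, n1); y <- sample(100, n2)  # may tie across samples
    r <- mann_whitney(x, y)
    rp <- mann_whitney(y, x)
    expect_equal(r$u_statistic, oracle_u(x, y))
    expect_equal(r$u_statistic + rp$u_statistic, n1 * n2)
  }
})

test_that("normal-approximation path engages for large or tied samples", {
  set.seed(2)
  x <- stats::rnorm(25); y <- stats::rnorm(25)
  r <- mann_whitney(x, y)  # 625 > 400
  expect_equal(r$method, "normal_approx")
  r2 <- mann_whitney(c(1, 1, 2), c(2, 3, 4))  # ties
  expect_equal(r2$method, "normal_approx")
  expect_true(r2$p_value > 0 && r2$p_value <= 1)
})

test_that("the Shapiro-Wilk gate routes heavy-tailed samples to the rank test", {
  set.seed(31)
  expect_true(normality_gate(stats::rlnorm(500, 0, 1)))
  flags <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    normality_gate(stats::rnorm(500))
  }, logical(1))
  expect_gte(sum(!flags), 18L)
  expect_warning(gate <- normality_gate(rep(3, 10)), "cannot test")
  expect_true(gate)
  # beyond the n = 5000 test limit, the gate still answers
  expect_true(normality_gate(stats::rlnorm(6000, 0, 1.5)))
})

test_that("focal-order comparison flags separated orders and not permutations", {
  set.seed(4)
  a <- stats::runif(20, 0.5, 1.0)
  rec <- data.frame(species = sprintf("sp%02d", 1:40),
                    order = rep(c("A", "B"), each = 20),
                    c_value_pg = c(a, a + 10))
  cmp <- compare_focal_order(rec, "A")
  expect_equal(nrow(cmp), 1L)
  expect_equal(cmp$significance, "****")
  expect_equal(cmp$other_order, "B")
  expect_equal(cmp$focal_mean_pg, mean(a))

  rec2 <- data.frame(species = sprintf("sp%02d", 1:40),
                     order = rep(c("A", "B"), each = 20),
                     c_value_pg = c(a, sample(a)))
  cmp2 <- compare_focal_order(rec2, "A")
  expect_equal(cmp2$significance, "ns")

  expect_error(compare_focal_order(rec, "Z"), "not present")

  welch <- compare_focal_order(rec, "A", test = "welch")
  expect_equal(welch$method, "welch_t")
  expect_equal(welch$significance, "****")
})

test_that("percentile report computes cutoffs, shares and focal percentiles", {
  rec <- data.frame(species = sprintf("sp%03d", 1:100),
                    order = rep(c("A", "B"), each = 50),
                    c_value_pg = 1:100)
  rep <- order_percentile_report(rec, qs = c(0.05, 0.10, 0.90),
                                 focal_order = "A")
  expect_equal(unname(rep$cutoffs[["0.05"]]), 5.95)
  # 5 species (values 1..5) fall at or below 5.95, all in order A
  expect_equal(rep$shares$pct_at_or_below_q5[rep$shares$order == "A"], 10)
  expect_equal(rep$shares$pct_at_or_below_q5[rep$shares$order == "B"], 0)
  expect_equal(rep$focal$n_species, 50L)

  one <- data.frame(species = sprintf("s%d", 1:12), order = "A",
                    c_value_pg = 1:12)
  r1 <- order_percentile_report(one, qs = 0.05)
  expect_equal(r1$shares$pct_at_or_below_q5, 100 * mean(1:12 <= r1$cutoffs[[1]]))
  expect_error(order_percentile_report(one[1:5, ]), "at least 10")
})

test_that("Spearman correlation handles monotone, reversed and tied inputs", {
  expect_equal(spearman_cor(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_cor(1:3, c(3, 2, 1))$rho, -1)
  r <- spearman_cor(c(1, 2, 2, 3), c(1, 2, 3, 4))
  expect_equal(r$rho, stats::cor(rank(c(1, 2, 2, 3)), rank(c(1, 2, 3, 4))))
  expect_error(spearman_cor(1:3, 1:4), "equal length")
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  # invariance under strictly monotone transforms
  set.seed(6)
  x <- stats::rlnorm(30); y <- stats::rnorm(30)
  expect_equal(spearman_cor(log(x), exp(y))$rho, spearman_cor(x, y)$rho)
})

test_that("genome correlates report the three size relationships", {
  df <- data.frame(species_label = letters[1:10],
                   genome_size_bp = (1:10) * 1e8,
                   te_pct = (1:10) * 3,
                   total_intron_bp = (1:10) * 1e7,
                   total_exon_bp = (1:10) * 2e6)
  gc <- genome_correlates(df)
  expect_equal(nrow(gc), 3L)
  expect_equal(gc$rho, c(1, 1, 1))
  expect_error(genome_correlates(df[1:2, ]), "at least 3")

  # shuffled TE content decorrelates from size (n = 27 null)
  rhos <- vapply(1:5, function(s) {
    set.seed(700 + s)
    d <- data.frame(genome_size_bp = (1:27) * 1e8,
                    te_pct = sample((1:27) * 2),
                    total_intron_bp = (1:27) * 1e7,
                    total_exon_bp = (1:27) * 2e6)
    genome_correlates(d)$rho[1]
  }, 0)
  expect_true(all(abs(rhos) < 0.5))
})

test_that("BUSCO percentage arithmetic reports one decimal", {
  expect_equal(busco_percent(busco_counts(identified = 3459, total = 3652)), 94.7)
  expect_equal(busco_percent(busco_counts(identified = 0, total = 100)), 0)
  expect_equal(busco_percent(busco_counts(identified = 50, total = 50)), 100)
})
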