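test_that("normality gate picks the test the Shapiro-Wilk check dictates", {
  set.seed(101)
  x <- rnorm(10); y <- rnorm(10)
  # verify the oracle before asserting on the gate
  stopifnot(shapiro.test(x)$p.value > 0.05, shapiro.test(y)$p.value > 0.05)
  expect_identical(normality_gate(x, y), "t_test")
  y_out <- c(rnorm(9), 50) # extreme outlier breaks normality
  stopifnot(shapiro.test(y_out)$p.value < 0.05)
  expect_identical(normality_gate(x, y_out), "mann_whitney")
  # small-n rule: no check possible below 3 per group
  expect_identical(normality_gate(c(1, 2), c(3, 4)), "mann_whitney")
  expect_warning(g <- normality_gate(rep(1, 5), rnorm(5)), "constant")
  expect_identical(g, "mann_whitney")
})

test_that("gated test handles ties, exactness, and identical groups", {
  expect_equal(gated_test(rep(2, 4), rep(2, 4))$p, 1)
  # exact Mann-Whitney for small untied samples matches wilcox.test exact
  x <- c(1.1, 2.3, 3.7); y <- c(4.2, 5.8, 6.1)
  res <- gated_test(c(x, 100), y) # outlier forces mann_whitney
  expect_identical(res$test, "mann_whitney")
  expect_equal(res$p, wilcox.test(c(x, 100), y, exact = TRUE)$p.value)
})

test_that("identical groups give zero difference and p = 1", {
  vals <- c(10, 12, 14, 11, 13)
  d <- data.frame(sample = paste0("s", 1:10),
                  genotype = rep(c("WT", "KO"), each = 5),
                  region = "r", site = "A", pct = rep(vals, 2))
  out <- compare_sites(d)
  expect_equal(out$difference, 0)
  expect_equal(out$p, 1)
  expect_false(out$significant)
})

test_that("a +3pp shift with n=10/10 and sd 1 is detected", {
  wt <- c(A = 0.6, B = 0.5, C = 0.05, D = 0.35, E = 0.3)
  ko <- replace(wt, "C", 0.08)
  d <- simulate_cohort_frequencies(10, 10, wt, ko, n_reads = 50000,
                                   between_sd_pp = 1, seed = 55)
  out <- compare_sites(d)
  crow <- out[out$site == "C", ]
  expect_lt(crow$p, 0.05)
  expect_equal(crow$difference, 3, tolerance = 0.6)
})

test_that("swapping genotype labels negates differences and inverts ratios", {
  wt <- c(A = 0.6, B = 0.5, C = 0.05, D = 0.35, E = 0.3)
  d <- simulate_cohort_frequencies(6, 6, wt, replace(wt, "A", 0.65),
                                   seed = 77)
  fwd <- compare_sites(d)
  rev <- compare_sites(d, ref_group = "KO", alt_group = "WT")
  expect_equal(fwd$difference, -rev$difference)
  expect_equal(fwd$p, rev$p)
  di <- data.frame(sample = rep(paste0("s", 1:8), each = 1),
                   genotype = rep(c("WT", "KO"), each = 4),
                   region = "r", pattern = "AB",
                   pct = c(10, 11, 9, 10, 21, 19, 20, 22))
  f <- compare_isoforms(di)
  r <- compare_isoforms(di, ref_group = "KO", alt_group = "WT")
  expect_equal(f$ko_wt_ratio, 1 / r$ko_wt_ratio, tolerance = 1e-12)
})

test_that("p-values are invariant under sample reordering within groups", {
  d <- simulate_cohort_frequencies(8, 8, seed = 91)
  shuffled <- d[sample(nrow(d)), ]
  expect_equal(compare_sites(d)$p, compare_sites(shuffled)$p)
})

test_that("missing frequencies exclude the sample with a warning", {
  d <- simulate_cohort_frequencies(5, 5, seed = 31)
  d$pct[d$sample == "WT_01" & d$site == "E"] <- NA
  expect_warning(out <- compare_sites(d), "missing frequency")
  expect_equal(nrow(out), 5)
})

test_that("isoform comparison flags a doubled rare isoform with ratio ~2", {
  # WT 2% -> KO 4% of a rare pattern, tight within-mouse sampling
  set.seed(123)
  n_complete <- 20000
  mk <- function(genotype, p) {
    vapply(1:12, function(i) 100 * rbinom(1, n_complete, p) / n_complete,
           numeric(1))
  }
  di <- data.frame(
    sample = c(sprintf("WT_%02d", 1:12), sprintf("KO_%02d", 1:12)),
    genotype = rep(c("WT", "KO"), each = 12),
    region = "hypothalamus", pattern = "ABD",
    pct = c(mk("WT", 0.02), mk("KO", 0.04)))
  out <- compare_isoforms(di)
  expect_lt(out$p, 0.05)
  expect_true(out$significant)
  expect_equal(out$ko_wt_ratio, 2, tolerance = 0.25)
  expect_true(out$low_abundance) # < 5% of total in WT
})

test_that("identical isoform tables yield unit ratios and no significance", {
  di <- expand.grid(sample = sprintf("m%02d", 1:8), pattern = c("A", "AB"),
                    stringsAsFactors = FALSE)
  di$genotype <- rep(rep(c("WT", "KO"), each = 4), 2)
  di$region <- "r"
  di$pct <- rep(c(30, 31, 29, 30), 4)
  out <- compare_isoforms(di)
  expect_true(all(out$ko_wt_ratio == 1))
  expect_true(all(!out$significant))
  # patterns absent everywhere are omitted
  di2 <- rbind(di, transform(di[di$pattern == "A", ], pattern = "CE", pct = 0))
  expect_message(out2 <- compare_isoforms(di2), "omitted")
  expect_false("CE" %in% out2$pattern)
})

test_that("permutation-null isoform tests are calibrated at alpha", {
  set.seed(202)
  n_sig <- 0; n_rows <- 0
  for (rep in 1:40) {
    di <- data.frame(sample = sprintf("m%02d", 1:16),
                     genotype = sample(rep(c("WT", "KO"), each = 8)),
                     region = "r", pattern = "A",
                     pct = rnorm(16, 20, 2))
    out <- compare_isoforms(di)
    n_sig <- n_sig + sum(out$significant)
    n_rows <- n_rows + nrow(out)
  }
  # expected ~ alpha * n_rows = 2; allow generous binomial slack
  expect_lte(n_sig, qbinom(0.999, n_rows, 0.05) + 1)
})

test_that("Benjamini-Hochberg adjustment matches the hand-derived values", {
  rows <- data.frame(region = "r", p = c(0.01, 0.02, 0.03, 0.04),
                     significant = c(TRUE, TRUE, TRUE, TRUE))
  none <- multiple_testing(rows, "none")
  expect_equal(none$p_adj, rows$p)
  bh <- multiple_testing(rows, "bh")
  # hand evaluation: p_(i) * n/i, cummin from the largest = 0.04 for all
  expect_equal(bh$p_adj, rep(0.04, 4))
  single <- multiple_testing(data.frame(region = "r", p = 0.03), "bh")
  expect_equal(single$p_adj, 0.03)
  # per-region adjustment is independent across regions
  two <- data.frame(region = c("r1", "r1", "r2"), p = c(0.01, 0.04, 0.02))
  adj <- multiple_testing(two, "bh")
  expect_equal(adj$p_adj, c(0.02, 0.04, 0.02))
})
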