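test_that("isoform distribution handles degenerate and symmetric cases", {
  f0 <- isoform_distribution(clean_config(probs = rep(0, 5)))
  expect_equal(unname(f0[["none"]]), 1)
  expect_equal(sum(f0), 1)
  f1 <- isoform_distribution(clean_config(probs = rep(1, 5)))
  expect_equal(unname(f1[["ABCDE"]]), 1)
  fh <- isoform_distribution(clean_config(probs = rep(0.5, 5)))
  expect_equal(unname(fh), rep(1 / 32, 32))
})

test_that("isoform distribution sums to 1 and marginalizes to per-site probs", {
  set.seed(11)
  pats <- enumerate_patterns()
  for (i in 1:20) {
    p <- runif(5)
    f <- isoform_distribution(clean_config(probs = p))
    expect_lt(abs(sum(f) - 1), 1e-9)
    marginal <- as.numeric(f %*% pats)
    expect_equal(marginal, unname(p), tolerance = 1e-12)
  }
})

test_that("explicit haplotype mode returns the supplied frequencies verbatim", {
  set.seed(2)
  h <- runif(32)
  h <- h / sum(h)
  cfg <- simulation_config(linkage_mode = "explicit_haplotypes",
                           haplotype_freqs = h, n_reads = 10)
  expect_equal(unname(isoform_distribution(cfg)), h)
  expect_error(simulation_config(linkage_mode = "explicit_haplotypes"),
               "requires haplotype_freqs")
  expect_error(simulation_config(linkage_mode = "explicit_haplotypes",
                                 haplotype_freqs = rep(1 / 32, 31)),
               "summing to 1")
})

test_that("simulation config validates its fields", {
  expect_error(simulation_config(per_site_probs = c(0.1, 0.2)), "length 5")
  expect_error(simulation_config(per_site_probs = c(0.1, 0.2, 0.3, 0.4, 1.5)),
               "probabilities")
  expect_error(simulation_config(n_reads = 0), "n_reads")
  expect_error(simulation_config(base_error_rate = 2), "base_error_rate")
})

test_that("error-free reads reproduce the reference or the edited sites exactly", {
  ref <- test_ref()
  sim0 <- generate_reads(ref, clean_config(probs = rep(0, 5), n_reads = 50))
  expect_true(all(sim0$seq == ref$sequence))
  sim1 <- generate_reads(ref, clean_config(probs = rep(1, 5), n_reads = 50))
  site_pos <- sort(ref$site_offsets) + 1
  expected <- ref$sequence
  for (p in site_pos) substr(expected, p, p) <- "G"
  expect_true(all(sim1$seq == expected))
  # G at exactly the 5 site offsets, nowhere else
  diffs <- which(strsplit(sim1$seq[1], "")[[1]] !=
                   strsplit(ref$sequence, "")[[1]])
  expect_equal(diffs, unname(site_pos))
})

test_that("fixed seed makes FASTQ output byte-identical across runs", {
  ref <- test_ref()
  cfg <- simulation_config(n_reads = 200, seed = 99)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(generate_reads(ref, cfg), f1)
  write_fastq(generate_reads(ref, cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_fastq(f1)
  expect_equal(length(back$seq), 200)
  expect_identical(back$seq[1], generate_reads(ref, cfg)$seq[1])
})

test_that("truth record is internally consistent", {
  ref <- test_ref()
  p <- c(A = 0.6, B = 0.8, C = 0.05, D = 0.5, E = 0.1)
  sim <- generate_reads(ref, clean_config(probs = p, n_reads = 500, seed = 3))
  expect_equal(unname(sim$truth$per_site_freqs), unname(p), tolerance = 1e-12)
  expect_equal(sum(sim$truth$pattern_tally), 500)
  expect_equal(as.integer(table(factor(sim$truth$pattern_index, levels = 1:32))),
               unname(sim$truth$pattern_tally))
})

test_that("end-count generator suppresses cleavage positions as configured", {
  pr <- generate_endcounts(300, methylated_sites = c(80, 150),
                           coverage = 2000, protection = c(1, 0.5), seed = 5)
  expect_equal(pr$counts[scored_position(80)], 0)
  expect_equal(nrow(pr$sites), 2)
  expect_true(all(pr$counts >= 0))
  expect_error(generate_endcounts(100, methylated_sites = 100),
               "in range")
})

test_that("flat profiles score near zero; protected sites score high", {
  # no methylation: residual scores reflect Poisson noise only
  flat <- generate_endcounts(400, coverage = 1000, seed = 8)
  sc <- vapply(50:350, function(p) meth_score(flat, p), numeric(1))
  expect_lt(max(sc), 0.25)
  expect_lt(mean(sc), 0.05)
  # protection 0.9 at 3 sites, coverage 1000: scores near 0.9
  pr <- generate_endcounts(400, methylated_sites = c(100, 200, 300),
                           coverage = 1000, protection = 0.9, seed = 9)
  sc3 <- meth_scores(pr)
  expect_true(all(sc3 >= 0.8))
})

test_that("summary-level cohort frequencies track the configured truth", {
  d <- simulate_cohort_frequencies(n_wt = 8, n_ko = 8, n_reads = 50000,
                                   between_sd_pp = 1, seed = 21)
  expect_equal(nrow(d), 2 * 8 * 5)
  m <- aggregate(pct ~ site, data = d[d$genotype == "WT", ], FUN = mean)
  truth <- 100 * c(A = 0.6, B = 0.5, C = 0.05, D = 0.35, E = 0.3)
  # group means within ~3 x (between-mouse sd / sqrt(8)) of truth
  expect_true(all(abs(m$pct - truth[m$site]) < 3 * 1 / sqrt(8) + 0.1))
})
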