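test_that("quality-gated calling follows the A/G-at-Q20 rule", {
  ref <- test_ref()
  # all reference bases at Q30: unedited at all five sites, complete
  calls <- call_sites(one_read(ref), ref)
  expect_true(all(calls$calls == "unedited"))
  expect_true(calls$complete)
  # G at site C but Q19: masked, read incomplete
  r <- set_site_qual(one_read(ref, edits = "C"), ref, "C", 19)
  calls <- call_sites(r, ref)
  expect_identical(unname(calls$calls[1, "C"]), "masked")
  expect_false(calls$complete)
  # same base at Q20 passes the gate
  r20 <- set_site_qual(one_read(ref, edits = "C"), ref, "C", 20)
  expect_identical(unname(call_sites(r20, ref)$calls[1, "C"]), "edited")
  # non-A/G base (sequencing error to T) is masked, not counted unedited
  rt <- one_read(ref, edits = "A", base = "T")
  expect_identical(unname(call_sites(rt, ref)$calls[1, "A"]), "masked")
  # site not covered by the read is masked
  short <- one_read(ref)
  short$seq <- substr(short$seq, 1, ref$site_offsets[["D"]]) # ends before D
  short$qual <- substr(short$qual, 1, ref$site_offsets[["D"]])
  cs <- call_sites(short, ref)
  expect_identical(unname(cs$calls[1, "D"]), "masked")
  expect_identical(unname(cs$calls[1, "A"]), "unedited")
})

test_that("site frequencies count covered and edited reads correctly", {
  ref <- test_ref()
  reads <- do.call(rbind, c(
    lapply(1:4, function(i) one_read(ref, edits = "A", id = paste0("e", i))),
    lapply(1:6, function(i) one_read(ref, id = paste0("u", i)))))
  sf <- site_frequencies(call_sites(reads, ref))
  expect_equal(sf$pct[sf$site == "A"], 40)
  expect_equal(sf$n_covered[sf$site == "A"], 10L)
  expect_equal(sf$pct[sf$site == "B"], 0)
  # all reads masked at E -> reported missing, not 0%
  masked <- do.call(rbind, lapply(1:3, function(i)
    set_site_qual(one_read(ref, id = paste0("m", i)), ref, "E", 5)))
  sfm <- site_frequencies(call_sites(masked, ref))
  expect_true(is.na(sfm$pct[sfm$site == "E"]))
  expect_equal(sfm$n_covered[sfm$site == "E"], 0L)
  # empty collection errors
  empty <- one_read(ref)[0, ]
  expect_error(site_frequencies(call_sites(empty, ref)), "empty")
})

test_that("isoform tabulation uses complete reads and conserves totals", {
  ref <- test_ref()
  reads <- rbind(one_read(ref, id = "r1"), one_read(ref, id = "r2"),
                 one_read(ref, edits = c("A", "B", "C", "D", "E"), id = "r3"),
                 set_site_qual(one_read(ref, id = "r4"), ref, "B", 10))
  calls <- call_sites(reads, ref)
  counts <- isoform_counts(calls)
  expect_equal(unname(counts[["none"]]), 2L)
  expect_equal(unname(counts[["ABCDE"]]), 1L)
  expect_equal(sum(counts), 3L)
  expect_equal(attr(counts, "n_incomplete"), 1L)
  # conservation: complete + incomplete = accepted
  expect_equal(sum(counts) + attr(counts, "n_incomplete"), nrow(reads))
})

test_that("complete-reads site frequencies equal the isoform marginal exactly", {
  ref <- test_ref()
  sim <- generate_reads(ref, simulation_config(n_reads = 2000, seed = 23))
  aln <- align_reads(sim, ref = ref)$aligned
  prof <- profile_sample(aln, ref, list(sample = "s"))
  pats <- enumerate_patterns()
  counts <- prof$isoforms$count
  marg_edited <- as.numeric(counts %*% pats)
  sc <- prof$sites_complete
  expect_equal(sc$n_edited, as.integer(marg_edited))
  expect_equal(sc$n_covered, rep(sum(counts), 5))
  # complete reads are a subset of covered reads at every site
  expect_true(all(marg_edited <= prof$sites$n_edited))
})

test_that("raising min_q never increases coverage at any site", {
  ref <- test_ref()
  sim <- generate_reads(ref, simulation_config(n_reads = 1000, seed = 29))
  aln <- align_reads(sim, ref = ref)$aligned
  cov <- sapply(c(10, 20, 30, 35), function(q)
    site_frequencies(call_sites(aln, ref, min_q = q))$n_covered)
  expect_true(all(apply(cov, 1, diff) <= 0))
})

test_that("error-free pipeline recovers the generator's pattern tally exactly", {
  ref <- test_ref()
  sim <- generate_reads(ref, clean_config(n_reads = 3000, seed = 41))
  aln <- align_reads(sim, ref = ref)$aligned
  counts <- isoform_counts(call_sites(aln, ref))
  expect_identical(as.integer(counts), unname(sim$truth$pattern_tally))
  expect_equal(attr(counts, "n_incomplete"), 0L)
})

test_that("sample profiling composes, writes TSV, and reports totals", {
  ref <- test_ref()
  prof1 <- profile_sample(one_read(ref), ref, list(sample = "single"))
  expect_true(all(prof1$sites$pct == 0))
  expect_equal(prof1$isoforms$count[prof1$isoforms$pattern == "none"], 1L)
  expect_error(profile_sample(one_read(ref)[0, ], ref,
                              list(sample = "empty")), "empty")

  sim <- generate_reads(ref, simulation_config(n_reads = 500, seed = 13))
  aln <- align_reads(sim, ref = ref)$aligned
  prof <- profile_sample(aln, ref, list(sample = "s13", genotype = "WT",
                                        region = "hypothalamus"))
  expect_equal(prof$n_reads, 500)
  expect_equal(sum(prof$isoforms$count), prof$n_complete)
  expect_equal(prof$n_complete + prof$n_incomplete, prof$n_reads)
  expect_equal(sum(prof$isoforms$pct), 100, tolerance = 1e-9)
  d <- withr::local_tempdir()
  paths <- write_profile(prof, d)
  sites_back <- read.delim(paths[1])
  iso_back <- read.delim(paths[2])
  expect_equal(nrow(sites_back), 5)
  expect_equal(nrow(iso_back), 32)
  expect_equal(sites_back$pct, round(prof$sites$pct, 2))
  expect_identical(iso_back$tripeptide[32], "VGV")
})

test_that("simulated profiles estimate site and isoform truth within sampling error", {
  ref <- test_ref()
  p <- c(A = 0.6, B = 0.5, C = 0.05, D = 0.35, E = 0.3)
  n <- 20000
  sim <- generate_reads(ref, simulation_config(per_site_probs = p,
                                               n_reads = n,
                                               base_error_rate = 0.001,
                                               seed = 71))
  aln <- align_reads(sim, ref = ref)$aligned
  prof <- profile_sample(aln, ref, list(sample = "wt_like"))
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(prof$sites$pct / 100 - p[prof$sites$site]) <
                    3 * se[prof$sites$site] + 0.001))
  # isoform proportions track the product-form truth
  truth <- isoform_distribution(clean_config(probs = p))
  est <- prof$isoforms$pct / 100
  se_iso <- sqrt(truth * (1 - truth) / prof$n_complete)
  expect_true(all(abs(est - truth) < 4 * se_iso + 0.002))
})
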