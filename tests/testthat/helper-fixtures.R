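# Shared fixtures, built in code at test time.

test_ref <- function() amplicon_reference()

# Config for exact-recovery settings: no base errors, uniform Q40 so no
# base falls under the call gate and every read is complete.
clean_config <- function(probs = c(A = 0.6, B = 0.5, C = 0.05,
                                   D = 0.35, E = 0.3),
                         n_reads = 1000, seed = 1, ...) {
  simulation_config(per_site_probs = probs, n_reads = n_reads,
                    base_error_rate = 0, quality_mean = 40, quality_sd = 0,
                    quality_dropout = 0, seed = seed, ...)
}

# One read in the aligned-reads layout, defaulting to the error-free
# reference sequence at Q30 everywhere.
one_read <- function(ref, edits = character(0), base = "G",
                     quals = NULL, id = "r1") {
  s <- strsplit(ref$sequence, "")[[1]]
  for (site in edits) s[ref$site_offsets[[site]] + 1L] <- base
  q <- if (is.null(quals)) strrep(rawToChar(as.raw(30 + 33)), length(s))
       else quals
  data.frame(id = id, start = 0L, strand = "+",
             seq = paste0(s, collapse = ""), qual = q,
             n_mismatch = 0L, source = "internal", stringsAsFactors = FALSE)
}

# Set one site's quality on a read data.frame.
set_site_qual <- function(reads, ref, site, q) {
  pos <- ref$site_offsets[[site]] + 1L
  substr(reads$qual, pos, pos) <- rawToChar(as.raw(q + 33L))
  reads
}
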