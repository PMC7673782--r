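# Seeded synthetic-data generators.
#
# The read generator emulates the amplicon deep-sequencing design: each read
# spans the full 249-nt amplicon, carries one of the 32 editing patterns
# (G substituted at edited sites), uniform substitution errors at a stated
# rate, and per-base Phred qualities from a simple truncated-normal model
# with a low-quality dropout fraction.  No indels are simulated: amplicon
# reads are handled gaplessly and indels fall under the aligner's mismatch
# cap instead.

.DNA_RAW <- charToRaw("ACGT")

#' Configuration for the amplicon read simulator
#'
#' @param per_site_probs Five editing probabilities in display order
#'   A, B, C, D, E (named or positional), each in \[0, 1\].
#' @param linkage_mode \code{"independent"} (sites edited independently) or
#'   \code{"explicit_haplotypes"} (isoform frequencies given directly).
#' @param haplotype_freqs Optional 32-vector of isoform frequencies in the
#'   binary pattern order of [enumerate_patterns()]; must sum to 1.
#'   Required in explicit mode.
#' @param n_reads Number of reads to generate (>= 1).
#' @param read_length Read length; reads span the full amplicon, so this
#'   must be at least the amplicon length and is capped there.  \code{NULL}
#'   (default) means the amplicon length.
#' @param base_error_rate Per-base substitution error probability.
#' @param quality_mean,quality_sd Mean and sd of the per-base Phred score
#'   (rounded, truncated to \[2, 40\]).
#' @param quality_dropout Fraction of bases assigned a low quality score
#'   (uniform on 2..15, i.e. below the default Q20 call gate).
#' @param seed Integer seed; fixing it makes the FASTQ output byte-identical
#'   across runs.
#' @return A validated list of class \code{simulation_config}.
#' @export
simulation_config <- function(per_site_probs = c(A = 0.6, B = 0.5, C = 0.05,
                                                 D = 0.35, E = 0.3),
                              linkage_mode = c("independent",
                                               "explicit_haplotypes"),
                              haplotype_freqs = NULL,
                              n_reads = 10000L,
                              read_length = NULL,
                              base_error_rate = 0.001,
                              quality_mean = 36, quality_sd = 3,
                              quality_dropout = 0.02,
                              seed = 1L) {
  linkage_mode <- match.arg(linkage_mode)
  if (length(per_site_probs) != 5)
    stop("configuration error: per_site_probs must have length 5")
  if (is.null(names(per_site_probs))) names(per_site_probs) <- .SITES_DISPLAY
  per_site_probs <- per_site_probs[.SITES_DISPLAY]
  if (anyNA(per_site_probs) || any(per_site_probs < 0 | per_site_probs > 1))
    stop("configuration error: per_site_probs must be probabilities named A-E")
  if (linkage_mode == "explicit_haplotypes") {
    if (is.null(haplotype_freqs))
      stop("configuration error: explicit_haplotypes mode requires haplotype_freqs")
    if (length(haplotype_freqs) != 32 || any(haplotype_freqs < 0) ||
        abs(sum(haplotype_freqs) - 1) > 1e-9)
      stop("configuration error: haplotype_freqs must be 32 non-negative values summing to 1")
  }
  if (n_reads < 1) stop("configuration error: n_reads must be >= 1")
  if (base_error_rate < 0 || base_error_rate > 1)
    stop("configuration error: base_error_rate must be in [0, 1]")
  if (quality_dropout < 0 || quality_dropout > 1)
    stop("configuration error: quality_dropout must be in [0, 1]")
  structure(list(per_site_probs = per_site_probs, linkage_mode = linkage_mode,
                 haplotype_freqs = haplotype_freqs,
                 n_reads = as.integer(n_reads), read_length = read_length,
                 base_error_rate = base_error_rate,
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 quality_dropout = quality_dropout, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Isoform frequency distribution implied by a simulation config
#'
#' In independent mode the frequency of pattern \eqn{b \in \{0,1\}^5} is
#' \eqn{\prod_i p_i^{b_i} (1-p_i)^{1-b_i}}; in explicit mode the supplied
#' haplotype frequencies are returned verbatim.
#'
#' @param cfg A \code{simulation_config}.
#' @return Named 32-vector of frequencies (pattern labels, binary order);
#'   sums to 1.
#' @export
isoform_distribution <- function(cfg) {
  pats <- enumerate_patterns()
  if (cfg$linkage_mode == "explicit_haplotypes") {
    f <- as.numeric(cfg$haplotype_freqs)
  } else {
    p <- cfg$per_site_probs
    f <- apply(pats, 1, function(b) prod(ifelse(b == 1, p, 1 - p)))
  }
  stats::setNames(f, rownames(pats))
}

#' Generate amplicon reads with ground truth
#'
#' Draws an editing pattern per read from the configured isoform
#' distribution, substitutes G at the edited site offsets, applies i.i.d.
#' uniform substitution errors, and assigns per-base Phred qualities.
#'
#' @param ref An \code{amplicon_ref}.
#' @param cfg A \code{simulation_config}.
#' @return A list of class \code{simulated_reads}: \code{id}, \code{seq},
#'   \code{qual} (Phred+33 strings) plus a \code{truth} record holding the
#'   generating per-site frequencies, the 32-vector of isoform frequencies,
#'   the per-read sampled pattern index and the exact sampled pattern tally
#'   (the oracle for exact-recovery checks).
#' @export
generate_reads <- function(ref, cfg) {
  set.seed(cfg$seed)
  L <- nchar(ref$sequence)
  if (!is.null(cfg$read_length) && cfg$read_length < L)
    stop("configuration error: read_length must cover the amplicon (>= ", L, ")")
  n <- cfg$n_reads
  pats <- enumerate_patterns()
  freqs <- isoform_distribution(cfg)
  idx <- sample.int(32L, n, replace = TRUE, prob = freqs)
  tally <- stats::setNames(tabulate(idx, 32L), rownames(pats))

  mat <- matrix(charToRaw(ref$sequence), nrow = L, ncol = n)
  site_pos1 <- ref$site_offsets[.SITES_DISPLAY] + 1L
  G <- charToRaw("G")
  for (j in seq_along(.SITES_DISPLAY)) {
    edited <- pats[idx, j] == 1L
    if (any(edited)) mat[site_pos1[j], edited] <- G
  }

  n_bases <- L * n
  n_err <- stats::rbinom(1, n_bases, cfg$base_error_rate)
  if (n_err > 0) {
    pos <- sample.int(n_bases, n_err)
    cur <- match(mat[pos], .DNA_RAW)
    shift <- sample.int(3L, n_err, replace = TRUE)
    mat[pos] <- .DNA_RAW[(cur - 1L + shift) %% 4L + 1L]
  }

  q <- round(stats::rnorm(n_bases, cfg$quality_mean, cfg$quality_sd))
  q <- pmin(pmax(q, 2), 40)
  if (cfg$quality_dropout > 0) {
    drop <- stats::runif(n_bases) < cfg$quality_dropout
    q[drop] <- sample(2:15, sum(drop), replace = TRUE)
  }

  all_seq <- rawToChar(as.vector(mat))
  all_qual <- rawToChar(as.raw(q + 33L))
  starts <- (seq_len(n) - 1L) * L + 1L
  seqs <- substring(all_seq, starts, starts + L - 1L)
  quals <- substring(all_qual, starts, starts + L - 1L)

  marginal <- as.numeric(freqs %*% pats)
  structure(list(
    id = sprintf("read_%06d", seq_len(n)),
    seq = seqs,
    qual = quals,
    truth = list(
      per_site_freqs = stats::setNames(marginal, .SITES_DISPLAY),
      isoform_freqs = freqs,
      pattern_index = idx,
      pattern_tally = tally
    )
  ), class = "simulated_reads")
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param reads A \code{simulated_reads} object, or any list with \code{id},
#'   \code{seq}, \code{qual} character vectors.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$id
  qs <- Biostrings::QualityScaledDNAStringSet(
    dna, Biostrings::PhredQuality(reads$qual))
  Biostrings::writeQualityScaledXStringSet(qs, filepath = path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ path.
#' @return A list with \code{id}, \code{seq}, \code{qual} character vectors.
#' @export
read_fastq <- function(path) {
  # metadata-drop warning from the quality container is expected and benign
  qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  list(id = sub(" .*", "", names(qs)),
       seq = unname(as.character(qs)),
       qual = unname(as.character(Biostrings::quality(qs))))
}

#' Simulate a RiboMeth-seq 5'-end count profile
#'
#' Per-position 5'-end read counts are drawn Poisson around a smoothly
#' varying coverage level.  A 2'-O-methyl at nucleotide m protects the
#' phosphodiester bond 3' of m, so the count at the cleavage position
#' m + 1 (see [scored_position()]) is suppressed by the protection factor.
#'
#' @param n_positions Length of the reference.
#' @param methylated_sites Integer vector of methylated nucleotide positions
#'   (1-based); their suppressed cleavage positions must be in range.
#' @param coverage Mean coverage level (counts per position).
#' @param protection Protection factor(s) in \[0, 1\], recycled over sites;
#'   1 means complete protection (zero end count at the cleavage position).
#' @param seed Integer seed.
#' @param site_names Optional labels for the annotated sites.
#' @return An \code{end_count_profile}: list with \code{counts} (integer
#'   vector over positions 1..n_positions) and \code{sites} (data.frame with
#'   \code{position}, \code{scored_pos}, \code{name}, \code{protection}).
#' @export
generate_endcounts <- function(n_positions, methylated_sites = integer(0),
                               coverage = 1000, protection = 0.9, seed = 1L,
                               site_names = NULL) {
  methylated_sites <- as.integer(methylated_sites)
  scored <- methylated_sites + RMS_CLEAVAGE_OFFSET
  if (length(methylated_sites) &&
      (any(methylated_sites < 1) || any(scored > n_positions)))
    stop("methylated sites (and their cleavage positions) must be in range")
  protection <- rep_len(protection, length(methylated_sites))
  if (any(protection < 0 | protection > 1))
    stop("protection factors must be in [0, 1]")
  set.seed(seed)
  i <- seq_len(n_positions)
  level <- coverage * (1 + 0.3 * sin(2 * pi * i / 50))
  level[scored] <- level[scored] * (1 - protection)
  counts <- stats::rpois(n_positions, level)
  if (is.null(site_names) && length(methylated_sites))
    site_names <- sprintf("site_%d", methylated_sites)
  structure(list(
    counts = counts,
    sites = data.frame(position = methylated_sites, scored_pos = scored,
                       name = site_names %||% character(0),
                       protection = protection, stringsAsFactors = FALSE)
  ), class = "end_count_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate per-mouse per-site editing frequencies for a cohort
#'
#' Summary-level counterpart of the read-level simulator: each mouse's true
#' per-site editing probability is jittered around the group value
#' (normal, sd in percentage points, clamped to \[0, 1\]) and its measured
#' frequency is Binomial(n_reads, p)/n_reads — exactly the distribution the
#' full read-level pipeline produces at base-error rate 0.  Used for
#' replicate-level power and calibration studies where re-simulating reads
#' would add nothing.
#'
#' @param n_wt,n_ko Mice per genotype.
#' @param wt_probs,ko_probs Group-level per-site editing probabilities in
#'   display order A, B, C, D, E.
#' @param n_reads Reads per mouse (binomial denominator).
#' @param between_sd_pp Between-mouse sd of the true editing level, in
#'   percentage points.
#' @param region Region label attached to every row.
#' @param seed Optional integer seed.
#' @return Long data.frame: \code{sample}, \code{genotype}, \code{region},
#'   \code{site}, \code{pct} (percent).
#' @export
simulate_cohort_frequencies <- function(n_wt = 10, n_ko = 10,
                                        wt_probs = c(A = 0.6, B = 0.5,
                                                     C = 0.05, D = 0.35,
                                                     E = 0.3),
                                        ko_probs = wt_probs,
                                        n_reads = 50000,
                                        between_sd_pp = 1,
                                        region = "sim", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  one_group <- function(n_mice, probs, genotype) {
    probs <- if (is.null(names(probs))) stats::setNames(probs, .SITES_DISPLAY)
             else probs[.SITES_DISPLAY]
    do.call(rbind, lapply(seq_len(n_mice), function(m) {
      p_m <- pmin(pmax(probs + stats::rnorm(5, 0, between_sd_pp / 100), 0), 1)
      k <- stats::rbinom(5, n_reads, p_m)
      data.frame(sample = sprintf("%s_%02d", genotype, m),
                 genotype = genotype, region = region,
                 site = .SITES_DISPLAY, pct = 100 * k / n_reads,
                 stringsAsFactors = FALSE)
    }))
  }
  rbind(one_group(n_wt, wt_probs, "WT"), one_group(n_ko, ko_probs, "KO"))
}
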