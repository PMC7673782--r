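# End-to-end orchestration: simulate -> align -> profile -> differential.
#
# One structured config drives all stages; all randomness flows from a
# single root seed expanded into per-sample seeds, so a rerun with the same
# config reproduces every artifact.

#' Built-in demo cohort configuration
#'
#' Two genotypes x two brain regions, 6 mice per group, 20,000 reads per
#' mouse, fixed seeds.  Editing probabilities follow the canonical regional
#' pattern (A, B and D sites more edited than C and E; cortex more edited
#' than hypothalamus), and the KO hypothalamus carries a +3 percentage-point
#' shift at the C site so the demo exercises the differential stage's
#' detection path.
#'
#' @param n_mice Mice per genotype per region.
#' @param n_reads Reads per mouse.
#' @param seed Root seed.
#' @return A config list accepted by [run_pipeline()].
#' @export
demo_config <- function(n_mice = 6, n_reads = 20000, seed = 20200L) {
  hypo_wt <- c(A = 0.60, B = 0.50, C = 0.05, D = 0.35, E = 0.30)
  hypo_ko <- replace(hypo_wt, "C", 0.08)
  ctx <- c(A = 0.85, B = 0.80, C = 0.15, D = 0.55, E = 0.35)
  list(
    name = "demo",
    seed = as.integer(seed),
    alpha = 0.05,
    adjust = "none",
    min_q = 20,
    max_mismatch_frac = 0.1,
    n_reads = n_reads,
    base_error_rate = 0.001,
    quality_mean = 36, quality_sd = 3, quality_dropout = 0.02,
    between_mouse_sd = 1,
    groups = list(
      list(genotype = "WT", region = "hypothalamus", n_mice = n_mice,
           probs = as.list(hypo_wt)),
      list(genotype = "KO", region = "hypothalamus", n_mice = n_mice,
           probs = as.list(hypo_ko)),
      list(genotype = "WT", region = "cortex", n_mice = n_mice,
           probs = as.list(ctx)),
      list(genotype = "KO", region = "cortex", n_mice = n_mice,
           probs = as.list(ctx))
    )
  )
}

#' Validate a pipeline configuration
#'
#' Checks structure and value ranges before any compute; errors name the
#' offending field.
#'
#' @param config Config list or path to a YAML file.
#' @return The config as a list, invisibly usable downstream.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  req <- c("name", "seed", "groups")
  miss <- setdiff(req, names(config))
  if (length(miss))
    stop("configuration error: missing field(s): ", paste(miss, collapse = ", "))
  if (!length(config$groups)) stop("configuration error: empty groups list")
  for (i in seq_along(config$groups)) {
    g <- config$groups[[i]]
    gmiss <- setdiff(c("genotype", "region", "n_mice", "probs"), names(g))
    if (length(gmiss))
      stop("configuration error: group ", i, " missing field(s): ",
           paste(gmiss, collapse = ", "))
    p <- unlist(g$probs)
    if (length(p) != 5 || any(p < 0 | p > 1))
      stop("configuration error: group ", i,
           ": probs must be 5 values in [0, 1]")
    if (g$n_mice < 1) stop("configuration error: group ", i, ": n_mice < 1")
  }
  defaults <- list(alpha = 0.05, adjust = "none", min_q = 20,
                   max_mismatch_frac = 0.1, n_reads = 20000,
                   base_error_rate = 0.001, quality_mean = 36,
                   quality_sd = 3, quality_dropout = 0.02,
                   between_mouse_sd = 1)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config
}

#' Run the full pipeline
#'
#' Simulates every sample of the configured cohort, aligns and profiles the
#' reads, writes per-sample site/isoform TSVs, and runs the differential
#' comparisons.  All outputs land under \code{outdir}; a manifest records
#' seeds, paths and per-stage record counts (reads generated = aligned +
#' rejected; complete + incomplete = accepted).
#'
#' @param config Config list (see [demo_config()]) or path to a YAML file.
#' @param outdir Output directory (created if needed).
#' @param keep_reads Also write per-sample FASTQ and SAM files (off by
#'   default; they dominate disk usage).
#' @return Invisibly, a list with \code{manifest}, the long \code{sites}
#'   and \code{isoforms} tables, the \code{differential_sites} and
#'   \code{differential_isoforms} tables and the per-sample
#'   \code{profiles}.
#' @export
run_pipeline <- function(config, outdir, keep_reads = FALSE) {
  config <- validate_config(config)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  ref <- amplicon_reference()
  write_reference_fasta(ref, file.path(outdir, "amplicon.fa"))

  config_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(config, config_path)
  config_hash <- unname(tools::md5sum(config_path))

  samples <- do.call(rbind, lapply(config$groups, function(g)
    data.frame(genotype = g$genotype, region = g$region,
               mouse = seq_len(g$n_mice),
               probs = I(rep(list(unlist(g$probs)), g$n_mice)),
               stringsAsFactors = FALSE)))
  samples$sample <- sprintf("%s_%s_%02d", samples$genotype,
                            gsub("[^A-Za-z0-9]", "", samples$region),
                            samples$mouse)
  set.seed(config$seed)
  samples$seed <- sample.int(.Machine$integer.max - 1L, nrow(samples))

  profile_dir <- file.path(outdir, "profiles")
  profiles <- vector("list", nrow(samples))
  counts <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    smp <- samples[i, ]
    set.seed(smp$seed)
    p_m <- pmin(pmax(smp$probs[[1]] + stats::rnorm(5, 0, config$between_mouse_sd / 100),
                     0), 1)
    read_seed <- sample.int(.Machine$integer.max - 1L, 1)
    cfg <- simulation_config(per_site_probs = p_m,
                             n_reads = config$n_reads,
                             base_error_rate = config$base_error_rate,
                             quality_mean = config$quality_mean,
                             quality_sd = config$quality_sd,
                             quality_dropout = config$quality_dropout,
                             seed = read_seed)
    sim <- generate_reads(ref, cfg)
    aln <- align_reads(sim, ref = ref,
                       max_mismatch_frac = config$max_mismatch_frac)
    if (keep_reads) {
      write_fastq(sim, file.path(outdir, paste0(smp$sample, ".fastq")))
      write_sam(aln$aligned, ref, file.path(outdir, paste0(smp$sample, ".sam")))
    }
    prof <- profile_sample(aln$aligned, ref,
                           metadata = list(sample = smp$sample,
                                           genotype = smp$genotype,
                                           region = smp$region),
                           min_q = config$min_q)
    write_profile(prof, profile_dir)
    profiles[[i]] <- prof
    counts[[i]] <- data.frame(
      sample = smp$sample, n_generated = cfg$n_reads,
      n_aligned = nrow(aln$aligned), n_rejected = nrow(aln$rejected),
      n_complete = prof$n_complete, n_incomplete = prof$n_incomplete,
      stringsAsFactors = FALSE)
    message(sprintf("[%s] %d reads -> %d aligned (%d rejected), %d complete",
                    smp$sample, cfg$n_reads, nrow(aln$aligned),
                    nrow(aln$rejected), prof$n_complete))
  }
  counts <- do.call(rbind, counts)

  sites <- site_table(profiles)
  isoforms <- isoform_table(profiles)
  diff_sites <- multiple_testing(compare_sites(sites, alpha = config$alpha),
                                 method = config$adjust, alpha = config$alpha)
  diff_iso <- multiple_testing(compare_isoforms(isoforms, alpha = config$alpha),
                               method = config$adjust, alpha = config$alpha)
  utils::write.table(diff_sites, file.path(outdir, "differential_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(diff_iso, file.path(outdir, "differential_isoforms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    tool_version = as.character(utils::packageVersion("htr2cedit")),
    config_hash = config_hash,
    root_seed = config$seed,
    sample_seeds = stats::setNames(as.list(samples$seed), samples$sample),
    paths = list(reference = file.path(outdir, "amplicon.fa"),
                 profiles = profile_dir,
                 differential_sites = file.path(outdir, "differential_sites.tsv"),
                 differential_isoforms = file.path(outdir, "differential_isoforms.tsv")),
    counts = counts
  )
  manifest_out <- manifest
  manifest_out$counts <- as.list(counts)
  yaml::write_yaml(manifest_out, file.path(outdir, "manifest.yaml"))

  invisible(list(manifest = manifest, sites = sites, isoforms = isoforms,
                 differential_sites = diff_sites,
                 differential_isoforms = diff_iso,
                 profiles = profiles))
}
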