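#!/usr/bin/env Rscript

# Stage 1 — define the synthetic cohort and demonstrate the read generator.
#
# The cohort emulates the amplicon deep-sequencing design: two genotypes
# (WT, Snord115-KO-like) x two brain regions, 6 mice per group, 20,000
# reads per mouse over the 249-nt exon IV/V junction amplicon.  The KO
# hypothalamus carries a configured +3 percentage-point shift at the C
# site, the site the snoRNA is predicted to target, so downstream stages
# have a known signal to find.

suppressPackageStartupMessages(library(htr2cedit))

dir.create("results", showWarnings = FALSE)
config <- demo_config()
config <- validate_config(config)
yaml::write_yaml(config, "results/config.yaml")
cat("Cohort config written to results/config.yaml:",
    length(config$groups), "groups,",
    sum(vapply(config$groups, `[[`, numeric(1), "n_mice")), "mice,",
    config$n_reads, "reads/mouse\n\n")

ref <- amplicon_reference()
print(ref)
write_reference_fasta(ref, "results/amplicon.fa")

# One illustrative sample: generate, write FASTQ, compare naive G-fraction
# at the site offsets against the generating truth.
cfg <- simulation_config(n_reads = 5000, seed = 42)
sim <- generate_reads(ref, cfg)
write_fastq(sim, "results/example_WT_hypothalamus.fastq")
naive_g <- vapply(c("A", "B", "C", "D", "E"), function(s) {
  pos <- ref$site_offsets[[s]] + 1
  mean(substring(sim$seq, pos, pos) == "G")
}, numeric(1))
truth <- data.frame(site = names(naive_g),
                    true_pct = round(100 * sim$truth$per_site_freqs, 2),
                    naive_G_pct = round(100 * naive_g, 2))
write.table(truth, "results/example_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nExample sample (5,000 reads, seed 42): generating truth vs raw G fraction\n")
print(truth, row.names = FALSE)
cat("\nThe raw G fraction tracks the truth to within binomial noise;\n",
    "quality gating and alignment in stage 2 refine it further.\n", sep = "")
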