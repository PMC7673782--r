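# htr2cedit

Quantification of combinatorial A-to-I RNA editing of the serotonin
receptor 2C (*Htr2c*) transcript from deep amplicon sequencing, with
replicate-aware differential statistics, RiboMeth-seq 2'-O-methylation
scoring, and indirect-calorimetry derivations — all driven by a seeded
synthetic-data generator so the whole pipeline is testable end to end
without external sequencing archives.

## The problem and who this is for

*Htr2c* pre-mRNA is edited at five adenosines clustered in exon V (sites
A, B, C, D, E; genomic order A, B, E, C, D). Editing is read as A→G and
recodes residues 156, 158 and 160 of the receptor's second intracellular
loop, so the five binary site states define **32 mRNA isoform classes**
that translate into **24 protein variants**, from unedited INI to fully
edited VGV. Groups studying this locus (e.g. snoRNA *Snord115* models of
Prader-Willi syndrome) sequence a 249-nt amplicon spanning the spliced
exon IV/V junction to ~10⁵–10⁶ reads per sample across 8–12 mice per
genotype, then ask: does a genotype shift the per-site editing
frequencies, or the proportions of the 32 isoforms?

The core per-read computation: after gapless alignment to the amplicon,
each site is called **edited** (G, quality ≥ 20), **unedited** (A,
quality ≥ 20) or **masked** (low quality, non-A/G base, uncovered).
Per-site frequency is 100·n_edited/n_covered over all covered reads; the
isoform table bins reads with all five sites called into the 32 patterns.
Mice (not reads) are the unit of replication: genotypes are compared per
site/isoform with Student's t-test, or the Mann-Whitney test when a
Shapiro-Wilk check rejects normality in either group.

## Worked example

```r
library(htr2cedit)

ref <- amplicon_reference()                      # 249-nt exon IV/V amplicon
cfg <- simulation_config(per_site_probs = c(A = 0.6, B = 0.5, C = 0.05,
                                            D = 0.35, E = 0.3),
                         n_reads = 20000, seed = 42)
sim  <- generate_reads(ref, cfg)                 # FASTQ-style reads + truth
aln  <- align_reads(sim, ref = ref)              # anchored gapless alignment
prof <- profile_sample(aln$aligned, ref,
                       list(sample = "WT_hypo_1", genotype = "WT",
                            region = "hypothalamus"))
print(prof)
```

```
Editing profile for sample 'WT_hypo_1' (WT, hypothalamus)
  reads: 20000 aligned; 17955 complete, 2045 incomplete
  site editing: A=60.28%  B=49.93%  C=5.05%  D=34.67%  E=29.99%
  top isoforms: AB (VNI) 13.36%, A (VNI) 13.09%, B (MNI) 8.66%
```

The recovered site percentages sit within binomial sampling error of the
configured truth (60/50/5/35/30); the 2,045 incomplete reads are those
with at least one site masked by the quality gate, and they are excluded
from the isoform bins but not from the site table. The combinatorics:

```r
tab <- recoding_table(ref)
nrow(tab)                         # 32 mRNA classes
length(unique(tab$tripeptide))    # 24 protein variants
translate_pattern("ABCDE", tab)   # "VGV"  (fully edited)
```

A full cohort run — two genotypes × two regions, 6 mice each, with a
configured +3 percentage-point KO shift at the C site — is one call:

```r
res <- run_pipeline(demo_config(), "results/run")
subset(res$differential_sites, significant)
```

which (seed 20200) reports the hypothalamus C site at +2.78 pp,
p = 2.6e-05, and elevates the C-containing isoforms with KO/WT ratios
around 1.5, most of them flagged as lowly expressed (< 5% of WT total).

The `analysis/` directory narrates the same workflow as numbered stages
(`01_simulate.R` … `05_calorimetry.R`), writing tables under `results/`;
run them in order from the repository root after installing the package.

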