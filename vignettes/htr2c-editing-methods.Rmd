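---
title: "Quantifying combinatorial Htr2c RNA editing from amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying combinatorial Htr2c RNA editing from amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htr2cedit)
```

## The biological problem

The serotonin receptor 2C transcript (*Htr2c*) undergoes adenosine-to-inosine
RNA editing at five adenosines clustered in exon V, conventionally named the
A, B, C, D and E sites (their genomic 5'→3' order along the transcript is
A, B, E, C, D). Inosine is read as guanosine by both sequencers and
ribosomes, so editing appears as A→G mismatches against the genome, and the
edited positions recode three amino acids (residues 156, 158 and 160) in the
receptor's second intracellular loop. The five binary site states define
$2^5 = 32$ mRNA isoform classes; translation collapses these to 24 distinct
protein variants because some codon edits are synonymous at the protein
level. The unedited protein is INI (Ile-Asn-Ile) and the fully edited one is
VGV (Val-Gly-Val), the least active receptor variant.

The quantification strategy is deep amplicon sequencing: a 249-nt cDNA
segment spanning the spliced exon IV/V junction is amplified and sequenced
to high depth (on the order of $10^5$–$10^6$ reads per sample, 8–12 mice per
genotype), each read is assigned an editing state at each site, and
per-sample site frequencies and isoform proportions are compared between
genotypes. This package implements that computation end to end, together
with a seeded synthetic-data generator so every stage can be validated
without external sequence archives.

## The amplicon reference and recoding model

`amplicon_reference()` builds a 249-nt reference with the three recoded
codons embedded in frame 3' of the junction:

* residue 156, codon ATA (Ile): site A at codon position 1, site B at
  position 3 — (A,B) edits give I → V / M / V;
* residue 158, codon AAT (Asn): site E at position 1, site C at position 2 —
  (E,C) edits give N → D / S / G;
* residue 160, codon ATT (Ile): site D at position 1 — D edit gives I → V.

The codon/recoding assignment is the established HTR2C arrangement; it is
carried as *data* on the reference object (`codon_map`, `site_offsets`), so
an alternative table can be injected and `recoding_table()` will re-derive
the 32-pattern → tripeptide map at run time by editing the codons and
translating with the standard genetic code. Nothing downstream hard-codes
the 24-protein result; it falls out of the translation.

The filler sequence around the codons is an arbitrary fixed non-repetitive
string produced by a small deterministic generator. The pipeline never
depends on filler identity (alignment anchors on the whole read, and calls
are made only at the site offsets), so the reference is fully specified by
its length, junction offset and codon offsets. All coordinates in the
amplicon modules are 0-based with half-open intervals.

## The read generator

`generate_reads()` draws each read's editing pattern from the configured
isoform distribution. Two linkage modes are supported:

* **independent** — pattern $b \in \{0,1\}^5$ has probability
  $\prod_i p_i^{b_i}(1-p_i)^{1-b_i}$ for per-site probabilities $p_i$;
* **explicit haplotypes** — a 32-vector of isoform frequencies is used
  verbatim, allowing arbitrary linkage between sites.

Edited sites are written as G on the reference sequence; substitution errors
are then applied i.i.d. at the configured per-base rate, uniformly over the
three alternative bases; per-base Phred qualities are rounded draws from a
normal (default mean 36, sd 3, truncated to \[2, 40\]), with a small
dropout fraction (default 2%) assigned uniform low qualities 2–15 to
exercise the call gate. Defaults — 20,000–50,000 single-end full-length
reads per sample, error rate $10^{-3}$ — were chosen once to reflect
Illumina amplicon runs at the study's scale (about a million reads per
genotype spread over 8–12 mice). Indels are not simulated: amplicon reads
are handled gaplessly and indel-bearing reads would simply fail the
aligner's mismatch cap.

The generator records the ground truth alongside the reads: the generating
frequencies and the exact sampled pattern tally. That tally is the oracle
for the exact-recovery tests: with error rate 0 and all qualities above the
gate, the full pipeline (align → call → tabulate) must reproduce it
bit-for-bit, which the test suite asserts at 20,000 reads.

Read layout: the sequencing design is paired-end, but the fragment is a
fixed 249-nt amplicon, so the default simulation is single-end full-length
reads. For data where mates each cover part of the amplicon,
`merge_mates()` implements overlap merging (higher quality wins;
confident disagreements are masked with N so they drop out of calling).

## Alignment

`align_reads()` scans every gapless placement of each read and of its
reverse complement against the reference and keeps the best. Editing-site
columns are excluded from the mismatch count, so a fully edited read aligns
with zero mismatches; acceptance requires a mismatch fraction of at most
0.1 (default). Reverse-strand reads are re-oriented to the reference strand
with qualities reversed. The genome-alignment route used on real data is
supported through `load_sam()`: primary mapped records are ingested from
SAM/BAM (via Rsamtools), secondary/supplementary records and indel-bearing
CIGARs are skipped with counts, soft clips are trimmed, and a
`chrom:start-end` region converts genome coordinates to amplicon
coordinates. A round-trip test asserts that site calls are identical
whichever route a read takes.

## Calling, site frequencies and isoform tabulation

`call_sites()` applies the per-read rule at each site: G at quality ≥ 20 →
EDITED; A at quality ≥ 20 → UNEDITED; anything else (low quality, non-A/G
base, uncovered site) → MASKED. Non-A/G bases are masked rather than
counted as unedited because only A→G carries editing information; a C or T
at a site is a sequencing error either way. Raising the quality threshold
can only shrink the covered-read set (a tested monotonicity property).

Two summaries follow:

* **site table** (`site_frequencies()`): per site,
  $100 \cdot n_{edited}/n_{covered}$ over *all* reads covering that site.
  A site covered by no read is reported missing, not 0%.
* **isoform table** (`isoform_counts()`): only reads with all five sites
  called contribute, each to exactly one of the 32 pattern bins; incomplete
  reads are counted separately.

Whether the per-site percentages should use all covered reads or only
complete reads is genuinely open; both are computed
(`profile_sample()` returns `sites` and `sites_complete`), with all-covered
as the default site table since it maximizes the data per site. The
complete-only variant is the exact marginal of the 32-vector — an identity
the tests assert — at the cost of discarding reads with a single masked
site. With full-length amplicon reads the two differ very little.

## Differential comparisons

The unit of replication is the mouse: each mouse contributes one frequency
per site (or one proportion per isoform), and groups of mice are compared.
Read-level tests would treat $10^5$ reads as independent replicates and be
wildly anticonfident; they are deliberately not offered.

Test selection follows the two-group policy: Student's t-test when both
groups pass a Shapiro-Wilk normality check at 0.05, otherwise the
Mann-Whitney test (`normality_gate()`). Groups smaller than 3 cannot be
checked and default to Mann-Whitney, as do constant groups. Mann-Whitney
p-values are exact for combined $n \le 20$ without ties and otherwise use
the normal approximation with tie correction; two indistinguishable groups
are reported as $p = 1$ by convention.

`compare_sites()` reports KO mean − WT mean in percentage points;
`compare_isoforms()` reports the KO/WT ratio of group means (not the mean
of per-mouse ratios, matching how group summaries are displayed), the WT
mean abundance, and flags isoforms under 5% of the WT total as lowly
expressed. Significance defaults to raw $p < 0.05$ per row — the per-figure
convention — with an optional per-region Benjamini-Hochberg adjustment
(`multiple_testing(..., "bh")`) since 32 isoforms × several regions is a
real multiplicity burden.

### Power and calibration studies

Replicate-level operating characteristics (power to detect a ≥ 2
percentage-point shift with $n = 10/10$ mice at 50,000 reads/mouse;
type-I error under the null) are estimated by Monte-Carlo over hundreds of
cohorts. These studies use `simulate_cohort_frequencies()`, which draws each
mouse's true editing level around the group value (normal, sd 1 percentage
point — the between-mouse variability assumed throughout, consistent with
the low inter-mouse variability of deep amplicon data) and its measured
frequency as $\mathrm{Binomial}(n_{reads}, p)/n_{reads}$. At base-error
rate 0 this is *exactly* the distribution the read-level pipeline produces,
so repeating the full FASTQ simulation hundreds of times would add
computation but no information; the equivalence itself is covered by the
exact-recovery and 3-SE read-level tests. The test suite runs 200
repetitions for power and 1000 for calibration, sizes chosen to keep
Monte-Carlo error small (binomial se ≈ 0.3% on the type-I estimate).

## RiboMeth-seq scoring

Alkaline fragmentation cleaves RNA at every phosphodiester bond except the
bond 3' of a 2'-O-methylated ribose. A methyl at nucleotide $m$ therefore
depletes read 5' ends at position $m+1$; generator and scorer share this
single cleavage-offset constant (`RMS_CLEAVAGE_OFFSET`, `scored_position()`).
The score at a position is the Score-C-style drop statistic

$$\mathrm{score} = \max\!\left(0,\; 1 - \frac{n_{pos}}{w}\right),$$

where $w$ is the weighted mean of end counts at offsets $\pm1 \ldots \pm k$
(default $k = 6$) with linearly decreasing weights $k, k-1, \ldots, 1$, and
scored positions of *other* annotated sites are excluded from the
neighbourhood so adjacent methylations do not depress the baseline. The
score is undefined (NA) when the neighbourhood mean is zero. Which published
score variant to implement was an open choice; the drop-statistic shape was
fixed here with the window and weights configurable. The score is
scale-invariant and monotone in the site count (tested properties), and on
synthetic Poisson profiles the recovered scores rank-match the configured
protection factors. Real-brain methylation levels are not reproduced here —
they require the deposited sequencing data — so this module is validated on
synthetic profiles only. Genotype comparison (`compare_meth()`) reuses the
gated two-group test with the usual 0.05/0.01/0.001 asterisk tiers.

## Calorimetry

The four printed formulas are implemented exactly as closed forms:
RER $= V_{CO_2}/V_{O_2}$; energy expenditure
$= 1.44 \cdot V_{O_2} \cdot (3.815 + 1.232 \cdot \mathrm{RER})$ in
kcal/day/kg$^{0.75}$; glucose oxidation
$= (4.545 \cdot V_{CO_2} - 3.205 \cdot V_{O_2})/1000$ and lipid oxidation
$= 1.672 \cdot (V_{O_2} - V_{CO_2})/1000$, both in g/min/kg$^{0.75}$.
Inputs are assumed already normalized per kg$^{0.75}$ of metabolic mass;
units are labels only and no conversion is attempted, so outputs are correct
up to the input unit supplied. Negative oxidation values are possible under
the formulas (e.g. RER > 1 during net lipogenesis) and are preserved and
flagged, never clipped. RER outside \[0.6, 1.3\] triggers a warning as a
unit-sanity check.

## Orchestration and reproducibility

`run_pipeline()` executes simulate → align → profile → differential from a
single config (list or YAML), writing per-sample TSVs, the differential
tables and a manifest with per-stage record counts that must reconcile
(generated = aligned + rejected; complete + incomplete = aligned). All
randomness flows from one root seed expanded into per-sample seeds, so
reruns are byte-identical — a tested contract. `demo_config()` bundles a
two-genotype × two-region cohort (6 mice/group, 20,000 reads/mouse) with a
+3 percentage-point C-site shift configured in the KO hypothalamus; the
`analysis/` scripts narrate a full run of it. The per-module command-line
surface is intentionally these thin numbered scripts over the package
functions rather than a separate CLI binary.

## Numerical and degenerate-case choices

* Alignment ties (equal mismatch counts) resolve to the forward strand and
  the smallest offset, deterministically.
* `isoform_distribution()` evaluates the product form directly, so $p_i \in
  \{0,1\}$ are exact, not log-space limits.
* Empty read sets error early and name the sample; degenerate reads yield
  all-MASKED calls rather than errors.
* Sites with zero coverage are excluded from group comparisons with a
  warning rather than imputed as 0%.
* Percentages are reported with 2 decimals in TSV outputs; full precision
  is retained in memory and in returned objects.

## Limitations

The generator emulates the *statistical* structure of amplicon data —
binomial sampling, site linkage, base errors, quality dropout — but not PCR
amplification bias, strand-specific error profiles, primer artifacts, index
hopping, or alignment ambiguity against a full genome. Passing tests
therefore demonstrate that the computation is correct under the stated
sampling model, not that the laboratory protocol is unbiased. The
RiboMeth-seq module likewise models fragmentation as Poisson counts around
a smooth level, not library-specific end biases. In-vivo effect sizes and
figure-level values from brain tissue require the deposited raw data and
are outside what synthetic validation can certify.
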