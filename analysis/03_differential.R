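#!/usr/bin/env Rscript

# Stage 3 — inspect the differential tables: which sites and which of the
# 32 isoforms shift between genotypes, per region.  Raw p-values mirror the
# per-figure convention; a Benjamini-Hochberg variant is written alongside.

suppressPackageStartupMessages(library(htr2cedit))

sites <- read.delim("results/run/differential_sites.tsv")
iso <- read.delim("results/run/differential_isoforms.tsv")

cat("Per-site KO-vs-WT comparison (difference in percentage points):\n")
sites_fmt <- transform(sites, mean_wt = round(mean_wt, 2),
                       mean_ko = round(mean_ko, 2),
                       difference = round(difference, 2),
                       p = signif(p, 3))
print(sites_fmt[, c("region", "site", "mean_wt", "mean_ko", "difference",
                    "p", "test", "significant")], row.names = FALSE)

sig_sites <- sites[sites$significant, ]
cat("\n", nrow(sig_sites), " significant site shift(s) at alpha = 0.05:\n",
    sep = "")
if (nrow(sig_sites))
  cat(sprintf("  %s %s: %+.2f pp (p = %.2g)\n", sig_sites$region,
              sig_sites$site, sig_sites$difference, sig_sites$p))

sig_iso <- iso[iso$significant, ]
cat("\nSignificant isoform proportion changes (KO/WT ratio of group means;\n",
    "'low' marks isoforms under 5% of WT total):\n", sep = "")
if (nrow(sig_iso)) {
  cat(sprintf("  %s %-6s ratio %.2f, WT %.2f%% (p = %.2g)%s\n",
              sig_iso$region, sig_iso$pattern, sig_iso$ko_wt_ratio,
              sig_iso$wt_mean_pct, sig_iso$p,
              ifelse(sig_iso$low_abundance, "  [low]", "")))
} else cat("  none\n")

iso_bh <- multiple_testing(iso, "bh")
write.table(iso_bh, "results/run/differential_isoforms_bh.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nAfter per-region BH adjustment, ", sum(iso_bh$significant),
    " isoform row(s) remain significant (written to",
    " results/run/differential_isoforms_bh.tsv).\n", sep = "")
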