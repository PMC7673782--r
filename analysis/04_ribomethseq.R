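#!/usr/bin/env Rscript

# Stage 4 — RiboMeth-seq scoring on synthetic rRNA end-count profiles.
# Three annotated 2'-O-methylation sites; the KO group loses most of the
# protection at the first site (emulating the loss of a snoRNA-guided
# methyl), while the other two stay unchanged.

suppressPackageStartupMessages(library(htr2cedit))

sites <- c(576, 1200, 3680)
names(sites) <- c("SSU-A576", "SSU-G1200", "LSU-C3680")
wt_prot <- c(0.95, 0.90, 0.85)
ko_prot <- c(0.70, 0.90, 0.85)

wt <- lapply(1:3, function(i)
  generate_endcounts(4000, sites, coverage = 3000, protection = wt_prot,
                     seed = 300 + i, site_names = names(sites)))
ko <- lapply(1:3, function(i)
  generate_endcounts(4000, sites, coverage = 3000, protection = ko_prot,
                     seed = 400 + i, site_names = names(sites)))

out <- compare_meth(wt, ko)
out$mean_wt <- round(out$mean_wt, 3)
out$mean_ko <- round(out$mean_ko, 3)
out$p <- signif(out$p, 3)
dir.create("results", showWarnings = FALSE)
write.table(out, "results/rms_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Methylation scores, WT vs KO (n = 3 replicates each):\n")
print(out, row.names = FALSE)
cat("\nThe configured protection drop (0.95 -> 0.70) at", names(sites)[1],
    "is recovered;\nunchanged sites stay concordant between genotypes.\n")
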