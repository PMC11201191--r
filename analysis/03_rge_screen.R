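#!/usr/bin/env Rscript
# Stage 3: gene-environment correlation screen.
#
# The moderated-regression framework needs parental education to be
# exogenous with respect to the genotypes. Each SNP (and the CGS) is
# tested for Pearson correlation with PE; SNPs significant at 0.05 are
# excluded and the CGS is recomputed on the retained panel.

suppressPackageStartupMessages(library(gxecross))

geno <- read_dosage_raw("results/cohort/dosages.raw")
pheno <- read_phenotypes("results/cohort/phenotypes.csv")
cohort <- gxe_cohort(pheno, geno$dosages)

scr <- screen_panel(cohort, alpha = 0.05)
print(scr$results, digits = 3)
cat("\nretained SNPs:", length(scr$retained), "of", ncol(cohort$dosages), "\n")
excl <- scr$results$label[scr$results$excluded & scr$results$label != "CGS"]
if (length(excl)) cat("excluded for rGE:", paste(excl, collapse = ", "), "\n")

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
write.table(scr$results, "results/tables/rge_screen.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(scr$retained, "results/tables/retained_snps.txt")
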