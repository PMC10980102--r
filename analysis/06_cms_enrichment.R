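#!/usr/bin/env Rscript
# Subtype enrichment of the causal genes: dichotomize each causal gene's
# log2 expression at the all-sample median into beneficial / non-beneficial
# (by the sign of its causal effect on the hazard) and call a subtype
# enriched when strictly more than 70% of its patients fall on one side.

suppressPackageStartupMessages(library(survMR))

disc <- readRDS("scratch/discovery_run.rds")
dat <- "results/data"
clin <- read_clinical_tsv(file.path(dat, "discovery_clinical.tsv"))

if (is.null(disc$causal) || !nrow(disc$causal)) {
  cat("no causal genes: nothing to enrich\n")
} else {
  cms <- clin$cms[match(colnames(disc$prep$E$values), clin$sample_id)]
  enr <- enrich_causal_genes(disc$prep$E, disc$causal, cms)
  utils::write.table(enr, "results/cms_enrichment.tsv", sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cat("enriched (gene, subtype, category) calls (> 70% rule):\n")
  print(enr[enr$enriched, c("gene_id", "subtype", "category", "rate",
                            "n_subtype")])
  cat("full rate table written to results/cms_enrichment.tsv\n")
}
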