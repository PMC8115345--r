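#!/usr/bin/env Rscript
# Generate the synthetic study cohort every later stage analyzes:
# a male time course (soma + FGCs at weeks 6/17/24) with planted
# promoter NDRs, demethylating/residual tiles, ICR-like intervals and a
# matched expression table. Ground truth is serialized next to the data.

library(scnome)

cohort_dir <- "results/cohort"
unlink(cohort_dir, recursive = TRUE)
co <- simulate_cohort(sim_config(seed = 1L), cohort_dir)

cat("cohort written to", cohort_dir, "\n")
cat(" cells:", nrow(co$manifest), "(", sum(co$manifest$assay == "scbs"),
    "scBS +", sum(co$manifest$assay == "cool"), "scCOOL )\n")
cat(" genome:", sum(chrom_sizes(co$sim$genome)), "bp on",
    length(co$sim$genome), "chromosomes;", nrow(co$sim$tss), "genes\n")
cat(" planted open promoters per group:\n")
for (g in names(co$truth$open_genes))
  cat("   ", g, ":", length(co$truth$open_genes[[g]]), "genes\n")
cat(" planted demethylating tiles:", length(co$truth$demeth_tiles),
    "| residual tiles:", length(co$truth$residual_tiles), "\n")
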