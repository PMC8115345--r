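#!/usr/bin/env Rscript
# Cell-to-cell heterogeneity: chi-squared lower-bound variance of DNA
# methylation (3000/600-bp windows, scBS cells) and chromatin
# accessibility (200/100-bp windows, scCOOL cells) per group, summarized
# by genomic element class.

library(scnome)

cfg <- analysis_config()
man <- read_manifest("results/cohort/manifest.tsv")
genome <- Biostrings::readDNAStringSet("results/cohort/genome.fa")
sizes <- chrom_sizes(genome)

scbs <- man[man$assay == "scbs", ]
cool <- man[man$assay == "cool", ]
read_group <- function(m) lapply(m$path, read_site_calls)

mv <- do.call(rbind, lapply(split(scbs, scbs$group), function(m)
  methylation_variance(read_group(m), cfg, sizes, group = m$group[1],
                       class = "CpG")))
av <- do.call(rbind, lapply(split(cool, cool$group), function(m)
  accessibility_variance(read_group(m), cfg, sizes, group = m$group[1])))
write.table(mv, "results/tables/meth_variance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(av, "results/tables/acc_variance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("median methylation variance lower bound per group:\n")
print(round(tapply(mv$var_lower, mv$group, median), 5))
cat("(early, residually methylated FGCs vary most cell-to-cell)\n\n")

ann_files <- list.files("results/cohort/annotations", "\\.bed$",
                        full.names = TRUE)
annotations <- lapply(setNames(ann_files,
                               sub("\\.bed$", "", basename(ann_files))),
                      read_bed)
ve <- rbind(
  cbind(suppressWarnings(variance_by_element(mv, annotations)),
        modality = "methylation"),
  cbind(suppressWarnings(variance_by_element(av, annotations)),
        modality = "accessibility"))
write.table(ve, "results/tables/variance_by_element.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("variance by genomic element (median lower bound):\n")
print(ve[, c("modality", "class", "n_windows", "median")],
      row.names = FALSE)
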