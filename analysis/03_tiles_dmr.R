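#!/usr/bin/env Rscript
# Tile-based methylomes: the clustering tile matrix, differential
# methylation between consecutive groups, the residual-methylation
# screen, hypergeometric enrichment of demethylated tiles, and ICR
# profiles.

library(scnome)

cfg <- analysis_config()
man <- read_manifest("results/cohort/manifest.tsv")
scbs <- man[man$assay == "scbs", ]
calls <- lapply(setNames(scbs$path, scbs$cell_id), read_site_calls)
genome <- Biostrings::readDNAStringSet("results/cohort/genome.fa")
sizes <- chrom_sizes(genome)

tm <- build_tile_matrix(calls, class = "CpG", cfg = cfg,
                        chrom_sizes = sizes)
write_tile_matrix(tm$values[, tm$retained, drop = FALSE],
                  "results/tables/tile_matrix.tsv")
cat(sum(tm$retained), "of", length(tm$retained),
    "tiles covered in >70% of cells (clustering export)\n")

groups <- split(scbs$cell_id, scbs$group)
ord <- c("male.week06.mitotic", "male.week17.mitotic_arrest",
         "male.week24.mitotic_arrest", "male.week17.soma")
dmr_all <- list()
for (i in seq_len(length(ord) - 1L)) {
  a <- ord[i]; b <- ord[i + 1L]
  d <- call_dmrs(tm$values[groups[[a]], ], tm$values[groups[[b]], ], cfg)
  d$comparison <- paste(a, "->", b)
  dmr_all[[i]] <- d
  cat(sprintf("%s -> %s: %d demethylated, %d de novo of %d tiles\n",
              a, b, sum(d$call == "demethylated"),
              sum(d$call == "de_novo"), nrow(d)))
}
dmr <- do.call(rbind, dmr_all)
write.table(dmr, "results/tables/dmr.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# residual methylation across the FGC stages
fgc_mats <- lapply(ord[1:3], function(g) tm$values[groups[[g]], ])
res <- residual_tiles(fgc_mats, cfg$residual_level, cfg$dmr_min_cell_frac)
writeLines(res, "results/tables/residual_tiles.txt")
cat(length(res), "tiles stay at methylation >= 0.4 across all FGC stages\n")

# enrichment of week6->week17 demethylated tiles in repeat families
ann_files <- list.files("results/cohort/annotations", "\\.bed$",
                        full.names = TRUE)
annotations <- lapply(setNames(ann_files,
                               sub("\\.bed$", "", basename(ann_files))),
                      read_bed)
d1 <- dmr_all[[1]]
bg <- scnome:::parse_interval_id(d1$tile)
cand <- scnome:::parse_interval_id(d1$tile[d1$call == "demethylated"])
enr <- do.call(rbind, lapply(names(annotations), function(a) {
  e <- hypergeom_enrichment(cand, bg, annotations[[a]])
  e$annotation <- a
  e
}))
write.table(enr, "results/tables/demeth_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\ndemethylated-tile enrichment (fold, p) by annotation:\n")
print(enr[order(enr$p), c("annotation", "k", "n", "fold", "p")],
      row.names = FALSE)

# ICR profile: demethylated in FGCs, ~0.5 in soma
icr <- annotations$icr
prof <- icr_profile(lapply(groups, function(ids) calls[ids]), icr,
                    class = "CpG")
write.table(data.frame(icr = rownames(prof), prof, check.names = FALSE),
            "results/tables/icr_profile.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nmean ICR methylation per group:\n")
print(round(colMeans(prof, na.rm = TRUE), 3))
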