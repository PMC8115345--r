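#!/usr/bin/env Rscript
# Three-omics integration: promoter CpG-density classes, promoter
# methylation/accessibility signals per group, Spearman correlations
# among expression, methylation and accessibility per class, and the
# phase-specific gene screen (expression vs proximal-NDR openness).

library(scnome)

cfg <- analysis_config()
man <- read_manifest("results/cohort/manifest.tsv")
cool <- man[man$assay == "cool", ]
calls <- lapply(setNames(cool$path, cool$cell_id), read_site_calls)
genome <- Biostrings::readDNAStringSet("results/cohort/genome.fa")
names(genome) <- sub("\\s.*", "", names(genome))
sizes <- chrom_sizes(genome)
tss <- read_tss("results/cohort/tss.tsv")
expr <- read_expression("results/cohort/expression.tsv")
truth <- jsonlite::read_json("results/cohort/truth.json",
                             simplifyVector = TRUE)

cls <- classify_promoters(genome, tss, cfg)
cat("promoter classes:", paste(names(table(cls$class)),
                               table(cls$class), collapse = ", "), "\n")
write.table(cls, "results/tables/promoter_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

groups <- lapply(split(cool$cell_id, cool$group),
                 function(ids) calls[ids])
sig <- promoter_signals(groups, tss, cfg, sizes)
write.table(sig, "results/tables/promoter_signals.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

rho <- do.call(rbind, lapply(intersect(names(groups), colnames(expr)),
                             function(g) {
  r <- suppressWarnings(
    omics_correlation(sig[sig$group == g, ], expr[, g], cls))
  r$group <- g
  r
}))
write.table(rho, "results/tables/promoter_omics_rho.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nexpression vs promoter accessibility (Spearman rho) by class:\n")
print(rho[, c("group", "class", "n_genes", "rho_expr_acc",
              "rho_expr_meth")], row.names = FALSE)

# phase-specific genes: pooled NDR openness tracking expression
ndr_files <- list.files("results/ndr", "\\.bed$", full.names = TRUE)
ndrs <- do.call(rbind, lapply(ndr_files, function(f) {
  nd <- read_bed(f)
  names(nd)[7:9] <- c("pooled_level", "log10_p", "class")
  nd
}))
prox <- scnome:::merge_intervals(
  ndrs[ndrs$class == "proximal", c("chrom", "start", "end")])
screen <- phase_specific_genes(prox, groups, expr, tss, cfg)
write.table(screen, "results/tables/phase_specific_genes.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
truth_genes <- unlist(truth$open_genes, use.names = FALSE)
sel <- unique(screen$gene[screen$selected])
cat(sprintf("\n%d of %d (gene, proximal NDR) pairs selected at r > %.1f\n",
            sum(screen$selected), nrow(screen), cfg$corr_r))
cat(sprintf("truth-open genes recovered: %d/%d; truth-closed controls selected: %d\n",
            length(intersect(sel, truth_genes)), length(truth_genes),
            length(intersect(sel, truth$closed_genes))))
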