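#!/usr/bin/env Rscript
# Nucleosome-depleted regions: per-group pooled GCH tracks, the
# sliding-window chi-square caller, proximal/distal classification,
# differential openness between groups, recovery against planted truth,
# and open-chromatin enrichment by genomic element.

library(scnome)

cfg <- analysis_config()
man <- read_manifest("results/cohort/manifest.tsv")
cool <- man[man$assay == "cool", ]
calls <- lapply(setNames(cool$path, cool$cell_id), read_site_calls)
genome <- Biostrings::readDNAStringSet("results/cohort/genome.fa")
sizes <- chrom_sizes(genome)
tss <- read_tss("results/cohort/tss.tsv")
truth <- jsonlite::read_json("results/cohort/truth.json",
                             simplifyVector = TRUE)

groups <- split(cool$cell_id, cool$group)
dir.create("results/ndr", showWarnings = FALSE, recursive = TRUE)
ndrs <- list()
for (g in names(groups)) {
  tr <- pool_group(calls[groups[[g]]], "GCH", group = g)
  nd <- classify_ndrs(call_ndrs(tr, cfg, sizes), tss, cfg$proximal_radius)
  ndrs[[g]] <- nd
  write_bed(nd[, c("chrom", "start", "end", "n_gch", "pooled_level",
                   "log10_p", "class")],
            file.path("results/ndr", paste0(g, ".bed")),
            score_field = "n_gch")
  tr_truth <- as.data.frame(truth$ndr_truth[[g]])
  rec <- evaluate_recovery(nd, tr_truth, 0.5)
  cat(sprintf("%s: %d NDRs (%d proximal); recall %.2f, precision %.2f vs %d planted\n",
              g, nrow(nd), sum(nd$class == "proximal"),
              rec$recall, rec$precision, rec$n_truth))
}

# differential openness between FGC phases and vs soma
pairs <- rbind(
  c("male.week06.mitotic", "male.week17.mitotic_arrest"),
  c("male.week17.mitotic_arrest", "male.week24.mitotic_arrest"),
  c("male.week24.mitotic_arrest", "male.week17.soma"))
do_all <- list()
for (i in seq_len(nrow(pairs))) {
  a <- pairs[i, 1]; b <- pairs[i, 2]
  reg <- scnome:::merge_intervals(
    rbind(ndrs[[a]][, c("chrom", "start", "end")],
          ndrs[[b]][, c("chrom", "start", "end")]))
  d <- differential_open(reg, calls[groups[[a]]], calls[groups[[b]]], cfg)
  d$comparison <- paste(a, "->", b)
  do_all[[i]] <- d
  cat(sprintf("%s -> %s: %d of %d union NDRs differentially open\n",
              a, b, sum(d$called), nrow(d)))
}
write.table(do.call(rbind, do_all), "results/tables/diffopen.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# open-chromatin enrichment by element class, per group
ann_files <- list.files("results/cohort/annotations", "\\.bed$",
                        full.names = TRUE)
annotations <- lapply(setNames(ann_files,
                               sub("\\.bed$", "", basename(ann_files))),
                      read_bed)
enr <- do.call(rbind, lapply(names(ndrs), function(g) {
  e <- open_enrichment(ndrs[[g]], annotations, sum(sizes))
  e$group <- g
  e
}))
write.table(enr, "results/tables/open_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nopen chromatin concentrates at promoters/CGIs (log2 enrichment):\n")
print(enr[enr$class %in% c("promoters", "cgi"),
          c("group", "class", "enrichment")], row.names = FALSE)
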