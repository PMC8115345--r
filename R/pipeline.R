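# End-to-end driver chaining every stage over a cohort directory.

#' Run the full downstream analysis over a cohort directory
#'
#' `data_dir` must contain `genome.fa`, `tss.tsv`, `annotations/*.bed`,
#' `expression.tsv`, `manifest.tsv` and `cell_stats.tsv` (the layout
#' written by [simulate_cohort()], or the same files prepared from real
#' calls). Stages, in order: library QC; tile matrix (scBS cells);
#' per-group NDR calling and proximal/distal classification (scCOOL
#' cells); differential openness between consecutive groups; differential
#' methylation between consecutive groups; annotation enrichment
#' (hypergeometric for demethylated tiles, base-level log2 for open
#' chromatin); residual-methylation tiles and ICR profile; promoter
#' classification, three-omics correlation and the phase-specific gene
#' screen; methylation and accessibility variance tracks with per-element
#' summaries. Every threshold used is logged to `config.log`.
#'
#' @param data_dir cohort directory.
#' @param out_dir result directory (created).
#' @param cfg an [analysis_config()]. For small synthetic genomes the QC
#'   site-count thresholds must be rescaled to the genome (e.g.
#'   `qc_scbs_min_cpg = 1000`).
#' @return invisibly, a list of the main in-memory results.
#' @export
run_pipeline <- function(data_dir, out_dir, cfg = analysis_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  need <- c("genome.fa", "tss.tsv", "expression.tsv", "manifest.tsv",
            "cell_stats.tsv")
  for (f in need)
    if (!file.exists(file.path(data_dir, f)))
      stop("missing input file: ", file.path(data_dir, f))
  write_config(cfg, file.path(out_dir, "config.log"))
  genome <- Biostrings::readDNAStringSet(file.path(data_dir, "genome.fa"))
  names(genome) <- sub("\\s.*", "", names(genome))
  sizes <- chrom_sizes(genome)
  tss <- read_tss(file.path(data_dir, "tss.tsv"))
  expr <- read_expression(file.path(data_dir, "expression.tsv"))
  manifest <- read_manifest(file.path(data_dir, "manifest.tsv"))
  ann_files <- list.files(file.path(data_dir, "annotations"),
                          pattern = "\\.bed$", full.names = TRUE)
  annotations <- lapply(stats::setNames(
    ann_files, sub("\\.bed$", "", basename(ann_files))), read_bed)
  # ---- stage 1: QC -------------------------------------------------
  stats_tbl <- as.data.frame(data.table::fread(
    file.path(data_dir, "cell_stats.tsv")))
  qc <- qc_filter(stats_tbl, cfg)
  data.table::fwrite(qc, file.path(out_dir, "qc_report.tsv"), sep = "\t")
  manifest <- manifest[manifest$cell_id %in% qc$cell_id[qc$pass], ,
                       drop = FALSE]
  if (nrow(manifest) == 0L) stop("no cells pass QC")
  miss <- manifest$cell_id[!file.exists(manifest$path)]
  if (length(miss)) stop("missing call table for cell: ", miss[1])
  calls <- lapply(stats::setNames(manifest$path, manifest$cell_id),
                  read_site_calls)
  scbs <- manifest[manifest$assay == "scbs", ]
  cool <- manifest[manifest$assay == "cool", ]
  # order cell groups for "consecutive" comparisons: FGC phases by week
  # first, then somatic groups (so phase transitions and the FGC-vs-soma
  # contrast are each compared)
  groups <- unique(manifest[, c("sex", "week", "phase", "group")])
  is_fgc_grp <- vapply(groups$group, function(g) {
    ids <- manifest$cell_id[manifest$group == g]
    any(qc$is_fgc[qc$cell_id %in% ids])
  }, logical(1))
  groups <- groups[order(!is_fgc_grp, groups$week, groups$phase), ,
                   drop = FALSE]
  by_group <- function(m) split(m$cell_id, m$group)
  scbs_groups <- by_group(scbs); cool_groups <- by_group(cool)
  # ---- stage 2: tile matrix (scBS, CpG context) --------------------
  tm <- build_tile_matrix(calls[scbs$cell_id], class = "CpG", cfg = cfg,
                          chrom_sizes = sizes)
  write_tile_matrix(tm$values[, tm$retained, drop = FALSE],
                    file.path(out_dir, "tile_matrix.tsv"))
  # ---- stage 3: NDRs per group (scCOOL) ----------------------------
  dir.create(file.path(out_dir, "ndr"), showWarnings = FALSE)
  ndrs <- list()
  for (g in names(cool_groups)) {
    track <- pool_group(calls[cool_groups[[g]]], class = "GCH", group = g)
    nd <- call_ndrs(track, cfg, sizes)
    nd <- classify_ndrs(nd, tss, cfg$proximal_radius)
    ndrs[[g]] <- nd
    write_bed(nd[, c("chrom", "start", "end", "n_gch", "pooled_level",
                     "log10_p", "class")],
              file.path(out_dir, "ndr", paste0(g, ".bed")),
              score_field = "n_gch")
  }
  all_ndrs <- do.call(rbind, unname(ndrs))
  data.table::fwrite(all_ndrs, file.path(out_dir, "ndr_all.tsv"),
                     sep = "\t")
  # ---- stage 4: differential openness (consecutive groups) ---------
  pairs <- if (nrow(groups) >= 2L)
    data.frame(a = groups$group[-nrow(groups)], b = groups$group[-1L],
               stringsAsFactors = FALSE) else NULL
  do_res <- list()
  for (i in seq_len(NROW(pairs))) {
    a <- pairs$a[i]; b <- pairs$b[i]
    if (is.null(ndrs[[a]]) || is.null(ndrs[[b]])) next
    reg <- rbind(ndrs[[a]][, c("chrom", "start", "end")],
                 ndrs[[b]][, c("chrom", "start", "end")])
    if (nrow(reg) == 0L) next
    reg <- merge_intervals(reg)
    d <- differential_open(reg, calls[cool_groups[[a]]],
                           calls[cool_groups[[b]]], cfg)
    d$group_a <- a; d$group_b <- b
    do_res[[paste(a, b)]] <- d
  }
  diffopen <- data.table::rbindlist(do_res)
  data.table::fwrite(diffopen, file.path(out_dir, "diffopen.tsv"),
                     sep = "\t")
  # ---- stage 5: DMRs between consecutive groups (scBS) -------------
  dmr_res <- list()
  for (i in seq_len(NROW(pairs))) {
    a <- pairs$a[i]; b <- pairs$b[i]
    ma <- tm$values[intersect(rownames(tm$values), scbs_groups[[a]]), ,
                    drop = FALSE]
    mb <- tm$values[intersect(rownames(tm$values), scbs_groups[[b]]), ,
                    drop = FALSE]
    if (nrow(ma) < 2L || nrow(mb) < 2L) next
    d <- call_dmrs(ma, mb, cfg)
    if (nrow(d)) { d$group_former <- a; d$group_latter <- b }
    dmr_res[[paste(a, b)]] <- d
  }
  dmrs <- data.table::rbindlist(dmr_res, fill = TRUE)
  data.table::fwrite(dmrs, file.path(out_dir, "dmr.tsv"), sep = "\t")
  # ---- stage 6: enrichment -----------------------------------------
  genome_bases <- sum(sizes)
  oe <- list()
  for (g in names(ndrs))
    if (nrow(ndrs[[g]])) {
      e <- open_enrichment(ndrs[[g]], annotations, genome_bases)
      e$group <- g
      oe[[g]] <- e
    }
  data.table::fwrite(data.table::rbindlist(oe),
                     file.path(out_dir, "open_enrichment.tsv"), sep = "\t")
  he <- list()
  if (nrow(dmrs) && any(dmrs$call == "demethylated")) {
    for (i in seq_len(NROW(pairs))) {
      key <- paste(pairs$a[i], pairs$b[i])
      d <- dmr_res[[key]]
      if (is.null(d) || !nrow(d)) next
      bg <- parse_interval_id(d$tile)
      cand <- parse_interval_id(d$tile[d$call == "demethylated"])
      if (nrow(cand) == 0L) next
      for (a in names(annotations)) {
        h <- hypergeom_enrichment(cand, bg, annotations[[a]])
        h$annotation <- a; h$comparison <- key
        he[[paste(key, a)]] <- h
      }
    }
  }
  data.table::fwrite(data.table::rbindlist(he),
                     file.path(out_dir, "demeth_enrichment.tsv"),
                     sep = "\t")
  # ---- stage 7: residual tiles and ICR profile ---------------------
  fgc_ids <- qc$cell_id[qc$pass & qc$is_fgc]
  fgc_groups <- scbs_groups[vapply(scbs_groups, function(x)
    all(x %in% fgc_ids), logical(1))]
  residual <- character(0)
  if (length(fgc_groups) >= 2L) {
    mats <- lapply(fgc_groups, function(idx)
      tm$values[idx, , drop = FALSE])
    residual <- residual_tiles(mats, cfg$residual_level,
                               cfg$dmr_min_cell_frac)
  }
  writeLines(residual, file.path(out_dir, "residual_tiles.txt"))
  if (!is.null(annotations$icr)) {
    icr_mat <- icr_profile(lapply(scbs_groups, function(idx) calls[idx]),
                           annotations$icr, class = "CpG")
    data.table::fwrite(data.table::as.data.table(icr_mat,
                                                 keep.rownames = "icr"),
                       file.path(out_dir, "icr_profile.tsv"), sep = "\t")
  }
  # ---- stage 8: promoter classes, correlations, gene screen --------
  prom_cls <- classify_promoters(genome, tss, cfg)
  data.table::fwrite(prom_cls, file.path(out_dir, "promoter_classes.tsv"),
                     sep = "\t")
  cool_group_calls <- lapply(cool_groups, function(idx) calls[idx])
  signals <- promoter_signals(cool_group_calls, tss, cfg, sizes)
  data.table::fwrite(signals, file.path(out_dir, "promoter_signals.tsv"),
                     sep = "\t")
  rho <- list()
  for (g in intersect(names(cool_group_calls), colnames(expr))) {
    s <- signals[signals$group == g, ]
    r <- omics_correlation(s, expr[, g], prom_cls)
    r$group <- g
    rho[[g]] <- r
  }
  data.table::fwrite(data.table::rbindlist(rho),
                     file.path(out_dir, "promoter_omics_rho.tsv"),
                     sep = "\t")
  screen <- NULL
  prox <- all_ndrs[all_ndrs$class == "proximal", , drop = FALSE]
  if (length(cool_group_calls) >= 3L && nrow(prox)) {
    prox_u <- merge_intervals(prox)
    screen <- phase_specific_genes(
      prox_u, cool_group_calls[intersect(names(cool_group_calls),
                                         colnames(expr))],
      expr, tss, cfg)
    data.table::fwrite(screen,
                       file.path(out_dir, "phase_specific_genes.tsv"),
                       sep = "\t")
  }
  # ---- stage 9: variance -------------------------------------------
  mv <- list(); av <- list()
  for (g in names(scbs_groups))
    mv[[g]] <- methylation_variance(calls[scbs_groups[[g]]], cfg, sizes,
                                    group = g, class = "CpG")
  for (g in names(cool_groups))
    av[[g]] <- accessibility_variance(calls[cool_groups[[g]]], cfg, sizes,
                                      group = g)
  mv <- data.table::rbindlist(mv); av <- data.table::rbindlist(av)
  data.table::fwrite(mv, file.path(out_dir, "meth_variance.tsv"),
                     sep = "\t")
  data.table::fwrite(av, file.path(out_dir, "acc_variance.tsv"),
                     sep = "\t")
  var_ann <- c(annotations[intersect(c("promoters", "cgi"),
                                     names(annotations))],
               list(proximal_ndr = prox,
                    distal_ndr = all_ndrs[all_ndrs$class == "distal", ,
                                          drop = FALSE]))
  ve <- list()
  if (nrow(mv)) {
    v <- suppressWarnings(variance_by_element(as.data.frame(mv), var_ann))
    if (nrow(v)) { v$modality <- "methylation"; ve$meth <- v }
  }
  if (nrow(av)) {
    v <- suppressWarnings(variance_by_element(as.data.frame(av), var_ann))
    if (nrow(v)) { v$modality <- "accessibility"; ve$acc <- v }
  }
  data.table::fwrite(data.table::rbindlist(ve),
                     file.path(out_dir, "variance_by_element.tsv"),
                     sep = "\t")
  invisible(list(qc = qc, tile_matrix = tm, ndrs = ndrs,
                 diffopen = as.data.frame(diffopen),
                 dmrs = as.data.frame(dmrs), residual = residual,
                 promoter_classes = prom_cls, screen = screen,
                 meth_variance = as.data.frame(mv),
                 acc_variance = as.data.frame(av)))
}
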