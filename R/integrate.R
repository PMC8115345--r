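# Promoter CpG-density classes, promoter-window signals, three-omics
# correlation, and the phase-specific gene screen linking expression to
# proximal-NDR openness.

#' Strand-oriented promoter windows
#'
#' For a plus-strand gene the window is `[TSS - up, TSS + down)`; for a
#' minus-strand gene upstream lies at higher coordinates and the window is
#' `[TSS - down + 1, TSS + up + 1)`. Windows are truncated at chromosome
#' ends with a warning.
#'
#' @param tss TSS table (`gene`, `chrom`, `tss`, `strand`).
#' @param up,down upstream/downstream extents in bp.
#' @param chrom_sizes named vector of chromosome lengths (optional; used
#'   for truncation).
#' @return interval data.frame with `gene`.
#' @export
promoter_windows <- function(tss, up, down, chrom_sizes = NULL) {
  plus <- tss$strand == "+"
  start <- ifelse(plus, tss$tss - up, tss$tss - down + 1L)
  end <- ifelse(plus, tss$tss + down, tss$tss + up + 1L)
  if (any(start < 0)) {
    warning("promoter window truncated at chromosome start")
    start <- pmax(start, 0L)
  }
  if (!is.null(chrom_sizes)) {
    lim <- unname(chrom_sizes[tss$chrom])
    if (any(end > lim)) warning("promoter window truncated at chromosome end")
    end <- pmin(end, lim)
  }
  data.frame(gene = tss$gene, chrom = tss$chrom,
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Classify promoters by CpG density (HCP / ICP / LCP)
#'
#' Weber-style criteria over the promoter window `[TSS-1000, TSS+500)`
#' (strand-oriented): a promoter is HCP when some 500-bp subwindow has
#' CpG observed/expected ratio > 0.75 *and* GC fraction > 0.55; LCP when
#' no subwindow exceeds observed/expected 0.48; ICP otherwise. The
#' observed/expected ratio is `nCpG / (nC * nG / L)`; subwindows slide
#' 1 bp. CpG density is strand-symmetric so the plus-strand sequence is
#' scanned for all genes.
#'
#' @param genome named character vector or [Biostrings::DNAStringSet].
#' @param tss TSS table.
#' @param cfg an [analysis_config()].
#' @return data.frame `gene`, `class`.
#' @export
classify_promoters <- function(genome, tss, cfg = analysis_config()) {
  if (inherits(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  win <- promoter_windows(tss, cfg$prom_meth_up, cfg$prom_meth_down,
                          chrom_sizes(genome))
  cls <- vapply(seq_len(nrow(win)), function(i) {
    s <- substr(genome[[win$chrom[i]]], win$start[i] + 1L, win$end[i])
    promoter_class_scan(s, cfg$prom_subwindow, cfg$hcp_obs_exp,
                        cfg$hcp_gc, cfg$lcp_obs_exp)
  }, "")
  data.frame(gene = win$gene, class = cls, stringsAsFactors = FALSE)
}

# Scan all subwindows of one promoter sequence; cumulative sums make the
# 1-bp slide cheap.
promoter_class_scan <- function(s, subwin, hcp_oe, hcp_gc, lcp_oe) {
  b <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  L <- length(b)
  w <- min(subwin, L)
  isC <- as.integer(b == "C")
  isG <- as.integer(b == "G")
  cpg <- as.integer(b == "C" & c(b[-1], "") == "G")  # CpG starting here
  csC <- c(0L, cumsum(isC)); csG <- c(0L, cumsum(isG))
  csP <- c(0L, cumsum(cpg))
  starts <- seq_len(L - w + 1L)
  nC <- csC[starts + w] - csC[starts]
  nG <- csG[starts + w] - csG[starts]
  # a CpG must start inside the subwindow and end inside it
  nP <- csP[pmin(starts + w - 1L, L)] - csP[starts]
  exp <- nC * nG / w
  oe <- ifelse(exp > 0, nP / exp, 0)
  gc <- (nC + nG) / w
  if (any(oe > hcp_oe & gc > hcp_gc)) "HCP"
  else if (!any(oe > lcp_oe)) "LCP"
  else "ICP"
}

#' Promoter methylation and accessibility signals per cell group
#'
#' Per gene and group: the mean of per-site pooled WCG levels over
#' `[TSS-1000, TSS+500)` (methylation) and of pooled GCH levels over
#' `[TSS-200, TSS+100)` (accessibility), both strand-oriented; `NA` when
#' no site is covered.
#'
#' @param groups named list of cell-call-table lists.
#' @param tss TSS table.
#' @param cfg an [analysis_config()].
#' @param chrom_sizes optional, for window truncation.
#' @param meth_class context class for methylation (default `"WCG"`).
#' @return data.frame `gene`, `group`, `meth_level`, `acc_level`.
#' @export
promoter_signals <- function(groups, tss, cfg = analysis_config(),
                             chrom_sizes = NULL, meth_class = "WCG") {
  mw <- promoter_windows(tss, cfg$prom_meth_up, cfg$prom_meth_down,
                         chrom_sizes)
  aw <- promoter_windows(tss, cfg$prom_acc_up, cfg$prom_acc_down,
                         chrom_sizes)
  out <- lapply(names(groups), function(g) {
    pm <- pool_group(groups[[g]], class = meth_class, group = g)
    pa <- pool_group(groups[[g]], class = "GCH", group = g)
    data.frame(gene = tss$gene, group = g,
               meth_level = as.numeric(
                 aggregate_region(pm, mw, class = meth_class)),
               acc_level = as.numeric(
                 aggregate_region(pa, aw, class = "GCH")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Spearman correlation among expression, promoter methylation and
#' promoter accessibility, per promoter class
#'
#' @param signals data.frame `gene`, `meth_level`, `acc_level` for one
#'   cell group.
#' @param expression named numeric vector of expression per gene (same
#'   group).
#' @param classes data.frame `gene`, `class` from [classify_promoters()].
#' @return data.frame per class: `n_genes`, `rho_expr_meth`,
#'   `rho_expr_acc`, `rho_meth_acc` (`NA` with a warning when fewer than
#'   3 complete genes, or when a signal is constant).
#' @export
omics_correlation <- function(signals, expression, classes) {
  df <- merge(signals, classes, by = "gene")
  df$expr <- unname(expression[df$gene])
  res <- lapply(split(df, df$class), function(d) {
    d <- d[stats::complete.cases(d[, c("expr", "meth_level",
                                       "acc_level")]), ]
    if (nrow(d) < 3L) {
      warning("fewer than 3 complete genes in a promoter class")
      return(data.frame(class = d$class[1] %||% NA_character_,
                        n_genes = nrow(d), rho_expr_meth = NA_real_,
                        rho_expr_acc = NA_real_, rho_meth_acc = NA_real_))
    }
    srho <- function(a, b) {
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      stats::cor(a, b, method = "spearman")
    }
    data.frame(class = d$class[1], n_genes = nrow(d),
               rho_expr_meth = srho(d$expr, d$meth_level),
               rho_expr_acc = srho(d$expr, d$acc_level),
               rho_meth_acc = srho(d$meth_level, d$acc_level),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Assign proximal NDRs to their nearest gene
#'
#' Nearest TSS by center distance, within `proximal_radius`; ties broken
#' by the lexicographically smaller gene id. NDRs with no TSS in range
#' are dropped.
#' @param ndrs NDR data.frame.
#' @param tss TSS table.
#' @param proximal_radius bp (inclusive).
#' @return `ndrs` with `gene` and `dist_tss` columns.
#' @export
assign_ndr_genes <- function(ndrs, tss, proximal_radius = 2000L) {
  ndrs <- as.data.frame(ndrs)
  ndrs$center <- (ndrs$start + ndrs$end) %/% 2L
  pick <- lapply(seq_len(nrow(ndrs)), function(i) {
    cand <- tss[tss$chrom == ndrs$chrom[i], ]
    if (nrow(cand) == 0L) return(NULL)
    d <- abs(cand$tss - ndrs$center[i])
    ok <- d <= proximal_radius
    if (!any(ok)) return(NULL)
    cand <- cand[ok, ]; d <- d[ok]
    best <- which(d == min(d))
    g <- sort(cand$gene[best])[1]
    data.frame(i = i, gene = g, dist_tss = min(d))
  })
  pick <- do.call(rbind, pick)
  if (is.null(pick))
    return(cbind(ndrs[0, ], gene = character(), dist_tss = numeric()))
  out <- ndrs[pick$i, , drop = FALSE]
  out$gene <- pick$gene
  out$dist_tss <- pick$dist_tss
  rownames(out) <- NULL
  out
}

#' Phase-specific genes: expression vs proximal-NDR openness
#'
#' Cells of each phase are pooled as a bulk sample; for every
#' (gene, proximal NDR) pair the Pearson correlation is computed between
#' the across-phase expression vector of the gene and the across-phase
#' pooled GCH level of the NDR. Pairs with `r` strictly above `corr_r`
#' (0.6) are selected. NDRs with accessibility missing in any phase are
#' skipped (with a message).
#'
#' @param ndrs proximal NDR data.frame (union over phases).
#' @param phases named list of cell-call-table lists, one per phase;
#'   names must match `expression` columns.
#' @param expression genes x phases matrix.
#' @param tss TSS table.
#' @param cfg an [analysis_config()].
#' @return data.frame `gene`, `chrom`, `start`, `end`, `r`, `selected`.
#' @export
phase_specific_genes <- function(ndrs, phases, expression, tss,
                                 cfg = analysis_config()) {
  stopifnot(length(phases) >= 3L,
            all(names(phases) %in% colnames(expression)))
  assigned <- assign_ndr_genes(ndrs, tss, cfg$proximal_radius)
  if (nrow(assigned) == 0L)
    return(data.frame(gene = character(), chrom = character(),
                      start = integer(), end = integer(), r = numeric(),
                      selected = logical(), stringsAsFactors = FALSE))
  acc <- vapply(names(phases), function(ph) {
    pooled <- pool_group(phases[[ph]], class = "GCH", group = ph)
    as.numeric(aggregate_region(pooled, assigned, class = "GCH"))
  }, numeric(nrow(assigned)))
  acc <- matrix(acc, nrow = nrow(assigned),
                dimnames = list(NULL, names(phases)))
  keep <- rowSums(is.na(acc)) == 0L & assigned$gene %in% rownames(expression)
  if (any(!keep))
    message(sum(!keep), " NDR(s) skipped: accessibility or expression ",
            "missing in some phase")
  assigned <- assigned[keep, , drop = FALSE]
  acc <- acc[keep, , drop = FALSE]
  r <- vapply(seq_len(nrow(assigned)), function(i) {
    e <- expression[assigned$gene[i], names(phases)]
    a <- acc[i, ]
    if (stats::sd(e) == 0 || stats::sd(a) == 0) return(NA_real_)
    stats::cor(e, a)
  }, numeric(1))
  data.frame(gene = assigned$gene, chrom = assigned$chrom,
             start = assigned$start, end = assigned$end, r = r,
             selected = !is.na(r) & r > cfg$corr_r,
             stringsAsFactors = FALSE)
}
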