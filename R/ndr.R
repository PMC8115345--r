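# Nucleosome-depleted-region (NDR) detection.
#
# Cells of a group are pooled site-by-site; open chromatin appears as
# runs of elevated GCH methylation (the GpC methyltransferase only labels
# accessible DNA). Candidate windows are scored by a one-sided chi-square
# test of the window's pooled GCH counts against the whole-genome
# background, significant windows are merged, and merged spans are
# filtered on length and GCH support.

#' Pool the GCH calls of a cell group site-by-site
#'
#' @param cell_calls list of call tables (one per cell of the group).
#' @param class context class to pool (default `"GCH"`).
#' @param group group label recorded on the track.
#' @return `data.table` with `chrom`, `pos`, `strand`, `n_meth`,
#'   `n_unmeth`, sorted; attributes `c_total`/`t_total` hold the
#'   genome-wide methylated/unmethylated totals and `group` the label.
#' @export
pool_group <- function(cell_calls, class = "GCH", group = "group") {
  stopifnot(length(cell_calls) >= 1L)
  all <- data.table::rbindlist(lapply(cell_calls, function(x)
    data.table::as.data.table(x)[context == class]))
  if (nrow(all) == 0L) {
    track <- data.table::data.table(chrom = character(), pos = integer(),
                                    strand = character(),
                                    context = character(),
                                    n_meth = integer(),
                                    n_unmeth = integer())
  } else {
    track <- all[, list(context = class, n_meth = sum(n_meth),
                        n_unmeth = sum(n_unmeth)),
                 by = list(chrom, pos, strand)]
    data.table::setorder(track, chrom, pos, strand)
  }
  data.table::setattr(track, "c_total", sum(track$n_meth))
  data.table::setattr(track, "t_total", sum(track$n_unmeth))
  data.table::setattr(track, "group", group)
  track[]
}

#' One-sided sliding-window chi-square test in log10 space
#'
#' Tests whether a window's pooled GCH methylation (methylated = protected
#' by the GpC enzyme = accessible) exceeds the whole-genome background.
#' The 2x2 table is {window C, T; genome-total C, T}; the window is not
#' subtracted from the background (it is a negligible fraction) and no
#' continuity correction is applied. If the window rate does not exceed
#' the background rate the p-value is 1. The p-value is returned as
#' log10(p) so values far below 1e-300 remain representable.
#'
#' @param c_w,t_w methylated/unmethylated counts in the window
#'   (vectorized).
#' @param c_tot,t_tot genome-wide totals (scalars).
#' @return log10 p-values (0 means p = 1).
#' @export
window_chisq <- function(c_w, t_w, c_tot, t_tot) {
  if (c_tot + t_tot <= 0) stop("background has zero reads")
  n_w <- c_w + t_w
  if (any(n_w < 1)) stop("each tested window needs >= 1 read")
  a <- as.numeric(c_w); b <- as.numeric(t_w)
  cc <- as.numeric(c_tot); d <- as.numeric(t_tot)
  rate_w <- a / (a + b)
  rate_bg <- cc / (cc + d)
  n <- a + b + cc + d
  stat <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  lp <- stats::pchisq(stat, df = 1, lower.tail = FALSE, log.p = TRUE) /
    log(10)
  lp[rate_w <= rate_bg] <- 0
  lp
}

# Per-window pooled counts via cumulative sums over sorted site positions.
# Returns data.table(start, c, t, n_sites) for windows with >= 1 read.
window_counts <- function(pos, n_meth, n_unmeth, len, window, step) {
  starts <- window_starts(len, window, step)
  if (length(starts) == 0L) return(NULL)
  o <- order(pos)
  pos <- pos[o]
  csC <- c(0, cumsum(as.numeric(n_meth[o])))
  csT <- c(0, cumsum(as.numeric(n_unmeth[o])))
  lo <- findInterval(starts - 0.5, pos)
  hi <- findInterval(starts + window - 0.5, pos)
  data.table::data.table(
    start = starts,
    c = csC[hi + 1L] - csC[lo + 1L],
    t = csT[hi + 1L] - csT[lo + 1L],
    n_sites = hi - lo)
}

#' Call NDRs from a pooled GCH track
#'
#' 100-bp windows advanced in 20-bp steps (configurable) are tested with
#' [window_chisq()]; windows with p at or below `ndr_p` are significant;
#' overlapping or book-ended significant windows are merged into candidate
#' spans; candidates longer than `ndr_min_len` (strict) with at least
#' `ndr_min_gch` covered GCH sites become NDRs. Windows with zero covered
#' reads are skipped, not scored.
#'
#' @param track a [pool_group()] track.
#' @param cfg an [analysis_config()].
#' @param chrom_sizes named vector of chromosome lengths.
#' @return data.frame with `chrom`, `start`, `end`, `n_gch`,
#'   `pooled_level`, `log10_p` (most significant constituent window), and
#'   `group`.
#' @export
call_ndrs <- function(track, cfg = analysis_config(), chrom_sizes) {
  c_tot <- attr(track, "c_total"); t_tot <- attr(track, "t_total")
  group <- attr(track, "group")
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_gch = integer(),
                      pooled_level = numeric(), log10_p = numeric(),
                      group = character(), stringsAsFactors = FALSE)
  if (nrow(track) == 0L) return(empty)
  log10_thresh <- log10(cfg$ndr_p)
  sig <- list()
  for (ch in intersect(names(chrom_sizes), unique(track$chrom))) {
    tr <- track[track$chrom == ch, ]
    wc <- window_counts(tr$pos, tr$n_meth, tr$n_unmeth,
                        chrom_sizes[[ch]], cfg$ndr_window, cfg$ndr_step)
    if (is.null(wc)) next
    wc <- wc[wc$c + wc$t >= 1, ]
    if (nrow(wc) == 0L) next
    wc[, lp := window_chisq(c, t, c_tot, t_tot)]
    wc <- wc[lp <= log10_thresh]
    if (nrow(wc))
      sig[[ch]] <- data.table::data.table(
        chrom = ch, start = wc$start,
        end = pmin(wc$start + cfg$ndr_window, chrom_sizes[[ch]]),
        lp = wc$lp)
  }
  if (length(sig) == 0L) return(empty)
  sigdt <- data.table::rbindlist(sig)
  cand <- merge_intervals(sigdt)
  cand <- cand[(cand$end - cand$start) > cfg$ndr_min_len, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  # per-candidate GCH support, pooled level, and best window p
  site_gr <- GenomicRanges::GRanges(
    track$chrom, IRanges::IRanges(track$pos + 1L, track$pos + 1L))
  cand_gr <- as_granges(cand)
  hits <- GenomicRanges::findOverlaps(cand_gr, site_gr)
  q <- S4Vectors::queryHits(hits); sj <- S4Vectors::subjectHits(hits)
  n_gch <- integer(nrow(cand)); cC <- numeric(nrow(cand))
  cT <- numeric(nrow(cand))
  if (length(q)) {
    agg <- data.table::data.table(
      q = q, m = track$n_meth[sj], u = track$n_unmeth[sj])[
        , list(n = .N, m = sum(m), u = sum(u)), by = q]
    n_gch[agg$q] <- agg$n; cC[agg$q] <- agg$m; cT[agg$q] <- agg$u
  }
  whits <- GenomicRanges::findOverlaps(cand_gr, as_granges(sigdt))
  best <- rep(0, nrow(cand))
  bt <- data.table::data.table(q = S4Vectors::queryHits(whits),
                               lp = sigdt$lp[S4Vectors::subjectHits(whits)])[
                                 , list(lp = min(lp)), by = q]
  best[bt$q] <- bt$lp
  out <- data.frame(chrom = cand$chrom, start = cand$start, end = cand$end,
                    n_gch = n_gch, pooled_level = cC / (cC + cT),
                    log10_p = best, group = group %||% "group",
                    stringsAsFactors = FALSE)
  out <- out[out$n_gch >= cfg$ndr_min_gch, , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify NDRs as proximal or distal to transcription start sites
#'
#' An NDR is proximal when its center lies within `proximal_radius`
#' (default 2 kb) of any TSS, upstream or downstream; otherwise distal.
#'
#' @param ndrs NDR data.frame from [call_ndrs()].
#' @param tss TSS table (`gene`, `chrom`, `tss`, `strand`).
#' @param proximal_radius distance threshold in bp (inclusive).
#' @return `ndrs` with `center`, `dist_tss`, and
#'   `class` (`"proximal"`/`"distal"`) columns.
#' @export
classify_ndrs <- function(ndrs, tss, proximal_radius = 2000L) {
  ndrs <- as.data.frame(ndrs)
  ndrs$center <- (ndrs$start + ndrs$end) %/% 2L
  ndrs$dist_tss <- vapply(seq_len(nrow(ndrs)), function(i) {
    cand <- tss$tss[tss$chrom == ndrs$chrom[i]]
    if (length(cand) == 0L) return(Inf)
    min(abs(cand - ndrs$center[i]))
  }, numeric(1))
  ndrs$class <- ifelse(ndrs$dist_tss <= proximal_radius,
                       "proximal", "distal")
  ndrs
}

#' Differential openness between two cell groups
#'
#' For each region (typically the union of both groups' NDR calls) the
#' per-cell GCH level is computed; a region is differentially open iff
#' (i) it is covered (>= 1 GCH site) in more than `do_min_cell_frac` of
#' cells in both groups, (ii) the group means differ by more than
#' `do_min_diff`, and (iii) in exactly one group more than half of covered
#' cells are open (level >= `do_open_level`); cells at or below
#' `do_closed_level` are closed, cells in between count toward coverage
#' but neither state.
#'
#' @param regions interval data.frame.
#' @param cells_a,cells_b lists of call tables for the two groups.
#' @param cfg an [analysis_config()].
#' @return data.frame per region: coverage fractions, means, open-cell
#'   counts, `called`, `direction` (`"A_open"`/`"B_open"`) and `reason`
#'   for uncalled regions.
#' @export
differential_open <- function(regions, cells_a, cells_b,
                              cfg = analysis_config()) {
  if (length(cells_a) == 0L || length(cells_b) == 0L)
    stop("both groups need at least one cell")
  lv <- function(cells) do.call(rbind, lapply(cells, function(cl)
    as.numeric(aggregate_region(cl, regions, class = "GCH",
                                min_sites = 1L))))
  A <- lv(cells_a); B <- lv(cells_b)
  covA <- colSums(!is.na(A)); covB <- colSums(!is.na(B))
  fracA <- covA / length(cells_a); fracB <- covB / length(cells_b)
  meanA <- suppressWarnings(colMeans(A, na.rm = TRUE))
  meanB <- suppressWarnings(colMeans(B, na.rm = TRUE))
  openA <- colSums(A >= cfg$do_open_level, na.rm = TRUE)
  openB <- colSums(B >= cfg$do_open_level, na.rm = TRUE)
  majA <- openA > covA / 2; majB <- openB > covB / 2
  cov_ok <- fracA > cfg$do_min_cell_frac & fracB > cfg$do_min_cell_frac
  diff_ok <- abs(meanA - meanB) > cfg$do_min_diff
  excl_ok <- xor(majA, majB)
  called <- cov_ok & diff_ok & excl_ok
  reason <- ifelse(called, "",
                   ifelse(!cov_ok, "coverage",
                          ifelse(!diff_ok, "difference", "exclusivity")))
  data.frame(regions[, c("chrom", "start", "end")],
             frac_covered_a = fracA, frac_covered_b = fracB,
             mean_a = meanA, mean_b = meanB,
             n_open_a = openA, n_open_b = openB,
             n_covered_a = covA, n_covered_b = covB,
             called = called,
             direction = ifelse(!called, "",
                                ifelse(majA, "A_open", "B_open")),
             reason = reason, stringsAsFactors = FALSE)
}

#' Open-chromatin enrichment by genomic element class
#'
#' Per annotation class: `log2((NDR bases in class / total NDR bases) /
#' (class bases / genome bases))`, all interval sets merged before
#' counting.
#'
#' @param ndrs NDR interval data.frame.
#' @param annotation_sets named list of interval data.frames.
#' @param genome_bases total genome length.
#' @return data.frame with per-class base counts and `enrichment`
#'   (`NA` with a warning for empty classes).
#' @export
open_enrichment <- function(ndrs, annotation_sets, genome_bases) {
  ndr_bases <- interval_bases(ndrs)
  res <- lapply(names(annotation_sets), function(cls) {
    ann <- annotation_sets[[cls]]
    cls_bases <- interval_bases(ann)
    if (cls_bases == 0) {
      warning("annotation class '", cls, "' has zero bases")
      return(data.frame(class = cls, ndr_in_class = NA_real_,
                        ndr_bases = ndr_bases, class_bases = 0,
                        enrichment = NA_real_, stringsAsFactors = FALSE))
    }
    inside <- interval_intersect_bases(ndrs, ann)
    data.frame(class = cls, ndr_in_class = inside, ndr_bases = ndr_bases,
               class_bases = cls_bases,
               enrichment = log2((inside / ndr_bases) /
                                   (cls_bases / genome_bases)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Match called regions against planted truth by reciprocal overlap
#'
#' A called region matches a truth region when their intersection covers
#' at least `min_frac` of both. Used to score simulator recovery.
#'
#' @param called,truth interval data.frames.
#' @param min_frac reciprocal-overlap fraction (default 0.5).
#' @return list with `recall`, `precision`, `n_called`, `n_truth`.
#' @export
evaluate_recovery <- function(called, truth, min_frac = 0.5) {
  if (nrow(truth) == 0L)
    return(list(recall = NA_real_,
                precision = if (nrow(called)) 0 else NA_real_,
                n_called = nrow(called), n_truth = 0L))
  if (nrow(called) == 0L)
    return(list(recall = 0, precision = NA_real_, n_called = 0L,
                n_truth = nrow(truth)))
  hits <- GenomicRanges::findOverlaps(as_granges(called), as_granges(truth))
  q <- S4Vectors::queryHits(hits); sj <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    as_granges(called)[q], as_granges(truth)[sj]))
  wc <- called$end[q] - called$start[q]
  wt <- truth$end[sj] - truth$start[sj]
  good <- ov >= min_frac * wc & ov >= min_frac * wt
  list(recall = length(unique(sj[good])) / nrow(truth),
       precision = length(unique(q[good])) / nrow(called),
       n_called = nrow(called), n_truth = nrow(truth))
}
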