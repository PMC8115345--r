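# Cytosine context classification and methylation-level estimation.
#
# In NOMe-seq-style data two cytosine classes are informative:
#   WCG (ACG/TCG)      — CpG sites unambiguous for endogenous methylation
#   GCH (GCA/GCC/GCT)  — GpC sites unambiguous for enzymatic accessibility
# GCG sites are ambiguous (both a CpG and a GpC) and are classified but
# excluded from both analyses; every other cytosine is "other".

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Classify every cytosine of a genome by trinucleotide context
#'
#' A plus-strand cytosine at position `i` is classified by the trinucleotide
#' `(i-1, i, i+1)`; a minus-strand cytosine (genomic G) by the
#' reverse-complement trinucleotide. Classes: `WCG` (ACG/TCG), `GCH`
#' (GCA/GCC/GCT), `GCG`, and `other` (including CCG, non-CpG non-GpC
#' cytosines, any trinucleotide containing N, and chromosome-edge cytosines
#' with a missing neighbor). The classes partition all cytosines; `is_cpg`
#' flags the CpG superset (next base G) regardless of class.
#'
#' @param genome named character vector of sequences or a
#'   [Biostrings::DNAStringSet]. Only A/C/G/T/N are permitted.
#' @return `data.table` with `chrom`, `pos` (0-based), `strand`, `context`,
#'   `is_cpg`, sorted by (chrom, pos, strand).
#' @export
classify_contexts <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    seqs <- stats::setNames(as.character(genome), names(genome))
  } else seqs <- genome
  res <- lapply(names(seqs), function(chrom) {
    s <- strsplit(toupper(seqs[[chrom]]), "", fixed = TRUE)[[1]]
    bad <- !s %in% c("A", "C", "G", "T", "N")
    if (any(bad))
      stop("non-IUPAC character '", s[which(bad)[1]], "' in ", chrom)
    n <- length(s)
    prev <- c(NA_character_, s[-n])
    nxt <- c(s[-1], NA_character_)
    out <- list()
    ip <- which(s == "C")
    if (length(ip)) {
      out$plus <- data.table::data.table(
        chrom = chrom, pos = ip - 1L, strand = "+",
        context = classify_trinucleotide(prev[ip], nxt[ip]),
        is_cpg = !is.na(nxt[ip]) & nxt[ip] == "G")
    }
    im <- which(s == "G")
    if (length(im)) {
      # minus-strand trinucleotide read 5'->3' is revcomp(s[i-1..i+1])
      prev_m <- unname(COMPLEMENT[nxt[im]])
      nxt_m <- unname(COMPLEMENT[prev[im]])
      out$minus <- data.table::data.table(
        chrom = chrom, pos = im - 1L, strand = "-",
        context = classify_trinucleotide(prev_m, nxt_m),
        is_cpg = !is.na(nxt_m) & nxt_m == "G")
    }
    data.table::rbindlist(out)
  })
  ctx <- data.table::rbindlist(res)
  if (nrow(ctx)) data.table::setorder(ctx, chrom, pos, strand)
  ctx[]
}

# Vectorized trinucleotide rule; prev/nxt are the 5' and 3' neighbors of a
# cytosine in its own strand orientation. NA or N neighbor -> "other".
classify_trinucleotide <- function(prev, nxt) {
  cls <- rep("other", length(prev))
  ok <- !is.na(prev) & !is.na(nxt) & prev != "N" & nxt != "N"
  cpg <- ok & nxt == "G"
  cls[cpg & prev %in% c("A", "T")] <- "WCG"
  cls[cpg & prev == "G"] <- "GCG"
  cls[ok & nxt != "G" & prev == "G"] <- "GCH"
  cls
}

#' Per-site methylation levels
#'
#' Level of a covered site = methylated reads / total reads at that site.
#'
#' @param calls a call table (see [read_site_calls()]).
#' @return the table with a `level` column appended.
#' @export
site_levels <- function(calls) {
  dt <- data.table::as.data.table(calls)
  if (nrow(dt) && any(dt$n_meth < 0 | dt$n_unmeth < 0))
    stop("negative counts in call table")
  dt[, level := n_meth / (n_meth + n_unmeth)]
  dt[]
}

#' Global (single-cell) level of one cytosine class
#'
#' The unweighted mean of per-site levels over all covered sites of the
#' class — the per-cell summary used for global methylation (WCG/CpG) and
#' global accessibility (GCH).
#'
#' @param calls call table.
#' @param class context class, e.g. `"WCG"`, `"GCH"`, or `"CpG"`.
#' @return a single level in `[0, 1]`, or `NA` with a warning when no site
#'   of the class is covered.
#' @export
global_level <- function(calls, class = "WCG") {
  dt <- site_levels(calls)
  dt <- dt[context == class]
  if (nrow(dt) == 0L) {
    warning("no covered ", class, " sites; global level is NA")
    return(NA_real_)
  }
  mean(dt$level)
}

#' Mean level per fixed-size genome tile for one cell
#'
#' The genome is partitioned into contiguous `tile_size`-bp windows
#' starting at coordinate 0. A tile's level for a cell is the mean of
#' per-site levels of covered sites of the class; tiles with fewer than
#' `min_sites` covered sites are missing (dropped from the result).
#'
#' @param calls call table for one cell.
#' @param class context class.
#' @param tile_size tile width in bp.
#' @param min_sites minimum covered sites per tile (inclusive).
#' @return `data.table` with `chrom`, `start`, `end`, `n_sites`, `level`.
#' @export
aggregate_tiles <- function(calls, class = "WCG", tile_size = 500L,
                            min_sites = 3L) {
  dt <- site_levels(calls)[context == class]
  if (nrow(dt) == 0L)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), n_sites = integer(),
                                  level = numeric()))
  dt[, start := (pos %/% tile_size) * tile_size]
  agg <- dt[, list(n_sites = .N, level = mean(level)),
            by = list(chrom, start)]
  agg <- agg[n_sites >= min_sites]
  agg[, end := start + as.integer(tile_size)]
  data.table::setorder(agg, chrom, start)
  agg[, list(chrom, start, end, n_sites, level)]
}

#' Mean level per arbitrary region for one cell (or a pooled group)
#'
#' @param calls call table.
#' @param regions interval data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param class context class.
#' @param min_sites minimum covered sites for a defined level (inclusive).
#' @return numeric vector of levels aligned with `regions` rows (`NA`
#'   where below `min_sites`), with attribute `n_sites`.
#' @export
aggregate_region <- function(calls, regions, class = "GCH",
                             min_sites = 1L) {
  lev <- rep(NA_real_, nrow(regions))
  nsites <- integer(nrow(regions))
  dt <- site_levels(data.table::as.data.table(calls))[context == class]
  if (nrow(dt)) {
    sites_gr <- GenomicRanges::GRanges(
      dt$chrom, IRanges::IRanges(dt$pos + 1L, dt$pos + 1L))
    hits <- GenomicRanges::findOverlaps(as_granges(regions), sites_gr)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits)
      lv <- dt$level[S4Vectors::subjectHits(hits)]
      agg <- data.table::data.table(q = q, lv = lv)[
        , list(n = .N, m = mean(lv)), by = q]
      nsites[agg$q] <- agg$n
      lev[agg$q] <- ifelse(agg$n >= min_sites, agg$m, NA_real_)
    }
  }
  attr(lev, "n_sites") <- nsites
  lev
}

#' Cells-by-tiles level matrix across a cell group
#'
#' Builds the full cells x tiles matrix of per-cell tile levels (missing
#' entries `NA`) and the covered-cell fraction per tile. The clustering
#' export retains tiles covered in more than `cluster_min_cell_frac`
#' of cells (strict inequality).
#'
#' @param cell_calls named list of call tables (names are cell ids).
#' @param class context class.
#' @param cfg an [analysis_config()].
#' @param chrom_sizes named vector of chromosome lengths (defines the full
#'   tile universe).
#' @return list with `tiles` (data.frame chrom/start/end), `values`
#'   (cells x tiles matrix, tile ids as colnames), `covered_frac`, and
#'   `retained` (logical, the clustering filter).
#' @export
build_tile_matrix <- function(cell_calls, class = "WCG",
                              cfg = analysis_config(), chrom_sizes) {
  stopifnot(length(cell_calls) >= 2L)
  ts <- cfg$tile_size
  tiles <- data.table::rbindlist(lapply(names(chrom_sizes), function(ch) {
    starts <- seq.int(0L, chrom_sizes[[ch]] - 1L, by = ts)
    data.table::data.table(chrom = ch, start = starts,
                           end = pmin(starts + ts, chrom_sizes[[ch]]))
  }))
  ids <- interval_id(tiles$chrom, tiles$start, tiles$end)
  values <- matrix(NA_real_, nrow = length(cell_calls), ncol = nrow(tiles),
                   dimnames = list(names(cell_calls), ids))
  key <- paste(tiles$chrom, tiles$start)
  for (cell in names(cell_calls)) {
    agg <- aggregate_tiles(cell_calls[[cell]], class = class,
                           tile_size = ts, min_sites = cfg$tile_min_cpg)
    if (nrow(agg)) {
      j <- match(paste(agg$chrom, agg$start), key)
      values[cell, j[!is.na(j)]] <- agg$level[!is.na(j)]
    }
  }
  covered_frac <- colMeans(!is.na(values))
  retained <- covered_frac > cfg$cluster_min_cell_frac
  if (!any(retained)) warning("no tiles pass the clustering coverage filter")
  list(tiles = as.data.frame(tiles), values = values,
       covered_frac = covered_frac, retained = retained)
}

#' Library quality-control filter
#'
#' Applies the published library filters. scBS libraries require mapping
#' rate >= 20%, bisulfite conversion rate >= 99%, non-CpG methylation
#' <= 0.02 and more than 2 million covered CpG sites; scCOOL libraries
#' require mapping rate >= 20%, more than 1 million covered WCG sites and
#' more than 10 million covered GCH sites. FGC libraries of either assay
#' additionally require a global DNA methylation level <= 0.2 (somatic
#' cells are exempt).
#'
#' @param cell_stats data.frame with columns `cell_id`, `assay`
#'   (`scbs`/`cool`), `is_fgc` (logical), `map_rate`, `conversion`,
#'   `non_cpg_meth`, `n_cpg`, `n_wcg`, `n_gch`, `global_meth`. A missing
#'   (NA) statistic fails its criterion with reason `missing:<stat>`.
#' @param cfg an [analysis_config()] (thresholds may be rescaled for small
#'   synthetic genomes).
#' @return the table with logical criterion columns, `pass`, and a
#'   semicolon-separated `reasons` string for failures.
#' @export
qc_filter <- function(cell_stats, cfg = analysis_config()) {
  st <- as.data.frame(cell_stats)
  stopifnot(all(st$assay %in% c("scbs", "cool")))
  chk <- function(ok) ifelse(is.na(ok), FALSE, ok)
  scbs <- st$assay == "scbs"
  crit <- data.frame(row.names = seq_len(nrow(st)))
  crit$map_rate <- chk(ifelse(scbs, st$map_rate >= cfg$qc_scbs_map_rate,
                              st$map_rate >= cfg$qc_cool_map_rate))
  crit$conversion <- ifelse(scbs, chk(st$conversion >= cfg$qc_scbs_conversion),
                            TRUE)
  crit$non_cpg_meth <- ifelse(scbs, chk(st$non_cpg_meth <= cfg$qc_scbs_non_cpg),
                              TRUE)
  crit$min_cpg <- ifelse(scbs, chk(st$n_cpg > cfg$qc_scbs_min_cpg), TRUE)
  crit$min_wcg <- ifelse(!scbs, chk(st$n_wcg > cfg$qc_cool_min_wcg), TRUE)
  crit$min_gch <- ifelse(!scbs, chk(st$n_gch > cfg$qc_cool_min_gch), TRUE)
  crit$fgc_max_meth <- ifelse(st$is_fgc,
                              chk(st$global_meth <= cfg$qc_fgc_max_meth),
                              TRUE)
  # reasons: name the threshold, or missing:<stat>
  stat_for <- c(map_rate = "map_rate", conversion = "conversion",
                non_cpg_meth = "non_cpg_meth", min_cpg = "n_cpg",
                min_wcg = "n_wcg", min_gch = "n_gch",
                fgc_max_meth = "global_meth")
  reasons <- vapply(seq_len(nrow(st)), function(i) {
    fails <- names(crit)[!unlist(crit[i, ])]
    msg <- vapply(fails, function(f) {
      if (is.na(st[[stat_for[[f]]]][i])) paste0("missing:", stat_for[[f]])
      else f
    }, "")
    paste(msg, collapse = ";")
  }, "")
  out <- cbind(st, crit)
  out$pass <- !nzchar(reasons)
  out$reasons <- reasons
  out
}
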