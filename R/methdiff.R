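# Tile-level differential methylation between cell groups, residual
# methylation screening, hypergeometric annotation enrichment and
# imprinting-control-region (ICR) profiling.

#' Call differentially methylated tiles between two cell groups
#'
#' Inputs are per-cell tile-level matrices (cells x tiles, `NA` = tile not
#' covered in that cell, tile ids `chrom:start-end` as column names) for a
#' former and a latter group. Only tiles covered in more than
#' `dmr_min_cell_frac` (10%) of cells in *both* groups are compared. The
#' per-tile p-value comes from a two-sample comparison of per-cell tile
#' levels (Wilcoxon rank-sum by default; exact permutation enumeration
#' when the smaller group has < 8 covered cells, since tied levels defeat
#' the classical exact path; Welch t selectable via `cfg$dmr_test`).
#' P-values are BH-adjusted across eligible tiles. A tile is called
#' `demethylated` when former mean > 0.75, latter mean < 0.25 and
#' q <= 0.05; `de_novo` under the mirrored condition; otherwise `stable`.
#'
#' @param tiles_former,tiles_latter cells x tiles matrices over a shared
#'   tile set (identical column order).
#' @param cfg an [analysis_config()].
#' @return data.frame per eligible tile: `tile`, `mean_former`,
#'   `mean_latter`, `n_former`, `n_latter`, `p`, `q`, `call`.
#' @export
call_dmrs <- function(tiles_former, tiles_latter, cfg = analysis_config()) {
  stopifnot(identical(colnames(tiles_former), colnames(tiles_latter)),
            nrow(tiles_former) >= 2L, nrow(tiles_latter) >= 2L)
  covF <- colSums(!is.na(tiles_former))
  covL <- colSums(!is.na(tiles_latter))
  eligible <- covF / nrow(tiles_former) > cfg$dmr_min_cell_frac &
    covL / nrow(tiles_latter) > cfg$dmr_min_cell_frac
  if (!any(eligible)) {
    warning("no tiles eligible for differential methylation")
    return(data.frame(tile = character(), mean_former = numeric(),
                      mean_latter = numeric(), n_former = integer(),
                      n_latter = integer(), p = numeric(), q = numeric(),
                      call = character(), stringsAsFactors = FALSE))
  }
  ids <- colnames(tiles_former)[eligible]
  F <- tiles_former[, eligible, drop = FALSE]
  L <- tiles_latter[, eligible, drop = FALSE]
  p <- vapply(seq_along(ids), function(j) {
    x <- F[, j][!is.na(F[, j])]
    y <- L[, j][!is.na(L[, j])]
    tile_test_p(x, y, cfg$dmr_test)
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  mf <- colMeans(F, na.rm = TRUE)
  ml <- colMeans(L, na.rm = TRUE)
  call <- rep("stable", length(ids))
  call[mf > cfg$dmr_hi & ml < cfg$dmr_lo & q <= cfg$dmr_alpha] <-
    "demethylated"
  call[mf < cfg$dmr_lo & ml > cfg$dmr_hi & q <= cfg$dmr_alpha] <- "de_novo"
  data.frame(tile = ids, mean_former = unname(mf), mean_latter = unname(ml),
             n_former = unname(covF[eligible]),
             n_latter = unname(covL[eligible]),
             p = p, q = q, call = call, stringsAsFactors = FALSE)
}

# Two-sample p-value for per-cell tile levels. Wilcoxon normal
# approximation with tie correction at usable group sizes; complete
# permutation enumeration of the rank-sum statistic when the smaller
# group has < 8 values (exact even under ties); Welch t as alternative.
tile_test_p <- function(x, y, test = "wilcoxon") {
  if (length(x) < 2L || length(y) < 2L) return(1)
  if (stats::sd(c(x, y)) == 0) return(1)
  if (test == "ttest") {
    if (stats::sd(x) == 0 && stats::sd(y) == 0) return(1)
    return(stats::t.test(x, y)$p.value)
  }
  if (min(length(x), length(y)) < 8L &&
      choose(length(x) + length(y), length(x)) <= 20000) {
    return(rank_sum_perm_p(x, y))
  }
  suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                      correct = TRUE)$p.value)
}

# Exact two-sided permutation p of the rank-sum statistic.
rank_sum_perm_p <- function(x, y) {
  r <- rank(c(x, y))
  nx <- length(x)
  obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(length(r), nx)
  sums <- colSums(matrix(r[combs], nrow = nx))
  e <- mean(sums)
  mean(abs(sums - e) >= abs(obs - e) - 1e-9)
}

#' Tiles with persistently high residual methylation across stages
#'
#' Returns tiles whose group-mean level is at or above `level_threshold`
#' at every stage, restricted to tiles eligible (covered in more than
#' `min_cell_frac` of cells) at *all* stages.
#'
#' @param stage_matrices named list of cells x tiles matrices (one per
#'   stage, shared tile columns).
#' @param level_threshold residual level (default 0.4, inclusive).
#' @param min_cell_frac per-stage eligibility fraction (strict >).
#' @return character vector of retained tile ids.
#' @export
residual_tiles <- function(stage_matrices, level_threshold = 0.4,
                           min_cell_frac = 0.10) {
  stopifnot(length(stage_matrices) >= 2L)
  ids <- colnames(stage_matrices[[1]])
  ok <- rep(TRUE, length(ids))
  for (m in stage_matrices) {
    stopifnot(identical(colnames(m), ids))
    elig <- colSums(!is.na(m)) / nrow(m) > min_cell_frac
    mm <- colMeans(m, na.rm = TRUE)
    ok <- ok & elig & !is.na(mm) & mm >= level_threshold
  }
  ids[ok]
}

#' Hypergeometric enrichment of a candidate tile set in an annotation
#'
#' With `N` background tiles of which `K` overlap the annotation (>= 1 bp,
#' annotation merged first), and `n` candidate tiles of which `k` overlap:
#' fold = (k/n)/(K/N) and p = P(X >= k), X ~ Hypergeometric(N, K, n).
#'
#' @param candidates,background interval data.frames of tiles
#'   (candidates must be a subset of background).
#' @param annotation interval data.frame.
#' @return one-row data.frame `N`, `K`, `n`, `k`, `fold`, `p`
#'   (`NA` with a warning when `n` or `K` is zero).
#' @export
hypergeom_enrichment <- function(candidates, background, annotation) {
  N <- nrow(background)
  n <- nrow(candidates)
  K <- sum(overlaps_any(background, annotation))
  k <- sum(overlaps_any(candidates, annotation))
  if (n == 0L || K == 0L) {
    warning("empty candidate set or annotation overlap; enrichment NA")
    return(data.frame(N = N, K = K, n = n, k = k, fold = NA_real_,
                      p = NA_real_))
  }
  data.frame(N = N, K = K, n = n, k = k,
             fold = (k / n) / (K / N),
             p = hypergeom_upper_p(N, K, n, k))
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' @param N background size, `K` successes in background, `n` draws,
#'   `k` observed successes.
#' @param K,n,k see above.
#' @return p in (0, 1].
#' @export
hypergeom_upper_p <- function(N, K, n, k) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Methylation profile of imprinting control regions per cell group
#'
#' For each ICR interval and each cell group: cells of the group are
#' pooled site-by-site over the class, and the ICR level is the mean of
#' per-site pooled levels within the interval (`NA` when no site is
#' covered).
#'
#' @param groups named list of cell-call-table lists (one entry per
#'   group).
#' @param icr interval data.frame of ICRs (a `name` column is used for
#'   rownames when present).
#' @param class context class (default `"WCG"`; use `"CpG"` for scBS-only
#'   tables).
#' @return matrix ICRs x groups of mean levels.
#' @export
icr_profile <- function(groups, icr, class = "WCG") {
  out <- matrix(NA_real_, nrow = nrow(icr), ncol = length(groups),
                dimnames = list(
                  if ("name" %in% names(icr)) icr$name else
                    interval_id(icr$chrom, icr$start, icr$end),
                  names(groups)))
  for (g in names(groups)) {
    pooled <- pool_group(groups[[g]], class = class, group = g)
    out[, g] <- as.numeric(aggregate_region(pooled, icr, class = class,
                                            min_sites = 1L))
  }
  out
}
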