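# Cell-to-cell epigenetic heterogeneity in sliding windows.
#
# Per window, each sufficiently covered cell contributes its mean site
# level; the across-cell sample variance is summarized by the lower
# endpoint of the two-sided chi-squared confidence interval, a
# conservative estimate that discounts windows where few cells are
# observed.

#' Chi-squared confidence lower bound of a sample variance
#'
#' The small endpoint of the two-sided CI at confidence `conf`:
#' `(n-1) * s2 / qchisq(1 - (1-conf)/2, n-1)`.
#'
#' @param s2 sample variance(s).
#' @param n number of observations (vectorized).
#' @param conf confidence level (default 0.95).
#' @return lower bound(s), `<= s2` always.
#' @export
variance_lower_bound <- function(s2, n, conf = 0.95) {
  alpha <- 1 - conf
  (n - 1) * s2 / stats::qchisq(1 - alpha / 2, df = n - 1)
}

# Shared machinery for both modalities.
sliding_variance <- function(cell_calls, class, window, step, min_sites,
                             min_cell_frac, min_cells, conf, chrom_sizes,
                             group = "group", modality = class) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cells = integer(),
                      s2 = numeric(), var_lower = numeric(),
                      modality = character(), group = character(),
                      stringsAsFactors = FALSE)
  if (length(cell_calls) < min_cells) {
    message("group '", group, "' has ", length(cell_calls), " cells (< ",
            min_cells, "); skipped from variance analysis")
    return(empty)
  }
  n_cells_total <- length(cell_calls)
  # per-cell per-window mean level and covered flag
  per_cell <- lapply(cell_calls, function(calls) {
    dt <- site_levels(data.table::as.data.table(calls))[context == class]
    dt
  })
  out <- list()
  for (ch in names(chrom_sizes)) {
    starts <- window_starts(chrom_sizes[[ch]], window, step)
    if (length(starts) == 0L) next
    means <- matrix(NA_real_, nrow = n_cells_total, ncol = length(starts))
    for (ci in seq_along(per_cell)) {
      dt <- per_cell[[ci]][chrom == ch]
      if (nrow(dt) == 0L) next
      o <- order(dt$pos)
      pos <- dt$pos[o]; lvl <- dt$level[o]
      csL <- c(0, cumsum(lvl))
      lo <- findInterval(starts - 0.5, pos)
      hi <- findInterval(starts + window - 0.5, pos)
      nsite <- hi - lo
      m <- (csL[hi + 1L] - csL[lo + 1L]) / nsite
      # strict "more than min_sites" per-cell coverage gate
      m[nsite <= min_sites] <- NA_real_
      means[ci, ] <- m
    }
    ncov <- colSums(!is.na(means))
    keep <- ncov / n_cells_total > min_cell_frac & ncov >= 2L
    if (!any(keep)) next
    s2 <- apply(means[, keep, drop = FALSE], 2,
                function(x) stats::var(x, na.rm = TRUE))
    nk <- ncov[keep]
    out[[ch]] <- data.frame(
      chrom = ch, start = starts[keep],
      end = pmin(starts[keep] + window, chrom_sizes[[ch]]),
      n_cells = nk, s2 = s2,
      var_lower = variance_lower_bound(s2, nk, conf),
      modality = modality, group = group, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cell-to-cell DNA methylation variance track
#'
#' 3000-bp windows with a 600-bp step; a cell contributes a window mean
#' only when it covers more than 3 CpG sites there (strict); windows
#' covered in more than 30% of cells are retained; groups with fewer
#' than `var_min_cells` (10) cells are skipped.
#'
#' @param cell_calls list of call tables (one group).
#' @param cfg an [analysis_config()].
#' @param chrom_sizes named vector of chromosome lengths.
#' @param group group label.
#' @param class context class for methylation (`"WCG"`, or `"CpG"` for
#'   scBS tables).
#' @return data.frame `chrom`, `start`, `end`, `n_cells`, `s2`,
#'   `var_lower`, `modality`, `group`.
#' @export
methylation_variance <- function(cell_calls, cfg = analysis_config(),
                                 chrom_sizes, group = "group",
                                 class = "WCG") {
  sliding_variance(cell_calls, class = class,
                   window = cfg$meth_var_window, step = cfg$meth_var_step,
                   min_sites = cfg$meth_var_min_cpg,
                   min_cell_frac = cfg$meth_var_min_cell_frac,
                   min_cells = cfg$var_min_cells, conf = cfg$var_conf,
                   chrom_sizes = chrom_sizes, group = group,
                   modality = "methylation")
}

#' Cell-to-cell chromatin accessibility variance track
#'
#' Same machinery on GCH levels with 200-bp windows, 100-bp steps, and a
#' strict more-than-5-GCH per-cell coverage gate.
#'
#' @inheritParams methylation_variance
#' @export
accessibility_variance <- function(cell_calls, cfg = analysis_config(),
                                   chrom_sizes, group = "group") {
  sliding_variance(cell_calls, class = "GCH",
                   window = cfg$acc_var_window, step = cfg$acc_var_step,
                   min_sites = cfg$acc_var_min_gch,
                   min_cell_frac = cfg$meth_var_min_cell_frac,
                   min_cells = cfg$var_min_cells, conf = cfg$var_conf,
                   chrom_sizes = chrom_sizes, group = group,
                   modality = "accessibility")
}

#' Summarize a variance track by genomic element class
#'
#' A window belongs to a class when its center falls inside the (merged)
#' class intervals; the per-class distribution of lower bounds is
#' summarized by quartiles.
#'
#' @param track a variance track.
#' @param annotation_sets named list of interval data.frames.
#' @return data.frame per class: `n_windows`, `q25`, `median`, `q75`
#'   (missing classes dropped with a warning).
#' @export
variance_by_element <- function(track, annotation_sets) {
  centers <- data.frame(chrom = track$chrom,
                        start = (track$start + track$end) %/% 2L)
  centers$end <- centers$start + 1L
  res <- lapply(names(annotation_sets), function(cls) {
    ann <- annotation_sets[[cls]]
    inside <- overlaps_any(centers, ann)
    if (!any(inside)) {
      warning("no variance windows in class '", cls, "'")
      return(NULL)
    }
    v <- track$var_lower[inside]
    data.frame(class = cls, n_windows = sum(inside),
               q25 = unname(stats::quantile(v, 0.25)),
               median = stats::median(v),
               q75 = unname(stats::quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(class = character(), n_windows = integer(),
                      q25 = numeric(), median = numeric(), q75 = numeric())
  rownames(out) <- NULL
  out
}
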