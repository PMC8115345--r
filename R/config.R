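#' Analysis configuration
#'
#' Returns the full set of tunable thresholds used across the pipeline.
#' Defaults are the published thresholds of the single-cell methylome /
#' chromatin-accessibility workflow this package implements; every stage
#' reads its cutoffs from this object so a run can be reproduced from the
#' logged configuration alone.
#'
#' Boundary conventions are applied exactly as printed in the protocol:
#' "more than" thresholds (tile cell-coverage 70%, DMR eligibility 10%,
#' differential-open coverage 40%, variance cell-coverage 30%, per-window
#' site gates) are strict `>`; "at least"/"no more than" thresholds
#' (mapping rate, conversion rate, FGC methylation cap, minimum CpG per
#' tile, minimum GCH per NDR) are inclusive.
#'
#' @param ... name = value overrides of any default listed below.
#'
#' @return A named list of class `scnome_config`.
#'
#' @section Main thresholds:
#' \describe{
#'   \item{tile_size, tile_min_cpg}{500-bp genome tiles; a cell's tile level
#'     requires >= 3 covered CpG/WCG sites.}
#'   \item{cluster_min_cell_frac}{tiles exported for clustering must be
#'     covered in > 70% of cells.}
#'   \item{dmr_hi, dmr_lo, dmr_alpha, dmr_min_cell_frac}{demethylated tile:
#'     former group mean > 0.75, latter < 0.25, BH-adjusted p <= 0.05; only
#'     tiles covered in > 10% of cells of both groups are compared.}
#'   \item{ndr_window, ndr_step, ndr_p, ndr_min_len, ndr_min_gch}{100-bp
#'     windows, 20-bp steps, chi-square p <= 1e-20 vs the whole-genome GCH
#'     background; merged candidates must be longer than 140 bp with >= 5
#'     covered GCH sites.}
#'   \item{proximal_radius}{NDR center within 2 kb of a TSS = proximal.}
#'   \item{do_min_cell_frac, do_min_diff, do_open_level, do_closed_level}{differential openness: coverage > 40% in both groups,
#'     |difference| > 0.2, open cells have level >= 0.5, closed <= 0.3.}
#'   \item{corr_r}{expression/accessibility Pearson screen keeps r > 0.6.}
#'   \item{residual_level}{residual-methylation screen level, 0.4.}
#'   \item{meth_var_window/step, acc_var_window/step, var_conf, var_min_cells}{3000/600-bp
#'     (methylation) and 200/100-bp (accessibility) variance windows;
#'     chi-squared CI confidence 0.95; groups with < 10 cells skipped.}
#'   \item{prom_meth_up/down, prom_acc_up/down}{promoter signal windows: WCG over `[TSS-1000, TSS+500)`,
#'     GCH over `[TSS-200, TSS+100)`, strand-oriented.}
#'   \item{hcp_obs_exp, hcp_gc, lcp_obs_exp, prom_subwindow}{CpG-density
#'     promoter classes via 500-bp subwindows (Weber-style criteria).}
#'   \item{qc thresholds}{library QC; see [qc_filter()].}
#' }
#' @export
analysis_config <- function(...) {
  cfg <- list(
    tile_size = 500L, tile_min_cpg = 3L, cluster_min_cell_frac = 0.70,
    dmr_hi = 0.75, dmr_lo = 0.25, dmr_alpha = 0.05,
    dmr_min_cell_frac = 0.10, dmr_test = "wilcoxon",
    ndr_window = 100L, ndr_step = 20L, ndr_p = 1e-20,
    ndr_min_len = 140L, ndr_min_gch = 5L, proximal_radius = 2000L,
    do_min_cell_frac = 0.40, do_min_diff = 0.2,
    do_open_level = 0.5, do_closed_level = 0.3,
    corr_r = 0.6, residual_level = 0.4,
    meth_var_window = 3000L, meth_var_step = 600L,
    meth_var_min_cpg = 3L, meth_var_min_cell_frac = 0.30,
    var_conf = 0.95,
    acc_var_window = 200L, acc_var_step = 100L, acc_var_min_gch = 5L,
    var_min_cells = 10L,
    prom_meth_up = 1000L, prom_meth_down = 500L,
    prom_acc_up = 200L, prom_acc_down = 100L,
    hcp_obs_exp = 0.75, hcp_gc = 0.55, lcp_obs_exp = 0.48,
    prom_subwindow = 500L,
    qc_scbs_map_rate = 0.20, qc_scbs_conversion = 0.99,
    qc_scbs_non_cpg = 0.02, qc_scbs_min_cpg = 2e6,
    qc_fgc_max_meth = 0.2,
    qc_cool_map_rate = 0.20, qc_cool_min_wcg = 1e6, qc_cool_min_gch = 1e7
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) stop("unknown config keys: ",
                              paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_config(cfg)
  class(cfg) <- c("scnome_config", "list")
  cfg
}

validate_config <- function(cfg) {
  fracs <- c("cluster_min_cell_frac", "dmr_hi", "dmr_lo", "dmr_alpha",
             "dmr_min_cell_frac", "do_min_cell_frac", "do_min_diff",
             "do_open_level", "do_closed_level", "corr_r", "residual_level",
             "meth_var_min_cell_frac", "var_conf", "qc_scbs_map_rate",
             "qc_scbs_conversion", "qc_scbs_non_cpg", "qc_fgc_max_meth",
             "qc_cool_map_rate", "hcp_obs_exp", "hcp_gc", "lcp_obs_exp")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("config `", f, "` must be a single fraction in [0, 1]")
  }
  pos <- c("tile_size", "tile_min_cpg", "ndr_window", "ndr_step",
           "ndr_min_len", "ndr_min_gch", "proximal_radius",
           "meth_var_window", "meth_var_step", "meth_var_min_cpg",
           "acc_var_window", "acc_var_step", "acc_var_min_gch",
           "var_min_cells", "prom_meth_up", "prom_meth_down",
           "prom_acc_up", "prom_acc_down", "prom_subwindow",
           "qc_scbs_min_cpg", "qc_cool_min_wcg", "qc_cool_min_gch")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 ||
        v != round(v))
      stop("config `", f, "` must be a positive integer count")
  }
  if (!is.numeric(cfg$ndr_p) || cfg$ndr_p <= 0 || cfg$ndr_p > 1)
    stop("config `ndr_p` must be a p-value in (0, 1]")
  if (!cfg$dmr_test %in% c("wilcoxon", "ttest"))
    stop("config `dmr_test` must be 'wilcoxon' or 'ttest'")
  invisible(cfg)
}

#' Read / write a flat `key = value` configuration file
#'
#' Every pipeline run logs the resolved configuration in this format so an
#' analysis can be re-run from the log.
#'
#' @param path file path.
#' @return [read_config()] returns an `scnome_config`;
#'   [write_config()] returns `path` invisibly.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  parsed <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) {
      if (num == round(num) && abs(num) < .Machine$integer.max) {
        # keep integer-valued keys integer
        if (num == as.integer(num)) num <- num
      }
      num
    } else v
  })
  names(parsed) <- keys
  # integers where defaults are integer
  def <- analysis_config()
  for (k in intersect(keys, names(def))) {
    if (is.integer(def[[k]]) && is.numeric(parsed[[k]]))
      parsed[[k]] <- as.integer(parsed[[k]])
  }
  do.call(analysis_config, parsed)
}

#' @rdname read_config
#' @param cfg an `scnome_config`.
#' @export
write_config <- function(cfg, path) {
  vals <- vapply(cfg, function(v) format(v, scientific = FALSE), "")
  writeLines(paste(names(cfg), "=", vals), path)
  invisible(path)
}
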