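# Synthetic single-cell cohort generator with planted ground truth.
#
# Emulates the statistical structure of a fetal-germ-cell (FGC) /
# gonadal-soma single-cell methylome + accessibility study: sparse
# per-cell coverage (~10-15% of sites at ~1x depth), phase-dependent
# global CpG methylation (hypermethylated soma ~0.67, demethylated FGCs
# 0.05-0.15), fully accessible planted promoter NDRs against a closed
# background (GpC labeling efficiency < 1, bisulfite non-conversion and
# nonspecific labeling folded into one background rate), planted
# residual-methylation and demethylating tiles, hypermethylated-in-soma
# ICR-like intervals, and an expression table in which genes whose
# promoter opens in a phase are high in that phase.

#' Simulation configuration
#'
#' Defaults are the cohort conditions the generator is calibrated to:
#' four groups mirroring a male time course (soma at 67.4% global CpG
#' methylation; FGCs at 14.5% in week 6, 4.9% in week 17, 7.2% in week
#' 24), ~12% site coverage at 1x depth, GpC labeling efficiency 0.85
#' over a 0.02 background.
#'
#' @param ... overrides of the defaults below.
#' @return list of class `scnome_sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_chroms = 2L, chrom_len = 150000L, gc_fraction = 0.42,
    n_genes = 60L, promoter_ndr_width = 300L,
    phases = list(
      list(name = "soma", sex = "male", week = 17L, is_fgc = FALSE,
           n_cells = 12L, mean_cpg_meth = 0.674),
      list(name = "mitotic", sex = "male", week = 6L, is_fgc = TRUE,
           n_cells = 12L, mean_cpg_meth = 0.145),
      list(name = "mitotic_arrest", sex = "male", week = 17L,
           is_fgc = TRUE, n_cells = 12L, mean_cpg_meth = 0.049),
      list(name = "mitotic_arrest", sex = "male", week = 24L,
           is_fgc = TRUE, n_cells = 12L, mean_cpg_meth = 0.072)),
    tile_size = 500L, tile_meth_dispersion = 0.05,
    enzyme_efficiency = 0.85, background_gch = 0.02,
    site_coverage_prob = 0.12, mean_read_depth = 1,
    open_genes_per_phase = 10L,
    residual_tile_frac = 0.03, residual_level = 0.6,
    demeth_tile_frac = 0.03, demeth_hi = 0.85, demeth_lo = 0.05,
    icr_n = 6L, icr_width = 1500L, icr_level = 0.5,
    repeat_families = c("ALR", "SVA", "L1", "ERVK"),
    repeats_per_family = 12L, repeat_width = 600L,
    seed = 1L)
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) stop("unknown sim_config keys: ",
                              paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  for (f in c("gc_fraction", "enzyme_efficiency", "background_gch",
              "site_coverage_prob", "residual_tile_frac",
              "demeth_tile_frac"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("sim_config `", f, "` must be in [0, 1]")
  if (cfg$enzyme_efficiency <= cfg$background_gch)
    warning("enzyme_efficiency <= background_gch: planted accessibility ",
            "is unrecoverable from the calls")
  if (sum(vapply(cfg$phases, `[[`, integer(1), "n_cells")) <= 0)
    stop("total number of cells must be positive")
  class(cfg) <- c("scnome_sim_config", "list")
  cfg
}

phase_ids <- function(cfg) {
  vapply(cfg$phases, function(p)
    sprintf("%s.week%02d.%s", p$sex, p$week, p$name), "")
}

#' Simulate a genome with annotations and planted truth
#'
#' Generates random chromosome sequences at the requested GC fraction, a
#' TSS per gene spaced so that +/-2 kb promoter windows never overlap,
#' planted promoter-NDR intervals, repeat-family / CGI-like / ICR-like
#' annotation BED sets, per-phase per-tile true methylation levels, and
#' per-phase open-promoter gene sets. Each phase's `mean_cpg_meth` is the
#' target *global* level: the background-tile mean is solved so that
#' planted residual / demethylating / ICR tiles do not bias the global
#' mean away from it.
#'
#' @param cfg a [sim_config()].
#' @param seed set the RNG seed before generating (`NULL` = use current
#'   RNG state, as [simulate_cohort()] does).
#' @return list: `genome` (named character vector), `tss`, `annotations`
#'   (named list of interval data.frames), `truth` (planted NDRs per
#'   phase, open genes per phase, tile truth matrix, special tile ids).
#' @export
simulate_genome <- function(cfg = sim_config(), seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  gc <- cfg$gc_fraction
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  seq_vec <- lapply(stats::setNames(chroms, chroms), function(ch)
    sample(c("A", "T", "G", "C"), cfg$chrom_len, replace = TRUE,
           prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)))
  # evenly spaced TSS (with jitter, so annotations do not alias against
  # the fixed tile/window grids) keeping +/-2kb promoter windows disjoint
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  margin <- 3000L
  usable <- cfg$chrom_len - 2L * margin
  if (usable / per_chrom < 4700)
    stop("promoter spacing infeasible: ", per_chrom, " genes on a ",
         cfg$chrom_len, "-bp chromosome")
  tss <- do.call(rbind, lapply(seq_along(chroms), function(i) {
    n_here <- min(per_chrom, cfg$n_genes - (i - 1L) * per_chrom)
    if (n_here <= 0L) return(NULL)
    idx <- seq_len(n_here)
    data.frame(
      gene = sprintf("gene_%03d", (i - 1L) * per_chrom + idx),
      chrom = chroms[i],
      tss = as.integer(round(margin + (idx - 0.5) * usable / per_chrom) +
                         sample(-250L:250L, n_here, replace = TRUE)),
      strand = sample(c("+", "-"), n_here, replace = TRUE),
      stringsAsFactors = FALSE)
  }))
  # engineer promoter CpG density so all three promoter classes exist:
  # every 3rd gene gets a CpG-island-like high-GC segment at the TSS
  # (HCP), the next a fully CpG-depleted promoter neighborhood (LCP),
  # the rest keep the genomic background (ICP)
  prom_class_truth <- rep(c("HCP", "LCP", "ICP"), length.out = nrow(tss))
  for (i in seq_len(nrow(tss))) {
    s <- seq_vec[[tss$chrom[i]]]
    t1 <- tss$tss[i] + 1L  # 1-based TSS index
    if (prom_class_truth[i] == "HCP") {
      idx <- (t1 - 250L):(t1 + 249L)
      s[idx] <- sample(c("A", "T", "G", "C"), length(idx), replace = TRUE,
                       prob = c(0.15, 0.15, 0.35, 0.35))
    } else if (prom_class_truth[i] == "LCP") {
      idx <- (t1 - 1100L):(t1 + 1100L)
      cg <- idx[s[idx] == "C" & s[idx + 1L] == "G"]
      # keep ~10% of CpGs: low-density, not zero, like genomic LCPs
      cg <- cg[stats::runif(length(cg)) < 0.9]
      s[cg + 1L] <- "A"
    }
    seq_vec[[tss$chrom[i]]] <- s
  }
  genome <- vapply(seq_vec, paste, "", collapse = "")
  half <- cfg$promoter_ndr_width %/% 2L
  promoter_ndrs <- data.frame(gene = tss$gene, chrom = tss$chrom,
                              start = tss$tss - half,
                              end = tss$tss - half + cfg$promoter_ndr_width,
                              stringsAsFactors = FALSE)
  ids <- phase_ids(cfg)
  open_genes <- list()
  pool <- tss$gene
  for (i in seq_along(ids)) {
    take <- utils::head(pool, cfg$open_genes_per_phase)
    open_genes[[ids[i]]] <- take
    pool <- setdiff(pool, take)
  }
  closed_genes <- pool  # never open in any phase: negative controls
  ndr_truth <- lapply(open_genes, function(gs)
    promoter_ndrs[promoter_ndrs$gene %in% gs, , drop = FALSE])
  # annotations ------------------------------------------------------
  promoters <- data.frame(chrom = tss$chrom, start = pmax(tss$tss - 1000L, 0L),
                          end = pmin(tss$tss + 500L, cfg$chrom_len))
  cgi_genes <- tss[prom_class_truth == "HCP", ]
  cgis <- data.frame(chrom = cgi_genes$chrom,
                     start = pmax(cgi_genes$tss - 250L, 0L),
                     end = pmin(cgi_genes$tss + 250L, cfg$chrom_len))
  rand_intervals <- function(n, width) {
    ch <- sample(chroms, n, replace = TRUE)
    st <- vapply(ch, function(x)
      sample.int(cfg$chrom_len - width, 1L), integer(1))
    data.frame(chrom = ch, start = st, end = st + width,
               stringsAsFactors = FALSE)
  }
  repeats <- lapply(stats::setNames(cfg$repeat_families,
                                    cfg$repeat_families),
                    function(f) rand_intervals(cfg$repeats_per_family,
                                               cfg$repeat_width))
  # ICRs avoid promoter windows
  icr <- NULL
  tries <- 0L
  while ((is.null(icr) || nrow(icr) < cfg$icr_n) && tries < 200L) {
    cand <- rand_intervals(1L, cfg$icr_width)
    if (!any(overlaps_any(cand, promoters)) &&
        (is.null(icr) || !any(overlaps_any(cand, icr))))
      icr <- rbind(icr, cand)
    tries <- tries + 1L
  }
  icr$name <- sprintf("ICR_%02d", seq_len(nrow(icr)))
  annotations <- c(list(promoters = promoters, cgi = cgis, icr = icr),
                   repeats)
  # tile truth -------------------------------------------------------
  ts <- cfg$tile_size
  tiles <- do.call(rbind, lapply(chroms, function(ch)
    data.frame(chrom = ch, start = seq.int(0L, cfg$chrom_len - 1L, by = ts),
               stringsAsFactors = FALSE)))
  tiles$end <- pmin(tiles$start + ts, cfg$chrom_len)
  tile_ids <- interval_id(tiles$chrom, tiles$start, tiles$end)
  n_tiles <- nrow(tiles)
  # special tile sets; demeth/residual biased toward the first repeat
  # family so annotation enrichment of demethylated tiles is real signal
  in_rep <- overlaps_any(tiles, do.call(rbind, unname(repeats)))
  pick_biased <- function(n, exclude = integer(0)) {
    avail <- setdiff(seq_len(n_tiles), exclude)
    w <- ifelse(in_rep[avail], 3, 1)
    sample(avail, n, prob = w)
  }
  n_dem <- max(1L, round(cfg$demeth_tile_frac * n_tiles))
  n_res <- max(1L, round(cfg$residual_tile_frac * n_tiles))
  dem_idx <- pick_biased(n_dem)
  res_idx <- pick_biased(n_res, exclude = dem_idx)
  icr_idx <- which(overlaps_any(tiles, icr))
  fgc <- vapply(cfg$phases, `[[`, logical(1), "is_fgc")
  weeks <- vapply(cfg$phases, `[[`, integer(1), "week")
  first_fgc <- ids[fgc][which.min(weeks[fgc])]
  tile_truth <- matrix(NA_real_, nrow = n_tiles, ncol = length(ids),
                       dimnames = list(tile_ids, ids))
  base_means <- numeric(length(ids)); names(base_means) <- ids
  for (i in seq_along(ids)) {
    ph <- cfg$phases[[i]]
    # per-tile target means with planted overrides
    m <- rep(NA_real_, n_tiles)
    f_over <- 0; contrib <- 0
    if (ph$is_fgc) {
      m[res_idx] <- cfg$residual_level
      m[dem_idx] <- if (ids[i] == first_fgc) cfg$demeth_hi else
        cfg$demeth_lo
      f_over <- (n_res + n_dem) / n_tiles
      contrib <- (n_res * cfg$residual_level +
                    n_dem * m[dem_idx][1]) / n_tiles
    } else {
      m[dem_idx] <- cfg$demeth_hi
      m[icr_idx] <- cfg$icr_level
      f_over <- (n_dem + length(icr_idx)) / n_tiles
      contrib <- (n_dem * cfg$demeth_hi +
                    length(icr_idx) * cfg$icr_level) / n_tiles
    }
    base <- (ph$mean_cpg_meth - contrib) / (1 - f_over)
    base <- min(max(base, 0), 1)
    base_means[i] <- base
    bg <- is.na(m)
    m[bg] <- base
    tile_truth[, i] <- rbeta_mean(m, cfg$tile_meth_dispersion)
  }
  list(genome = genome, tss = tss, annotations = annotations,
       truth = list(promoter_class = stats::setNames(prom_class_truth,
                                                     tss$gene),
                    ndr_truth = ndr_truth, open_genes = open_genes,
                    closed_genes = closed_genes,
                    promoter_ndrs = promoter_ndrs,
                    tiles = tiles, tile_ids = tile_ids,
                    tile_truth = tile_truth,
                    demeth_tiles = tile_ids[dem_idx],
                    residual_tiles = tile_ids[res_idx],
                    icr_tiles = tile_ids[icr_idx],
                    base_means = base_means))
}

# Beta draw parameterized by mean and dispersion d in [0, 1):
# shape1 = m (1-d)/d, shape2 = (1-m)(1-d)/d; d -> 0 collapses to the mean.
rbeta_mean <- function(m, d) {
  if (d <= 0) return(m)
  m2 <- pmin(pmax(m, 1e-9), 1 - 1e-9)
  out <- stats::rbeta(length(m2), m2 * (1 - d) / d,
                      (1 - m2) * (1 - d) / d)
  out[m <= 0] <- 0
  out[m >= 1] <- 1
  out
}

#' Simulate one cell's call table
#'
#' Every site of the assay's context set is covered independently with
#' probability `site_coverage_prob`; a covered site draws depth
#' `1 + Poisson(mean_read_depth - 1)` (so depth 1 at the default 1x
#' regime). WCG/CpG sites draw methylated counts
#' `Binomial(depth, tile truth level)`; GCH sites inside a planted NDR of
#' the cell's phase are methylated (= accessible) at `enzyme_efficiency`,
#' outside at `background_gch`; GCG sites are emitted with context `GCG`
#' at the background rate so exclusion logic is exercised.
#'
#' @param ctx a [classify_contexts()] table for the simulated genome.
#' @param sim output of [simulate_genome()].
#' @param phase_id one of the cohort's phase ids.
#' @param cfg the [sim_config()].
#' @param assay `"cool"` (WCG + GCH + GCG contexts) or `"scbs"` (all CpG
#'   sites, context written `CpG`).
#' @return a call table `data.table`.
#' @export
simulate_cell <- function(ctx, sim, phase_id, cfg = sim_config(),
                          assay = c("cool", "scbs")) {
  assay <- match.arg(assay)
  ctx <- data.table::as.data.table(ctx)
  truth <- sim$truth
  ts <- cfg$tile_size
  tile_of <- function(chrom, pos) {
    match(interval_id(chrom, (pos %/% ts) * ts,
                      pmin((pos %/% ts) * ts + ts,
                           chrom_sizes(sim$genome)[chrom])),
          truth$tile_ids)
  }
  lvl <- truth$tile_truth[, phase_id]
  emit <- function(sub, rate) {
    cov <- stats::runif(nrow(sub)) < cfg$site_coverage_prob
    sub <- sub[cov]
    if (nrow(sub) == 0L) return(sub[, list(chrom, pos, strand, context,
                                           n_meth = integer(0),
                                           n_unmeth = integer(0))])
    depth <- 1L + stats::rpois(nrow(sub), max(cfg$mean_read_depth - 1, 0))
    n_meth <- stats::rbinom(nrow(sub), depth, rate(sub))
    sub[, list(chrom, pos, strand, context,
               n_meth = n_meth, n_unmeth = depth - n_meth)]
  }
  parts <- list()
  if (assay == "cool") {
    wcg <- ctx[context == "WCG"]
    parts$wcg <- emit(wcg, function(s) lvl[tile_of(s$chrom, s$pos)])
    gch <- ctx[context == "GCH"]
    ndrs <- truth$ndr_truth[[phase_id]]
    in_ndr <- if (is.null(ndrs) || nrow(ndrs) == 0L)
      rep(FALSE, nrow(gch)) else
        overlaps_any(data.frame(chrom = gch$chrom, start = gch$pos,
                                end = gch$pos + 1L), ndrs)
    gch[, rate := ifelse(in_ndr, cfg$enzyme_efficiency,
                         cfg$background_gch)]
    parts$gch <- emit(gch, function(s) s$rate)
    gcg <- ctx[context == "GCG"]
    parts$gcg <- emit(gcg, function(s) cfg$background_gch)
  } else {
    cpg <- ctx[is_cpg == TRUE]
    cpg <- cpg[, list(chrom, pos, strand, context = "CpG")]
    parts$cpg <- emit(cpg, function(s) lvl[tile_of(s$chrom, s$pos)])
  }
  parts <- lapply(parts, function(p)
    p[, list(chrom, pos, strand, context, n_meth, n_unmeth)])
  out <- data.table::rbindlist(parts)
  data.table::setorder(out, chrom, pos, strand)
  out[]
}

#' Simulate a full cohort on disk
#'
#' Writes everything the pipeline consumes under `out_dir`: `genome.fa`,
#' `tss.tsv`, `annotations/*.bed`, `expression.tsv` (genes x groups;
#' open-promoter genes are ~10x baseline in their phase), per-cell call
#' tables under `cells/` (one scBS-style and one scCOOL-style library per
#' simulated cell), `manifest.tsv`, `cell_stats.tsv` (library QC
#' statistics drawn from passing ranges; covered-site counts and global
#' levels computed from the written calls), and `truth.json`.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created).
#' @return list with `manifest`, `truth`, `sim` (the in-memory genome),
#'   `cell_stats`, and `dir`.
#' @export
simulate_cohort <- function(cfg = sim_config(), out_dir) {
  set.seed(cfg$seed)
  sim <- simulate_genome(cfg, seed = NULL)
  ctx <- classify_contexts(sim$genome)
  dir.create(file.path(out_dir, "cells"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "annotations"), showWarnings = FALSE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$genome),
    file.path(out_dir, "genome.fa"))
  data.table::fwrite(sim$tss, file.path(out_dir, "tss.tsv"), sep = "\t")
  for (a in names(sim$annotations))
    write_bed(sim$annotations[[a]],
              file.path(out_dir, "annotations", paste0(a, ".bed")))
  ids <- phase_ids(cfg)
  manifest <- list(); stats <- list(); cell_params <- list()
  for (i in seq_along(ids)) {
    ph <- cfg$phases[[i]]
    for (j in seq_len(ph$n_cells)) {
      for (assay in c("scbs", "cool")) {
        cell_id <- sprintf("%s.%s.c%02d", ids[i], assay, j)
        calls <- simulate_cell(ctx, sim, ids[i], cfg, assay = assay)
        rel <- file.path("cells", paste0(cell_id, ".tsv"))
        write_site_calls(calls, file.path(out_dir, rel))
        manifest[[cell_id]] <- data.frame(
          cell_id = cell_id, assay = assay, sex = ph$sex, week = ph$week,
          phase = ph$name, path = rel, stringsAsFactors = FALSE)
        gm <- if (assay == "scbs") global_level(calls, "CpG") else
          global_level(calls, "WCG")
        stats[[cell_id]] <- data.frame(
          cell_id = cell_id, assay = assay, is_fgc = ph$is_fgc,
          map_rate = stats::runif(1, 0.25, 0.6),
          conversion = stats::runif(1, 0.992, 0.999),
          non_cpg_meth = stats::runif(1, 0.002, 0.012),
          n_cpg = sum(calls$context == "CpG"),
          n_wcg = sum(calls$context == "WCG"),
          n_gch = sum(calls$context == "GCH"),
          global_meth = gm, stringsAsFactors = FALSE)
        cell_params[[cell_id]] <- data.frame(
          cell_id = cell_id, group = ids[i], assay = assay,
          global_meth = gm, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  stats <- do.call(rbind, stats); rownames(stats) <- NULL
  data.table::fwrite(stats, file.path(out_dir, "cell_stats.tsv"),
                     sep = "\t")
  # expression: baseline 1 with lognormal noise; ~10x in the open phase
  genes <- sim$tss$gene
  expr <- matrix(exp(stats::rnorm(length(genes) * length(ids), 0, 0.05)),
                 nrow = length(genes),
                 dimnames = list(genes, ids))
  for (ph in ids)
    expr[sim$truth$open_genes[[ph]], ph] <-
      expr[sim$truth$open_genes[[ph]], ph] * 10
  write_expression(expr, file.path(out_dir, "expression.tsv"))
  truth_out <- list(
    ndr_truth = sim$truth$ndr_truth,
    open_genes = sim$truth$open_genes,
    closed_genes = sim$truth$closed_genes,
    demeth_tiles = sim$truth$demeth_tiles,
    residual_tiles = sim$truth$residual_tiles,
    icr_tiles = sim$truth$icr_tiles,
    base_means = as.list(sim$truth$base_means),
    cell_params = do.call(rbind, cell_params))
  jsonlite::write_json(truth_out, file.path(out_dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  manifest$group <- cell_group(manifest)
  manifest$path <- file.path(out_dir, manifest$path)
  list(manifest = manifest, truth = sim$truth, sim = sim,
       cell_stats = stats, dir = out_dir)
}
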