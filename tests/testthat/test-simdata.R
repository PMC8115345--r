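test_that("simulated genomes honor GC fraction, spacing and determinism", {
  cfg <- sim_config(n_chroms = 1L, chrom_len = 120000L, n_genes = 20L,
                    gc_fraction = 0.40, open_genes_per_phase = 4L,
                    seed = 31L)
  sim <- simulate_genome(cfg)
  s <- strsplit(sim$genome[[1]], "")[[1]]
  gc <- mean(s %in% c("G", "C"))
  expect_lt(abs(gc - 0.40), 0.02)
  # +/-2 kb promoter windows never overlap
  tssd <- diff(sort(sim$tss$tss))
  expect_true(all(tssd > 4000))
  expect_equal(nrow(sim$tss), 20L)
  # every planted NDR overlaps exactly one promoter window
  prom <- data.frame(chrom = sim$tss$chrom, start = sim$tss$tss - 2000L,
                     end = sim$tss$tss + 2000L)
  for (ph in names(sim$truth$ndr_truth)) {
    nd <- sim$truth$ndr_truth[[ph]]
    hits <- GenomicRanges::countOverlaps(
      scnome:::as_granges(nd), scnome:::as_granges(prom))
    expect_true(all(hits == 1L))
  }
  # determinism: same seed, identical sequence
  sim2 <- simulate_genome(cfg)
  expect_identical(sim$genome, sim2$genome)
  expect_identical(sim$truth$tile_truth, sim2$truth$tile_truth)
  # infeasible spacing errors out
  expect_error(simulate_genome(sim_config(n_chroms = 1L,
                                          chrom_len = 30000L,
                                          n_genes = 20L)),
               "infeasible")
})

test_that("degenerate compositions behave: gc 0 and methylation 0", {
  cfg <- sim_config(n_chroms = 1L, chrom_len = 50000L, n_genes = 8L,
                    gc_fraction = 0, seed = 5L,
                    phases = list(list(name = "p", sex = "f", week = 1L,
                                       is_fgc = TRUE, n_cells = 2L,
                                       mean_cpg_meth = 0)),
                    open_genes_per_phase = 2L,
                    tile_meth_dispersion = 0,
                    residual_tile_frac = 0.001,
                    demeth_tile_frac = 0.001, icr_n = 1L)
  sim <- simulate_genome(cfg)
  s <- unique(strsplit(gsub("[GC]", "", sim$genome[[1]]), "")[[1]])
  # outside engineered promoter segments the sequence is A/T only
  at_frac <- mean(strsplit(sim$genome[[1]], "")[[1]] %in% c("A", "T"))
  expect_gt(at_frac, 0.9)
})

test_that("zero methylation and zero dispersion give all-unmethylated WCG", {
  cfg <- sim_config(n_chroms = 1L, chrom_len = 60000L, n_genes = 10L,
                    seed = 6L, tile_meth_dispersion = 0,
                    open_genes_per_phase = 2L,
                    residual_tile_frac = 1e-9, demeth_tile_frac = 1e-9,
                    phases = list(list(name = "p", sex = "f", week = 1L,
                                       is_fgc = TRUE, n_cells = 2L,
                                       mean_cpg_meth = 0)))
  set.seed(1)
  sim <- simulate_genome(cfg, seed = cfg$seed)
  # a planted tile is unavoidable (>= 1 tile each); zero them for this
  # degenerate check of the generative chain
  sim$truth$tile_truth[] <- 0
  ctx <- classify_contexts(sim$genome)
  cell <- simulate_cell(ctx, sim, scnome:::phase_ids(cfg)[1], cfg, "cool")
  expect_true(all(cell[cell$context == "WCG", ]$n_meth == 0L))
})

test_that("noise-free accessibility separates planted NDRs perfectly", {
  cfg <- sim_config(n_chroms = 1L, chrom_len = 60000L, n_genes = 10L,
                    seed = 7L, enzyme_efficiency = 1, background_gch = 0,
                    open_genes_per_phase = 10L, mean_read_depth = 1,
                    phases = list(list(name = "p", sex = "f", week = 1L,
                                       is_fgc = TRUE, n_cells = 2L,
                                       mean_cpg_meth = 0.1)))
  set.seed(2)
  sim <- simulate_genome(cfg, seed = cfg$seed)
  ctx <- classify_contexts(sim$genome)
  pid <- scnome:::phase_ids(cfg)[1]
  cell <- simulate_cell(ctx, sim, pid, cfg, "cool")
  gch <- cell[cell$context == "GCH", ]
  in_ndr <- scnome:::overlaps_any(
    data.frame(chrom = gch$chrom, start = gch$pos, end = gch$pos + 1L),
    sim$truth$ndr_truth[[pid]])
  expect_gt(sum(in_ndr), 0L)
  expect_true(all(gch$n_unmeth[in_ndr] == 0L))
  expect_true(all(gch$n_meth[!in_ndr] == 0L))
})

test_that("pooled GCH rates calibrate to efficiency and background", {
  co <- shared_cohort()
  pid <- "female.week10.mitotic"
  cool <- co$manifest[co$manifest$assay == "cool" &
                        co$manifest$group == pid, ]
  cells <- lapply(cool$path, read_site_calls)
  pooled <- pool_group(cells, "GCH")
  truth_ndr <- co$truth$ndr_truth[[pid]]
  in_ndr <- scnome:::overlaps_any(
    data.frame(chrom = pooled$chrom, start = pooled$pos,
               end = pooled$pos + 1L), truth_ndr)
  rate_in <- sum(pooled$n_meth[in_ndr]) /
    sum(pooled$n_meth[in_ndr] + pooled$n_unmeth[in_ndr])
  n_in <- sum(pooled$n_meth[in_ndr] + pooled$n_unmeth[in_ndr])
  expect_lt(abs(rate_in - 0.85), 3 * sqrt(0.85 * 0.15 / n_in))
  rate_out <- sum(pooled$n_meth[!in_ndr]) /
    sum(pooled$n_meth[!in_ndr] + pooled$n_unmeth[!in_ndr])
  n_out <- sum(pooled$n_meth[!in_ndr] + pooled$n_unmeth[!in_ndr])
  expect_lt(abs(rate_out - 0.02), 3 * sqrt(0.02 * 0.98 / n_out))
})

test_that("per-cell global WCG levels track the phase means", {
  co <- shared_cohort()
  st <- co$cell_stats
  man <- co$manifest
  grp <- function(g, assay) st$global_meth[st$cell_id %in%
                                             man$cell_id[man$group == g &
                                                           man$assay == assay]]
  soma <- grp("female.week17.soma", "scbs")
  expect_lt(abs(mean(soma) - 0.674), 0.02)
  mito <- grp("female.week10.mitotic", "scbs")
  expect_lt(abs(mean(mito) - 0.145), 0.02)
  mei <- grp("female.week17.meiotic", "scbs")
  expect_lt(abs(mean(mei) - 0.06), 0.02)
})

test_that("cohorts write one call file per cell per assay, deterministically", {
  cfg <- small_sim_config(seed = 55L)
  d1 <- file.path(tempdir(), "coh-det1")
  d2 <- file.path(tempdir(), "coh-det2")
  unlink(c(d1, d2), recursive = TRUE)
  co1 <- simulate_cohort(cfg, d1)
  co2 <- simulate_cohort(cfg, d2)
  expect_equal(nrow(co1$manifest), 2L * 30L)
  expect_equal(sum(file.exists(co1$manifest$path)), nrow(co1$manifest))
  # same seed: identical manifest and identical call files
  h1 <- tools::md5sum(file.path(d1, "manifest.tsv"))
  h2 <- tools::md5sum(file.path(d2, "manifest.tsv"))
  expect_equal(unname(h1), unname(h2))
  f1 <- sort(list.files(file.path(d1, "cells"), full.names = TRUE))
  f2 <- sort(list.files(file.path(d2, "cells"), full.names = TRUE))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a phase with zero cells is absent from the manifest", {
  cfg <- small_sim_config(seed = 77L)
  cfg$phases[[3]]$n_cells <- 0L
  d <- file.path(tempdir(), "coh-zero")
  unlink(d, recursive = TRUE)
  co <- simulate_cohort(cfg, d)
  expect_false(any(co$manifest$phase == "meiotic"))
  # truth still lists the phase's parameters
  expect_true("female.week17.meiotic" %in%
                colnames(co$truth$tile_truth))
  unlink(d, recursive = TRUE)
})

test_that("an efficiency at or below background warns", {
  expect_warning(sim_config(enzyme_efficiency = 0.02,
                            background_gch = 0.05), "unrecoverable")
})
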