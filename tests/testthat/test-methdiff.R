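# simulate per-cell tile-level matrices: each cell's tile level is the
# mean of `sites` Bernoulli(level) site calls, NA with prob miss
sim_tile_matrix <- function(n_cells, levels, sites = 5L, miss = 0.2,
                            prefix = "c") {
  n_tiles <- length(levels)
  m <- matrix(NA_real_, n_cells, n_tiles,
              dimnames = list(paste0(prefix, seq_len(n_cells)),
                              sprintf("chr1:%d-%d",
                                      (seq_len(n_tiles) - 1L) * 500L,
                                      seq_len(n_tiles) * 500L)))
  for (i in seq_len(n_cells)) {
    covered <- runif(n_tiles) > miss
    m[i, covered] <- rbinom(sum(covered), sites, levels[covered]) / sites
  }
  m
}

test_that("DMR calls require both mean thresholds and the FDR gate", {
  set.seed(4)
  lv_a <- c(rep(0.9, 5), rep(0.5, 45))
  lv_b <- c(rep(0.1, 5), rep(0.5, 45))
  A <- sim_tile_matrix(20, lv_a, miss = 0.1)
  B <- sim_tile_matrix(20, lv_b, miss = 0.1, prefix = "d")
  d <- call_dmrs(A, B, analysis_config())
  expect_true(all(d$call[1:5] == "demethylated"))
  expect_true(all(d$call[-(1:5)] == "stable"))
  # mirrored direction
  d2 <- call_dmrs(B, A, analysis_config())
  expect_true(all(d2$call[1:5] == "de_novo"))
  # big mean difference but insignificant q stays stable: two cells with
  # extreme levels in tiny groups cannot reach q <= 0.05 jointly with
  # 50 hypotheses at these group sizes? enforce via the q column instead
  expect_true(all(d$q[d$call == "demethylated"] <= 0.05))
  expect_true(all(d$mean_former[d$call == "demethylated"] > 0.75))
  expect_true(all(d$mean_latter[d$call == "demethylated"] < 0.25))
})

test_that("eligibility requires > 10% covered cells in both groups", {
  set.seed(6)
  A <- sim_tile_matrix(20, rep(0.5, 10), miss = 0)
  B <- sim_tile_matrix(20, rep(0.5, 10), miss = 0, prefix = "d")
  A[3:20, 1] <- NA  # 2/20 = 10%, not > 10%
  d <- call_dmrs(A, B, analysis_config())
  expect_false(colnames(A)[1] %in% d$tile)
  A2 <- A; A2[3, 1] <- 0.5  # 3/20 = 15%
  d2 <- call_dmrs(A2, B, analysis_config())
  expect_true(colnames(A)[1] %in% d2$tile)
})

test_that("identical groups stay calibrated and BH q is rank-monotone", {
  set.seed(10)
  false_rates <- replicate(10, {
    lv <- rbeta(100, 2, 8)
    A <- sim_tile_matrix(20, lv, miss = 0.2)
    B <- sim_tile_matrix(20, lv, miss = 0.2, prefix = "d")
    d <- call_dmrs(A, B, analysis_config())
    mean(d$call != "stable")
  })
  expect_true(mean(false_rates <= 0.05) >= 0.9)
  # BH monotone in p rank
  lv <- rbeta(60, 2, 2)
  A <- sim_tile_matrix(15, lv)
  B <- sim_tile_matrix(15, pmin(lv + 0.2, 1), prefix = "d")
  d <- call_dmrs(A, B, analysis_config())
  o <- order(d$p)
  expect_true(all(diff(d$q[o]) >= -1e-12))
})

test_that("true 0.9-vs-0.1 tiles are detected with >= 10 cells per group", {
  set.seed(12)
  hits <- replicate(20, {
    A <- sim_tile_matrix(12, rep(0.9, 20), miss = 0)
    B <- sim_tile_matrix(12, rep(0.1, 20), miss = 0, prefix = "d")
    d <- call_dmrs(A, B, analysis_config())
    mean(d$call == "demethylated")
  })
  expect_gte(mean(hits), 0.95)
})

test_that("exact permutation p is used at small n and is well calibrated", {
  # with 4 vs 4 distinct values the most extreme split has p = 2/70
  x <- c(10, 11, 12, 13) / 20
  y <- c(1, 2, 3, 4) / 20
  p <- scnome:::rank_sum_perm_p(x, y)
  expect_equal(p, 2 / choose(8, 4))
  expect_equal(scnome:::tile_test_p(x, y), p)
})

test_that("residual screen keeps tiles at or above 0.4 at every stage", {
  ids <- sprintf("chr1:%d-%d", 0:4 * 500L, 1:5 * 500L)
  mk <- function(means) {
    m <- matrix(rep(means, each = 10), 10, 5, byrow = FALSE,
                dimnames = list(paste0("c", 1:10), ids))
    m
  }
  s1 <- mk(c(0.5, 0.5, 0.45, 0.39, 0.6))
  s2 <- mk(c(0.45, 0.39, 0.41, 0.5, 0.6))
  s3 <- mk(c(0.41, 0.5, 0.40, 0.5, NA))  # tile 5 uncovered at stage 3
  s3[, 5] <- NA
  keep <- residual_tiles(list(s1, s2, s3), 0.4, 0.10)
  expect_setequal(keep, ids[c(1, 3)])
  # brute-force scan on a random fixture
  set.seed(14)
  stages <- replicate(3, sim_tile_matrix(10, runif(30, 0.2, 0.6)),
                      simplify = FALSE)
  keep2 <- residual_tiles(stages, 0.4, 0.10)
  brute <- colnames(stages[[1]])[apply(
    vapply(stages, function(m)
      colSums(!is.na(m)) / nrow(m) > 0.1 &
        !is.na(colMeans(m, na.rm = TRUE)) &
        colMeans(m, na.rm = TRUE) >= 0.4, logical(30)), 1, all)]
  expect_setequal(keep2, brute)
})

test_that("hypergeometric enrichment equals the factorial closed form", {
  # N=100, K=10, n=10, k=10: p = C(10,10) C(90,0) / C(100,10)
  tiles <- data.frame(chrom = "chr1", start = 0:99 * 500L)
  tiles$end <- tiles$start + 500L
  ann <- tiles[1:10, ]
  cand <- tiles[1:10, ]
  e <- hypergeom_enrichment(cand, tiles, ann)
  expect_equal(e$k, 10); expect_equal(e$K, 10); expect_equal(e$n, 10)
  expect_equal(e$p, 1 / choose(100, 10), tolerance = 1e-12)
  expect_equal(e$fold, 10)
  # candidates = background: fold 1, p = 1
  e2 <- hypergeom_enrichment(tiles, tiles, ann)
  expect_equal(e2$fold, 1)
  expect_equal(e2$p, 1)
  # normalization of the mass function
  expect_equal(sum(dhyper(0:10, 10, 90, 10)), 1, tolerance = 1e-12)
  expect_warning(hypergeom_enrichment(tiles[0, ], tiles, ann), "empty")
})

test_that("ICR profiles equal a brute-force per-interval recount", {
  set.seed(16)
  icr <- data.frame(chrom = "chr1", start = c(1000L, 5000L),
                    end = c(2000L, 6000L), name = c("ICR_a", "ICR_b"))
  groups <- list(
    g1 = replicate(4, calls_df("chr1", sort(sample(0:7000, 100)), "WCG",
                               rbinom(100, 1, 0.8), 0L),
                   simplify = FALSE),
    g2 = replicate(4, calls_df("chr1", sort(sample(0:7000, 100)), "WCG",
                               rbinom(100, 1, 0.1), 0L),
                   simplify = FALSE))
  groups <- lapply(groups, function(g) lapply(g, function(x) {
    x$n_unmeth <- 1L - x$n_meth; x }))
  prof <- icr_profile(groups, icr, "WCG")
  # brute force: pool counts per site, mean of site levels inside interval
  for (g in names(groups)) {
    allc <- data.table::rbindlist(groups[[g]])
    pooled <- allc[, list(m = sum(n_meth), t = sum(n_meth + n_unmeth)),
                   by = pos]
    for (i in 1:2) {
      inside <- pooled[pos >= icr$start[i] & pos < icr$end[i]]
      expect_equal(prof[icr$name[i], g], mean(inside$m / inside$t))
    }
  }
  # fully methylated interval is exactly 1; uncovered interval is NA
  g3 <- list(all1 = list(calls_df("chr1", 1100:1110, "WCG", 1L, 0L)))
  prof3 <- icr_profile(g3, icr, "WCG")
  expect_equal(unname(prof3["ICR_a", "all1"]), 1)
  expect_true(is.na(prof3["ICR_b", "all1"]))
})
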