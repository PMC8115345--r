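test_that("promoter windows orient by strand", {
  tss <- data.frame(gene = c("p", "m"), chrom = "chr1",
                    tss = c(5000L, 9000L), strand = c("+", "-"))
  w <- promoter_windows(tss, up = 1000L, down = 500L)
  expect_equal(c(w$start[1], w$end[1]), c(4000L, 5500L))
  # minus strand: upstream lies above the TSS
  expect_equal(c(w$start[2], w$end[2]), c(8501L, 10001L))
  expect_equal(w$end - w$start, c(1500L, 1500L))
})

test_that("degenerate promoters classify as expected", {
  # alternating CG repeat: maximal CpG density -> HCP
  cg <- paste(rep("CG", 2000), collapse = "")
  pad <- paste(rep("AT", 2000), collapse = "")
  genome <- c(chr1 = paste0(pad, cg, pad))
  tss <- data.frame(gene = "g", chrom = "chr1", tss = 5000L, strand = "+")
  expect_equal(classify_promoters(genome, tss)$class, "HCP")
  # no CpGs at all -> LCP
  genome2 <- c(chr1 = paste(rep("ATGA", 3000), collapse = ""))
  expect_equal(classify_promoters(genome2, tss)$class, "LCP")
})

test_that("promoter classification matches a brute-force subwindow scan", {
  co <- shared_cohort()
  cfg <- analysis_config()
  got <- classify_promoters(co$sim$genome, co$sim$tss, cfg)
  brute_one <- function(seq) {
    b <- strsplit(seq, "")[[1]]
    L <- length(b)
    best_hcp <- FALSE; any_mid <- FALSE
    for (s in seq_len(L - 500 + 1)) {
      w <- b[s:(s + 499)]
      nC <- sum(w == "C"); nG <- sum(w == "G")
      nP <- sum(w[-500] == "C" & w[-1] == "G")
      oe <- if (nC * nG > 0) nP / (nC * nG / 500) else 0
      if (oe > cfg$hcp_obs_exp && (nC + nG) / 500 > cfg$hcp_gc)
        best_hcp <- TRUE
      if (oe > cfg$lcp_obs_exp) any_mid <- TRUE
    }
    if (best_hcp) "HCP" else if (!any_mid) "LCP" else "ICP"
  }
  set.seed(77)
  idx <- sample(nrow(co$sim$tss), 8)
  w <- promoter_windows(co$sim$tss[idx, ], cfg$prom_meth_up,
                        cfg$prom_meth_down, chrom_sizes(co$sim$genome))
  brute <- vapply(seq_len(nrow(w)), function(i)
    brute_one(substr(co$sim$genome[[w$chrom[i]]], w$start[i] + 1L,
                     w$end[i])), "")
  expect_equal(got$class[idx], brute)
  # classes partition all genes
  expect_equal(sum(table(got$class)), nrow(co$sim$tss))
})

test_that("promoter signals equal a brute-force recount and orient windows", {
  tss <- data.frame(gene = c("p", "m"), chrom = "chr1",
                    tss = c(2000L, 6000L), strand = c("+", "-"))
  set.seed(19)
  cells <- replicate(3, {
    pos <- sort(sample(0:7999, 600))
    x <- calls_df("chr1", pos, sample(c("WCG", "GCH"), 600, TRUE),
                  rbinom(600, 1, 0.4), 0L)
    x$n_unmeth <- 1L - x$n_meth
    x
  }, simplify = FALSE)
  sig <- promoter_signals(list(g = cells), tss, analysis_config())
  pooled_w <- pool_group(cells, "WCG")
  pooled_a <- pool_group(cells, "GCH")
  brute_mean <- function(pool, lo, hi) {
    p <- pool[pool$pos >= lo & pool$pos < hi, ]
    mean(p$n_meth / (p$n_meth + p$n_unmeth))
  }
  expect_equal(sig$meth_level[1], brute_mean(pooled_w, 1000, 2500))
  expect_equal(sig$acc_level[1], brute_mean(pooled_a, 1800, 2100))
  # minus-strand gene: meth window [tss-499, tss+1001)
  expect_equal(sig$meth_level[2], brute_mean(pooled_w, 5501, 7001))
  expect_equal(sig$acc_level[2], brute_mean(pooled_a, 5901, 6201))
})

test_that("per-class Spearman correlations behave on constructed data", {
  genes <- sprintf("g%02d", 1:12)
  classes <- data.frame(gene = genes, class = rep("HCP", 12))
  expr <- setNames(1:12, genes)
  sig <- data.frame(gene = genes, meth_level = rev(1:12) / 12,
                    acc_level = (1:12) / 12)
  rho <- omics_correlation(sig, expr, classes)
  expect_equal(rho$rho_expr_meth, -1)
  expect_equal(rho$rho_expr_acc, 1)
  # invariance under monotone transform of expression
  rho2 <- omics_correlation(sig, exp(expr / 3), classes)
  expect_equal(rho2$rho_expr_meth, rho$rho_expr_meth)
  # constant accessibility: rho undefined
  sig$acc_level <- 0.5
  rho3 <- omics_correlation(sig, expr, classes)
  expect_true(is.na(rho3$rho_expr_acc))
  # < 3 complete genes: missing with warning
  sig4 <- sig[1:2, ]
  expect_warning(r4 <- omics_correlation(sig4, expr, classes), "fewer")
  expect_true(is.na(r4$rho_expr_meth))
  # rank oracle on a 10-gene fixture
  set.seed(23)
  sig5 <- data.frame(gene = genes[1:10], meth_level = runif(10),
                     acc_level = runif(10))
  e5 <- setNames(runif(10), genes[1:10])
  r5 <- omics_correlation(sig5, e5, classes[1:10, ])
  expect_equal(r5$rho_expr_meth,
               cor(rank(e5), rank(sig5$meth_level)))
})

test_that("NDRs map to their nearest gene with lexicographic ties", {
  tss <- data.frame(gene = c("b_gene", "a_gene"), chrom = "chr1",
                    tss = c(1000L, 3000L), strand = "+")
  nd <- data.frame(chrom = "chr1", start = c(1900L, 900L, 8000L),
                   end = c(2100L, 1100L, 8200L))
  got <- assign_ndr_genes(nd, tss, 2000L)
  # center 2000 is equidistant: tie broken to "a_gene"
  expect_equal(got$gene, c("a_gene", "b_gene"))
  expect_equal(nrow(got), 2L)  # NDR at 8000 has no TSS within 2 kb
})

test_that("phase screen selects proportional pairs above r = 0.6 only", {
  tss <- data.frame(gene = c("up", "down"), chrom = "chr1",
                    tss = c(1000L, 5000L), strand = "+")
  nd <- data.frame(chrom = "chr1", start = c(900L, 4900L),
                   end = c(1100L, 5100L))
  mk_phase <- function(lv1, lv2) list(
    calls_df("chr1", c(seq(920L, 1080L, 20L), seq(4920L, 5080L, 20L)),
             "GCH",
             as.integer(c(rep(lv1, 9), rep(lv2, 9))),
             as.integer(c(rep(1 - lv1, 9), rep(1 - lv2, 9)))))
  phases <- list(p1 = mk_phase(1, 0), p2 = mk_phase(0, 1),
                 p3 = mk_phase(0, 1), p4 = mk_phase(0, 0))
  # expression proportional to each NDR's accessibility profile
  expr <- rbind(up = c(10, 1, 1, 1), down = c(1, 10, 10, 1))
  colnames(expr) <- names(phases)
  got <- phase_specific_genes(nd, phases, expr, tss, analysis_config())
  expect_equal(got$selected[got$gene == "up"], TRUE)
  expect_equal(got$selected[got$gene == "down"], TRUE)
  expect_true(all(got$r > 0.99))
  # anti-proportional: r = -1, not selected
  expr2 <- rbind(up = c(1, 10, 10, 10), down = c(10, 1, 1, 10))
  colnames(expr2) <- names(phases)
  got2 <- phase_specific_genes(nd, phases, expr2, tss, analysis_config())
  expect_true(all(!got2$selected))
  expect_true(all(got2$r < -0.99))
})
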