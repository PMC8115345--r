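# helper: a pooled GCH track from explicit site specs
gch_track <- function(pos, n_meth, n_unmeth, chrom = "chr1") {
  pool_group(list(calls_df(chrom, pos, "GCH", n_meth, n_unmeth)), "GCH")
}

test_that("pooling sums counts per site and is identity for one cell", {
  a <- calls_df("chr1", c(10, 20), "GCH", c(1, 2), c(0, 1))
  b <- calls_df("chr1", c(10, 30), "GCH", c(2, 1), c(1, 0))
  p <- pool_group(list(a, b), "GCH")
  expect_equal(p[p$pos == 10L, ]$n_meth, 3L)
  expect_equal(p[p$pos == 10L, ]$n_unmeth, 1L)
  expect_equal(nrow(p), 3L)
  one <- pool_group(list(a), "GCH")
  expect_equal(one$n_meth, a$n_meth)
  expect_equal(attr(p, "c_total"), 6L)
  expect_equal(attr(p, "t_total"), 2L)
})

test_that("window chi-square is one-sided and matches an independent tail", {
  # wrong direction: all-unmethylated window has p = 1 (log10 p = 0)
  expect_equal(window_chisq(0, 10, 3e4, 9.7e5), 0)
  # monotone in the methylated count
  lps <- window_chisq(c(5, 10, 20, 40), 0, 3e4, 9.7e5)
  expect_true(all(diff(lps) < 0))
  # independent evaluation: chisq.test statistic + normal-tail identity
  oracle <- function(a, b, cc, d) {
    stat <- suppressWarnings(stats::chisq.test(
      matrix(c(a, b, cc, d), 2, byrow = TRUE), correct = FALSE)$statistic)
    (log(2) + stats::pnorm(sqrt(stat), lower.tail = FALSE,
                           log.p = TRUE)) / log(10)
  }
  got <- window_chisq(40, 10, 3e4, 9.7e5)
  expect_equal(got, unname(oracle(40, 10, 3e4, 9.7e5)),
               tolerance = 1e-10)
  expect_error(window_chisq(1, 0, 0, 0), "zero")
})

test_that("NDR calling follows the window/step/length/site geometry", {
  cfg <- analysis_config()
  sizes <- c(chr1 = 20000L)
  bg_pos <- seq(5000L, 19000L, by = 10L)
  bg <- list(pos = bg_pos, m = rep(0L, length(bg_pos)),
             u = rep(1L, length(bg_pos)))
  # hot sites across [5, 95] with deep methylated coverage: windows
  # starting 0..80 are significant, span [0, 180) -> one NDR (len 180)
  hot_pos <- seq(5L, 95L, by = 10L)
  tr <- gch_track(c(hot_pos, bg$pos), c(rep(30L, 10), bg$m),
                  c(rep(0L, 10), bg$u))
  nd <- call_ndrs(tr, cfg, sizes)
  expect_equal(nrow(nd), 1L)
  expect_equal(c(nd$start, nd$end), c(0L, 180L))
  expect_gte(nd$n_gch, 5L)
  expect_true(nd$pooled_level > attr(tr, "c_total") /
                (attr(tr, "c_total") + attr(tr, "t_total")))
  # one isolated significant window (span 100 <= 140): no NDR
  iso_pos <- c(2L, 4L, 6L, 8L, 10L)
  tr2 <- gch_track(c(iso_pos, bg$pos), c(rep(30L, 5), bg$m),
                   c(rep(0L, 5), bg$u))
  expect_equal(nrow(call_ndrs(tr2, cfg, sizes)), 0L)
  # no significant windows at all: empty
  tr3 <- gch_track(bg$pos, bg$m, bg$u)
  expect_equal(nrow(call_ndrs(tr3, cfg, sizes)), 0L)
})

test_that("relaxing the NDR p threshold only grows the called set", {
  co <- shared_cohort()
  cool <- co$manifest[co$manifest$assay == "cool" &
                        co$manifest$phase == "mitotic", ]
  cells <- lapply(cool$path, read_site_calls)
  tr <- pool_group(cells, "GCH")
  sizes <- chrom_sizes(co$sim$genome)
  strict <- call_ndrs(tr, analysis_config(ndr_p = 1e-40), sizes)
  loose <- call_ndrs(tr, analysis_config(ndr_p = 1e-20), sizes)
  expect_gte(nrow(loose), nrow(strict))
  if (nrow(strict)) {
    contained <- vapply(seq_len(nrow(strict)), function(i) {
      any(loose$chrom == strict$chrom[i] &
            loose$start <= strict$start[i] &
            loose$end >= strict$end[i])
    }, logical(1))
    expect_true(all(contained))
  }
})

test_that("NDR centers classify proximal within 2 kb, distal beyond", {
  tss <- data.frame(gene = c("g1", "g2"), chrom = "chr1",
                    tss = c(10000L, 50000L), strand = c("+", "-"))
  nd <- data.frame(chrom = "chr1",
                   start = c(9900L, 12000L - 100L, 12001L - 100L,
                             47999L - 100L),
                   end = c(10100L, 12000L + 100L, 12001L + 100L,
                           47999L + 100L))
  cls <- classify_ndrs(nd, tss, 2000L)
  # centers: 10000 (at a TSS), 12000 (exactly 2 kb: proximal),
  # 12001 (2001 bp from every TSS: distal), 47999 (2001 bp: distal)
  expect_equal(cls$class, c("proximal", "proximal", "distal", "distal"))
  # all-pairs oracle on a random fixture
  set.seed(13)
  nd2 <- data.frame(chrom = "chr1", start = sample.int(60000, 80))
  nd2$end <- nd2$start + 200L
  cls2 <- classify_ndrs(nd2, tss, 2000L)
  brute <- vapply(seq_len(nrow(nd2)), function(i) {
    ctr <- (nd2$start[i] + nd2$end[i]) %/% 2
    if (min(abs(tss$tss - ctr)) <= 2000) "proximal" else "distal"
  }, "")
  expect_equal(cls2$class, brute)
})

test_that("differential openness applies coverage, difference and
           exclusivity gates", {
  cfg <- analysis_config()
  reg <- data.frame(chrom = "chr1", start = 0L, end = 200L)
  mk_cell <- function(level, n_sites = 6L) {
    calls_df("chr1", seq(10L, by = 30L, length.out = n_sites), "GCH",
             as.integer(round(level * 1)), 1L - as.integer(round(level)))
  }
  # group A open (level 1), group B closed (level 0)
  A <- replicate(10, mk_cell(1), simplify = FALSE)
  B <- replicate(10, mk_cell(0), simplify = FALSE)
  d <- differential_open(reg, A, B, cfg)
  expect_true(d$called)
  expect_equal(d$direction, "A_open")
  # swapping groups flips direction only
  d2 <- differential_open(reg, B, A, cfg)
  expect_true(d2$called)
  expect_equal(d2$direction, "B_open")
  # coverage gate: only 4/10 cells of A covered (0.4 not > 0.4)
  A_sparse <- c(replicate(4, mk_cell(1), simplify = FALSE),
                replicate(6, calls_df("chr1", integer(0), character(0),
                                      integer(0), integer(0)),
                          simplify = FALSE))
  d3 <- differential_open(reg, A_sparse, B, cfg)
  expect_false(d3$called)
  expect_equal(d3$reason, "coverage")
  expect_error(differential_open(reg, list(), B, cfg), "at least one")
})

test_that("label permutation between identical groups rarely calls regions", {
  set.seed(99)
  cfg <- analysis_config()
  n_reg <- 200L
  regions <- data.frame(chrom = "chr1",
                        start = seq(0L, by = 300L, length.out = n_reg))
  regions$end <- regions$start + 200L
  mk_cell <- function() {
    rows <- lapply(seq_len(n_reg), function(r) {
      pos <- regions$start[r] + sort(sample(0:199, 5))
      calls_df("chr1", pos, "GCH", rbinom(5, 1, 0.35), 0L)
    })
    out <- data.table::rbindlist(rows)
    out$n_unmeth <- 1L - out$n_meth
    out
  }
  cells <- replicate(30, mk_cell(), simplify = FALSE)
  idx <- sample(30)
  d <- differential_open(regions, cells[idx[1:15]], cells[idx[16:30]], cfg)
  expect_lte(sum(d$called), 0.05 * n_reg)
})

test_that("open-chromatin enrichment matches closed forms and a base-level
           recount", {
  ndrs <- data.frame(chrom = "chr1", start = c(100L, 800L),
                     end = c(300L, 1000L))
  whole <- data.frame(chrom = "chr1", start = 0L, end = 10000L)
  e0 <- open_enrichment(ndrs, list(all = whole), 10000)
  expect_equal(e0$enrichment, 0)
  quarter <- data.frame(chrom = "chr1", start = 0L, end = 2500L)
  e2 <- open_enrichment(ndrs, list(q = quarter), 10000)
  expect_equal(e2$enrichment, 2)  # log2(1 / 0.25)
  # base-by-base oracle on a 10-kb toy genome
  set.seed(41)
  nd <- data.frame(chrom = "chr1", start = sample(0:9800, 12))
  nd$end <- nd$start + sample(50:150, 12, TRUE)
  ann <- data.frame(chrom = "chr1", start = sample(0:9500, 8))
  ann$end <- ann$start + sample(100:400, 8, TRUE)
  e <- open_enrichment(nd, list(x = ann), 10000)
  in_nd <- rep(FALSE, 10000); in_ann <- rep(FALSE, 10000)
  for (i in seq_len(nrow(nd))) in_nd[(nd$start[i] + 1):nd$end[i]] <- TRUE
  for (i in seq_len(nrow(ann)))
    in_ann[(ann$start[i] + 1):ann$end[i]] <- TRUE
  brute <- log2((sum(in_nd & in_ann) / sum(in_nd)) /
                  (sum(in_ann) / 10000))
  expect_equal(e$enrichment, brute)
  expect_warning(open_enrichment(nd, list(z = whole[0, ]), 10000), "zero")
})
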