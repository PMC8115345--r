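# Shared fixtures, built in code.

# quick call-table constructor (0-based positions)
calls_df <- function(chrom, pos, context, n_meth, n_unmeth,
                     strand = "+") {
  if (length(pos) == 0L)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  strand = character(),
                                  context = character(),
                                  n_meth = integer(),
                                  n_unmeth = integer()))
  data.table::data.table(chrom = chrom, pos = as.integer(pos),
                         strand = strand, context = context,
                         n_meth = as.integer(n_meth),
                         n_unmeth = as.integer(n_unmeth))
}

# independent brute-force trinucleotide classifier: literal rule table
oracle_classify_tri <- function(tri) {
  wcg <- c("ACG", "TCG"); gch <- c("GCA", "GCC", "GCT")
  if (tri %in% wcg) "WCG"
  else if (tri %in% gch) "GCH"
  else if (tri == "GCG") "GCG"
  else "other"
}

revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

all_trinucs <- function() {
  b <- c("A", "C", "G", "T")
  apply(expand.grid(b, b, b), 1, paste, collapse = "")
}

# a small cohort shared across tests (built once per run)
.fixture_env <- new.env(parent = emptyenv())

small_sim_config <- function(seed = 42L) {
  sim_config(
    n_chroms = 1L, chrom_len = 100000L, n_genes = 18L,
    open_genes_per_phase = 4L,
    phases = list(
      list(name = "soma", sex = "female", week = 17L, is_fgc = FALSE,
           n_cells = 10L, mean_cpg_meth = 0.674),
      list(name = "mitotic", sex = "female", week = 10L, is_fgc = TRUE,
           n_cells = 10L, mean_cpg_meth = 0.145),
      list(name = "meiotic", sex = "female", week = 17L, is_fgc = TRUE,
           n_cells = 10L, mean_cpg_meth = 0.06)),
    seed = seed)
}

shared_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    dir <- file.path(tempdir(), "scnome-shared-cohort")
    unlink(dir, recursive = TRUE)
    .fixture_env$cohort <- simulate_cohort(small_sim_config(), dir)
  }
  .fixture_env$cohort
}

relaxed_qc_config <- function(...) {
  analysis_config(qc_scbs_min_cpg = 200, qc_cool_min_wcg = 100,
                  qc_cool_min_gch = 500, ...)
}

# Library QC boundary fixture: cells straddling every printed threshold.
qc_fixture <- function() {
  data.frame(
    cell_id = sprintf("c%02d", 1:10),
    assay = c(rep("scbs", 7), rep("cool", 3)),
    is_fgc = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
               TRUE, TRUE, TRUE),
    map_rate = c(0.19, 0.20, 0.30, 0.30, 0.30, 0.30, 0.30,
                 0.20, 0.19, 0.30),
    conversion = c(0.995, 0.995, 0.989, 0.990, 0.995, 0.995, 0.995,
                   NA, NA, NA),
    non_cpg_meth = c(0.01, 0.01, 0.01, 0.02, 0.021, 0.01, 0.01,
                     NA, NA, NA),
    n_cpg = c(3e6, 3e6, 3e6, 3e6, 3e6, 2e6 - 1, 2e6 + 1,
              NA, NA, NA),
    n_wcg = c(NA, NA, NA, NA, NA, NA, NA, 1e6 + 1, 1e6 + 1, 1e6 - 1),
    n_gch = c(NA, NA, NA, NA, NA, NA, NA, 1e7 + 1, 1e7 - 1, 1e7 + 1),
    global_meth = c(0.15, 0.20, 0.15, 0.15, 0.15, 0.15, 0.21,
                    0.20, 0.15, 0.15),
    stringsAsFactors = FALSE)
}

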