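#' Read a per-cell cytosine call table
#'
#' The on-disk dialect is bismark-coverage-like: tab-separated columns
#' `chrom`, `pos` (1-based), `strand` (+/-), `context`
#' (WCG/GCH/GCG/CpG/other), `n_meth`, `n_unmeth`, with or without a header
#' line. Positions are converted to 0-based on read; rows with zero total
#' depth are dropped; output is sorted by (chrom, pos, strand). Cytosines on
#' the two strands are independent records and are never collapsed.
#'
#' @param path call-table TSV.
#' @param expected_contexts contexts allowed in the file; anything else is a
#'   validation error.
#' @return A `data.table` with columns `chrom`, `pos` (0-based), `strand`,
#'   `context`, `n_meth`, `n_unmeth`.
#' @export
read_site_calls <- function(path,
                            expected_contexts = c("WCG", "GCH", "GCG",
                                                  "CpG", "other")) {
  cols <- c("chrom", "pos", "strand", "context", "n_meth", "n_unmeth")
  first <- tryCatch(readLines(path, n = 1L), error = function(e)
    stop("cannot read call table: ", path))
  if (length(first) == 0L) {
    dt <- data.table::data.table(
      chrom = character(), pos = integer(), strand = character(),
      context = character(), n_meth = integer(), n_unmeth = integer())
    return(dt)
  }
  has_header <- startsWith(first, "chrom")
  dt <- data.table::fread(path, header = has_header, sep = "\t",
                          colClasses = list(character = c(1L, 3L, 4L)))
  if (ncol(dt) != 6L)
    stop("call table ", path, ": expected 6 columns, found ", ncol(dt))
  data.table::setnames(dt, cols)
  line0 <- if (has_header) 1L else 0L
  bad_pos <- which(!is.finite(dt$pos) | dt$pos < 1 | dt$pos != round(dt$pos))
  if (length(bad_pos))
    stop("call table ", path, " line ", bad_pos[1] + line0,
         ": malformed position ", dt$pos[bad_pos[1]])
  bad_strand <- which(!dt$strand %in% c("+", "-"))
  if (length(bad_strand))
    stop("call table ", path, " line ", bad_strand[1] + line0,
         ": strand must be + or -")
  bad_counts <- which(!is.finite(dt$n_meth) | !is.finite(dt$n_unmeth) |
                        dt$n_meth < 0 | dt$n_unmeth < 0)
  if (length(bad_counts))
    stop("call table ", path, " line ", bad_counts[1] + line0,
         ": negative or missing counts")
  bad_ctx <- which(!dt$context %in% expected_contexts)
  if (length(bad_ctx))
    stop("call table ", path, " line ", bad_ctx[1] + line0,
         ": unexpected context '", dt$context[bad_ctx[1]], "'")
  dt[, `:=`(pos = as.integer(pos - 1L),
            n_meth = as.integer(n_meth), n_unmeth = as.integer(n_unmeth))]
  dt <- dt[n_meth + n_unmeth > 0L]
  data.table::setorder(dt, chrom, pos, strand)
  dt[]
}

#' @rdname read_site_calls
#' @param calls a call table as returned by [read_site_calls()] (0-based).
#' @export
write_site_calls <- function(calls, path) {
  out <- data.table::as.data.table(calls)
  out <- out[, list(chrom, pos = pos + 1L, strand, context,
                    n_meth, n_unmeth)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write / read intervals as BED
#'
#' Standard BED6 (chrom, start, end, name, score, strand), 0-based
#' half-open; extra columns beyond the six are appended and round-trip
#' through [read_bed()].
#'
#' @param intervals data.frame with `chrom`, `start`, `end`; optional
#'   `name`, `strand`, extra columns.
#' @param path output path.
#' @param score_field name of the column written to the BED score slot
#'   (default: constant 0).
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, score_field = NULL) {
  df <- as.data.frame(intervals)
  if (nrow(df) > 0L && any(df$start >= df$end))
    stop("invalid interval: start >= end")
  if (nrow(df) == 0L) { file.create(path); return(invisible(path)) }
  name <- if ("name" %in% names(df)) df$name else
    paste0("region_", seq_len(nrow(df)))
  score <- if (!is.null(score_field)) df[[score_field]] else 0
  strand <- if ("strand" %in% names(df)) df$strand else "."
  extra <- df[, setdiff(names(df), c("chrom", "start", "end", "name",
                                     "strand")), drop = FALSE]
  if (!is.null(score_field)) extra[[score_field]] <- NULL
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = name, score = score, strand = strand,
                    stringsAsFactors = FALSE)
  if (ncol(extra)) out <- cbind(out, extra)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  base <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(dt, seq_len(min(ncol(dt), 6L)),
                       base[seq_len(min(ncol(dt), 6L))])
  if (ncol(dt) > 6L)
    data.table::setnames(dt, 7L:ncol(dt), paste0("V", 7L:ncol(dt) - 6L))
  if (any(dt$start >= dt$end)) stop("invalid BED interval: start >= end")
  as.data.frame(dt)
}

#' Read / write a cell manifest
#'
#' A manifest is a TSV with columns `cell_id`, `assay` (`scbs` or `cool`),
#' `sex`, `week`, `phase`, `path` (call table file, relative to the
#' manifest's directory or absolute). Cells are grouped by
#' `(sex, week, phase)` throughout the pipeline.
#'
#' @param path manifest TSV.
#' @return data.frame with the manifest columns plus `group` and a resolved
#'   absolute `path`.
#' @export
read_manifest <- function(path) {
  m <- as.data.frame(data.table::fread(path, sep = "\t",
                                       colClasses = list(character = "cell_id")))
  need <- c("cell_id", "assay", "sex", "week", "phase", "path")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(m$assay %in% c("scbs", "cool")))
    stop("manifest assay must be 'scbs' or 'cool'")
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m$group <- cell_group(m)
  m
}

#' @rdname read_manifest
#' @param manifest manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  keep <- c("cell_id", "assay", "sex", "week", "phase", "path")
  data.table::fwrite(manifest[, keep], path, sep = "\t")
  invisible(path)
}

#' Group label for manifest rows: `sex.weekNN.phase`
#' @param manifest manifest data.frame.
#' @export
cell_group <- function(manifest) {
  sprintf("%s.week%02d.%s", manifest$sex, as.integer(manifest$week),
          manifest$phase)
}

#' Read a genes-by-groups expression table
#'
#' TSV with a `gene` column followed by one numeric column per cell group.
#'
#' @param path expression TSV.
#' @return numeric matrix, genes as rownames, groups as colnames.
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  if (names(dt)[1] != "gene") stop("expression table must start with 'gene'")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt$gene
  if (any(m < 0)) stop("expression values must be nonnegative")
  m
}

#' @rdname read_expression
#' @param expr genes-by-groups matrix.
#' @export
write_expression <- function(expr, path) {
  dt <- data.table::data.table(gene = rownames(expr))
  dt <- cbind(dt, data.table::as.data.table(expr))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Write a tile matrix as TSV (tiles as rows, cells as columns)
#'
#' Missing entries are written as empty strings so the export loads into
#' any clustering tool.
#'
#' @param tm a tile matrix as returned by [build_tile_matrix()] (or its
#'   `values` matrix with `chrom:start-end` rownames).
#' @param path output TSV.
#' @export
write_tile_matrix <- function(tm, path) {
  values <- if (is.list(tm) && !is.null(tm$values)) tm$values else tm
  dt <- data.table::data.table(tile = rownames(values))
  dt <- cbind(dt, data.table::as.data.table(values))
  data.table::fwrite(dt, path, sep = "\t", na = "")
  invisible(path)
}

#' Read a TSS / gene annotation table
#'
#' TSV with columns `gene`, `chrom`, `tss` (0-based position of the
#' transcription start site), `strand`.
#' @param path TSS TSV.
#' @return data.frame.
#' @export
read_tss <- function(path) {
  tss <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("gene", "chrom", "tss", "strand")
  miss <- setdiff(need, names(tss))
  if (length(miss)) stop("TSS table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(tss$strand %in% c("+", "-"))) stop("TSS strand must be + or -")
  tss
}
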