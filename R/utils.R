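# Interval helpers. All intervals in the package are 0-based half-open
# [start, end) on an unstranded genome unless a strand column is present.

#' Convert an interval data.frame to a GRanges
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `strand`.
#' @return A [GenomicRanges::GRanges] (1-based closed, as GRanges requires).
#' @keywords internal
as_granges <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  strand <- if ("strand" %in% names(df))
    ifelse(df$strand %in% c("+", "-"), df$strand, "*") else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

#' Convert a GRanges back to a 0-based half-open data.frame
#' @keywords internal
granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Merge overlapping or book-ended intervals
#' @param df interval data.frame (chrom/start/end, 0-based half-open).
#' @return merged intervals, same convention, sorted.
#' @keywords internal
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  granges_to_df(GenomicRanges::reduce(as_granges(df)))
}

#' Total bases covered by an interval set (after merging)
#' @keywords internal
interval_bases <- function(df) {
  if (nrow(df) == 0L) return(0)
  m <- merge_intervals(df)
  sum(m$end - m$start)
}

#' Bases shared between two interval sets (each merged first)
#' @keywords internal
interval_intersect_bases <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  ov <- GenomicRanges::intersect(
    GenomicRanges::reduce(as_granges(a)),
    GenomicRanges::reduce(as_granges(b))
  )
  sum(GenomicRanges::width(ov))
}

#' Does each query interval overlap any subject interval by >= 1 bp?
#' @keywords internal
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0L) return(logical(0))
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  # chromosome sets may legitimately differ between query and subject
  suppressWarnings(IRanges::overlapsAny(as_granges(query),
                                        as_granges(subject)))
}

#' Chromosome sizes of a genome
#' @param genome named character vector or [Biostrings::DNAStringSet].
#' @return named integer vector of sequence lengths.
#' @export
chrom_sizes <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else {
    vapply(genome, nchar, integer(1))
  }
}

#' Sliding-window starts covering [0, len)
#' @keywords internal
window_starts <- function(len, window, step) {
  if (len < window) return(integer(0))
  seq.int(0L, len - window, by = step)
}

# format a tile/interval id like "chr1:0-500"
interval_id <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, start, end)
}

parse_interval_id <- function(id) {
  m <- regmatches(id, regexec("^(.+):([0-9]+)-([0-9]+)$", id))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("malformed interval id: ", id[bad][1])
  data.frame(
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}
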