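#' Configuration for long-read quality control
#'
#' Defaults mirror the published final read filter (keep reads longer
#' than 1500 bp with mean quality above Phred 10) and a sliding-window
#' splitter that removes low-quality regions: reads are tiled with
#' non-overlapping `window_len` windows, windows at or below
#' `window_min_meanq` are removed, and the surviving runs are re-emitted
#' as segments of at least `min_segment_len`.
#'
#' @param filter_min_len minimum read length (strict `>`), nt.
#' @param filter_min_meanq minimum mean Phred quality (strict `>`).
#' @param window_len window size for [split_reads()], nt.
#' @param window_min_meanq windows with mean quality `<=` this are removed.
#' @param min_segment_len shortest segment worth keeping, nt.
#' @return object of class `qc_config`.
#' @export
qc_config <- function(filter_min_len = 1500L, filter_min_meanq = 10,
                      window_len = 100L, window_min_meanq = 10,
                      min_segment_len = 500L) {
  assert_count(filter_min_len, "filter_min_len", min = 1L)
  assert_count(window_len, "window_len", min = 1L)
  assert_count(min_segment_len, "min_segment_len", min = 1L)
  if (filter_min_meanq < 0 || window_min_meanq < 0)
    stopf("invalid config: quality thresholds must be positive")
  if (window_len > min_segment_len)
    warnf("window_len (%d) exceeds min_segment_len (%d); single kept windows will be dropped",
          window_len, min_segment_len)
  structure(list(filter_min_len = as.integer(filter_min_len),
                 filter_min_meanq = filter_min_meanq,
                 window_len = as.integer(window_len),
                 window_min_meanq = window_min_meanq,
                 min_segment_len = as.integer(min_segment_len)),
            class = "qc_config")
}

#' Mean read quality in probability space
#'
#' Per-base Phred scores are converted to error probabilities, averaged,
#' and converted back: `-10 log10(mean(10^(-Q/10)))`.  This is the
#' standard definition used by long-read QC tools (a plain average of
#' Phred values would understate the error rate).
#'
#' @param qualities numeric vector of per-base Phred scores.
#' @return mean quality (Phred).
#' @examples
#' mean_quality(c(20, 0))  # ~2.97, dominated by the bad base
#' @export
mean_quality <- function(qualities) {
  if (!length(qualities)) stopf("input error: empty quality vector")
  -10 * log10(mean(10^(-qualities / 10)))
}

#' Read / write FASTQ (Sanger Phred+33)
#' @param path FASTQ path.
#' @return `read_fastq` returns a `QualityScaledDNAStringSet`.
#' @export
read_fastq <- function(path) {
  Biostrings::readQualityScaledDNAStringSet(path)
}

#' @rdname read_fastq
#' @param reads a `QualityScaledDNAStringSet`.
#' @export
write_fastq <- function(reads, path) {
  x <- as(reads, "DNAStringSet")
  S4Vectors::mcols(x) <- NULL
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::quality(reads))
  invisible(path)
}

quality_ints <- function(reads) {
  as(Biostrings::quality(reads), "IntegerList")
}

resolve_reads <- function(reads) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  if (!is(reads, "QualityScaledDNAStringSet"))
    stopf("parse error: expected a FASTQ path or QualityScaledDNAStringSet")
  reads
}

#' Filter reads by length and mean quality
#'
#' Keeps reads with length strictly greater than `filter_min_len` and
#' probability-space mean quality strictly greater than
#' `filter_min_meanq`; record order and content are preserved.
#'
#' @param reads FASTQ path or `QualityScaledDNAStringSet`.
#' @param config a [qc_config()].
#' @param out optional output FASTQ path.
#' @return the kept `QualityScaledDNAStringSet`.
#' @export
filter_reads <- function(reads, config = qc_config(), out = NULL) {
  reads <- resolve_reads(reads)
  q <- quality_ints(reads)
  meanq <- vapply(seq_along(reads), function(i) mean_quality(q[[i]]), numeric(1))
  keep <- Biostrings::width(reads) > config$filter_min_len &
    meanq > config$filter_min_meanq
  kept <- reads[keep]
  if (!is.null(out)) write_fastq(kept, out)
  kept
}

#' Split reads at low-quality regions
#'
#' Each read is tiled with non-overlapping windows of `window_len` nt
#' (the final partial window included).  Windows whose probability-space
#' mean quality is at or below `window_min_meanq` are removed; maximal
#' runs of kept windows become segments, segments shorter than
#' `min_segment_len` are discarded.  Segment ids are suffixed
#' `:<start>-<end>` (0-based half-open on the source read).
#'
#' @param reads FASTQ path or `QualityScaledDNAStringSet`.
#' @param config a [qc_config()].
#' @param out optional output FASTQ path for the segments.
#' @return list with `segments` (a `QualityScaledDNAStringSet`) and
#'   `removed` (data frame `read`, `window_start`, `window_end`,
#'   `mean_q` of removed windows).
#' @export
split_reads <- function(reads, config = qc_config(), out = NULL) {
  reads <- resolve_reads(reads)
  q <- quality_ints(reads)
  ids <- names(reads) %||% sprintf("read%04d", seq_along(reads))
  seg_seq <- character(); seg_q <- character(); seg_id <- character()
  removed <- list()
  for (i in seq_along(reads)) {
    qi <- q[[i]]
    len <- length(qi)
    starts <- seq.int(0L, len - 1L, by = config$window_len)
    ends <- pmin(starts + config$window_len, len)
    wq <- vapply(seq_along(starts), function(w)
      mean_quality(qi[(starts[w] + 1L):ends[w]]), numeric(1))
    bad <- wq <= config$window_min_meanq
    if (any(bad))
      removed[[length(removed) + 1L]] <- data.frame(
        read = ids[i], window_start = starts[bad], window_end = ends[bad],
        mean_q = wq[bad], stringsAsFactors = FALSE)
    # maximal runs of kept windows
    r <- rle(!bad)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      s0 <- starts[idx_start[k]]; e0 <- ends[idx_end[k]]
      if (e0 - s0 < config$min_segment_len) next
      seg_id <- c(seg_id, sprintf("%s:%d-%d", ids[i], s0, e0))
      seg_seq <- c(seg_seq, substr(as.character(reads[[i]]), s0 + 1L, e0))
      seg_q <- c(seg_q, intToUtf8(qi[(s0 + 1L):e0] + 33L))
    }
  }
  segments <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(seg_seq, seg_id)),
    Biostrings::PhredQuality(seg_q))
  removed <- if (length(removed)) do.call(rbind, removed)
             else data.frame(read = character(), window_start = integer(),
                             window_end = integer(), mean_q = numeric())
  if (!is.null(out)) write_fastq(segments, out)
  list(segments = segments, removed = removed)
}
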