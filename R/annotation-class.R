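#' Construct a circular genome annotation
#'
#' The central container for an annotated circular genome: an ordered table
#' of gene calls on a circular coordinate system.  Coordinates are 1-based
#' inclusive; a call whose `end` exceeds the genome length wraps across the
#' origin (interpreted modulo the length).  Calls are kept sorted by start.
#'
#' @param genome_id identifier of the genome.
#' @param genome_length genome length in nucleotides.
#' @param calls data frame with columns `gene` (symbol, or `NA` for
#'   hypothetical calls), `status` (one of `functional`,
#'   `putative_pseudogene`, `pseudogene`, `hypothetical`),
#'   `length_fraction`, `start`, `end`, `strand` (`+`/`-`); optional
#'   columns `type` (default `"CDS"`), `match_score`, `call_id`.
#' @param translation_table `"standard-bacterial"` or `"uga-trp"`.
#' @return an object of class `circular_annotation`.
#' @export
circular_annotation <- function(genome_id, genome_length, calls,
                                translation_table = "standard-bacterial") {
  statuses <- c("functional", "putative_pseudogene", "pseudogene", "hypothetical")
  needed <- c("gene", "status", "start", "end", "strand")
  if (!all(needed %in% names(calls)))
    stopf("annotation calls must have columns: %s", paste(needed, collapse = ", "))
  if (nrow(calls)) {
    bad <- setdiff(unique(calls$status), statuses)
    if (length(bad)) stopf("unknown call status: %s", paste(bad, collapse = ", "))
    if (any(calls$start < 1 | calls$start > genome_length))
      stopf("call start coordinates must lie in [1, genome length]")
  }
  if (is.null(calls$type)) calls$type <- "CDS"
  if (is.null(calls$length_fraction)) calls$length_fraction <- NA_real_
  if (is.null(calls$call_id))
    calls$call_id <- sprintf("%s_call%04d", genome_id, seq_len(nrow(calls)))
  calls <- calls[order(calls$start), , drop = FALSE]
  rownames(calls) <- NULL
  structure(list(genome_id = genome_id,
                 genome_length = as.integer(genome_length),
                 calls = calls,
                 translation_table = translation_table),
            class = "circular_annotation")
}

#' @export
print.circular_annotation <- function(x, ...) {
  tab <- table(factor(x$calls$status,
                      c("functional", "putative_pseudogene", "pseudogene", "hypothetical")))
  cat(sprintf("circular_annotation '%s': %d nt, %d calls (%s)\n",
              x$genome_id, x$genome_length, nrow(x$calls),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Extract the circular gene order of an annotation
#'
#' Returns the calls restricted to the requested statuses and feature
#' types, ordered by start position, with duplicate gene symbols (e.g. the
#' two parts of an origin-spanning feature) merged to the part with the
#' lower start so that each symbol occurs once.
#'
#' @param ann a `circular_annotation`.
#' @param include_statuses statuses treated as orderable markers.
#' @param include_types feature types to keep.
#' @return data frame `gene`, `strand`, `start`, `end`, `status`, `type`.
#' @export
gene_order <- function(ann, include_statuses = c("functional", "putative_pseudogene"),
                       include_types = NULL) {
  calls <- ann$calls
  calls <- calls[!is.na(calls$gene) & calls$status %in% include_statuses, , drop = FALSE]
  if (!is.null(include_types)) calls <- calls[calls$type %in% include_types, , drop = FALSE]
  calls <- calls[order(calls$start), , drop = FALSE]
  dup <- duplicated(calls$gene)
  calls <- calls[!dup, , drop = FALSE]
  rownames(calls) <- NULL
  calls[, c("gene", "strand", "start", "end", "status", "type")]
}
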