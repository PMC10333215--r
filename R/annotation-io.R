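#' Read / write a single circular genome FASTA
#'
#' The header carries `circular=true length=<n>` after the record id.
#' @param path FASTA path.
#' @return `read_genome_fasta` returns a `DNAStringSet` of length one.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stopf("input error: empty FASTA '%s'", path)
  x
}

#' @rdname read_genome_fasta
#' @param seq genome sequence (character or `DNAString`).
#' @param id record id.
#' @export
write_genome_fasta <- function(seq, id, path) {
  s <- Biostrings::DNAStringSet(as.character(seq))
  names(s) <- sprintf("%s circular=true length=%d", id, nchar(as.character(seq)))
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Write an annotation to GFF3
#'
#' Features are written as type CDS (or the call's `type`) with `ID`,
#' `gene` and `status` attributes, 1-based inclusive coordinates.  Calls
#' wrapping the origin are split into two parts sharing an `ID`.
#'
#' @param ann a [circular_annotation()].
#' @param path output path.
#' @export
write_annotation_gff3 <- function(ann, path) {
  calls <- ann$calls
  L <- ann$genome_length
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    if (cl$end <= L) {
      rows[[length(rows) + 1L]] <- cl
    } else {
      p1 <- cl; p1$end <- L
      p2 <- cl; p2$start <- 1L; p2$end <- cl$end - L
      rows[[length(rows) + 1L]] <- p1
      rows[[length(rows) + 1L]] <- p2
    }
  }
  flat <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = ann$genome_id,
    ranges = IRanges::IRanges(start = flat$start, end = flat$end),
    strand = flat$strand)
  GenomeInfoDb::seqlengths(gr) <- L
  GenomeInfoDb::isCircular(gr) <- TRUE
  S4Vectors::mcols(gr)$type <- flat$type
  S4Vectors::mcols(gr)$phase <- ifelse(flat$type == "CDS", 0L, NA_integer_)
  S4Vectors::mcols(gr)$ID <- flat$call_id
  S4Vectors::mcols(gr)$gene <- ifelse(is.na(flat$gene), NA_character_, flat$gene)
  S4Vectors::mcols(gr)$status <- flat$status
  S4Vectors::mcols(gr)$length_fraction <-
    ifelse(is.na(flat$length_fraction), NA_character_,
           sprintf("%.6f", flat$length_fraction))
  rtracklayer::export(gr, path, format = "gff3")
  # rtracklayer does not emit the sequence-region pragma; add it so the
  # genome length round-trips
  lines <- readLines(path)
  pragma <- sprintf("##sequence-region %s 1 %d", ann$genome_id, L)
  lines <- append(lines, pragma, after = 1L)
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 annotation back into a circular_annotation
#'
#' Rejoins origin-spanning features split into two parts sharing an `ID`.
#'
#' @param path GFF3 path.
#' @param genome_length genome length; if `NULL`, taken from the GFF3
#'   sequence-region header.
#' @param translation_table recorded translation table label.
#' @return a [circular_annotation()].
#' @export
read_annotation_gff3 <- function(path, genome_length = NULL,
                                 translation_table = "standard-bacterial") {
  gr <- rtracklayer::import(path, format = "gff3")
  id <- as.character(GenomeInfoDb::seqnames(gr)[1])
  L <- genome_length %||% suppressWarnings(GenomeInfoDb::seqlengths(gr)[[1]])
  if (is.null(L) || is.na(L)) {
    pr <- grep("^##sequence-region", readLines(path, n = 50L), value = TRUE)
    if (length(pr)) L <- as.integer(strsplit(pr[1], "\\s+")[[1]][4])
  }
  if (is.null(L) || is.na(L))
    stopf("input error: '%s' has no sequence-region length; pass genome_length", path)
  df <- data.frame(
    call_id = as.character(gr$ID),
    gene = as.character(gr$gene),
    status = as.character(gr$status),
    length_fraction = suppressWarnings(as.numeric(gr$length_fraction)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    stringsAsFactors = FALSE)
  # rejoin split origin-spanning features
  dup_ids <- unique(df$call_id[duplicated(df$call_id)])
  for (d in dup_ids) {
    idx <- which(df$call_id == d)
    if (length(idx) != 2L) stopf("input error: feature '%s' has %d parts", d, length(idx))
    lo <- idx[which.min(df$start[idx])]   # part starting at 1
    hi <- idx[which.max(df$start[idx])]
    if (df$start[lo] != 1L)
      stopf("input error: split feature '%s' does not touch the origin", d)
    df$end[hi] <- L + df$end[lo]
    df <- df[-lo, , drop = FALSE]
  }
  circular_annotation(id, L, df, translation_table)
}

#' Write / read the per-genome gene call table (TSV)
#'
#' Columns: genome, gene, status, length_fraction, start, end, strand,
#' type.
#' @param ann a `circular_annotation`.
#' @param path TSV path.
#' @export
write_call_table <- function(ann, path) {
  df <- cbind(genome = ann$genome_id,
              ann$calls[, c("gene", "status", "length_fraction",
                            "start", "end", "strand", "type")])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_call_table
#' @param genome_length genome length in nt.
#' @export
read_call_table <- function(path, genome_length) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  circular_annotation(df$genome[1], genome_length, df[, -1])
}
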