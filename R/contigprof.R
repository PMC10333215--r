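#' Configuration for contig profiling
#'
#' @param plot_min_len contigs strictly longer than this are flagged for
#'   plotting (the published figures plot contigs larger than 1500 bp).
#' @param min_vote_fraction fraction of chunk votes a label must win to
#'   be assigned (0.5 = simple majority).
#' @param chunk_len chunk size (nt) for taxonomic voting.
#' @param kmer nucleotide k-mer size used for chunk-vs-reference scoring.
#' @return object of class `prof_config`.
#' @export
prof_config <- function(plot_min_len = 1500L, min_vote_fraction = 0.5,
                        chunk_len = 1000L, kmer = 15L) {
  assert_count(plot_min_len, "plot_min_len", min = 1L)
  if (min_vote_fraction < 0.5 || min_vote_fraction > 1)
    stopf("invalid config: min_vote_fraction must be in [0.5, 1]")
  assert_count(chunk_len, "chunk_len", min = 1L)
  assert_count(kmer, "kmer", min = 4L)
  structure(list(plot_min_len = as.integer(plot_min_len),
                 min_vote_fraction = min_vote_fraction,
                 chunk_len = as.integer(chunk_len), kmer = as.integer(kmer)),
            class = "prof_config")
}

#' Profile assembly contigs
#'
#' Computes length, GC fraction (over A/C/G/T only) and mean coverage
#' per contig, plus the plotting flag (length strictly greater than
#' `plot_min_len`), reproducing the data behind GC/coverage scatter
#' plots of metagenomic bins.
#'
#' @param contigs FASTA path or `DNAStringSet`.
#' @param coverage data frame (or TSV path) with columns `contig_id`,
#'   `mean_depth`; contigs without a row get coverage 0 with a warning.
#' @param config a [prof_config()].
#' @return data frame: `id`, `length`, `gc`, `coverage`, `label`
#'   (initially `"unassigned"`), `plotted`.
#' @export
profile_contigs <- function(contigs, coverage = NULL, config = prof_config()) {
  if (is.character(contigs) && length(contigs) == 1L)
    contigs <- Biostrings::readDNAStringSet(contigs)
  ids <- sub("\\s.*$", "", names(contigs))
  if (anyDuplicated(ids))
    stopf("input error: duplicate contig ids: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.character(coverage) && length(coverage) == 1L)
    coverage <- read.delim(coverage, stringsAsFactors = FALSE)
  freq <- Biostrings::letterFrequency(contigs, c("G", "C", "A", "T"))
  gc <- (freq[, "G"] + freq[, "C"]) / rowSums(freq)
  cov <- rep(0, length(contigs))
  if (!is.null(coverage)) {
    m <- match(ids, coverage$contig_id)
    if (anyNA(m))
      warnf("no coverage for contig(s) %s; using 0",
            paste(ids[is.na(m)], collapse = ", "))
    cov[!is.na(m)] <- coverage$mean_depth[m[!is.na(m)]]
  }
  data.frame(id = ids, length = Biostrings::width(contigs), gc = as.numeric(gc),
             coverage = cov, label = "unassigned",
             plotted = Biostrings::width(contigs) > config$plot_min_len,
             stringsAsFactors = FALSE)
}

# canonical k-mer set of a sequence (both strands)
ref_kmer_set <- function(seqs, k) {
  kms <- character()
  for (s in as.character(seqs)) {
    for (x in c(s, revcomp_chr(s))) {
      n <- nchar(x)
      if (n >= k) kms <- c(kms, substring(x, seq_len(n - k + 1L), k:n))
    }
  }
  unique(kms)
}

#' Assign contig taxonomy by chunked best-hit voting
#'
#' Each contig is cut into `chunk_len` chunks; each chunk is scored
#' against every labeled reference set by shared nucleotide k-mers
#' (strand-insensitive) and votes for the best-scoring label (no shared
#' k-mers, or a tie, casts no vote).  A contig receives the majority
#' label when its vote fraction reaches `min_vote_fraction`, otherwise
#' `"unassigned"`.  Profile metrics are never altered.
#'
#' @param profiles output of [profile_contigs()].
#' @param contigs the contig sequences (FASTA path or `DNAStringSet`),
#'   same ids as `profiles`.
#' @param references named list of labeled reference sequence sets
#'   (each a `DNAStringSet`, FASTA path or character vector).
#' @param config a [prof_config()].
#' @return `profiles` with `label` filled in and a `votes` list column
#'   (named vote counts per label).
#' @export
assign_taxonomy <- function(profiles, contigs, references, config = prof_config()) {
  if (!length(references) || is.null(names(references)))
    stopf("config error: 'references' must be a non-empty named list")
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs))
    contigs <- Biostrings::readDNAStringSet(contigs)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  k <- config$kmer
  refsets <- lapply(references, function(r) {
    if (is.character(r) && length(r) == 1L && file.exists(r))
      r <- Biostrings::readDNAStringSet(r)
    ref_kmer_set(r, k)
  })
  labels <- names(references)
  profiles$votes <- vector("list", nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    s <- as.character(contigs[[profiles$id[i]]])
    n <- nchar(s)
    starts <- seq.int(1L, n, by = config$chunk_len)
    votes <- setNames(integer(length(labels)), labels)
    for (st in starts) {
      chunk <- substr(s, st, min(n, st + config$chunk_len - 1L))
      if (nchar(chunk) < k) next
      ckm <- unique(substring(chunk, seq_len(nchar(chunk) - k + 1L), k:nchar(chunk)))
      hitn <- vapply(refsets, function(rs) sum(ckm %in% rs), integer(1))
      best <- max(hitn)
      if (best == 0L || sum(hitn == best) > 1L) next  # no hit or tie: no vote
      w <- labels[which.max(hitn)]
      votes[w] <- votes[w] + 1L
    }
    profiles$votes[[i]] <- votes
    total <- sum(votes)
    if (total > 0L) {
      top <- which.max(votes)
      if (votes[top] / total >= config$min_vote_fraction)
        profiles$label[i] <- labels[top]
    }
  }
  profiles
}
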