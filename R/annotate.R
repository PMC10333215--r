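#' Configuration for reference-guided annotation
#'
#' Threshold semantics follow the published classifier: a call is
#' functional when its ORF retains more than `functional_threshold` of the
#' reference protein length, a putative pseudogene above
#' `putative_threshold`, and a pseudogene otherwise; both inequalities are
#' strict, so a fraction of exactly 0.85 is putative and exactly 0.60 is a
#' pseudogene.  Unassigned ORFs longer than `min_hypothetical_orf_nt` are
#' reported as hypothetical genes; shorter ones are dropped.
#'
#' @param min_hypothetical_orf_nt minimum nucleotide length (strict `>`)
#'   for an unassigned ORF to be kept as hypothetical.  Default 300.
#' @param functional_threshold,putative_threshold length-fraction
#'   breakpoints (defaults 0.85 and 0.60).
#' @param significance_cutoff E-value cutoff for homology assignment.
#' @param translation_table `"standard-bacterial"` (table 11) or
#'   `"uga-trp"` (UGA read as tryptophan, as in some reduced symbiont
#'   genomes).
#' @param start_codons set of start codons (default `ATG`).
#' @param min_orf_aa smallest ORF (amino acids, excluding the stop) worth
#'   reporting from the six-frame scan; keeps the homology search off the
#'   vast pool of spurious few-codon ORFs.
#' @param seed_kmer,min_seed_hits amino acid k-mer size and minimum number
#'   of shared k-mers for a reference to enter pairwise alignment.
#' @return object of class `annotation_config`.
#' @export
annotation_config <- function(min_hypothetical_orf_nt = 300L,
                              functional_threshold = 0.85,
                              putative_threshold = 0.60,
                              significance_cutoff = 0.01,
                              translation_table = c("standard-bacterial", "uga-trp"),
                              start_codons = "ATG",
                              min_orf_aa = 10L,
                              seed_kmer = 4L, min_seed_hits = 2L) {
  translation_table <- match.arg(translation_table)
  if (!(putative_threshold > 0 && putative_threshold < functional_threshold &&
        functional_threshold <= 1))
    stopf("invalid config: need 0 < putative_threshold < functional_threshold <= 1")
  assert_count(min_hypothetical_orf_nt, "min_hypothetical_orf_nt", min = 1L)
  if (significance_cutoff <= 0) stopf("invalid config: significance_cutoff must be > 0")
  if (!length(start_codons) || !all(grepl("^[ACGT]{3}$", start_codons)))
    stopf("invalid config: start_codons must be ACGT triplets")
  assert_count(min_orf_aa, "min_orf_aa", min = 1L)
  structure(list(min_hypothetical_orf_nt = as.integer(min_hypothetical_orf_nt),
                 functional_threshold = functional_threshold,
                 putative_threshold = putative_threshold,
                 significance_cutoff = significance_cutoff,
                 translation_table = translation_table,
                 start_codons = toupper(start_codons),
                 min_orf_aa = as.integer(min_orf_aa),
                 seed_kmer = as.integer(seed_kmer),
                 min_seed_hits = as.integer(min_seed_hits)),
            class = "annotation_config")
}

genetic_code_for <- function(translation_table) {
  switch(translation_table,
         "standard-bacterial" = Biostrings::getGeneticCode("11"),
         "uga-trp" = Biostrings::getGeneticCode("4"),
         stopf("unknown translation table '%s'", translation_table))
}

# one-strand scan of a tripled circular sequence; returns 0-based starts
# (relative to the middle copy) of maximal start..stop ORFs
scan_frames <- function(tripled, L, starts_ok, stops, min_orf_aa) {
  res <- list()
  n3 <- nchar(tripled)
  for (f in 0:2) {
    pos <- seq.int(f + 1L, n3 - 2L, by = 3L)
    codons <- substring(tripled, pos, pos + 2L)
    is_stop <- codons %in% stops
    is_start <- codons %in% starts_ok
    stop_idx <- which(is_stop)
    if (length(stop_idx) < 2L) next
    # segments strictly between consecutive stops
    for (k in seq_len(length(stop_idx) - 1L)) {
      a <- stop_idx[k] + 1L; b <- stop_idx[k + 1L]  # b = closing stop
      if (b - a < min_orf_aa) next                  # aa count = b - start
      seg_starts <- which(is_start[a:(b - 1L)])
      if (!length(seg_starts)) next
      s <- a + seg_starts[1L] - 1L                  # first start codon: maximal ORF
      start0 <- pos[s] - 1L
      if (start0 < L || start0 >= 2L * L) next      # keep middle-copy starts only
      len <- (b - s + 1L) * 3L
      if (len > L) next                             # cannot exceed the circle
      if (b - s < min_orf_aa) next
      res[[length(res) + 1L]] <- c(start0 - L, len)
    }
  }
  if (!length(res)) return(matrix(integer(), ncol = 2L))
  do.call(rbind, res)
}

#' Extract open reading frames from a circular genome
#'
#' Scans all six frames of the circular sequence, including ORFs that span
#' the origin, and returns maximal start-to-stop ORFs.  Coordinates are
#' 0-based half-open on the forward strand; `end` may exceed the genome
#' length to denote origin wrap.  Under the `uga-trp` table, TGA is not a
#' stop codon.
#'
#' @param genome character, `DNAString`(Set) or FASTA path.
#' @param config an [annotation_config()].
#' @return data frame with columns `start`, `end`, `strand`, `aa_length`
#'   (stop excluded) and `translation`.
#' @export
extract_orfs <- function(genome, config = annotation_config()) {
  s <- as_genome_string(genome)
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0)
    stopf("input error: non-ACGT character '%s' at offset %d",
          substr(s, bad, bad), as.integer(bad) - 1L)
  L <- nchar(s)
  code <- genetic_code_for(config$translation_table)
  stops <- names(code)[code == "*"]
  fwd <- scan_frames(paste0(s, s, s), L, config$start_codons, stops, config$min_orf_aa)
  rc <- revcomp_chr(s)
  rev_ <- scan_frames(paste0(rc, rc, rc), L, config$start_codons, stops, config$min_orf_aa)
  orf <- data.frame(start = integer(), end = integer(), strand = character(),
                    aa_length = integer(), translation = character(),
                    stringsAsFactors = FALSE)
  grab <- function(mat, strand, src) {
    if (!nrow(mat)) return(NULL)
    seqs <- substring(paste0(src, src), mat[, 1] + 1L, mat[, 1] + mat[, 2])
    tr <- as.character(Biostrings::translate(Biostrings::DNAStringSet(seqs),
                                             genetic.code = code))
    tr <- sub("\\*$", "", tr)
    if (strand == "+") {
      start <- mat[, 1]
    } else {
      # map reverse-complement coordinates back to forward-strand circle
      start <- (L - (mat[, 1] + mat[, 2])) %% L
    }
    data.frame(start = start, end = start + mat[, 2], strand = strand,
               aa_length = mat[, 2] %/% 3L - 1L, translation = tr,
               stringsAsFactors = FALSE)
  }
  orf <- rbind(grab(fwd, "+", s), grab(rev_, "-", rc))
  if (is.null(orf) || !nrow(orf))
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      aa_length = integer(), translation = character()))
  orf <- orf[!duplicated(orf[, c("start", "strand")]), , drop = FALSE]
  orf <- orf[order(orf$start, orf$strand), , drop = FALSE]
  rownames(orf) <- NULL
  orf
}

aa_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character())
  unique(substring(x, seq_len(n - k + 1L), k:n))
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Assign ORFs to reference genes by similarity
#'
#' Seed-and-extend homology search: references sharing at least
#' `min_seed_hits` amino acid k-mers with an ORF's translation are scored
#' by local pairwise alignment (BLOSUM62, gap open 10 / extend 0.5) and
#' the alignment score is converted to a Karlin-Altschul style E-value
#' against the catalog as database.  Matches above `significance_cutoff`
#' are discarded.  Assignments are then made by iterative best-hit: the
#' highest-scoring (ORF, gene) pairs are claimed first and each reference
#' gene keeps only its best ORF (unless `keep_duplicates`).
#'
#' @param orfs data frame from [extract_orfs()].
#' @param catalog a `gene_catalog`.
#' @param config an [annotation_config()].
#' @param keep_duplicates report secondary ORFs matching an already
#'   claimed gene instead of demoting them to no-hit.
#' @return `orfs` with added columns `gene` (`NA` when unassigned),
#'   `match_score` and `evalue`.
#' @export
assign_homology <- function(orfs, catalog, config = annotation_config(),
                            keep_duplicates = FALSE) {
  if (!inherits(catalog, "gene_catalog") || !nrow(catalog$entries))
    stopf("catalog integrity error: empty or invalid catalog")
  orfs$gene <- rep(NA_character_, nrow(orfs))
  orfs$match_score <- rep(NA_real_, nrow(orfs))
  orfs$evalue <- rep(NA_real_, nrow(orfs))
  if (!nrow(orfs)) return(orfs)
  prot <- catalog$entries$protein
  syms <- catalog$entries$symbol
  k <- config$seed_kmer
  index <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(prot)) {
    for (km in aa_kmers(prot[i], k)) {
      index[[km]] <- c(index[[km]], i)
    }
  }
  db_len <- sum(nchar(prot))
  lambda <- 0.267; Kconst <- 0.041   # gapped BLOSUM62 statistics
  hits <- list()
  for (j in seq_len(nrow(orfs))) {
    tr <- orfs$translation[j]
    kms <- aa_kmers(tr, k)
    if (!length(kms)) next
    cand <- unlist(lapply(kms, function(km) index[[km]]), use.names = FALSE)
    if (!length(cand)) next
    tab <- table(cand)
    cand <- as.integer(names(tab)[tab >= config$min_seed_hits])
    if (!length(cand)) next
    scores <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAStringSet(prot[cand]),
      subject = Biostrings::AAString(tr),
      type = "local", substitutionMatrix = blosum62(),
      gapOpening = 10, gapExtension = 0.5, scoreOnly = TRUE)
    ev <- Kconst * nchar(tr) * db_len * exp(-lambda * scores)
    ok <- ev <= config$significance_cutoff
    if (!any(ok)) next
    best <- which(ok)[which.max(scores[ok])]
    hits[[length(hits) + 1L]] <- data.frame(
      orf = j, ref = cand[best], score = scores[best], evalue = ev[best])
  }
  if (!length(hits)) return(orfs)
  hits <- do.call(rbind, hits)
  hits <- hits[order(-hits$score, hits$ref, hits$orf), , drop = FALSE]
  ref_taken <- logical(length(syms))
  for (r in seq_len(nrow(hits))) {
    i <- hits$ref[r]; j <- hits$orf[r]
    if (!keep_duplicates && ref_taken[i]) next
    ref_taken[i] <- TRUE
    orfs$gene[j] <- syms[i]
    orfs$match_score[j] <- hits$score[r]
    orfs$evalue[j] <- hits$evalue[r]
  }
  orfs
}

#' Classify assigned ORFs into gene calls
#'
#' Computes `length_fraction` = ORF length / reference protein length and
#' applies the strict length-fraction thresholds; unassigned ORFs longer
#' than `min_hypothetical_orf_nt` become hypothetical calls, shorter ones
#' are dropped.  When a symbol occurs multiple times in the catalog the
#' median reference length is used.
#'
#' @param assignments output of [assign_homology()].
#' @param catalog the `gene_catalog`.
#' @param config an [annotation_config()].
#' @param genome_id,genome_length identity of the annotated genome.
#' @return a [circular_annotation()].
#' @export
classify_calls <- function(assignments, catalog, config = annotation_config(),
                           genome_id = "genome", genome_length) {
  ref_len <- tapply(catalog$entries$aa_length, catalog$entries$symbol, median)
  if (any(ref_len == 0)) stopf("catalog integrity error: reference length 0")
  a <- assignments
  assigned <- !is.na(a$gene)
  keep_hyp <- !assigned & (a$end - a$start) > config$min_hypothetical_orf_nt
  a <- a[assigned | keep_hyp, , drop = FALSE]
  if (nrow(a)) {
    frac <- ifelse(is.na(a$gene), NA_real_,
                   a$aa_length / as.numeric(ref_len[a$gene]))
    status <- ifelse(is.na(a$gene), "hypothetical",
                     status_from_fraction(frac, config$functional_threshold,
                                          config$putative_threshold))
  } else {
    frac <- numeric(); status <- character()
  }
  calls <- data.frame(gene = a$gene, status = status, length_fraction = frac,
                      start = a$start + 1L, end = a$end,
                      strand = a$strand, type = "CDS",
                      match_score = a$match_score,
                      stringsAsFactors = FALSE)
  circular_annotation(genome_id, genome_length, calls, config$translation_table)
}

#' Annotate a circular genome end to end
#'
#' Convenience composition of [extract_orfs()], [assign_homology()] and
#' [classify_calls()]; optionally writes the result as GFF3 (which
#' round-trips through [read_annotation_gff3()] to an identical
#' annotation).
#'
#' @param genome character, `DNAString`(Set) or FASTA path.
#' @param catalog a `gene_catalog` of reference proteins.
#' @param config an [annotation_config()].
#' @param genome_id genome identifier.
#' @param gff_out optional GFF3 output path.
#' @return a [circular_annotation()].
#' @export
annotate_genome <- function(genome, catalog, config = annotation_config(),
                            genome_id = "genome", gff_out = NULL) {
  s <- as_genome_string(genome)
  orfs <- extract_orfs(s, config)
  ass <- assign_homology(orfs, catalog, config)
  ann <- classify_calls(ass, catalog, config, genome_id, nchar(s))
  if (!is.null(gff_out)) write_annotation_gff3(ann, gff_out)
  ann
}
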