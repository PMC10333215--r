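#' @noRd
status_from_fraction <- function(frac, functional_threshold = 0.85,
                                 putative_threshold = 0.60) {
  ifelse(frac > functional_threshold, "functional",
         ifelse(frac > putative_threshold, "putative_pseudogene", "pseudogene"))
}

#' Simulate descendant genomes from an ancestral catalog
#'
#' Each descendant starts from the catalog's ancestral circular gene order
#' and is transformed by planted evolutionary events applied in the fixed
#' order loss -> pseudogenize -> invert:
#'
#' * loss: each gene is dropped independently with `loss_prob`;
#' * pseudogenization: each retained gene is truncated from the 3' end
#'   with `pseudo_prob`, keeping the start codon; the retained length
#'   fraction is drawn uniformly from `pseudo_retained_fraction` and a
#'   premature stop codon is written at the truncation point;
#' * inversion: `n_inversions` non-overlapping contiguous segments of the
#'   post-loss order are reversed with strands flipped.
#'
#' Genes are emitted with an in-frame stop codon immediately upstream of
#' the start codon so that maximal-ORF extraction recovers planted gene
#' boundaries exactly.  Intergenic spacers are drawn (exponential lengths)
#' to hit `target_coding_density` in expectation; spacer and codon
#' composition follow the genome GC target, keeping realized GC within a
#' few percent of `genome_gc`.
#'
#' @param catalog a [generate_catalog()] result; all configs must refer to
#'   the same catalog size.
#' @param configs a single [sim_config()] or a list of them (one per
#'   descendant); list names become genome ids.
#' @param out_dir optional directory: per descendant, writes
#'   `<id>.fasta`, `<id>.gff3`, `<id>_truth.json` and `<id>_genes.tsv`.
#' @param sequence if `FALSE`, skip nucleotide sequence emission (gene
#'   orders, coordinates and truth are unchanged; much faster for
#'   gene-order studies).
#' @return named list, one element per descendant, each with components
#'   `annotation` (a [circular_annotation()]), `truth` (class `sim_truth`:
#'   replayable planted events plus the final gene table), `sequence`
#'   (character or `NULL`) and `gc` (realized GC or `NA`).
#' @export
simulate_descendants <- function(catalog, configs, out_dir = NULL, sequence = TRUE) {
  if (!inherits(catalog, "gene_catalog")) stopf("expected a gene_catalog")
  if (inherits(configs, "sim_config")) configs <- list(configs)
  n <- nrow(catalog$entries)
  ids <- names(configs) %||% sprintf("sim%02d", seq_along(configs))
  ids[!nzchar(ids)] <- sprintf("sim%02d", which(!nzchar(ids)))
  for (cfg in configs) {
    if (!inherits(cfg, "sim_config")) stopf("invalid config: expected sim_config objects")
    if (cfg$n_genes != n)
      stopf("invalid config: n_genes (%d) does not match the catalog (%d genes)",
            cfg$n_genes, n)
    if (cfg$inversion_size_genes[2] > n)
      stopf("invalid config: inversion_size_genes max (%d) exceeds gene count (%d)",
            cfg$inversion_size_genes[2], n)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  out <- setNames(vector("list", length(configs)), ids)
  for (d in seq_along(configs))
    out[[d]] <- simulate_one(catalog, configs[[d]], ids[d], out_dir, sequence)
  out
}

simulate_one <- function(catalog, cfg, id, out_dir, sequence) {
  entries <- catalog$entries
  aa_of <- setNames(entries$aa_length, entries$symbol)
  cds_of <- setNames(entries$cds, entries$symbol)
  with_seed(cfg$seed, {
    cur <- catalog$ancestral_order
    n <- nrow(cur)
    events <- list()

    lost_mask <- runif(n) < cfg$loss_prob
    if (any(lost_mask))
      events[[length(events) + 1L]] <-
        list(kind = "loss", genes = cur$symbol[lost_mask])
    cur <- cur[!lost_mask, , drop = FALSE]
    m <- nrow(cur)
    if (m < 2L) stopf("simulation left fewer than 2 genes; lower loss_prob")
    cur$retained_fraction <- 1

    ps_mask <- runif(m) < cfg$pseudo_prob
    if (any(ps_mask)) {
      fr <- runif(sum(ps_mask), cfg$pseudo_retained_fraction[1],
                  cfg$pseudo_retained_fraction[2])
      aa_full <- aa_of[cur$symbol[ps_mask]]
      retained_aa <- pmax(2L, as.integer(floor(fr * aa_full)))
      realized <- as.numeric(retained_aa / aa_full)
      cur$retained_fraction[ps_mask] <- realized
      events[[length(events) + 1L]] <-
        list(kind = "pseudogenize", genes = cur$symbol[ps_mask],
             retained_fraction = realized)
    }
    cur$status <- status_from_fraction(cur$retained_fraction)

    if (cfg$n_inversions > 0L) {
      size_range <- seq(cfg$inversion_size_genes[1], cfg$inversion_size_genes[2])
      sizes <- if (length(size_range) == 1L)
        rep(size_range, cfg$n_inversions)
      else sample(size_range, cfg$n_inversions, replace = TRUE)
      if (sum(sizes) > m)
        stopf("invalid config: %d inversions of total size %d exceed the %d retained genes",
              cfg$n_inversions, sum(sizes), m)
      # non-overlapping placement: distribute the free genes among the
      # gaps before each segment (segments may touch but never overlap)
      free <- m - sum(sizes)
      offs <- sort(sample.int(free + 1L, length(sizes), replace = TRUE)) - 1L
      starts <- offs + c(0L, cumsum(sizes[-length(sizes)])) + 1L
      for (k in seq_along(sizes)) {
        idx <- starts[k]:(starts[k] + sizes[k] - 1L)
        events[[length(events) + 1L]] <-
          list(kind = "invert", genes = cur$symbol[idx],
               start_index = starts[k], size = sizes[k])
        cur[idx, ] <- cur[rev(idx), ]
        cur$strand[idx] <- ifelse(cur$strand[idx] == "+", "-", "+")
      }
    }

    # emitted CDS lengths (nt, incl. stop); pseudogenes truncated + stop
    retained_aa <- pmax(2L, as.integer(round(cur$retained_fraction * aa_of[cur$symbol])))
    full <- cur$retained_fraction == 1
    cds_len <- ifelse(full, 3L * (aa_of[cur$symbol] + 1L), 3L * retained_aa + 3L)

    dens <- cfg$target_coding_density
    mean_sp <- max(0, sum(cds_len) * (1 - dens) / dens / m - 3)
    sp_len <- if (mean_sp > 0)
      as.integer(round(rexp(m, rate = 1 / mean_sp))) else integer(m)

    # coordinates: [spacer][TAA guard][cds] per gene
    gstart <- integer(m); gend <- integer(m)
    offset <- 0L
    for (i in seq_len(m)) {
      gstart[i] <- offset + sp_len[i] + 3L + 1L
      gend[i] <- gstart[i] + cds_len[i] - 1L
      offset <- gend[i]
    }
    # on the minus strand the guard sits 3' of the CDS in plus coordinates
    minus <- cur$strand == "-"
    gstart[minus] <- gstart[minus] - 3L
    gend[minus] <- gend[minus] - 3L
    L <- offset

    genome <- NULL; gc <- NA_real_
    if (sequence) {
      parts <- character(m)
      for (i in seq_len(m)) {
        cds_em <- if (full[i]) cds_of[[cur$symbol[i]]] else
          paste0(substr(cds_of[[cur$symbol[i]]], 1L, 3L * retained_aa[i]), "TAA")
        cassette <- paste0("TAA", cds_em)
        if (minus[i]) cassette <- revcomp_chr(cassette)
        parts[i] <- paste0(random_dna(sp_len[i], cfg$genome_gc), cassette)
      }
      genome <- paste(parts, collapse = "")
      stopifnot(nchar(genome) == L)
      gc <- gc_fraction(genome)
    }

    calls <- data.frame(gene = cur$symbol, status = cur$status,
                        length_fraction = cur$retained_fraction,
                        start = gstart, end = gend, strand = cur$strand,
                        type = "CDS", stringsAsFactors = FALSE)
    ann <- circular_annotation(id, L, calls)
    truth <- structure(list(
      genome_id = id, seed = cfg$seed, events = events,
      gene_table = data.frame(gene = cur$symbol, strand = cur$strand,
                              status = cur$status,
                              retained_fraction = cur$retained_fraction,
                              start = gstart, end = gend,
                              stringsAsFactors = FALSE)
    ), class = "sim_truth")

    if (!is.null(out_dir)) {
      if (sequence)
        write_genome_fasta(genome, id, file.path(out_dir, paste0(id, ".fasta")))
      write_annotation_gff3(ann, file.path(out_dir, paste0(id, ".gff3")))
      jsonlite::write_json(
        list(genome_id = id, seed = cfg$seed, events = truth$events),
        file.path(out_dir, paste0(id, "_truth.json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write.table(truth$gene_table, file.path(out_dir, paste0(id, "_genes.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(annotation = ann, truth = truth, sequence = genome, gc = gc)
  })
}

#' Replay planted events on the ancestral order
#'
#' Applies a `sim_truth` event list to the catalog's ancestral gene order
#' and returns the resulting order.  Used as the replay oracle: the result
#' must reproduce the emitted gene order, strands and statuses exactly.
#'
#' @param catalog the `gene_catalog` the truth was simulated from.
#' @param truth a `sim_truth` (or its `events` list).
#' @return data frame `gene`, `strand`, `status`, `retained_fraction`.
#' @export
replay_truth <- function(catalog, truth) {
  events <- if (inherits(truth, "sim_truth")) truth$events else truth
  cur <- catalog$ancestral_order
  names(cur)[names(cur) == "symbol"] <- "gene"
  cur$status <- "functional"
  cur$retained_fraction <- 1
  for (ev in events) {
    switch(ev$kind,
      loss = {
        cur <- cur[!(cur$gene %in% ev$genes), , drop = FALSE]
      },
      pseudogenize = {
        idx <- match(ev$genes, cur$gene)
        if (anyNA(idx)) stopf("replay error: pseudogenized gene missing from order")
        cur$retained_fraction[idx] <- ev$retained_fraction
        cur$status[idx] <- status_from_fraction(ev$retained_fraction)
      },
      invert = {
        idx <- match(ev$genes, cur$gene)
        if (anyNA(idx) || any(diff(idx) != 1L))
          stopf("replay error: inverted gene set not contiguous in current order")
        cur[idx, ] <- cur[rev(idx), ]
        cur$strand[idx] <- ifelse(cur$strand[idx] == "+", "-", "+")
      },
      stopf("replay error: unknown event kind '%s'", ev$kind)
    )
  }
  rownames(cur) <- NULL
  cur
}

#' Configuration for the long-read simulator
#'
#' @param n_reads number of reads (0 gives an empty FASTQ).
#' @param length_mean,length_sd read length distribution (nt, normal,
#'   truncated at 50 nt).
#' @param base_quality mean per-base Phred quality in `[0, 60]`.
#' @param quality_jitter per-base qualities are `base_quality` plus a
#'   uniform integer jitter in `[-quality_jitter, quality_jitter]`.
#' @param planted_low_windows `NULL` or a data frame with columns `read`
#'   (1-based read index), `start`, `end` (0-based half-open within the
#'   read) and `q` (the planted low Phred value).
#' @param seed integer RNG seed.
#' @return an object of class `read_sim_config`.
#' @export
read_sim_config <- function(n_reads = 100L, length_mean = 5000, length_sd = 2000,
                            base_quality = 20, quality_jitter = 1L,
                            planted_low_windows = NULL, seed = 1L) {
  assert_count(n_reads, "n_reads")
  if (base_quality < 0 || base_quality > 60)
    stopf("invalid config: base_quality must be in [0, 60]")
  assert_count(quality_jitter, "quality_jitter")
  assert_count(seed, "seed")
  if (!is.null(planted_low_windows)) {
    w <- planted_low_windows
    if (!all(c("read", "start", "end", "q") %in% names(w)))
      stopf("invalid config: planted_low_windows needs columns read, start, end, q")
    if (any(w$start < 0) || any(w$end <= w$start))
      stopf("invalid config: planted windows must satisfy 0 <= start < end")
    if (any(w$q < 0 | w$q > 60))
      stopf("invalid config: planted Phred values must be in [0, 60]")
  }
  structure(list(n_reads = as.integer(n_reads), length_mean = length_mean,
                 length_sd = length_sd, base_quality = base_quality,
                 quality_jitter = as.integer(quality_jitter),
                 planted_low_windows = planted_low_windows,
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

#' Simulate Nanopore-like reads from a circular genome
#'
#' Reads are drawn uniformly from the circle on both strands with
#' normally distributed lengths and near-constant per-base Phred
#' qualities; configured low-quality windows are overwritten with the
#' requested Phred value exactly, giving a machine-readable truth table
#' for read-splitting tests.
#'
#' @param genome genome sequence (character, `DNAString`(Set) or FASTA
#'   path).
#' @param config a [read_sim_config()].
#' @param out_fastq optional FASTQ output path (Sanger Phred+33).
#' @return list with `reads` (a `QualityScaledDNAStringSet`) and `truth`
#'   (the planted window table, zero rows when none were requested).
#' @export
simulate_reads <- function(genome, config, out_fastq = NULL) {
  if (!inherits(config, "read_sim_config")) stopf("expected a read_sim_config")
  s <- as_genome_string(genome)
  L <- nchar(s)
  doubled <- paste0(s, s)
  wins <- config$planted_low_windows
  with_seed(config$seed, {
    n <- config$n_reads
    seqs <- character(n); quals <- vector("list", n)
    if (n > 0L) {
      lens <- pmax(50L, as.integer(round(rnorm(n, config$length_mean, config$length_sd))))
      lens <- pmin(lens, L)  # a read cannot be longer than the circle
      starts <- sample.int(L, n, replace = TRUE) - 1L
      strands <- sample(c("+", "-"), n, replace = TRUE)
      j <- config$quality_jitter
      for (i in seq_len(n)) {
        sq <- substr(doubled, starts[i] + 1L, starts[i] + lens[i])
        if (strands[i] == "-") sq <- revcomp_chr(sq)
        q <- config$base_quality + sample(seq(-j, j), lens[i], replace = TRUE)
        q <- pmin(60L, pmax(0L, as.integer(round(q))))
        seqs[i] <- sq; quals[[i]] <- q
      }
      if (!is.null(wins)) {
        for (k in seq_len(nrow(wins))) {
          i <- wins$read[k]
          if (i < 1L || i > n)
            stopf("invalid config: planted window read index %d outside 1..%d", i, n)
          if (wins$end[k] > length(quals[[i]]))
            stopf("invalid config: planted window [%d,%d) outside read %d (length %d)",
                  wins$start[k], wins$end[k], i, length(quals[[i]]))
          quals[[i]][(wins$start[k] + 1L):wins$end[k]] <- as.integer(wins$q[k])
        }
      }
    }
    ids <- if (n > 0L) sprintf("read%04d", seq_len(n)) else character()
    reads <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(seqs, ids)),
      Biostrings::PhredQuality(vapply(quals, function(q) intToUtf8(q + 33L), "")))
    truth <- if (is.null(wins))
      data.frame(read = integer(), start = integer(), end = integer(), q = integer())
    else wins
    if (!is.null(out_fastq)) write_fastq(reads, out_fastq)
    list(reads = reads, truth = truth)
  })
}
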