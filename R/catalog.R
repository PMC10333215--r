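#' Configuration for the synthetic genome simulator
#'
#' Bundles the parameters controlling one simulated descendant genome.
#' Defaults emulate the published statistics of planthopper endosymbiont
#' chromosomes: roughly 150 genes on a gene-dense (coding density ~0.9),
#' AT-rich (GC ~0.22) circle of 100--200 kb.
#'
#' @param n_genes number of protein-coding genes in the ancestral catalog.
#' @param genome_gc target genome GC fraction in `[0, 1]`.
#' @param target_coding_density target fraction of the genome covered by
#'   coding sequence; intergenic spacer lengths are drawn so that this is
#'   hit in expectation.
#' @param n_inversions number of non-overlapping segmental inversions to
#'   plant in the descendant.
#' @param inversion_size_genes `(min, max)` inversion size in genes.
#' @param loss_prob per-gene probability of loss.
#' @param pseudo_prob per-gene probability of truncation-pseudogenization
#'   among retained genes.
#' @param pseudo_retained_fraction `(min, max)` fraction of the original
#'   protein length retained by a pseudogene (5'-intact truncation).
#' @param seed integer RNG seed; a fixed seed makes all outputs
#'   byte-identical across runs.
#' @return an object of class `sim_config`.
#' @seealso [generate_catalog()], [simulate_descendants()]
#' @export
sim_config <- function(n_genes = 150L, genome_gc = 0.22,
                       target_coding_density = 0.90,
                       n_inversions = 0L, inversion_size_genes = c(2L, 40L),
                       loss_prob = 0, pseudo_prob = 0,
                       pseudo_retained_fraction = c(0.2, 0.5),
                       seed = 1L) {
  assert_count(n_genes, "n_genes", min = 1L)
  assert_fraction(genome_gc, "genome_gc")
  assert_fraction(target_coding_density, "target_coding_density")
  if (target_coding_density <= 0)
    stopf("invalid config: 'target_coding_density' must be > 0")
  assert_count(n_inversions, "n_inversions")
  assert_range(inversion_size_genes, "inversion_size_genes")
  if (inversion_size_genes[1] < 1)
    stopf("invalid config: inversion sizes must be >= 1 gene")
  assert_fraction(loss_prob, "loss_prob")
  assert_fraction(pseudo_prob, "pseudo_prob")
  assert_range(pseudo_retained_fraction, "pseudo_retained_fraction")
  assert_fraction(pseudo_retained_fraction[1], "pseudo_retained_fraction[1]")
  assert_fraction(pseudo_retained_fraction[2], "pseudo_retained_fraction[2]")
  assert_count(seed, "seed")
  structure(list(
    n_genes = as.integer(n_genes), genome_gc = genome_gc,
    target_coding_density = target_coding_density,
    n_inversions = as.integer(n_inversions),
    inversion_size_genes = as.integer(inversion_size_genes),
    loss_prob = loss_prob, pseudo_prob = pseudo_prob,
    pseudo_retained_fraction = pseudo_retained_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Functional category vocabulary
#'
#' The fixed controlled vocabulary of functional groups used for catalog
#' genes and for ordering the columns of [gene_content_matrix()].  Shipped
#' as an editable table in `inst/extdata/functional_groups.tsv`.
#'
#' @return character vector of group names.
#' @export
functional_groups <- function() {
  path <- system.file("extdata", "functional_groups.tsv", package = "endosym")
  read.delim(path, header = TRUE, stringsAsFactors = FALSE)$group
}

# codon sampling model: base composition implied by the genome GC target,
# stop codons excluded.  AT-biased codons dominate at low GC, which also
# skews amino acid composition the way real symbiont proteomes are skewed.
codon_model <- function(gc) {
  bases <- c("A", "C", "G", "T")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  w <- as.vector(outer(outer(p, p, `*`), p, `*`))
  stops <- c("TAA", "TAG", "TGA")
  keep <- !(codons %in% stops)
  list(codons = codons[keep], weights = w[keep] / sum(w[keep]),
       stops = stops, stop_weights = {
         sw <- w[match(stops, codons)]
         sw / sum(sw)
       })
}

#' Generate an ancestral gene catalog
#'
#' Draws `n_genes` reference proteins (random codon sequences under the
#' genome GC model, lengths lognormal around ~230 aa, minimum 30 aa), each
#' with a unique symbol and a functional category, plus an ancestral
#' circular gene order: a uniform random permutation with strands assigned
#' independently (p = 0.5 forward).
#'
#' @param config a [sim_config()].
#' @return an object of class `gene_catalog` with components
#'   `entries` (data frame: `symbol`, `category`, `aa_length`, `protein`,
#'   `cds`) and `ancestral_order` (data frame: `symbol`, `strand`).
#' @examples
#' cat <- generate_catalog(sim_config(n_genes = 5, seed = 1))
#' cat$entries$symbol
#' @export
generate_catalog <- function(config) {
  if (!inherits(config, "sim_config")) stopf("invalid config: expected a sim_config")
  n <- config$n_genes
  cm <- codon_model(config$genome_gc)
  code <- Biostrings::getGeneticCode("11")
  groups <- functional_groups()
  with_seed(config$seed, {
    lens <- pmax(30L, as.integer(round(rlnorm(n, meanlog = log(230), sdlog = 0.35))))
    symbol <- sprintf("g%03d", seq_len(n))
    category <- sample(groups, n, replace = TRUE)
    cds <- character(n)
    protein <- character(n)
    for (i in seq_len(n)) {
      body <- sample(cm$codons, lens[i] - 1L, replace = TRUE, prob = cm$weights)
      stopc <- sample(cm$stops, 1L, prob = cm$stop_weights)
      cds[i] <- paste0("ATG", paste(body, collapse = ""), stopc)
      protein[i] <- paste0("M", paste(code[body], collapse = ""))
    }
    ord <- sample.int(n)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    structure(list(
      entries = data.frame(symbol = symbol, category = category,
                           aa_length = lens, protein = protein, cds = cds,
                           stringsAsFactors = FALSE),
      ancestral_order = data.frame(symbol = symbol[ord], strand = strands,
                                   stringsAsFactors = FALSE),
      genome_gc = config$genome_gc
    ), class = "gene_catalog")
  })
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("gene_catalog: %d genes, %d-%d aa (median %d), GC model %.2f\n",
              nrow(x$entries), min(x$entries$aa_length), max(x$entries$aa_length),
              as.integer(median(x$entries$aa_length)), x$genome_gc))
  invisible(x)
}

#' Write / read a gene catalog as TSV
#'
#' Two tables are written: `<stem>.tsv` with the catalog entries and
#' `<stem>_order.tsv` with the ancestral gene order.
#' @param catalog a `gene_catalog`.
#' @param stem output path stem (no extension).
#' @return `write_catalog` returns the paths invisibly; `read_catalog`
#'   returns a `gene_catalog`.
#' @export
write_catalog <- function(catalog, stem) {
  p1 <- paste0(stem, ".tsv"); p2 <- paste0(stem, "_order.tsv")
  write.table(catalog$entries, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(catalog$ancestral_order, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}

#' @rdname write_catalog
#' @export
read_catalog <- function(stem) {
  entries <- read.delim(paste0(stem, ".tsv"), stringsAsFactors = FALSE)
  ord <- read.delim(paste0(stem, "_order.tsv"), stringsAsFactors = FALSE)
  structure(list(entries = entries, ancestral_order = ord,
                 genome_gc = NA_real_), class = "gene_catalog")
}
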