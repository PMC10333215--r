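# shared fixture builders (all synthetic, generated at test time)

tiny_sim_config <- function(n_genes = 20L, seed = 1L, ...) {
  sim_config(n_genes = n_genes,
             inversion_size_genes = c(2L, min(6L, n_genes)), seed = seed, ...)
}

tiny_catalog <- function(n_genes = 20L, seed = 1L) {
  generate_catalog(tiny_sim_config(n_genes, seed))
}

# a hand-built circular annotation: genes laid out evenly on the circle
manual_annotation <- function(id, genes, strands, L = 1000L * length(genes),
                              statuses = "functional") {
  n <- length(genes)
  start <- as.integer(seq(1L, L - 900L, length.out = n))
  calls <- data.frame(gene = genes, status = rep_len(statuses, n),
                      length_fraction = 1, start = start, end = start + 899L,
                      strand = rep_len(strands, n), type = "CDS",
                      stringsAsFactors = FALSE)
  circular_annotation(id, L, calls)
}

# rotate a circular sequence so it starts at 1-based position k+1
rotate_seq <- function(s, k) {
  L <- nchar(s)
  k <- k %% L
  if (k == 0) return(s)
  paste0(substr(s, k + 1L, L), substr(s, 1L, k))
}

pyrops_presence <- function() {
  path <- system.file("extdata", "pyrops_eaa_genes.tsv", package = "endosym")
  read.delim(path, stringsAsFactors = FALSE)
}
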