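# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Restores the caller's RNG state on exit so that library functions do not
#' clobber the session's random number stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("invalid config: '%s' must be a single fraction in [0, 1]", name)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stopf("invalid config: '%s' must be an integer >= %d", name, min)
}

assert_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[1] > x[2])
    stopf("invalid config: '%s' must be a (min, max) pair with min <= max", name)
}

#' Sample random DNA with a given GC fraction
#' @noRd
random_dna <- function(n, gc) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

gc_fraction <- function(x) {
  x <- Biostrings::DNAString(as.character(x))
  counts <- Biostrings::letterFrequency(x, c("G", "C", "A", "T"))
  sum(counts[c("G", "C")]) / sum(counts)
}

#' Resolve a genome argument to a plain uppercase character string
#' @noRd
as_genome_string <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_genome_fasta(genome)
  if (is(genome, "DNAStringSet")) {
    if (length(genome) == 0L) stopf("input error: empty FASTA (no sequence records)")
    genome <- genome[[1L]]
  }
  s <- toupper(as.character(genome))
  if (!nzchar(s)) stopf("input error: empty genome sequence")
  s
}
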