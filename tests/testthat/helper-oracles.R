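# Independent brute-force oracles.  These re-derive expected results from
# first principles and must stay independent of the package internals.

# --- circular maximal-run finder ------------------------------------------
# A set of circularly consecutive query positions is a run when every
# adjacent pair of values is a circular +1 step with positive signs
# (forward) or a circular -1 step with negative signs (inverted).  Blocks
# are the non-extendable runs.
oracle_is_run <- function(v, pos) {
  if (length(pos) == 1L) return(TRUE)
  n <- length(v)
  a <- v[pos[-length(pos)]]
  b <- v[pos[-1L]]
  fwd <- all(a > 0 & b > 0 & (a %% n) + 1L == b)
  inv <- all(a < 0 & b < 0 & (abs(b) %% n) + 1L == abs(a))
  fwd || inv
}

oracle_blocks <- function(v) {
  n <- length(v)
  circ <- function(p, l) ((p - 1L + 0:(l - 1L)) %% n) + 1L
  found <- list()
  keys <- character()
  for (p in seq_len(n)) {
    for (l in seq_len(n)) {
      pos <- circ(p, l)
      if (!oracle_is_run(v, pos)) break   # runs cannot have run-holes
      if (l == n) { ext <- FALSE } else {
        ext <- oracle_is_run(v, circ(p - 1L, l + 1L)) ||
               oracle_is_run(v, circ(p, l + 1L))
      }
      if (!ext) {
        key <- paste(sort(pos), collapse = ",")
        if (!key %in% keys) {
          keys <- c(keys, key)
          found[[length(found) + 1L]] <- list(
            positions = pos,
            orientation = if (v[pos[1L]] > 0) "forward" else "inverted")
        }
      }
      if (l == n) break
    }
  }
  found
}

oracle_synteny_fraction <- function(v) {
  b <- oracle_blocks(v)
  good <- vapply(b, function(x)
    if (x$orientation == "forward" && length(x$positions) >= 2L)
      length(x$positions) else 0L, integer(1))
  sum(good) / length(v)
}

# compare package blocks (which carry positions) with oracle blocks by the
# set of member positions plus orientation
expect_same_blocks <- function(got, want) {
  g <- sort(vapply(got, function(b)
    paste0(b$orientation, ":", paste(sort(b$positions), collapse = ",")), ""))
  w <- sort(vapply(want, function(b)
    paste0(b$orientation, ":", paste(sort(b$positions), collapse = ",")), ""))
  expect_identical(g, w)
}

# all signed permutations of 1..n
all_signed_perms <- function(n) {
  perms <- function(x) {
    if (length(x) == 1L) return(list(x))
    out <- list()
    for (i in seq_along(x))
      for (p in perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
    out
  }
  base <- perms(seq_len(n))
  signs <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
  out <- list()
  for (p in base)
    for (r in seq_len(nrow(signs)))
      out[[length(out) + 1L]] <- p * signs[r, ]
  out
}

random_signed_perm <- function(n) sample.int(n) * sample(c(1L, -1L), n, TRUE)

# --- exhaustive parsimony --------------------------------------------------
# minimal number of state changes over all labelings of internal nodes
oracle_parsimony <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tip_states <- tip_states[tree$tip.label]
  best <- Inf
  for (mask in 0:(2^nnode - 1L)) {
    internal <- as.integer(intToBits(mask))[seq_len(nnode)]
    st <- c(tip_states, internal)
    changes <- sum(st[tree$edge[, 1L]] != st[tree$edge[, 2L]])
    best <- min(best, changes)
  }
  best
}

# --- brute-force six-frame circular ORF scan ------------------------------
# walks every position of the circle on both strands, codon by codon
oracle_orfs <- function(seq, start_codons = "ATG",
                        stops = c("TAA", "TAG", "TGA"), min_aa = 1L) {
  L <- nchar(seq)
  scan_one <- function(s, strand) {
    cands <- list()
    big <- paste0(s, s)
    for (i in 0:(L - 1L)) {
      if (!(substr(big, i + 1L, i + 3L) %in% start_codons)) next
      len <- NA_integer_
      for (kk in seq_len(L %/% 3L + 1L)) {
        cstart <- i + 3L * kk
        if (cstart + 3L > 2L * L) break
        if (substr(big, cstart + 1L, cstart + 3L) %in% stops) {
          len <- 3L * (kk + 1L); break
        }
      }
      if (is.na(len) || len > L) next
      aa <- len %/% 3L - 1L
      if (aa < min_aa) next
      cands[[length(cands) + 1L]] <- data.frame(
        rc_start = i, len = len, stop_at = (i + len) %% L)
    }
    if (!length(cands)) return(NULL)
    d <- do.call(rbind, cands)
    # maximal ORF per stop: longest
    d <- d[order(d$stop_at, -d$len), , drop = FALSE]
    d <- d[!duplicated(d$stop_at), , drop = FALSE]
    if (strand == "+") {
      data.frame(start = d$rc_start, end = d$rc_start + d$len, strand = "+",
                 aa_length = d$len %/% 3L - 1L)
    } else {
      st <- (L - (d$rc_start + d$len)) %% L
      data.frame(start = st, end = st + d$len, strand = "-",
                 aa_length = d$len %/% 3L - 1L)
    }
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  out <- rbind(scan_one(seq, "+"), scan_one(rc, "-"))
  if (is.null(out)) return(data.frame(start = integer(), end = integer(),
                                      strand = character(), aa_length = integer()))
  out[order(out$start, out$strand), , drop = FALSE]
}

orf_key <- function(df) {
  sort(sprintf("%d:%d:%s", df$start, df$end, df$strand))
}
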