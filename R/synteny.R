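#' Configuration for circular gene-order comparison
#'
#' @param anchor_gene gene used to rotation-normalize both circles
#'   (`lipB` is the conventional anchor for Sulcia-type comparisons,
#'   `tufA` for beta-symbiont comparisons).  If the anchor is missing
#'   from either genome, the lexicographically smallest shared symbol is
#'   used and a warning is emitted.
#' @param include_statuses call statuses treated as orderable markers.
#' @param max_gap_genes permitted gap (in shared-gene positions) inside a
#'   collinear block; the default 0 is appropriate because
#'   lineage-specific genes are already removed by the shared-gene
#'   restriction.
#' @param span_tolerance_nt tolerance attached to nucleotide span
#'   comparisons (reported spans are approximate).
#' @return object of class `synteny_config`.
#' @export
synteny_config <- function(anchor_gene = "lipB",
                           include_statuses = c("functional", "putative_pseudogene"),
                           max_gap_genes = 0L, span_tolerance_nt = 2000L) {
  assert_count(max_gap_genes, "max_gap_genes")
  assert_count(span_tolerance_nt, "span_tolerance_nt")
  structure(list(anchor_gene = anchor_gene, include_statuses = include_statuses,
                 max_gap_genes = as.integer(max_gap_genes),
                 span_tolerance_nt = as.integer(span_tolerance_nt)),
            class = "synteny_config")
}

#' Construct a signed permutation directly
#'
#' Low-level constructor used when the permutation is already known
#' (e.g. in oracle tests); [build_permutation()] derives one from two
#' annotations.
#'
#' @param order integer vector: query order as signed reference indices;
#'   absolute values must be a permutation of `1..n`.
#' @param genes optional shared gene symbols in reference order.
#' @param ref_id,qry_id genome identifiers.
#' @return object of class `signed_permutation`.
#' @export
signed_permutation <- function(order, genes = NULL, ref_id = "ref", qry_id = "qry") {
  n <- length(order)
  if (!n || any(order == 0) || !setequal(abs(order), seq_len(n)))
    stopf("signed permutation must contain each of 1..n exactly once (signed)")
  genes <- genes %||% sprintf("gene%03d", seq_len(n))
  structure(list(ref_id = ref_id, qry_id = qry_id,
                 genes = genes, order = as.integer(order)),
            class = "signed_permutation")
}

# rotate a gene-order table so `anchor` is first; if the anchor is on the
# minus strand, reverse-complement the whole circle (reverse order, flip
# strands) so the anchor reads forward
normalize_order <- function(ord, anchor) {
  i <- match(anchor, ord$gene)
  if (ord$strand[i] == "-") {
    ord <- ord[rev(seq_len(nrow(ord))), , drop = FALSE]
    ord$strand <- ifelse(ord$strand == "+", "-", "+")
    i <- match(anchor, ord$gene)
  }
  idx <- c(i:nrow(ord), if (i > 1L) 1:(i - 1L))
  ord <- ord[idx, , drop = FALSE]
  rownames(ord) <- NULL
  ord
}

#' Build a signed permutation of the shared gene order
#'
#' Both circular genomes are rotated so the anchor gene comes first and
#' reads forward; genes absent from either genome (or outside the
#' included statuses) are excluded; origin-split duplicates are merged by
#' [gene_order()].  The query order is then expressed as signed reference
#' indices, the sign recording relative orientation.
#'
#' @param ref,qry [circular_annotation()] objects.
#' @param config a [synteny_config()].
#' @return a [signed_permutation()] carrying the query coordinate table
#'   (`qry_coords`) and genome lengths needed for span measurements.
#' @export
build_permutation <- function(ref, qry, config = synteny_config()) {
  ro <- gene_order(ref, config$include_statuses)
  qo <- gene_order(qry, config$include_statuses)
  shared <- intersect(ro$gene, qo$gene)
  if (length(shared) < 2L)
    stopf("comparison error: fewer than 2 shared genes between '%s' and '%s'",
          ref$genome_id, qry$genome_id)
  ro <- ro[ro$gene %in% shared, , drop = FALSE]
  qo <- qo[qo$gene %in% shared, , drop = FALSE]
  anchor <- config$anchor_gene
  if (!(anchor %in% shared)) {
    anchor <- sort(shared)[1L]
    warnf("anchor gene '%s' missing from a genome; falling back to '%s'",
          config$anchor_gene, anchor)
  }
  ro <- normalize_order(ro, anchor)
  qo <- normalize_order(qo, anchor)
  ref_pos <- setNames(seq_len(nrow(ro)), ro$gene)
  sgn <- ifelse(qo$strand == ro$strand[match(qo$gene, ro$gene)], 1L, -1L)
  p <- signed_permutation(sgn * ref_pos[qo$gene], genes = ro$gene,
                          ref_id = ref$genome_id, qry_id = qry$genome_id)
  p$qry_coords <- gene_order(qry, config$include_statuses)  # original coordinates
  p$qry_length <- qry$genome_length
  p$ref_length <- ref$genome_length
  p
}

#' Decompose a signed permutation into collinear blocks
#'
#' Finds the minimal set of maximal blocks: runs of consecutive query
#' positions whose reference indices increase by +1 with positive sign
#' (forward) or decrease by 1 with negative sign (inverted).  Adjacency
#' is circular on both sides: position n is followed by position 1 and
#' reference index n is circularly adjacent to index 1, so blocks do not
#' depend on where the circle was cut.
#'
#' @param perm a [signed_permutation()].
#' @return list of blocks; each block has `positions` (query positions),
#'   `ref_indices`, `genes` (when carried by the permutation) and
#'   `orientation` (`"forward"` or `"inverted"`).
#' @export
call_blocks <- function(perm) {
  v <- perm$order
  n <- length(v)
  nxt <- c(seq_len(n)[-1L], 1L)
  conn <- vapply(seq_len(n), function(j) {
    a <- v[j]; b <- v[nxt[j]]
    (a > 0 && b > 0 && (a %% n) + 1L == b) ||
      (a < 0 && b < 0 && (abs(b) %% n) + 1L == abs(a))
  }, logical(1))
  blocks <- list()
  if (all(conn)) {
    runs <- list(seq_len(n))
  } else {
    # walk the circle starting just after a break
    brk <- which(!conn)
    start <- (brk[1L] %% n) + 1L
    ordpos <- ((start - 1L + 0:(n - 1L)) %% n) + 1L
    runs <- list(); cur <- ordpos[1L]
    for (k in seq_len(n)) {
      j <- ordpos[k]
      if (conn[j] && k < n) {
        cur <- c(cur, ordpos[k + 1L])
      } else {
        runs[[length(runs) + 1L]] <- cur
        if (k < n) cur <- ordpos[k + 1L]
      }
    }
  }
  for (r in runs) {
    vals <- v[r]
    blocks[[length(blocks) + 1L]] <- list(
      positions = r,
      ref_indices = abs(vals),
      genes = if (!is.null(perm$genes)) perm$genes[abs(vals)] else NULL,
      orientation = if (all(vals > 0)) "forward" else "inverted")
  }
  blocks
}

#' Call inversions from a block decomposition
#'
#' Emits one call per inverted block, with the number of member CDS
#' features and the nucleotide span of the block on the query circle
#' (first to last member coordinate, measured on the arc containing the
#' members).  rRNA or other non-CDS markers contribute to the block but
#' not to `cds_count`.
#'
#' @param blocks output of [call_blocks()].
#' @param perm the [signed_permutation()] the blocks came from (carries
#'   query coordinates), or a `circular_annotation` of the query.
#' @return data frame of class `inversion_calls`: `genes` (list column),
#'   `n_genes`, `cds_count`, `query_span_nt`, `ref_id`, `qry_id`.
#' @export
call_inversions <- function(blocks, perm) {
  if (inherits(perm, "circular_annotation")) {
    coords <- gene_order(perm, unique(perm$calls$status))
    L <- perm$genome_length; qid <- perm$genome_id; rid <- NA_character_
  } else {
    coords <- perm$qry_coords; L <- perm$qry_length
    qid <- perm$qry_id; rid <- perm$ref_id
  }
  inv <- Filter(function(b) identical(b$orientation, "inverted"), blocks)
  if (!length(inv)) {
    out <- data.frame(n_genes = integer(), cds_count = integer(),
                      query_span_nt = integer(),
                      ref_id = character(), qry_id = character())
    out$genes <- list()
    class(out) <- c("inversion_calls", class(out))
    return(out)
  }
  rows <- lapply(inv, function(b) {
    g <- b$genes
    cds <- if (!is.null(coords)) sum(coords$type[match(g, coords$gene)] == "CDS")
           else length(g)
    span <- NA_integer_
    if (!is.null(coords) && !is.null(L)) {
      m <- coords[match(g, coords$gene), , drop = FALSE]
      m <- m[order(m$start), , drop = FALSE]
      k <- nrow(m)
      if (k == 1L) {
        span <- m$end[1L] - m$start[1L] + 1L
      } else {
        # members are consecutive on the query circle; the arc containing
        # them is bounded by the largest gap between successive starts
        gaps <- diff(c(m$start, m$start[1L] + L))
        cut <- which.max(gaps)            # largest gap follows member `cut`
        first <- (cut %% k) + 1L
        span <- ((m$end[cut] - m$start[first]) %% L) + 1L
      }
    }
    data.frame(n_genes = length(g), cds_count = cds,
               query_span_nt = as.integer(span),
               ref_id = rid, qry_id = qid, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$genes <- lapply(inv, `[[`, "genes")
  rownames(out) <- NULL
  class(out) <- c("inversion_calls", class(out))
  out
}

#' Fraction of shared genes in conserved forward blocks
#'
#' A simple global synteny statistic: the fraction of shared genes lying
#' inside forward blocks of at least 2 genes.  1 for perfectly collinear
#' genomes, 0 when every shared gene is a singleton block.
#'
#' @param blocks output of [call_blocks()].
#' @param perm the underlying [signed_permutation()].
#' @return fraction in `[0, 1]`.
#' @export
synteny_fraction <- function(blocks, perm) {
  n <- length(perm$order)
  good <- vapply(blocks, function(b)
    if (identical(b$orientation, "forward") && length(b$positions) >= 2L)
      length(b$positions) else 0L, integer(1))
  sum(good) / n
}

#' Write ribbon-plot data for external plotting
#'
#' Linearized gene positions of both genomes plus block membership, as
#' JSON, the handoff point to any plotting layer.
#' @param perm a [build_permutation()] result.
#' @param blocks output of [call_blocks()].
#' @param path JSON output path.
#' @export
write_ribbon_json <- function(perm, blocks, path) {
  payload <- list(
    ref_id = perm$ref_id, qry_id = perm$qry_id,
    genes = perm$genes, order = perm$order,
    blocks = lapply(blocks, function(b)
      list(genes = b$genes, orientation = b$orientation)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
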