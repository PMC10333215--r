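#' Map derived gene-order characters onto a host tree by parsimony
#'
#' Each distinct derived genome arrangement is coded as a binary
#' character (0 = ancestral order, 1 = derived order) on the tips of the
#' host phylogeny.  Fitch parsimony (Hartigan's generalization, so
#' multifurcations are allowed) reconstructs ancestral states per
#' character; rearrangement events are assigned to the branches where the
#' reconstructed state changes.  Ambiguous reconstructions are resolved
#' by retaining the parental state wherever parsimony permits, with the
#' root preferring the ancestral order -- for derived states confined to
#' a clade this places the event on the single deepest branch compatible
#' with the tip states.
#'
#' @param characters either a tips-by-characters matrix/data frame of
#'   0/1 states with taxa as row names, or a long data frame with columns
#'   `taxon`, `character`, `state`.
#' @param tree an `ape::phylo` object, a newick string, or a path to a
#'   newick file.
#' @return object of class `event_placement`: `tree`, `states` (the tip
#'   matrix), `events` (data frame `character`, `parent`, `child`,
#'   `branch` -- the tip label or internal node number below the event),
#'   `scores` (per-character parsimony score) and `total`.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' m <- matrix(c(1, 1, 0, 0), 4, 1, dimnames = list(c("A", "B", "C", "D"), "inv1"))
#' map_events_on_tree(m, tr)$total  # one event on the (A,B) stem
#' @export
map_events_on_tree <- function(characters, tree) {
  if (is.character(tree) && length(tree) == 1L) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  }
  if (!inherits(tree, "phylo")) stopf("input error: 'tree' must be a phylo or newick")
  states <- as_character_matrix(characters)
  missing_in_tree <- setdiff(rownames(states), tree$tip.label)
  if (length(missing_in_tree))
    stopf("input error: taxa absent from the tree: %s",
          paste(missing_in_tree, collapse = ", "))
  missing_states <- setdiff(tree$tip.label, rownames(states))
  if (length(missing_states))
    stopf("input error: tree tips without character states: %s",
          paste(missing_states, collapse = ", "))
  if (!all(states %in% c(0L, 1L)))
    stopf("input error: characters must be binary (0 = ancestral, 1 = derived)")
  states <- states[tree$tip.label, , drop = FALSE]

  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  children <- split(edge[, 2L], edge[, 1L])

  events <- list()
  scores <- integer(ncol(states))
  for (ci in seq_len(ncol(states))) {
    tipst <- states[, ci]
    # Hartigan down-pass over {0,1}: sets encoded 1=\{0\}, 2=\{1\}, 3=\{0,1\}
    sets <- integer(ntip + nnode)
    sets[seq_len(ntip)] <- ifelse(tipst == 0L, 1L, 2L)
    nch <- vapply(children, length, 1L)
    acc0 <- acc1 <- seen <- integer(ntip + nnode)
    score <- 0L
    for (e in seq_len(nrow(edge))) {  # postorder: child sets known here
      node <- edge[e, 1L]; child <- edge[e, 2L]
      acc0[node] <- acc0[node] + (sets[child] %in% c(1L, 3L))
      acc1[node] <- acc1[node] + (sets[child] %in% c(2L, 3L))
      seen[node] <- seen[node] + 1L
      if (seen[node] == nch[[as.character(node)]]) {
        # a child set {0,1} supports either state; count support per state
        m <- max(acc0[node], acc1[node])
        sets[node] <- if (acc0[node] == m && acc1[node] == m) 3L
                      else if (acc0[node] == m) 1L else 2L
        score <- score + (seen[node] - m)
      }
    }
    scores[ci] <- score
    # top-down resolution: keep the parental state when permitted
    final <- integer(ntip + nnode)
    final[root] <- if (sets[root] %in% c(1L, 3L)) 0L else 1L
    for (e in rev(seq_len(nrow(edge)))) {   # preorder
      parent <- edge[e, 1L]; child <- edge[e, 2L]
      ps <- final[parent]
      cs <- sets[child]
      final[child] <- if (cs == 3L) ps else cs - 1L
      if (final[child] != ps) {
        branch <- if (child <= ntip) tree$tip.label[child]
                  else sprintf("node%d", child)
        events[[length(events) + 1L]] <- data.frame(
          character = colnames(states)[ci], parent = parent, child = child,
          branch = branch, stringsAsFactors = FALSE)
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events)
            else data.frame(character = character(), parent = integer(),
                            child = integer(), branch = character())
  structure(list(tree = tree, states = states, events = events,
                 scores = setNames(scores, colnames(states)),
                 total = sum(scores)),
            class = "event_placement")
}

as_character_matrix <- function(characters) {
  if (is.matrix(characters)) {
    storage.mode(characters) <- "integer"
    return(characters)
  }
  if (is.data.frame(characters) &&
      all(c("taxon", "character", "state") %in% names(characters))) {
    taxa <- unique(characters$taxon)
    chars <- unique(characters$character)
    m <- matrix(NA_integer_, length(taxa), length(chars),
                dimnames = list(taxa, chars))
    m[cbind(match(characters$taxon, taxa), match(characters$character, chars))] <-
      as.integer(characters$state)
    if (anyNA(m)) stopf("input error: incomplete taxon x character table")
    return(m)
  }
  if (is.data.frame(characters)) {
    m <- as.matrix(characters)
    storage.mode(m) <- "integer"
    return(m)
  }
  stopf("input error: unsupported character table")
}

#' @export
print.event_placement <- function(x, ...) {
  cat(sprintf("event_placement: %d characters, %d events total\n",
              ncol(x$states), x$total))
  if (nrow(x$events)) {
    for (i in seq_len(nrow(x$events)))
      cat(sprintf("  %s -> branch above %s\n",
                  x$events$character[i], x$events$branch[i]))
  }
  invisible(x)
}
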