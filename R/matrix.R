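#' Cross-lineage gene-content presence matrix
#'
#' Builds the presence/status matrix comparing gene content across
#' annotated lineages: rows are lineages, columns are gene symbols
#' (ordered by functional category then name), and every cell is one of
#' `functional`, `putative_pseudogene`, `pseudogene` or `absent`.
#' Hypothetical calls are excluded; when a lineage carries duplicate
#' calls for a symbol the most intact status is kept.
#'
#' @param annotations named list of [circular_annotation()] objects (or
#'   data frames with `gene` and `status`); names become row ids.
#' @param gene_categories named character vector mapping gene symbol to
#'   functional category (e.g. `setNames(entries$category,
#'   entries$symbol)` from a catalog); unmapped genes sort last.
#' @param categories optional filter: keep only genes in these
#'   functional categories.  Unknown category names are an error listing
#'   the valid vocabulary.
#' @return character matrix of class `presence_matrix` with a
#'   `categories` attribute giving each column's category.
#' @export
gene_content_matrix <- function(annotations, gene_categories = NULL,
                                categories = NULL) {
  if (!length(annotations)) stopf("input error: need at least one annotation")
  ids <- names(annotations) %||% sprintf("lineage%02d", seq_along(annotations))
  statuses <- c("functional", "putative_pseudogene", "pseudogene")
  tabs <- lapply(annotations, function(a) {
    calls <- if (inherits(a, "circular_annotation")) a$calls else a
    calls[!is.na(calls$gene) & calls$status %in% statuses,
          c("gene", "status"), drop = FALSE]
  })
  genes <- unique(unlist(lapply(tabs, `[[`, "gene")))
  cat_of <- setNames(rep(NA_character_, length(genes)), genes)
  if (!is.null(gene_categories)) {
    hit <- intersect(genes, names(gene_categories))
    cat_of[hit] <- gene_categories[hit]
  }
  if (!is.null(categories)) {
    valid <- functional_groups()
    bad <- setdiff(categories, valid)
    if (length(bad))
      stopf("config error: unknown categories %s; valid categories are: %s",
            paste(bad, collapse = ", "), paste(valid, collapse = "; "))
    genes <- genes[!is.na(cat_of[genes]) & cat_of[genes] %in% categories]
  }
  ord <- order(ifelse(is.na(cat_of[genes]), "zzz", cat_of[genes]), genes)
  genes <- genes[ord]
  m <- matrix("absent", length(annotations), length(genes),
              dimnames = list(ids, genes))
  rank <- setNames(seq_along(statuses), statuses)
  for (i in seq_along(tabs)) {
    t <- tabs[[i]]
    t <- t[t$gene %in% genes, , drop = FALSE]
    if (!nrow(t)) next
    t <- t[order(rank[t$status]), , drop = FALSE]   # most intact first
    t <- t[!duplicated(t$gene), , drop = FALSE]
    m[i, t$gene] <- t$status
  }
  structure(m, categories = cat_of[genes], class = c("presence_matrix", "matrix"))
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: %d lineages x %d genes\n", nrow(x), ncol(x)))
  counts <- apply(unclass(x), 1, function(r) table(factor(
    r, c("functional", "putative_pseudogene", "pseudogene", "absent"))))
  print(t(counts))
  invisible(x)
}

#' Write a presence matrix as TSV
#' @param m a `presence_matrix`.
#' @param path output path.
#' @export
write_presence_matrix <- function(m, path) {
  df <- data.frame(lineage = rownames(m), unclass(m), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
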