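#' Load essential amino acid biosynthesis pathway definitions
#'
#' The ten EAA pathways are shipped as data (an editable TSV), one row per
#' reaction step with the set of alternative gene symbols sufficient for
#' that step (isozymes grouped within a step, complex subunits as
#' separate steps).
#'
#' @param path pathway TSV with columns `eaa`, `step`, `genes`
#'   (comma-separated alternatives); defaults to the built-in table.
#' @return named list of `pathway_def` objects, each with fields `eaa`
#'   and `steps` (list of character vectors).
#' @export
load_builtin_pathways <- function(path = NULL) {
  path <- path %||% system.file("extdata", "eaa_pathways.tsv", package = "endosym")
  df <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("eaa", "step", "genes")
  if (!all(needed %in% names(df)))
    stopf("pathway schema error: need columns %s", paste(needed, collapse = ", "))
  for (i in seq_len(nrow(df))) {
    if (is.na(df$eaa[i]) || !nzchar(df$eaa[i]) ||
        is.na(df$genes[i]) || !nzchar(df$genes[i]) ||
        is.na(df$step[i]))
      stopf("pathway schema error in row %d of '%s'", i, path)
  }
  out <- list()
  for (eaa in unique(df$eaa)) {
    sub <- df[df$eaa == eaa, , drop = FALSE]
    sub <- sub[order(sub$step), , drop = FALSE]
    steps <- lapply(strsplit(sub$genes, ","), trimws)
    if (any(!vapply(steps, length, 1L)))
      stopf("pathway schema error: empty step gene set for '%s'", eaa)
    out[[eaa]] <- structure(list(eaa = eaa, steps = steps), class = "pathway_def")
  }
  out
}

# genes counted as present for pathway scoring
present_genes <- function(annotation, include_putative = FALSE) {
  ok <- if (include_putative) c("functional", "putative_pseudogene") else "functional"
  if (inherits(annotation, "circular_annotation")) {
    calls <- annotation$calls
    unique(calls$gene[!is.na(calls$gene) & calls$status %in% ok])
  } else if (is.data.frame(annotation)) {
    if (!all(c("gene", "status") %in% names(annotation)))
      stopf("annotation data frame needs 'gene' and 'status' columns")
    unique(annotation$gene[annotation$status %in% ok])
  } else if (is.character(annotation)) {
    unique(annotation)
  } else stopf("unsupported annotation object")
}

#' Score pathway completeness against an annotation
#'
#' A step counts as present iff at least one of its alternative genes is
#' functional in the annotation (optionally also counting putative
#' pseudogenes).  Gene symbols in the annotation that no pathway uses are
#' ignored.
#'
#' @param annotation a [circular_annotation()], a data frame with `gene`
#'   and `status` columns, or a character vector of present gene symbols.
#' @param pathways list from [load_builtin_pathways()].
#' @param include_putative count putative pseudogenes as present.
#' @return data frame of class `eaa_completeness` with columns `eaa`,
#'   `steps_present`, `steps_total` and a list column `missing_steps`.
#' @export
completeness <- function(annotation, pathways = load_builtin_pathways(),
                         include_putative = FALSE) {
  genes <- present_genes(annotation, include_putative)
  rows <- lapply(pathways, function(p) {
    hit <- vapply(p$steps, function(alt) any(alt %in% genes), logical(1))
    data.frame(eaa = p$eaa, steps_present = sum(hit),
               steps_total = length(hit), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$missing_steps <- I(lapply(pathways, function(p) {
    hit <- vapply(p$steps, function(alt) any(alt %in% genes), logical(1))
    p$steps[!hit]
  }))
  rownames(res) <- NULL
  class(res) <- c("eaa_completeness", class(res))
  res
}

#' Partition EAA provisioning between two co-symbionts
#'
#' Each amino acid is credited to the symbiont with strictly more present
#' pathway steps; equal counts (including 0-0 ties) leave it unassigned.
#' This strictly-more rule credits a symbiont with a pathway even when a
#' terminal step is missing, as long as its partner retains less of it.
#'
#' @param a,b [completeness()] results covering the same EAAs.
#' @param labels names of the two symbionts.
#' @return list of class `eaa_partition` with `credited` (named list of
#'   EAA vectors per symbiont) and `unassigned`.
#' @export
partition <- function(a, b, labels = c("symbiont_a", "symbiont_b")) {
  if (!setequal(a$eaa, b$eaa))
    stopf("input error: completeness tables cover different EAA sets")
  b <- b[match(a$eaa, b$eaa), , drop = FALSE]
  credit_a <- a$eaa[a$steps_present > b$steps_present]
  credit_b <- a$eaa[b$steps_present > a$steps_present]
  unassigned <- setdiff(a$eaa, c(credit_a, credit_b))
  structure(list(credited = setNames(list(credit_a, credit_b), labels),
                 unassigned = unassigned),
            class = "eaa_partition")
}

#' @export
print.eaa_partition <- function(x, ...) {
  for (nm in names(x$credited))
    cat(sprintf("%s: %d EAAs (%s)\n", nm, length(x$credited[[nm]]),
                paste(x$credited[[nm]], collapse = ", ")))
  if (length(x$unassigned))
    cat("unassigned:", paste(x$unassigned, collapse = ", "), "\n")
  invisible(x)
}
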