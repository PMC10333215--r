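#' Run the analysis pipeline from a declarative config
#'
#' Executes the requested stages in order -- `simulate`, `annotate`,
#' `pathways`, `synteny`, `matrix` -- from a single YAML config, writing
#' per-stage outputs and a manifest (seeds, config digest, output file
#' digests) into the output directory.  Reruns with an identical config
#' and seed are byte-identical; a failing stage stops the run with an
#' error naming the stage.
#'
#' Config schema (YAML):
#' \preformatted{
#' seed: 1
#' out_dir: out
#' stages: [simulate, annotate, synteny, matrix]
#' simulate:
#'   n_genomes: 3
#'   n_genes: 40
#'   n_inversions: 1
#'   loss_prob: 0.02
#'   pseudo_prob: 0.05
#' annotate: {}
#' synteny:
#'   reference: sim01
#' }
#'
#' @param config path to a YAML config file, or an equivalent list.
#' @param out_dir overrides the config's `out_dir`.
#' @return the output directory, invisibly; the manifest is
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: '%s'", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$stages))
    stopf("config error: 'stages' is required")
  out_dir <- out_dir %||% config$out_dir %||% stop("config error: out_dir required")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  known <- c("simulate", "annotate", "pathways", "synteny", "matrix")
  bad <- setdiff(config$stages, known)
  if (length(bad))
    stopf("config error: unknown stage(s) %s; known stages: %s",
          paste(bad, collapse = ", "), paste(known, collapse = ", "))

  state <- new.env(parent = emptyenv())
  for (stage in config$stages) {
    res <- tryCatch(
      switch(stage,
             simulate = stage_simulate(config, seed, out_dir, state),
             annotate = stage_annotate(config, out_dir, state),
             pathways = stage_pathways(config, out_dir, state),
             synteny = stage_synteny(config, out_dir, state),
             matrix = stage_matrix(config, out_dir, state)),
      error = function(e) stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE), "manifest.json"))
  tf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, tf)
  manifest <- list(
    seed = seed,
    stages = config$stages,
    config_digest = unname(tools::md5sum(tf)),
    outputs = as.list(setNames(unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

stage_simulate <- function(config, seed, out_dir, state) {
  p <- config$simulate %||% list()
  n_genomes <- p$n_genomes %||% 3L
  base <- sim_config(
    n_genes = p$n_genes %||% 40L,
    genome_gc = p$genome_gc %||% 0.22,
    target_coding_density = p$target_coding_density %||% 0.9,
    seed = seed)
  catalog <- generate_catalog(base)
  cfgs <- lapply(seq_len(n_genomes), function(i) {
    sim_config(n_genes = base$n_genes, genome_gc = base$genome_gc,
               target_coding_density = base$target_coding_density,
               n_inversions = if (i == 1L) 0L else p$n_inversions %||% 1L,
               inversion_size_genes = c(p$inversion_min %||% 2L,
                                        p$inversion_max %||% 8L),
               loss_prob = if (i == 1L) 0 else p$loss_prob %||% 0,
               pseudo_prob = if (i == 1L) 0 else p$pseudo_prob %||% 0,
               seed = seed + i)
  })
  names(cfgs) <- sprintf("sim%02d", seq_len(n_genomes))
  sims <- simulate_descendants(catalog, cfgs, out_dir = out_dir)
  write_catalog(catalog, file.path(out_dir, "catalog"))
  state$catalog <- catalog
  state$sims <- sims
  state$annotations <- lapply(sims, `[[`, "annotation")
  invisible(NULL)
}

stage_annotate <- function(config, out_dir, state) {
  p <- config$annotate %||% list()
  if (is.null(state$sims)) {
    fastas <- p$genomes %||% stopf("no simulated genomes and no 'genomes' given")
    missing <- fastas[!file.exists(fastas)]
    if (length(missing)) stopf("genome FASTA not found: '%s'", missing[1])
    catalog <- state$catalog %||% read_catalog(p$catalog %||%
      stopf("annotate stage needs a 'catalog' path"))
    state$catalog <- catalog
    ids <- sub("\\.[^.]+$", "", basename(fastas))
    anns <- lapply(seq_along(fastas), function(i)
      annotate_genome(fastas[i], catalog, annotation_config(), ids[i]))
    names(anns) <- ids
  } else {
    anns <- lapply(names(state$sims), function(id)
      annotate_genome(state$sims[[id]]$sequence, state$catalog,
                      annotation_config(), id))
    names(anns) <- names(state$sims)
  }
  for (id in names(anns))
    write_call_table(anns[[id]], file.path(out_dir, paste0(id, "_calls.tsv")))
  state$annotations <- anns
  invisible(NULL)
}

stage_pathways <- function(config, out_dir, state) {
  if (is.null(state$annotations)) stopf("pathways stage needs annotations")
  pws <- load_builtin_pathways()
  for (id in names(state$annotations)) {
    comp <- completeness(state$annotations[[id]], pws)
    write.table(comp[, c("eaa", "steps_present", "steps_total")],
                file.path(out_dir, paste0(id, "_eaa_completeness.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}

stage_synteny <- function(config, out_dir, state) {
  anns <- state$annotations
  if (is.null(anns) || length(anns) < 2L)
    stopf("synteny stage needs at least two annotations")
  p <- config$synteny %||% list()
  ref_id <- p$reference %||% names(anns)[1L]
  if (!ref_id %in% names(anns)) stopf("reference '%s' not among annotations", ref_id)
  anchor <- p$anchor_gene %||% sort(gene_order(anns[[ref_id]])$gene)[1L]
  cfg <- synteny_config(anchor_gene = anchor)
  inv_rows <- list(); frac <- list()
  for (id in setdiff(names(anns), ref_id)) {
    perm <- build_permutation(anns[[ref_id]], anns[[id]], cfg)
    blocks <- call_blocks(perm)
    inv <- call_inversions(blocks, perm)
    if (nrow(inv)) {
      inv$genes <- vapply(inv$genes, paste, "", collapse = ",")
      inv_rows[[id]] <- inv
    }
    frac[[id]] <- data.frame(ref = ref_id, qry = id,
                             synteny_fraction = synteny_fraction(blocks, perm))
    write_ribbon_json(perm, blocks, file.path(out_dir, paste0(id, "_ribbon.json")))
  }
  inv_all <- if (length(inv_rows)) do.call(rbind, inv_rows) else
    data.frame(n_genes = integer(), cds_count = integer(),
               query_span_nt = integer(), ref_id = character(),
               qry_id = character(), genes = character())
  write.table(inv_all, file.path(out_dir, "inversions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(do.call(rbind, frac), file.path(out_dir, "synteny_fraction.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

stage_matrix <- function(config, out_dir, state) {
  if (is.null(state$annotations)) stopf("matrix stage needs annotations")
  gene_cats <- if (!is.null(state$catalog))
    setNames(state$catalog$entries$category, state$catalog$entries$symbol)
  m <- gene_content_matrix(state$annotations, gene_categories = gene_cats)
  write_presence_matrix(m, file.path(out_dir, "gene_content_matrix.tsv"))
  invisible(NULL)
}
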