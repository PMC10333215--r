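test_that("six-frame circular ORF extraction matches the brute-force oracle", {
  # a lone gene embedded in a 60 nt circle
  circle <- paste0(strrep("C", 51), "ATGAAATAA")
  cfg <- annotation_config(min_orf_aa = 1)
  got <- extract_orfs(circle, cfg)
  expect_equal(nrow(got), 1)
  expect_identical(got$strand, "+")
  expect_equal(got$aa_length, 2)
  expect_identical(got$translation, "MK")
  want <- oracle_orfs(circle)
  expect_identical(orf_key(got), orf_key(want))

  # no start codon, no ORFs
  expect_equal(nrow(extract_orfs(strrep("CCT", 30), cfg)), 0)

  # ORF written across the origin: same ORF, end > genome length,
  # translation identical to the linearized rotation
  rotated <- rotate_seq(circle, 55)
  got_rot <- extract_orfs(rotated, cfg)
  expect_equal(nrow(got_rot), 1)
  expect_gt(got_rot$end, nchar(rotated))
  expect_identical(got_rot$translation, got$translation)
  expect_identical(orf_key(got_rot), orf_key(oracle_orfs(rotated)))

  # random AT-rich circles against the oracle, both strands
  for (seed in 1:4) {
    s <- with(list(), {
      set.seed(seed)
      paste(sample(c("A", "C", "G", "T"), 240, TRUE, c(.4, .1, .1, .4)),
            collapse = "")
    })
    got <- extract_orfs(s, annotation_config(min_orf_aa = 2))
    want <- oracle_orfs(s, min_aa = 2)
    expect_identical(orf_key(got), orf_key(want))
    expect_true(all((got$end - got$start) %% 3 == 0))
    expect_equal(got$aa_length, (got$end - got$start) / 3 - 1)
  }

  expect_error(extract_orfs("ATGANATAA"), "offset 4")
})

test_that("UGA is read through under the uga-trp translation table", {
  circle <- paste0(strrep("C", 45), "ATGAAATGAAAATAA")
  std <- extract_orfs(circle, annotation_config(min_orf_aa = 1))
  alt <- extract_orfs(circle, annotation_config(min_orf_aa = 1,
                                                translation_table = "uga-trp"))
  expect_equal(std$aa_length[std$strand == "+"][1], 2)
  expect_equal(alt$aa_length[alt$strand == "+"][1], 4)
  expect_identical(alt$translation[alt$strand == "+"][1], "MKWK")
})

test_that("homology assignment is best-hit with significance and demotion", {
  cat_ <- tiny_catalog(10, seed = 4)
  prot <- cat_$entries$protein
  mkorf <- function(tr, start) data.frame(
    start = start, end = start + 3L * (nchar(tr) + 1L), strand = "+",
    aa_length = nchar(tr), translation = tr, stringsAsFactors = FALSE)

  # verbatim translation is assigned to its gene
  orfs <- rbind(mkorf(prot[3], 0), mkorf(prot[7], 5000))
  got <- assign_homology(orfs, cat_, annotation_config())
  expect_identical(got$gene, cat_$entries$symbol[c(3, 7)])

  # a random ORF scores below the cutoff against every reference
  set.seed(1)
  rnd <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 80, TRUE),
               collapse = "")
  scores <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(prot), subject = Biostrings::AAString(rnd),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5, scoreOnly = TRUE)
  ev <- 0.041 * nchar(rnd) * sum(nchar(prot)) * exp(-0.267 * scores)
  expect_true(all(ev > 0.01))
  got2 <- assign_homology(mkorf(rnd, 0), cat_, annotation_config())
  expect_true(is.na(got2$gene))

  # two ORFs matching one gene: only the higher-scoring one is kept
  half <- substr(prot[3], 1, nchar(prot[3]) %/% 2)
  orfs3 <- rbind(mkorf(prot[3], 0), mkorf(half, 5000))
  got3 <- assign_homology(orfs3, cat_, annotation_config())
  expect_identical(got3$gene[1], cat_$entries$symbol[3])
  expect_true(is.na(got3$gene[2]))
  # ... unless duplicate reporting is enabled
  got4 <- assign_homology(orfs3, cat_, annotation_config(), keep_duplicates = TRUE)
  expect_identical(got4$gene, rep(cat_$entries$symbol[3], 2))

  # empty ORF list is not an error
  empty <- assign_homology(extract_orfs(strrep("CCT", 30)), cat_)
  expect_equal(nrow(empty), 0)
})

test_that("length-fraction classification uses strict printed thresholds", {
  fake_cat <- structure(list(entries = data.frame(
    symbol = "gX", category = "translation", aa_length = 1000L,
    protein = "", cds = "", stringsAsFactors = FALSE)), class = "gene_catalog")
  mk <- function(aa, gene = "gX", start = 0L) data.frame(
    start = start, end = start + 3L * (aa + 1L), strand = "+", aa_length = aa,
    translation = "", gene = gene, match_score = 100, evalue = 1e-10,
    stringsAsFactors = FALSE)
  a <- rbind(mk(851, start = 0L), mk(850, start = 4000L),
             mk(601, start = 8000L), mk(600, start = 12000L))
  ann <- classify_calls(a, fake_cat, annotation_config(), "t", 20000L)
  expect_identical(ann$calls$status,
                   c("functional", "putative_pseudogene",
                     "putative_pseudogene", "pseudogene"))
  expect_equal(ann$calls$length_fraction, c(0.851, 0.850, 0.601, 0.600))

  # unassigned ORFs: kept as hypothetical only when strictly over 300 nt
  mkh <- function(nt, start) data.frame(
    start = start, end = start + nt, strand = "+", aa_length = nt / 3 - 1,
    translation = "", gene = NA_character_, match_score = NA_real_,
    evalue = NA_real_, stringsAsFactors = FALSE)
  h <- rbind(mkh(312, 0L), mkh(300, 2000L), mkh(150, 4000L))
  ann2 <- classify_calls(h, fake_cat, annotation_config(), "t", 20000L)
  expect_equal(nrow(ann2$calls), 1)
  expect_identical(ann2$calls$status, "hypothetical")
  expect_true(is.na(ann2$calls$gene))
})

test_that("end-to-end annotation recovers planted truth exactly", {
  cat_ <- tiny_catalog(20, seed = 6)
  cfg0 <- tiny_sim_config(20, seed = 6)
  sim <- simulate_descendants(cat_, cfg0)[[1]]
  ann <- annotate_genome(sim$sequence, cat_, genome_id = "d0")
  got <- ann$calls[!is.na(ann$calls$gene), ]
  tg <- sim$truth$gene_table
  expect_setequal(got$gene, tg$gene)
  m <- match(got$gene, tg$gene)
  expect_true(all(got$status == "functional"))
  expect_equal(got$start, tg$start[m])
  expect_equal(got$end, tg$end[m])
  expect_identical(got$strand, tg$strand[m])

  # a genome with pseudogenized genes: statuses recovered from fractions
  cfg1 <- sim_config(n_genes = 20, pseudo_prob = 0.3,
                     pseudo_retained_fraction = c(0.4, 0.5),
                     inversion_size_genes = c(2, 6), seed = 8)
  sim1 <- simulate_descendants(cat_, cfg1)[[1]]
  expect_gt(sum(sim1$truth$gene_table$status == "pseudogene"), 0)
  ann1 <- annotate_genome(sim1$sequence, cat_, genome_id = "d1")
  got1 <- ann1$calls[!is.na(ann1$calls$gene), ]
  m1 <- match(got1$gene, sim1$truth$gene_table$gene)
  expect_setequal(got1$gene, sim1$truth$gene_table$gene)
  expect_identical(got1$status, sim1$truth$gene_table$status[m1])
  expect_equal(got1$length_fraction,
               sim1$truth$gene_table$retained_fraction[m1], tolerance = 1e-9)

  expect_error(annotate_genome(Biostrings::DNAStringSet(), cat_), "empty")
})

test_that("annotation is invariant under rotation and reverse complement", {
  cat_ <- tiny_catalog(15, seed = 11)
  sim <- simulate_descendants(cat_, tiny_sim_config(15, seed = 11))[[1]]
  base <- annotate_genome(sim$sequence, cat_, genome_id = "g")
  bg <- base$calls[!is.na(base$calls$gene), ]
  L <- base$genome_length

  k <- 1234L
  rot <- annotate_genome(rotate_seq(sim$sequence, k), cat_, genome_id = "g")
  rg <- rot$calls[!is.na(rot$calls$gene), ]
  m <- match(bg$gene, rg$gene)
  expect_false(anyNA(m))
  expect_identical(bg$status, rg$status[m])
  expect_identical(bg$strand, rg$strand[m])
  expect_true(all(((bg$start - 1 - k) %% L) == ((rg$start[m] - 1) %% L)))

  rc <- annotate_genome(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sim$sequence))), cat_, genome_id = "g")
  cg <- rc$calls[!is.na(rc$calls$gene), ]
  m2 <- match(bg$gene, cg$gene)
  expect_false(anyNA(m2))
  expect_identical(bg$status, cg$status[m2])
  expect_identical(ifelse(bg$strand == "+", "-", "+"), cg$strand[m2])
})

test_that("GFF3 output round-trips to an identical annotation", {
  cat_ <- tiny_catalog(12, seed = 13)
  sim <- simulate_descendants(cat_, tiny_sim_config(12, seed = 13))[[1]]
  path <- tempfile(fileext = ".gff3")
  write_annotation_gff3(sim$annotation, path)
  back <- read_annotation_gff3(path)
  expect_identical(back$calls$gene, sim$annotation$calls$gene)
  expect_equal(back$calls$start, sim$annotation$calls$start)
  expect_equal(back$calls$end, sim$annotation$calls$end)
  expect_identical(back$calls$strand, sim$annotation$calls$strand)
  expect_identical(back$calls$status, sim$annotation$calls$status)
  expect_equal(back$genome_length, sim$annotation$genome_length)
})
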