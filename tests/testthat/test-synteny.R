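test_that("permutation building normalizes rotation and orientation", {
  genes <- sprintf("g%02d", 1:8)
  ref <- manual_annotation("r", genes, rep(c("+", "-"), 4))
  # identical annotations give the identity permutation
  p <- build_permutation(ref, ref, synteny_config(anchor_gene = "g01"))
  expect_identical(p$order, 1:8)
  expect_identical(p$genes[1], "g01")

  # a reverse-complemented query normalizes back to the identity
  qcalls <- ref$calls
  L <- ref$genome_length
  rc <- data.frame(gene = rev(qcalls$gene), status = "functional",
                   length_fraction = 1,
                   start = rev(L - qcalls$end + 1), end = rev(L - qcalls$start + 1),
                   strand = rev(ifelse(qcalls$strand == "+", "-", "+")),
                   type = "CDS")
  qry <- circular_annotation("q", L, rc)
  p2 <- build_permutation(ref, qry, synteny_config(anchor_gene = "g01"))
  expect_identical(p2$order, 1:8)

  # rotating the query does not change the permutation
  rot <- qcalls
  k <- 3500L
  rot$start <- ((rot$start - 1 + k) %% L) + 1
  rot$end <- rot$start + 899L
  qry2 <- circular_annotation("q2", L, rot)
  p3 <- build_permutation(ref, qry2, synteny_config(anchor_gene = "g01"))
  expect_identical(p3$order, 1:8)

  # missing anchor falls back to the smallest shared symbol with a warning
  expect_warning(build_permutation(ref, ref, synteny_config(anchor_gene = "lipB")),
                 "falling back")
  # fewer than two shared genes is a comparison error
  other <- manual_annotation("x", c("h1", "h2", "g01"), "+")
  expect_error(build_permutation(ref, manual_annotation("y", c("h3", "h4"), "+")),
               "fewer than 2 shared genes")
  expect_error(suppressWarnings(build_permutation(ref, other)),
               "fewer than 2 shared genes")
})

test_that("block decomposition matches the brute-force finder", {
  # the textbook case: two inverted genes inside a collinear backbone,
  # read circularly (position 6 joins back to 1 across the cut)
  b <- call_blocks(signed_permutation(c(1, 2, -5, -4, -3, 6)))
  expect_same_blocks(b, oracle_blocks(c(1, 2, -5, -4, -3, 6)))
  orient <- vapply(b, `[[`, "", "orientation")
  expect_equal(sum(orient == "inverted"), 1)
  inv_block <- b[[which(orient == "inverted")]]
  expect_setequal(inv_block$ref_indices, 3:5)

  # identity: one forward block covering everything
  b1 <- call_blocks(signed_permutation(1:7))
  expect_length(b1, 1)
  expect_identical(b1[[1]]$orientation, "forward")
  expect_equal(synteny_fraction(b1, signed_permutation(1:7)), 1.0)

  # every gene a singleton: fraction 0
  v0 <- c(1L, -3L, 2L, -5L, 4L)
  expect_equal(synteny_fraction(call_blocks(signed_permutation(v0)),
                                signed_permutation(v0)),
               oracle_synteny_fraction(v0))

  # exhaustive at n <= 4, random at n = 5..8
  for (n in 2:4) {
    for (v in all_signed_perms(n)) {
      p <- signed_permutation(v)
      expect_same_blocks(call_blocks(p), oracle_blocks(v))
    }
  }
  set.seed(99)
  for (i in 1:120) {
    n <- sample(5:8, 1)
    v <- random_signed_perm(n)
    p <- signed_permutation(v)
    bb <- call_blocks(p)
    expect_same_blocks(bb, oracle_blocks(v))
    expect_equal(synteny_fraction(bb, p), oracle_synteny_fraction(v))
    # conservation: every shared gene lies in exactly one block
    expect_identical(sort(unlist(lapply(bb, `[[`, "positions"))), 1:n)
  }
})

test_that("inversion calls report member genes, CDS counts and spans", {
  # no inverted blocks -> empty call set
  genes <- sprintf("g%02d", 1:8)
  ref <- manual_annotation("r", genes, "+")
  p <- build_permutation(ref, ref, synteny_config(anchor_gene = "g01"))
  expect_equal(nrow(call_inversions(call_blocks(p), p)), 0)

  # planted 5-gene inversion in a simulated pair
  cat_ <- tiny_catalog(30, seed = 21)
  cfg0 <- tiny_sim_config(30, seed = 21)
  cfg1 <- sim_config(n_genes = 30, n_inversions = 1, inversion_size_genes = c(5, 5),
                     seed = 22)
  sims <- simulate_descendants(cat_, list(ref = cfg0, qry = cfg1))
  tr_inv <- Filter(function(e) e$kind == "invert", sims$qry$truth$events)[[1]]
  anchor <- setdiff(cat_$ancestral_order$symbol, tr_inv$genes)[1]
  perm <- build_permutation(sims$ref$annotation, sims$qry$annotation,
                            synteny_config(anchor_gene = anchor))
  inv <- call_inversions(call_blocks(perm), perm)
  expect_equal(nrow(inv), 1)
  expect_setequal(inv$genes[[1]], tr_inv$genes)
  expect_equal(inv$cds_count, 5)
  # span covers the members on the query circle
  tg <- sims$qry$truth$gene_table
  mem <- tg[tg$gene %in% tr_inv$genes, ]
  expect_equal(inv$query_span_nt, max(mem$end) - min(mem$start) + 1)
  expect_lt(inv$query_span_nt, sims$qry$annotation$genome_length)

  # rRNA markers order the comparison but are excluded from cds_count
  qc <- sims$qry$annotation$calls
  qc$type[qc$gene %in% tr_inv$genes[1]] <- "rRNA"
  qry_rrna <- circular_annotation("qr", sims$qry$annotation$genome_length, qc)
  perm2 <- build_permutation(sims$ref$annotation, qry_rrna,
                             synteny_config(anchor_gene = anchor))
  inv2 <- call_inversions(call_blocks(perm2), perm2)
  expect_equal(inv2$n_genes, 5)
  expect_equal(inv2$cds_count, 4)
})

test_that("an inversion spanning the query coordinate origin has a sane span", {
  genes <- sprintf("g%02d", 1:8)
  ref <- manual_annotation("r", genes, "+")
  # query: collinear except the ref segment (g05, g06) is inverted, and
  # the query is rotated so that inverted pair straddles the coordinate
  # origin: ..., g04, g06(-), [origin], g05(-), g07, ...
  L <- 8000L
  ord <- c("g05", "g07", "g08", "g01", "g02", "g03", "g04", "g06")
  strands <- ifelse(ord %in% c("g05", "g06"), "-", "+")
  start <- seq(1L, L - 900L, length.out = 8)
  qry <- circular_annotation("q", L, data.frame(
    gene = ord, status = "functional", length_fraction = 1,
    start = as.integer(start), end = as.integer(start) + 800L,
    strand = strands, type = "CDS"))
  perm <- build_permutation(ref, qry, synteny_config(anchor_gene = "g01"))
  inv <- call_inversions(call_blocks(perm), perm)
  expect_equal(nrow(inv), 1)
  expect_setequal(inv$genes[[1]], c("g05", "g06"))
  # the arc runs from g06's start near the end of the circle across the
  # origin to g05's end, so the span stays well below the genome length
  g5 <- qry$calls[qry$calls$gene == "g05", ]
  g6 <- qry$calls[qry$calls$gene == "g06", ]
  expect_equal(inv$query_span_nt, ((g5$end - g6$start) %% L) + 1)
  expect_lt(inv$query_span_nt, L)
})

test_that("synteny is invariant to genome representation and symmetric", {
  cat_ <- tiny_catalog(24, seed = 31)
  cfg0 <- tiny_sim_config(24, seed = 31)
  cfg1 <- sim_config(n_genes = 24, n_inversions = 2, inversion_size_genes = c(2, 5),
                     seed = 32)
  sims <- simulate_descendants(cat_, list(ref = cfg0, qry = cfg1), sequence = FALSE)
  invs <- Filter(function(e) e$kind == "invert", sims$qry$truth$events)
  anchor <- setdiff(cat_$ancestral_order$symbol,
                    unlist(lapply(invs, `[[`, "genes")))[1]
  cfgS <- synteny_config(anchor_gene = anchor)
  base <- call_inversions(call_blocks(
    build_permutation(sims$ref$annotation, sims$qry$annotation, cfgS)),
    build_permutation(sims$ref$annotation, sims$qry$annotation, cfgS))

  # reverse-complementing the query leaves the calls unchanged
  q <- sims$qry$annotation
  L <- q$genome_length
  rc_calls <- data.frame(gene = rev(q$calls$gene), status = rev(q$calls$status),
                         length_fraction = rev(q$calls$length_fraction),
                         start = rev(L - q$calls$end + 1),
                         end = rev(L - q$calls$start + 1),
                         strand = rev(ifelse(q$calls$strand == "+", "-", "+")),
                         type = "CDS")
  q_rc <- circular_annotation("qrc", L, rc_calls)
  flipped <- call_inversions(call_blocks(
    build_permutation(sims$ref$annotation, q_rc, cfgS)),
    build_permutation(sims$ref$annotation, q_rc, cfgS))
  key <- function(x) sort(vapply(x$genes, function(g) paste(sort(g), collapse = ","), ""))
  expect_identical(key(base), key(flipped))
  expect_identical(sort(base$cds_count), sort(flipped$cds_count))

  # swapping reference and query preserves inverted-block membership
  swapped <- call_inversions(call_blocks(
    build_permutation(sims$qry$annotation, sims$ref$annotation, cfgS)),
    build_permutation(sims$qry$annotation, sims$ref$annotation, cfgS))
  expect_identical(key(base), key(swapped))
})

test_that("parsimony event mapping matches exhaustive minimal-change counts", {
  # forced placements on a four-tip tree
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  m <- matrix(c(1, 1, 0, 0), 4, 1, dimnames = list(c("A", "B", "C", "D"), "inv"))
  ep <- map_events_on_tree(m, tr)
  expect_equal(ep$total, 1)
  expect_equal(nrow(ep$events), 1)
  expect_false(ep$events$child %in% 1:4)  # on the (A,B) stem, not a tip branch

  m2 <- matrix(c(1, 0, 0, 0), 4, 1, dimnames = list(c("A", "B", "C", "D"), "inv"))
  ep2 <- map_events_on_tree(m2, tr)
  expect_equal(ep2$total, 1)
  expect_identical(ep2$events$branch, "A")

  # random binary characters on random trees vs. exhaustive enumeration
  set.seed(7)
  for (i in 1:60) {
    n <- sample(4:6, 1)
    tree <- ape::rtree(n, br = NULL)
    states <- setNames(sample(0:1, n, replace = TRUE), tree$tip.label)
    m <- matrix(states, ncol = 1, dimnames = list(names(states), "c1"))
    ep <- map_events_on_tree(m, tree)
    expect_equal(ep$total, oracle_parsimony(tree, states))
    # the resolved placement realizes the parsimony score
    expect_equal(nrow(ep$events), ep$total)
  }

  # cross-check against phangorn's Fitch implementation
  skip_if_not_installed("phangorn")
  set.seed(8)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    tree <- ape::rtree(n, br = NULL)
    states <- setNames(sample(0:1, n, replace = TRUE), tree$tip.label)
    dat <- phangorn::phyDat(matrix(states, ncol = 1,
                                   dimnames = list(names(states), NULL)),
                            type = "USER", levels = 0:1)
    expect_equal(map_events_on_tree(matrix(states, ncol = 1,
                                           dimnames = list(names(states), "c")),
                                    tree)$total,
                 as.integer(phangorn::fitch(tree, dat)))
  }

  # input validation
  expect_error(map_events_on_tree(
    matrix(1, 1, 1, dimnames = list("Z", "c")), tr), "absent from the tree")
  expect_error(map_events_on_tree(
    matrix(c(1, 1, 0, 2), 4, 1, dimnames = list(c("A", "B", "C", "D"), "c")), tr),
    "binary")
})

test_that("the published gene-order arrangements map to one ancestral and five recent events", {
  chars <- read.delim(system.file("extdata", "sulcia_gene_order_characters.tsv",
                                  package = "endosym"))
  tree <- system.file("extdata", "auchenorrhyncha_host_tree.nwk", package = "endosym")
  ep <- map_events_on_tree(chars, tree)
  expect_equal(ep$total, 6)
  expect_equal(unname(ep$scores["fulgoromorpha_arrangement"]), 1)
  # the deep event sits on an internal branch (a clade stem), the other
  # five are more recent
  deep <- ep$events[ep$events$character == "fulgoromorpha_arrangement", ]
  expect_match(deep$branch, "^node")
  recent <- ep$events[ep$events$character != "fulgoromorpha_arrangement", ]
  expect_equal(nrow(recent), 5)
})
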