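test_that("homology edges follow the shared k-mer criterion", {
  pep <- tibble::tibble(
    clone_id = c("a", "b", "c", "d"),
    aa_seq = c("MKVLAAGHKLMNPQRSTVWY",
               "MKVLAAGHKLMNPQRSTVWY",                 # identical to a
               paste0("CCCCCCC", "WYWYWYWYWYWYW"),     # shares nothing
               paste0("DDDDDD", "KVLAAGH", "EEEEEE"))) # shares a 7-mer with a
  g <- build_homology_graph(pep, k = 7)
  expect_true(igraph::are_adjacent(g, "a", "b"))
  expect_true(igraph::are_adjacent(g, "a", "d"))
  expect_false(igraph::are_adjacent(g, "a", "c"))
  expect_true(igraph::is_simple(g))
  expect_error(build_homology_graph(
    tibble::tibble(clone_id = c("a", "a"), aa_seq = c("MKV", "MKV"))),
    "duplicate")
})

test_that("k-mer index edges equal the exhaustive pairwise oracle", {
  set.seed(50)
  pep <- tibble::tibble(clone_id = sprintf("p%02d", 1:60),
                        aa_seq = replicate(60, random_peptide(56)))
  # salt in some guaranteed homology
  pep$aa_seq[5] <- paste0(substr(pep$aa_seq[1], 10, 30), random_peptide(35))
  pep$aa_seq[6] <- paste0(random_peptide(30), substr(pep$aa_seq[2], 1, 12))
  g <- build_homology_graph(pep, k = 7)
  for (i in 1:59) for (j in (i + 1):60) {
    expect_equal(
      igraph::are_adjacent(g, pep$clone_id[i], pep$clone_id[j]),
      brute_share_kmer(pep$aa_seq[i], pep$aa_seq[j], 7),
      info = paste(i, j))
  }
})

test_that("greedy breadth handles canonical small graphs", {
  pep <- tibble::tibble(
    clone_id = c("a", "b", "c"),
    aa_seq = c(paste0(strrep("A", 10), strrep("W", 46)),       # a ~ b
               paste0(strrep("W", 10), strrep("C", 46)),       # b ~ a,c
               paste0(strrep("C", 10), strrep("D", 46))))      # c ~ b
  g <- build_homology_graph(pep, k = 7)
  expect_true(igraph::are_adjacent(g, "a", "b"))
  expect_true(igraph::are_adjacent(g, "b", "c"))
  expect_false(igraph::are_adjacent(g, "a", "c"))
  b <- breadth(g, c("a", "b", "c"))
  expect_equal(b$members, c("a", "c"))
  expect_equal(b$breadth, 2)
  # triangle collapses to breadth 1
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("x", "y", "z")
  expect_equal(breadth(tri, c("x", "y", "z"))$breadth, 1)
  # isolated reactive nodes: breadth equals the set size
  iso <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(iso)$name <- letters[1:4]
  expect_equal(breadth(iso, letters[1:4])$breadth, 4)
  expect_equal(breadth(iso, character(0))$breadth, 0)
})

test_that("breadth results are independent, maximal and bounded", {
  set.seed(60)
  for (rep in 1:50) {
    g <- random_named_graph(sample(5:18, 1), runif(1, 0.05, 0.5))
    reactive <- sample(igraph::V(g)$name,
                       sample(seq_len(igraph::vcount(g)), 1))
    b <- breadth(g, reactive)
    # independence: no edge inside the member set
    if (b$breadth > 1) {
      sub <- igraph::induced_subgraph(g, b$members)
      expect_equal(igraph::ecount(sub), 0)
    }
    # maximality: every excluded reactive node touches a member
    excluded <- setdiff(reactive, b$members)
    for (v in excluded) {
      nb <- igraph::V(g)$name[as.integer(
        igraph::neighbors(g, v))]
      expect_true(any(b$members %in% nb))
    }
    # bounds: breadth <= |reactive|, equality iff independent
    expect_lte(b$breadth, length(reactive))
    sub_r <- igraph::induced_subgraph(g, reactive)
    if (igraph::ecount(sub_r) == 0) {
      expect_equal(b$breadth, length(reactive))
    }
    # greedy never exceeds the exact maximum independent set
    exact <- igraph::independence_number(sub_r)
    expect_lte(b$breadth, exact)
  }
})

test_that("epitope clusters are sorted components with singletons aside", {
  g <- igraph::make_empty_graph(6, directed = FALSE)
  igraph::V(g)$name <- letters[1:6]
  g <- igraph::add_edges(g, c("a", "b", "b", "c", "a", "c", "d", "e"))
  cl <- epitope_clusters(g, letters[1:6])
  expect_equal(cl$components, list(c("a", "b", "c"), c("d", "e")))
  expect_equal(cl$singletons, "f")
  expect_equal(epitope_clusters(g, character(0))$components, list())
})

test_that("the simulated discriminator family forms one 3-node component", {
  coh <- small_cohort(seed = 61)
  pep <- coh$annotation[, c("clone_id", "aa_seq")]
  g <- build_homology_graph(pep, k = 7)
  cl <- epitope_clusters(g, coh$epitope_ids)
  expect_equal(length(cl$components), 1)
  expect_setequal(cl$components[[1]], coh$epitope_ids)
})

test_that("consensus motifs anchor on the shared k-mer", {
  pep <- tibble::tibble(clone_id = c("a", "b"),
                        aa_seq = c("MKVLAAGHKLMNPQRSTVWY",
                                   "MKVLAAGHKLMNPQRSTVWY"))
  pfm <- consensus_motif(pep, anchor_k = 7, flank = 0)
  expect_true(all(apply(pfm, 2, max) == 1))
  expect_equal(colSums(pfm), rep(1, ncol(pfm)), ignore_attr = TRUE)
  # one differing anchored column splits 0.5/0.5 (anchor tie-break is
  # lexicographic, so KLMNPQR wins over the W-containing k-mers)
  pep2 <- tibble::tibble(clone_id = c("a", "b"),
                         aa_seq = c("WWWWKLMNPQRWWWA",
                                    "WWWWKLMNPQRWWWC"))
  pfm2 <- consensus_motif(pep2, anchor_k = 7, flank = 4)
  last <- pfm2[, ncol(pfm2)]
  expect_equal(sort(unname(last[last > 0])), c(0.5, 0.5))
  # planted motif among random flanks is recovered as the anchor
  set.seed(70)
  motif <- "WCDEFGH"
  fam <- tibble::tibble(
    clone_id = sprintf("f%d", 1:5),
    aa_seq = vapply(1:5, function(i)
      paste0(random_peptide(20), motif, random_peptide(20)), character(1)))
  pfm3 <- consensus_motif(fam, anchor_k = 7, flank = 2)
  expect_equal(attr(pfm3, "anchor"), motif)
  expect_equal(attr(pfm3, "n_anchored"), 5)
  # no universally shared k-mer: largest anchorable subset with a warning
  mixed <- dplyr::bind_rows(fam,
    tibble::tibble(clone_id = "odd", aa_seq = strrep("Y", 30)))
  expect_warning(pfm4 <- consensus_motif(mixed, anchor_k = 7), "anchoring")
  expect_equal(attr(pfm4, "n_anchored"), 5)
})
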