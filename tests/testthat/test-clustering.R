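# Similarity graph, Markov clustering and cluster categorisation.

test_that("local alignment scores match the brute-force DP oracle", {
  # self alignment equals the sum of diagonal substitution scores
  s <- "MKVLWAALLVTFLAGCQA"
  b62 <- orphanevo:::blosum62()
  expect_equal(smith_waterman(s, s),
               sum(diag(b62)[strsplit(s, "")[[1]]]))

  expect_equal(
    smith_waterman("TGTTACGG", "GGTTGACTA", match = 3, mismatch = -3,
                   gap_open = 0, gap_extend = 2),
    sw_oracle("TGTTACGG", "GGTTGACTA", 3, -3, 2))

  withr::local_seed(101)
  for (i in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(5:15, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(5:15, 1), TRUE), collapse = "")
    expect_equal(
      smith_waterman(a, b, match = 2, mismatch = -1, gap_open = 0, gap_extend = 1),
      sw_oracle(a, b, 2, -1, 1), label = paste(a, b))
  }

  # no positively scoring residue pair: local-alignment floor of zero
  expect_equal(smith_waterman("AAAA", "TTTT", match = 1, mismatch = -2,
                              gap_open = 0, gap_extend = 1), 0)
  expect_error(smith_waterman("MKV", "MK1"), "unknown residue")
})

test_that("graph construction separates planted families", {
  # two planted families: high intra-family identity, unrelated otherwise
  fam1 <- simulate_codon_msa(simulate_tree(3, 0.3, seed = 1), 0.2, 2,
                             n_codons = 80, seed = 21)
  fam2 <- simulate_codon_msa(simulate_tree(3, 0.3, seed = 2), 0.2, 2,
                             n_codons = 90, seed = 22)
  prots <- tibble::tibble(
    id = c(paste0("f1_", fam1$id), paste0("f2_", fam2$id)),
    seq = sub("\\*$", "", translate_cds(c(fam1$seq, fam2$seq))))
  g <- build_graph(prots, min_normalized_score = 0.3)
  cl <- markov_cluster(g)
  expect_equal(nrow(cl), 2)
  got <- lapply(cl$members, sort)
  expect_true(list(sort(prots$id[1:3])) %in% got)
  expect_true(list(sort(prots$id[4:6])) %in% got)

  # threshold above 1: no edges possible
  g_empty <- build_graph(prots, min_normalized_score = 1.01)
  expect_equal(nrow(g_empty$edges), 0)
})

test_that("Markov clustering handles cliques, isolates and the barbell", {
  mk_graph <- function(nodes, edge_df) {
    structure(list(nodes = nodes, edges = edge_df), class = "similarity_graph")
  }
  # two disjoint triangles plus an isolated node
  e <- tibble::tibble(
    from = c("a", "a", "b", "d", "d", "e"),
    to = c("b", "c", "c", "e", "f", "f"),
    weight = 1)
  cl <- markov_cluster(mk_graph(c("a", "b", "c", "d", "e", "f", "iso"), e))
  parts <- lapply(cl$members, sort)
  expect_equal(length(parts), 3)
  expect_true(list(c("a", "b", "c")) %in% parts)
  expect_true(list("iso") %in% parts)

  # 5-node barbell: clique {A,B,C} - bridge - clique {D,E}
  eb <- tibble::tibble(
    from = c("A", "A", "B", "C", "D"),
    to = c("B", "C", "C", "D", "E"),
    weight = 1)
  nodes <- c("A", "B", "C", "D", "E")
  clb <- markov_cluster(mk_graph(nodes, eb), inflation = 2)
  # independent dense-matrix oracle
  adj <- matrix(0, 5, 5, dimnames = list(nodes, nodes))
  adj[cbind(eb$from, eb$to)] <- 1; adj <- adj + t(adj)
  oracle_comp <- mcl_oracle(adj)
  got_comp <- integer(5); names(got_comp) <- nodes
  for (i in seq_len(nrow(clb))) got_comp[clb$members[[i]]] <- i
  expect_equal(adjusted_rand_index(got_comp, oracle_comp), 1)
  expect_equal(sort(unlist(clb$members)), nodes)   # a partition
  expect_true(list(c("A", "B", "C")) %in% lapply(clb$members, sort))
  expect_true(list(c("D", "E")) %in% lapply(clb$members, sort))
})

test_that("cluster categorisation applies the hybrid and species rules", {
  labels <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g4", "g5"),
                           label = c("orphan", "conserved", "orphan",
                                     "conserved", "conserved"))
  labels$orphan <- labels$label == "orphan"
  clusters <- tibble::tibble(
    cluster_id = c("c1", "c2", "c3", "c4"),
    members = list(
      c("ppa|g1", "pex|x1"),                       # orphan ortholog pair
      c("ppa|g1", "ppa|g2", "pex|x2"),             # hybrid -> excluded
      c("ppa|g4", "ppa|g5", "ppa|g2", "pex|x3"),   # ortholog + paralog
      c("pex|x4", "pex|x5")))                      # sister-specific
  res <- categorize_clusters(clusters, labels)
  rec <- res$records
  expect_equal(rec$category, c("orphan", "hybrid", "conserved", "pex_specific"))
  expect_equal(rec$in_ortholog, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(rec$in_paralog, c(FALSE, FALSE, TRUE, FALSE))
  expect_setequal(res$exclusions$cluster_id, c("c2", "c4"))
  expect_setequal(rec$paralog_members[[3]], c("ppa|g4", "ppa|g5", "ppa|g2"))
  bad <- tibble::tibble(cluster_id = "cx", members = list("ppa|unknown"))
  expect_error(categorize_clusters(bad, labels), "unlabeled gene: unknown")
})

test_that("clade pairs implant single differences exactly", {
  gene <- tibble::tibble(
    gene_id = "g1", contig = "ctg", strand = "+",
    cds = "ATGAAACCCGGG", valid = TRUE,
    exons = list(tibble::tibble(start = 101, end = 112)))
  v_syn <- tibble::tibble(contig = "ctg", pos = 106L, ref = "A", alt = "G")
  none <- v_syn[0, ]
  cp <- build_clade_pairs(gene, none, v_syn)
  expect_identical(cp$seq_a1, gene$cds)
  expect_equal(cp$n_diff, 1)
  expect_identical(substr(cp$seq_a2, 6, 6), "G")   # AAA -> AAG, synonymous
  cp0 <- build_clade_pairs(gene, none, none)
  expect_identical(cp0$seq_a1, cp0$seq_a2)
})
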