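# Evidence integration: dataset flags, Venn regions, classification,
# candidates, feature statistics.

mk_selection <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r)
    tibble::tibble(cluster_id = r[[1]], dataset = r[[2]],
                   omega = r[[3]], q_value = r[[4]],
                   lnl_ha = 0, lnl_h0 = 0, statistic = 0,
                   p_value = r[[4]], flags = "")))
}

test_that("genes inherit cluster omega/q and the liberal/conservative rules", {
  sel <- mk_selection(
    list("c1", "ortholog", 0.55, 0.2),
    list("c2", "cladeAB", 1.3, 0.5),
    list("c3", "ortholog", 0.9, 0.01),
    list("c4", "paralog", 0.7, 0.5))
  mem <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g3"),
    dataset = c("ortholog", "cladeAB", "ortholog", "paralog"),
    cluster_id = c("c1", "c2", "c3", "c4"))
  ev <- gene_selection_evidence(sel, mem)
  g1 <- ev[ev$gene_id == "g1", ]
  expect_true(g1$liberal)            # 0.55 < 0.6 in one dataset
  expect_false(g1$conservative)      # no dataset with omega < 1 and q < 0.05
  g2 <- ev[ev$gene_id == "g2", ]
  expect_false(g2$liberal)           # 0.9 >= 0.6
  expect_true(g2$conservative)       # 0.9 < 1 with q = 0.01
  expect_equal(g1$omega_min, 0.55)
  expect_equal(g1$n_datasets, 2)

  dup <- tibble::tibble(gene_id = c("g1", "g1"),
                        dataset = c("ortholog", "ortholog"),
                        cluster_id = c("c1", "c3"))
  expect_error(gene_selection_evidence(sel, dup), "two clusters")
})

test_that("Venn regions partition the union and match enumeration", {
  counts <- function(v) stats::setNames(v$count, v$region)
  disj <- venn3(list(A = c("1", "2"), B = c("3"), C = c("4", "5")))
  cd <- counts(disj)
  expect_equal(unname(cd[c("A", "B", "C")]), c(2, 1, 2))
  expect_equal(sum(cd), 5)
  expect_equal(unname(cd["A&B&C"]), 0)

  same <- venn3(list(A = c("x", "y"), B = c("x", "y"), C = c("x", "y")))
  cs <- counts(same)
  expect_equal(unname(cs["A&B&C"]), 2)
  expect_equal(sum(cs), 2)

  abc <- venn3(list(A = c("1", "2"), B = c("2", "3"), C = c("3")))
  ca <- counts(abc)
  expect_equal(unname(ca["A"]), 1)
  expect_equal(unname(ca["A&B"]), 1)
  expect_equal(unname(ca["B&C"]), 1)
  expect_equal(sum(ca), 3)
  # region sums reproduce the input set sizes
  expect_equal(unname(ca["A"] + ca["A&B"] + ca["A&C"] + ca["A&B&C"]), 2)
})

test_that("classification follows the evidence precedence", {
  base <- tibble::tibble(
    gene_id = paste0("g", 1:6),
    orphan = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    expressed = c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE),
    robust = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE),
    liberal = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    conservative = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
    peptide_hit = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  cl <- classify_genes(base)
  # orphan with significant selection but no expression: still coding
  expect_equal(cl$class[1], "coding_orphan")
  # robust expression, no strong selection: non-coding-RNA candidate
  expect_equal(cl$class[2], "ncrna_candidate")
  # never expressed, no strong selection: artifact or pseudogene
  expect_equal(cl$class[3], "artifact_or_pseudogene")
  # weak expression only: unassigned
  expect_equal(cl$class[4], "unassigned")
  expect_equal(cl$class[5], "conserved")
  # robust expression but liberal selection signal: not an ncRNA candidate
  expect_equal(cl$class[6], "unassigned")
  expect_false(any(is.na(cl$class)))   # classes exhaustive
})

test_that("validation candidates require all four intersecting criteria", {
  base <- tibble::tibble(
    gene_id = paste0("g", 1:4),
    orphan = TRUE, conservative = TRUE,
    zero_everywhere = c(TRUE, TRUE, FALSE, TRUE),
    n_liberal_datasets = c(2, 2, 2, 1),
    n_exons = c(3, 2, 3, 5))
  got <- select_validation_candidates(base)
  expect_identical(got, "g1")   # g2: only 2 exons; g3: expressed; g4: 1 dataset
})

test_that("contig percentiles rank by decreasing length with min-tie rank", {
  contigs <- tibble::tibble(contig = paste0("c", 1:100),
                            length = seq(1000, 10, length.out = 100))
  gm <- tibble::tibble(gene_id = c("gBig", "gSmall"),
                       contig = c("c1", "c100"))
  pct <- contig_percentile(contigs, gm)
  expect_equal(pct$contig_percentile, c(1, 100))

  ties <- tibble::tibble(contig = c("a", "b", "c", "d"),
                         length = c(100, 50, 50, 10))
  gt <- tibble::tibble(gene_id = c("g1", "g2", "g3"), contig = c("b", "c", "d"))
  pt <- contig_percentile(ties, gt)
  expect_equal(pt$contig_percentile, c(50, 50, 100))
  expect_error(contig_percentile(ties, tibble::tibble(gene_id = "g", contig = "zz")),
               "unknown contig")
})

test_that("feature statistics use exact rank-sum tests on small samples", {
  ev <- tibble::tibble(
    class = rep(c("x", "y"), each = 3),
    transcript_length = c(1, 2, 3, 4, 5, 6),
    n_exons = c(1, 1, 2, 2, 3, 3),
    gc = runif(6), contig_percentile = runif(6))
  fs <- feature_stats(ev)
  p_len <- fs$tests$p_value[fs$tests$feature == "transcript_length"]
  expect_equal(p_len, 0.1)   # exact two-sided rank-sum for (1,2,3) vs (4,5,6)
  expect_equal(nrow(fs$summary), 2 * 4)

  # a class duplicated into two groups: p = 1
  dup <- tibble::tibble(class = rep(c("x", "y"), each = 3),
                        transcript_length = rep(c(10, 20, 30), 2),
                        n_exons = 1, gc = 0.5, contig_percentile = 1)
  fd <- feature_stats(dup, features = "transcript_length")
  expect_equal(fd$tests$p_value, 1)
})

test_that("cumulative omega curves hit 0 and 1 at the extremes", {
  sel <- tibble::tibble(
    cluster_id = paste0("c", 1:5), dataset = "ortholog",
    category = "orphan", omega = c(0.1, 0.3, 0.5, 0.8, 1.4))
  cur <- omega_cumulative(sel, thresholds = c(0, 0.4, 2))
  expect_equal(cur$proportion[cur$threshold == 0], 0)
  expect_equal(cur$proportion[cur$threshold == 2], 1)
  expect_equal(cur$proportion[cur$threshold == 0.4], 0.4)
})
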