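# The synthetic dataset generator: label conservation, file round trips,
# determinism, and the planted marginal contrasts.

test_that("generated files parse back consistently with the in-memory truth", {
  td <- small_test_dataset()
  ds <- td$ds; dir <- td$dir

  labels <- read_labels(file.path(dir, "labels.tsv"))
  expect_equal(sum(labels$orphan), ds$config$n_orphan)
  expect_equal(sum(!labels$orphan), ds$config$n_conserved)

  genes <- read_gff3(file.path(dir, "genes.gff3"), file.path(dir, "genome.fasta"))
  expect_setequal(genes$gene_id, ds$genes$gene_id)
  m <- dplyr::inner_join(ds$genes, genes, by = "gene_id", suffix = c(".t", ".p"))
  expect_identical(m$cds.t, m$cds.p)
  expect_identical(m$protein.t, m$protein.p)
  expect_equal(m$n_exons.t, m$n_exons.p)
  expect_true(all(genes$valid))

  # every gene appears in exactly one truth record and one true cluster
  expect_setequal(ds$truth$gene_id, ds$genes$gene_id)
  expect_false(anyDuplicated(ds$truth$gene_id) > 0)
  members <- unlist(ds$clusters_true$members)
  ppa_members <- sub("^ppa\\|", "", members[startsWith(members, "ppa|")])
  expect_setequal(ppa_members, ds$genes$gene_id)
  expect_false(anyDuplicated(ppa_members) > 0)
})

test_that("identical configurations give byte-identical outputs", {
  cfg <- sim_config(n_conserved = 8, n_orphan = 6, n_hybrid = 1,
                    n_pex_specific = 1, n_contigs = 4, seed = 77L)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  generate_dataset(cfg, out_dir = d1)
  generate_dataset(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
})

test_that("class-conditional settings shape the emitted evidence", {
  cfg <- sim_config(n_conserved = 10, n_orphan = 0, n_hybrid = 0,
                    n_pex_specific = 0, n_contigs = 3, seed = 5L,
                    peptide_coverage = c(conserved = 1, coding = 0,
                                         ncrna = 0, artifact = 0),
                    expressed_fraction = c(conserved = 0, coding = 0,
                                           ncrna = 0, artifact = 0))
  ds <- generate_dataset(cfg)
  expect_false(any(ds$labels$label == "orphan"))
  # expressed_fraction 0: expression matrix all zero
  expect_true(all(as.matrix(ds$expression[, -1]) == 0))
  # full peptide coverage: every gene has an exact-substring peptide
  real <- ds$peptides[!ds$peptides$decoy, ]
  hit <- vapply(ds$genes$protein, function(pr)
    any(vapply(real$seq, function(p) grepl(p, pr, fixed = TRUE), logical(1))),
    logical(1))
  expect_true(all(hit))
  # decoys never match any protein
  dec <- ds$peptides[ds$peptides$decoy, ]
  miss <- vapply(dec$seq, function(p)
    any(grepl(p, ds$genes$protein, fixed = TRUE)), logical(1))
  expect_false(any(miss))
})

test_that("orphans are shorter with fewer exons; clade divergence is on target", {
  td <- small_test_dataset()
  ds <- td$ds
  expect_lt(median(ds$genes$transcript_length[ds$genes$orphan]),
            median(ds$genes$transcript_length[!ds$genes$orphan]))
  expect_lt(mean(ds$genes$n_exons[ds$genes$orphan]),
            mean(ds$genes$n_exons[!ds$genes$orphan]))

  genes <- read_gff3(file.path(td$dir, "genes.gff3"),
                     file.path(td$dir, "genome.fasta"))
  cp <- build_clade_pairs(genes,
                          read_variants(file.path(td$dir, "variants_A1.tsv")),
                          read_variants(file.path(td$dir, "variants_A2.tsv")))
  expect_equal(nrow(cp), nrow(genes))   # one pair per gene, singletons included
  div <- sum(cp$n_diff) / sum(nchar(cp$seq_a1))
  expect_gt(div, 0.006); expect_lt(div, 0.014)  # ~1 % with sampling noise
})

test_that("interspecies divergence in ortholog pairs is near the target", {
  td <- small_test_dataset()
  ds <- td$ds
  pairs <- ds$clusters_true[vapply(ds$clusters_true$members, function(m)
    length(m) == 2 && sum(startsWith(m, "ppa|")) == 1 &&
      sum(startsWith(m, "pex|")) == 1, logical(1)), ]
  cds_ppa <- stats::setNames(ds$genes$cds, ds$genes$gene_id)
  cds_pex <- stats::setNames(ds$pex_genes$cds, ds$pex_genes$gene_id)
  diffs <- lens <- 0
  for (i in seq_len(nrow(pairs))) {
    m <- pairs$members[[i]]
    a <- cds_ppa[[sub("^ppa\\|", "", m[startsWith(m, "ppa|")])]]
    b <- cds_pex[[sub("^pex\\|", "", m[startsWith(m, "pex|")])]]
    a <- substr(a, 1, nchar(a) - 3); b <- substr(b, 1, nchar(b) - 3)
    diffs <- diffs + sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    lens <- lens + nchar(a)
  }
  # ~10 % expected substitutions/site, observed slightly lower (multiple hits)
  expect_gt(diffs / lens, 0.055); expect_lt(diffs / lens, 0.12)
})
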