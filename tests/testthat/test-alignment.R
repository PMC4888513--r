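# Protein alignment, back-translation, length filter and variant
# implantation.

test_that("pairwise global alignment matches the brute-force DP oracle", {
  simple <- function(alpha) {
    m <- matrix(-1, length(alpha), length(alpha), dimnames = list(alpha, alpha))
    diag(m) <- 1
    m
  }
  a <- "GATTACA"; b <- "GCATGCT"
  msa <- progressive_align(tibble::tibble(id = c("a", "b"), seq = c(a, b)),
                           substitution = simple(c("A", "C", "G", "T")),
                           gap_open = 0, gap_extend = 1)
  score <- function(r1, r2) {
    x <- strsplit(r1, "")[[1]]; y <- strsplit(r2, "")[[1]]
    sum(ifelse(x == "-" | y == "-", -1, ifelse(x == y, 1, -1)))
  }
  expect_equal(score(msa$seq[1], msa$seq[2]), nw_oracle(a, b, 1, -1, 1))

  withr::local_seed(7)
  for (i in 1:10) {
    x <- paste(sample(c("A", "C", "G", "T"), sample(4:10, 1), TRUE), collapse = "")
    y <- paste(sample(c("A", "C", "G", "T"), sample(4:10, 1), TRUE), collapse = "")
    m <- progressive_align(tibble::tibble(id = c("x", "y"), seq = c(x, y)),
                           substitution = simple(c("A", "C", "G", "T")),
                           gap_open = 0, gap_extend = 1)
    expect_equal(score(m$seq[1], m$seq[2]), nw_oracle(x, y, 1, -1, 1),
                 label = paste(x, y))
  }
})

test_that("multiple alignment keeps residue order and pads prefixes", {
  idseq <- tibble::tibble(id = c("a", "b", "c"),
                          seq = rep("MKVLWAALLV", 3))
  m <- progressive_align(idseq)
  expect_identical(unique(m$seq), "MKVLWAALLV")   # identical: gap-free

  pre <- tibble::tibble(id = c("a", "b", "c"),
                        seq = c("MKVLWAALLVTF", "MKVLWAALLVTF", "MKVLWAA"))
  mp <- progressive_align(pre)
  row_c <- mp$seq[mp$id == "c"]
  expect_identical(gsub("-", "", row_c), "MKVLWAA")
  expect_match(row_c, "-----$")                   # prefix padded with gaps
  # columns preserve per-sequence residue order
  for (i in 1:3) {
    expect_identical(gsub("-", "", mp$seq[i]), pre$seq[pre$id == mp$id[i]])
  }
  expect_error(progressive_align(tibble::tibble(id = "a", seq = "MK")), "2")
})

test_that("back-translation maps residue columns to codons and gaps to ---", {
  msa <- tibble::tibble(id = c("s1", "s2"), seq = c("MKR-", "M-KC"))
  cds <- c(s1 = "ATGAAAAGA", s2 = "ATGAAATGC")
  aln <- backtranslate(msa, cds)
  expect_identical(aln$seq[1], "ATGAAAAGA---")
  expect_identical(aln$seq[2], "ATG---AAATGC")

  # "M-K" with CDS ATGAAA: gap becomes ---
  one <- backtranslate(tibble::tibble(id = "x", seq = "M-K"),
                       c(x = "ATGAAA"))
  expect_identical(one$seq, "ATG---AAA")

  # terminal stops stripped; internal stops and mismatches rejected
  ok <- backtranslate(tibble::tibble(id = "x", seq = "MK"), c(x = "ATGAAATAA"))
  expect_identical(ok$seq, "ATGAAA")
  expect_error(backtranslate(tibble::tibble(id = "x", seq = "MXK"),
                             c(x = "ATGTAAAAA")), class = "orphanevo_backtranslate_error")
  expect_error(backtranslate(tibble::tibble(id = "x", seq = "MK"),
                             c(x = "ATGAAAA")), class = "orphanevo_backtranslate_error")
  expect_error(backtranslate(tibble::tibble(id = "x", seq = "MM"),
                             c(x = "ATGAAA")), class = "orphanevo_backtranslate_error")
})

test_that("the minimum-length filter cuts strictly below the threshold", {
  aln150 <- tibble::tibble(id = c("a", "b"), seq = rep(strrep("ATG", 50), 2))
  aln149 <- tibble::tibble(id = c("a", "b"),
                           seq = rep(paste0(strrep("ATG", 49), "AT"), 2))
  expect_true(filter_min_length(aln150, 150))
  expect_false(filter_min_length(aln149, 150))
})

test_that("variant implantation honours strand and validates alleles", {
  plus <- tibble::tibble(
    gene_id = "gp", contig = "c1", strand = "+", cds = "ATGAAACCC",
    exons = list(tibble::tibble(start = 11, end = 19)))
  minus <- tibble::tibble(
    gene_id = "gm", contig = "c1", strand = "-", cds = "ATGAAACCC",
    exons = list(tibble::tibble(start = 11, end = 19)))
  expect_identical(implant_variants(plus, tibble::tibble(
    contig = character(), pos = integer(), ref = character(),
    alt = character())), "ATGAAACCC")

  v <- tibble::tibble(contig = "c1", pos = 12L, ref = "T", alt = "C")
  out <- implant_variants(plus, v)
  expect_equal(sum(strsplit(out, "")[[1]] != strsplit("ATGAAACCC", "")[[1]]), 1)
  expect_identical(substr(out, 2, 2), "C")

  # minus strand: CDS position 1 is the rightmost genome base; genome-strand
  # alleles are complemented into CDS space
  vm <- tibble::tibble(contig = "c1", pos = 19L, ref = "T", alt = "C")
  outm <- implant_variants(minus, vm)
  expect_identical(substr(outm, 1, 1), "G")
  expect_identical(substr(outm, 2, 9), substr("ATGAAACCC", 2, 9))

  bad <- tibble::tibble(contig = "c1", pos = 12L, ref = "G", alt = "C")
  expect_error(implant_variants(plus, bad), "ref mismatch")
  overlap <- tibble::tibble(contig = "c1", pos = c(12L, 12L),
                            ref = c("T", "T"), alt = c("C", "G"))
  expect_error(implant_variants(plus, overlap), "overlapping")
})
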