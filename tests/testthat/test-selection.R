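# Selection engine: counting oracle, rate matrix, frequencies, trees,
# pruning likelihood, M0 fits, LRT and FDR.

pair_aln <- function(s1, s2) tibble::tibble(id = c("a", "b"), seq = c(s1, s2))

test_that("Nei-Gojobori counting matches hand-enumerated synonymy", {
  ident <- ng86_dnds(pair_aln("ATGAAA", "ATGAAA"))
  expect_equal(ident$dn, 0); expect_equal(ident$ds, 0)
  expect_true(is.na(ident$omega))

  # TTT vs TTC: the third-position change is synonymous (both Phe)
  syn <- ng86_dnds(pair_aln("TTT", "TTC"))
  expect_equal(syn$dn, 0)
  expect_gt(syn$ps, 0)
  expect_equal(syn$omega, 0)

  # TTT vs GTT: Phe -> Val, nonsynonymous; dS = 0 so omega undefined
  nonsyn <- ng86_dnds(pair_aln("TTT", "GTT"))
  expect_equal(nonsyn$ds, 0)
  expect_gt(nonsyn$dn, 0)
  expect_true(is.na(nonsyn$omega))
  expect_true("ds_zero" %in% nonsyn$flags)

  expect_error(ng86_dnds(pair_aln("---", "---")), "one comparable codon")
})

test_that("F3x4 frequencies follow positional composition and normalise", {
  # each codon position uses a single nucleotide: one codon gets mass 1
  single <- f3x4_frequencies(c("ATGATGATG"), floor = 0)
  expect_equal(unname(single["ATG"]), 1)

  unif <- f3x4_frequencies(c("ACGTACGTACGT", "GTACGTACGTAC",
                             "CGTACGTACGTA", "TACGTACGTACG"))
  expect_equal(unname(unif), rep(1 / 61, 61), tolerance = 1e-12)

  withr::local_seed(3)
  rnd <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  pi <- f3x4_frequencies(rnd)
  expect_equal(sum(pi), 1, tolerance = 1e-12)
})

test_that("the GY94 rate matrix encodes kappa, omega and detailed balance", {
  pi <- as.numeric(f3x4_frequencies(c("ATGAAACCCTTTGGGCACTGGCTT")))
  Q <- gy94_rate_matrix(omega = 0.4, kappa = 3, pi = pi)
  expect_equal(unname(rowSums(Q)), rep(0, 61), tolerance = 1e-12)
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)

  # synonymous transition / transversion with equal target frequencies
  # TTT -> TTC is a synonymous transition; CCT -> CCA a synonymous
  # transversion: ratio of (rate / pi_target) must be kappa
  r_ti <- Q["TTT", "TTC"] / pi[match("TTC", rownames(Q))]
  r_tv <- Q["CCT", "CCA"] / pi[match("CCA", rownames(Q))]
  expect_equal(r_ti / r_tv, 3, tolerance = 1e-10)
  # nonsyn/syn of the same mutational type: TTT->GTT (nonsyn transversion)
  # vs CCT->CCA (syn transversion)
  r_ns <- Q["TTT", "GTT"] / pi[match("GTT", rownames(Q))]
  expect_equal(r_ns / r_tv, 0.4, tolerance = 1e-10)

  withr::local_seed(11)
  for (k in 1:100) {
    ij <- sample.int(61, 2)
    expect_equal(pi[ij[1]] * Q[ij[1], ij[2]], pi[ij[2]] * Q[ij[2], ij[1]],
                 tolerance = 1e-12)
  }
  expect_error(gy94_rate_matrix(-1, 2), "omega")
})

test_that("neighbor-joining trees satisfy the stated shape contracts", {
  tr <- simulate_tree(2, 0.4, seed = 2)
  aln <- simulate_codon_msa(tr, 0.5, 2, n_codons = 300, seed = 5)
  nj2 <- nj_tree(aln)
  d <- ape::cophenetic.phylo(nj2)
  p <- mean(mapply(function(x, y) x != y,
                   strsplit(aln$seq[1], "")[[1]], strsplit(aln$seq[2], "")[[1]]))
  expect_equal(unname(d[1, 2]), 3 * (-0.75 * log(1 - 4 * p / 3)),
               tolerance = 1e-9)

  tr4 <- simulate_tree(4, 0.6, seed = 8)
  aln4 <- simulate_codon_msa(tr4, 0.5, 2, n_codons = 400, seed = 9)
  nj4 <- nj_tree(aln4)
  expect_equal(ape::Ntip(nj4), 4)
  # permuting input order: same unrooted topology
  perm <- aln4[c(3, 1, 4, 2), ]
  njp <- nj_tree(perm)
  expect_equal(ape::dist.topo(ape::unroot(nj4), ape::unroot(njp))[1], 0)
  # simulated topology recovered at this depth
  expect_equal(ape::dist.topo(ape::unroot(nj4), ape::unroot(tr4))[1], 0)
})

test_that("pruning equals the closed-form pair likelihood and is root-invariant", {
  tr <- ape::read.tree(text = "(a:0.15,b:0.25);")
  aln <- simulate_codon_msa(tr, 0.3, 2, n_codons = 200, seed = 31)
  pi <- f3x4_frequencies(aln$seq)
  st <- orphanevo:::alignment_states(aln)
  ll_direct <- function(t_tot, om, ka) {
    P <- gy94_transition_matrix(t_tot, om, ka, pi)
    sum(log(pi[st[1, ]] * P[cbind(st[1, ], st[2, ])]))
  }
  expect_equal(pruning_loglik(aln, tr, 0.3, 2, pi), ll_direct(0.4, 0.3, 2),
               tolerance = 1e-8)

  # zero-time limit: lnL -> sum of log pi over columns
  tr0 <- ape::read.tree(text = "(a:1e-9,b:1e-9);")
  aln_id <- pair_aln(aln$seq[1], aln$seq[1])
  expect_equal(pruning_loglik(aln_id, tr0, 0.5, 2, pi),
               sum(log(pi[st[1, ]])), tolerance = 1e-4)

  # reversibility: likelihood invariant to re-rooting an unrooted tree
  tr4 <- simulate_tree(4, 0.5, seed = 3)
  aln4 <- simulate_codon_msa(tr4, 0.4, 2, n_codons = 150, seed = 17)
  pi4 <- f3x4_frequencies(aln4$seq)
  lls <- vapply(tr4$tip.label[1:3], function(tip) {
    rerooted <- ape::unroot(ape::root(tr4, outgroup = tip, resolve.root = TRUE))
    pruning_loglik(aln4, rerooted, 0.4, 2, pi4)
  }, numeric(1))
  expect_lt(max(lls) - min(lls), 1e-6)
})

test_that("M0 fits are nested, recover omega, and flag degenerate inputs", {
  tr <- simulate_tree(2, 0.3, seed = 6)
  aln <- simulate_codon_msa(tr, 0.3, 2, n_codons = 1000, seed = 77)
  ha <- fit_m0(aln)
  h0 <- fit_m0(aln, tree = ha$tree, fix_omega = 1)
  expect_gte(ha$loglik, h0$loglik - 1e-6)   # nesting
  expect_gt(ha$omega, 0.2); expect_lt(ha$omega, 0.4)

  td <- tidy(ha); gl <- glance(ha)
  expect_true(all(c("omega", "kappa") %in% td$term))
  expect_equal(gl$omega, ha$omega)

  same <- pair_aln(aln$seq[1], aln$seq[1])
  fid <- fit_m0(same)
  expect_true("identical_sequences" %in% fid$flags)
  expect_true(is.na(fid$omega))
  expect_equal(fid$branch_lengths, rep(1e-6, 2))
})

test_that("three-taxon fits estimate a shared omega on the cluster tree", {
  tr3 <- ape::read.tree(text = "(a:0.15,b:0.15,c:0.2);")
  aln3 <- simulate_codon_msa(tr3, 0.25, 2, n_codons = 600, seed = 55)
  ha <- fit_m0(aln3)
  h0 <- fit_m0(aln3, tree = ha$tree, fix_omega = 1)
  expect_gte(ha$loglik, h0$loglik)
  expect_gt(ha$omega, 0.15); expect_lt(ha$omega, 0.4)
})

test_that("the LRT and BH adjustment match their closed-form oracles", {
  expect_equal(lrt(-100, -100)$statistic, 0)
  expect_equal(lrt(-100, -100)$p_value, 1)
  # chi-squared(1) upper tails via the error-function identity
  erf_p <- function(x) 2 * (1 - stats::pnorm(sqrt(x)))
  expect_equal(lrt(-50, -50 - 3.841459 / 2)$p_value, erf_p(3.841459),
               tolerance = 1e-10)
  expect_equal(lrt(-50, -50 - 3.841459 / 2)$p_value, 0.05, tolerance = 1e-4)
  expect_equal(lrt(-10, -10 - 6.634897 / 2)$p_value, 0.01, tolerance = 1e-4)
  expect_warning(lrt(-101, -100), "clipped")

  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  withr::local_seed(19)
  for (i in 1:1000) {
    p <- stats::runif(sample(1:12, 1))
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
})

test_that("dataset runs flag identical clusters and adjust within dataset", {
  alns <- list(
    id1 = pair_aln(strrep("ATGAAACCCTTTGGGCAC", 10), strrep("ATGAAACCCTTTGGGCAC", 10)),
    div = simulate_codon_msa(simulate_tree(2, 0.3, seed = 2), 0.1, 2,
                             n_codons = 400, seed = 23))
  res <- run_dataset(alns, "ortholog")
  expect_s3_class(res, "selection_results")
  expect_equal(nrow(res), 2)
  r1 <- res[res$cluster_id == "id1", ]
  expect_true(grepl("identical_sequences", r1$flags))
  expect_equal(r1$p_value, 1)
  expect_true(all(res$q_value >= res$p_value, na.rm = TRUE))
  r2 <- res[res$cluster_id == "div", ]
  expect_lt(r2$omega, 0.6)
  expect_lt(r2$p_value, 0.05)
})
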