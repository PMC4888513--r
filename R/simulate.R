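# Seeded simulation of phylogenies and codon alignments under the GY94 M0
# model.  Substitutions only (no indels); the state space is restricted to
# the 61 sense codons, so simulated sequences never contain stop codons.

#' Simulate a random unrooted phylogeny
#'
#' Draws a random unrooted binary topology and exponential branch lengths,
#' rescaled so that the mean pairwise (patristic) distance between leaves
#' equals `total_depth`.  With two taxa the tree is the single edge of
#' length `total_depth` (represented as two half-edges from the root node).
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param total_depth Target mean pairwise distance, in expected codon
#'   substitutions per site.
#' @param seed Integer seed; the same seed yields the identical tree.
#' @return An [ape::phylo] object with branch lengths.
#' @export
simulate_tree <- function(n_taxa, total_depth, seed = 1L) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  stopifnot(total_depth > 0)
  withr::with_seed(as.integer(seed), {
    if (n_taxa == 2) {
      tr <- ape::read.tree(text = sprintf("(t1:%g,t2:%g);",
                                          total_depth / 2, total_depth / 2))
    } else {
      tr <- ape::rtopology(n_taxa, rooted = FALSE, br = NULL)
      tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1) + 0.05
      d <- ape::cophenetic.phylo(tr)
      mean_d <- mean(d[upper.tri(d)])
      tr$edge.length <- tr$edge.length * total_depth / mean_d
    }
    tr
  })
}

# Sample child codon states given parent states and a transition matrix.
sample_states <- function(parent, P) {
  cum <- t(apply(P, 1, cumsum))
  r <- stats::runif(length(parent))
  rows <- cum[parent, , drop = FALSE]
  max.col(rows >= r, ties.method = "first")
}

#' Simulate a codon alignment along a phylogeny
#'
#' Evolves codon sequences under the GY94 M0 model: the root sequence is
#' drawn from `pi` (or supplied), and each branch applies the transition
#' matrix `exp(Q t)`.  Sequences are ungapped, stop-free and of length
#' `3 * n_codons`.
#'
#' @param tree An [ape::phylo] with branch lengths in codon substitutions
#'   per site.
#' @param omega,kappa,pi GY94 M0 parameters (see [gy94_rate_matrix()]).
#' @param n_codons Number of codons per sequence.
#' @param seed Integer seed (byte-identical output for equal seeds).
#' @param root_seq Optional nucleotide string (length `3 * n_codons`,
#'   sense codons only) used as the root state instead of sampling from
#'   `pi`.
#' @return A tibble with columns `id` and `seq` (one row per leaf), with
#'   the codon-index matrix in attribute `states`.
#' @export
simulate_codon_msa <- function(tree, omega, kappa, pi = rep(1 / 61, 61),
                               n_codons = 100, seed = 1L, root_seq = NULL) {
  ct <- codon_tables
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (!is.null(root_seq)) {
    root_states <- codon_index(split_codons(toupper(root_seq)))
    if (anyNA(root_states)) stop("root_seq contains stop codons or non-ACGT characters")
    n_codons <- length(root_states)
  }
  Q <- gy94_rate_matrix(omega, kappa, pi)
  dec <- decompose_rate_matrix(Q, pi)
  n_nodes <- max(tree$edge)
  root <- ape::Ntip(tree) + 1L
  withr::with_seed(as.integer(seed), {
    states <- matrix(NA_integer_, nrow = n_nodes, ncol = n_codons)
    states[root, ] <- if (is.null(root_seq)) {
      sample.int(ct$n_sense, n_codons, replace = TRUE, prob = pi)
    } else root_states
    # preorder: parents before children
    ord <- order(match(tree$edge[, 1], c(root, tree$edge[, 2])))
    for (k in ord) {
      par <- tree$edge[k, 1]; child <- tree$edge[k, 2]
      t_br <- tree$edge.length[k]
      if (t_br <= 0) {
        states[child, ] <- states[par, ]
      } else {
        P <- transition_prob(dec, t_br)
        P <- P / rowSums(P)
        states[child, ] <- sample_states(states[par, ], P)
      }
    }
    leaf_states <- states[seq_len(ape::Ntip(tree)), , drop = FALSE]
    seqs <- apply(leaf_states, 1, function(s) paste0(ct$sense[s], collapse = ""))
    out <- tibble::tibble(id = tree$tip.label, seq = unname(seqs))
    attr(out, "states") <- leaf_states
    out
  })
}
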