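# Goldman-Yang (GY94) M0 codon substitution model: rate matrix, transition
# probabilities via eigendecomposition in the pi-symmetrised basis, and the
# F3x4 codon frequency estimator.

#' Goldman-Yang M0 instantaneous rate matrix
#'
#' Builds the 61 x 61 rate matrix of the GY94 codon model with a single
#' nonsynonymous/synonymous rate ratio `omega`, transition/transversion
#' ratio `kappa` and target codon frequencies `pi`.  Only single-nucleotide
#' changes have non-zero rate; the matrix is scaled so that the expected
#' number of substitutions per codon site per unit time is one.
#'
#' @param omega dN/dS ratio (> 0).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param pi Numeric vector of 61 sense-codon frequencies summing to 1
#'   (default uniform).
#' @return A 61 x 61 rate matrix with rows summing to zero, codon names on
#'   both dimensions.
#' @export
gy94_rate_matrix <- function(omega, kappa, pi = rep(1 / 61, 61)) {
  ct <- codon_tables
  stopifnot(length(pi) == ct$n_sense)
  if (!is.finite(omega) || omega <= 0) stop("omega must be > 0")
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0")
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-6) {
    stop("pi must be non-negative and sum to 1")
  }
  Q <- matrix(0, ct$n_sense, ct$n_sense,
              dimnames = list(ct$sense, ct$sense))
  rate <- pi[ct$pair_j] *
    ifelse(ct$pair_transition, kappa, 1) *
    ifelse(ct$pair_synonymous, 1, omega)
  Q[cbind(ct$pair_i, ct$pair_j)] <- rate
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q / scale
}

# Eigendecomposition of a reversible Q in the symmetrised basis.
# Returns an object from which P(t) = exp(Qt) is cheap for any t.
decompose_rate_matrix <- function(Q, pi) {
  d <- sqrt(pi)
  S <- Q * (d %o% (1 / d))       # D^{1/2} Q D^{-1/2}, symmetric
  S <- (S + t(S)) / 2            # guard tiny asymmetry
  e <- eigen(S, symmetric = TRUE)
  list(
    U = e$vectors / d,           # D^{-1/2} U
    Vt = t(e$vectors * d),       # U' D^{1/2}
    values = e$values
  )
}

# P(t) from a decomposition; clamps tiny negative entries from roundoff.
transition_prob <- function(dec, t) {
  P <- dec$U %*% (exp(dec$values * t) * dec$Vt)
  P[P < 0] <- 0
  P
}

#' Codon transition probability matrix
#'
#' `exp(Q t)` for a GY94 rate matrix, computed by eigendecomposition of the
#' reversible generator in the frequency-symmetrised basis.
#'
#' @inheritParams gy94_rate_matrix
#' @param t Branch length in expected codon substitutions per site (>= 0).
#' @return A 61 x 61 stochastic matrix.
#' @export
gy94_transition_matrix <- function(t, omega, kappa, pi = rep(1 / 61, 61)) {
  stopifnot(t >= 0)
  Q <- gy94_rate_matrix(omega, kappa, pi)
  P <- transition_prob(decompose_rate_matrix(Q, pi), t)
  dimnames(P) <- dimnames(Q)
  P
}

#' F3x4 codon frequencies from a codon alignment
#'
#' Estimates sense-codon frequencies as the product of position-specific
#' nucleotide frequencies, with stop codons excluded and the result
#' renormalised to sum to one (the codeml M0 default).  Gap codons are
#' ignored.  Frequencies are floored at a small positive value before
#' renormalisation so that rate matrices built from sparse alignments stay
#' irreducible.
#'
#' @param seqs Character vector of aligned nucleotide sequences (equal
#'   lengths divisible by 3; `-` for gaps).
#' @param floor Minimum codon frequency before renormalisation.
#' @return Numeric vector of 61 codon frequencies (named) summing to 1.
#' @export
f3x4_frequencies <- function(seqs, floor = 1e-6) {
  ct <- codon_tables
  stopifnot(length(seqs) >= 1)
  chars <- strsplit(toupper(paste0(seqs, collapse = "")), "")[[1]]
  n <- nchar(seqs[1])
  stopifnot(n %% 3 == 0)
  posn <- rep_len(rep(1:3, length.out = n), length(chars))
  keep <- chars %in% c("A", "C", "G", "T")
  freq <- matrix(0.25, nrow = 3, ncol = 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (p in 1:3) {
    b <- chars[keep & posn == p]
    if (length(b) > 0) {
      tab <- table(factor(b, levels = c("A", "C", "G", "T")))
      freq[p, ] <- as.numeric(tab) / length(b)
    }
  }
  pi <- freq[1, ct$codon_nt[, 1]] * freq[2, ct$codon_nt[, 2]] * freq[3, ct$codon_nt[, 3]]
  pi <- pmax(pi, floor)
  pi <- pi / sum(pi)
  names(pi) <- ct$sense
  pi
}
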