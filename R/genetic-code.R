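# Codon machinery shared by the simulator and the selection engine.
# State space is the 61 sense codons of the standard genetic code; stop
# codons are excluded everywhere (the M0 state space).

codon_tables <- local({
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  sense <- codons[code != "*"]
  aa <- unname(code[sense])

  nt <- c("A", "C", "G", "T")
  cmat <- do.call(rbind, strsplit(sense, ""))
  is_transition <- function(x, y) {
    (x == "A" & y == "G") | (x == "G" & y == "A") |
      (x == "C" & y == "T") | (x == "T" & y == "C")
  }

  # enumerate ordered sense-codon pairs differing at exactly one position
  n <- length(sense)
  diffs <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    sum(cmat[i, ] != cmat[j, ])
  }))
  idx <- which(diffs == 1L, arr.ind = TRUE)
  pos <- integer(nrow(idx))
  ti <- logical(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    p <- which(cmat[i, ] != cmat[j, ])
    pos[k] <- p
    ti[k] <- is_transition(cmat[i, p], cmat[j, p])
  }
  syn <- aa[idx[, 1]] == aa[idx[, 2]]

  list(
    codons64 = codons,
    sense = sense,
    n_sense = n,
    aa = aa,
    codon_nt = cmat,
    pair_i = idx[, 1],
    pair_j = idx[, 2],
    pair_pos = pos,
    pair_transition = ti,
    pair_synonymous = syn
  )
})

#' Translate coding sequences under the standard genetic code
#'
#' @param cds Character vector of nucleotide coding sequences (lengths
#'   divisible by 3).  Terminal stop codons are translated to `*`.
#' @return Character vector of amino-acid sequences.
#' @export
translate_cds <- function(cds) {
  if (length(cds) == 0) return(character(0))
  out <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(toupper(cds)), no.init.codon = TRUE
  ))
  unname(out)
}

# codon string vector -> integer indices into the 61 sense codons (NA for
# gaps "---" or stops)
codon_index <- function(codon_strings) {
  match(codon_strings, codon_tables$sense)
}

# split an ungapped or gapped nucleotide sequence into codon triplets
split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3 == 0)
  if (n == 0) return(character(0))
  substring(seq, seq(1, n, by = 3), seq(3, n, by = 3))
}

has_internal_stop <- function(cds) {
  codons <- split_codons(toupper(cds))
  if (length(codons) == 0) return(FALSE)
  internal <- codons[-length(codons)]
  any(internal %in% c("TAA", "TAG", "TGA"))
}

strip_terminal_stop <- function(cds) {
  codons <- split_codons(toupper(cds))
  if (length(codons) > 0 && codons[length(codons)] %in% c("TAA", "TAG", "TGA")) {
    cds <- paste0(codons[-length(codons)], collapse = "")
  }
  cds
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

gc_fraction <- function(seq) {
  b <- strsplit(toupper(seq), "")[[1]]
  mean(b %in% c("G", "C"))
}
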