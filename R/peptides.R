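# Peptide evidence: full-length 100 %-identity matches of observed
# peptides against the predicted proteome.

#' Match peptides against a proteome at 100 % identity
#'
#' Reports every exact, full-length occurrence of each peptide as a
#' substring of a protein (leucine and isoleucine are distinct; no
#' tolerance).  Peptides containing characters outside the amino-acid
#' alphabet are skipped with a warning.
#'
#' @param peptides Tibble with `peptide_id`, `seq`.
#' @param proteome Tibble with `id`, `seq` (predicted proteins).
#' @return A list: `hits` (tibble `peptide_id`, `protein_id`, `start`
#'   \[0-based offset\], `length`) and `gene_flags` (tibble `id`,
#'   `peptide_hit`), one row per protein.
#' @export
match_peptides <- function(peptides, proteome) {
  aa_ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", peptides$seq)
  if (any(!aa_ok)) {
    warning("skipping ", sum(!aa_ok), " peptide(s) with illegal characters",
            call. = FALSE)
    peptides <- peptides[aa_ok, ]
  }
  if (nrow(peptides) == 0 || any(!nzchar(peptides$seq))) {
    stopifnot(all(nzchar(peptides$seq)))
  }
  hits <- list()
  for (i in seq_len(nrow(peptides))) {
    loc <- stringr::str_locate_all(proteome$seq, stringr::fixed(peptides$seq[i]))
    n_hit <- vapply(loc, nrow, integer(1))
    prot <- which(n_hit > 0)
    if (length(prot) > 0) {
      hits[[length(hits) + 1]] <- tibble::tibble(
        peptide_id = peptides$peptide_id[i],
        protein_id = rep(proteome$id[prot], n_hit[prot]),
        start = unname(unlist(lapply(loc[prot], function(m) m[, "start"]))) - 1L,
        length = nchar(peptides$seq[i]))
    }
  }
  hits <- if (length(hits) > 0) dplyr::bind_rows(hits) else
    tibble::tibble(peptide_id = character(), protein_id = character(),
                   start = integer(), length = integer())
  gene_flags <- tibble::tibble(
    id = proteome$id,
    peptide_hit = proteome$id %in% hits$protein_id)
  list(hits = hits, gene_flags = gene_flags)
}
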