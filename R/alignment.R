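# Protein multiple alignment (progressive, affine gaps), back-translation
# to codon alignments, the minimum-length filter, and implantation of
# lineage fixed differences into reference coding sequences.

aa_freq_profile <- function(rows, alphabet) {
  # rows: character matrix (sequences x columns); returns alphabet x columns
  # residue frequency matrix, gaps excluded
  apply(rows, 2, function(col) {
    col <- col[col != "-"]
    f <- table(factor(col, levels = alphabet))
    n <- sum(f)
    if (n == 0) rep(0, length(alphabet)) else as.numeric(f) / n
  })
}

# Global affine-gap alignment of two profiles (Gotoh, rows vectorised).
# Returns the aligned path as two logical vectors: advance in A / in B.
align_profiles <- function(fa, fb, sub, gap_open, gap_extend) {
  n <- ncol(fa); m <- ncol(fb)
  S <- t(fa) %*% sub %*% fb          # n x m column-pair scores
  go <- gap_open + gap_extend; ge <- gap_extend
  NEG <- -1e12
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)   # gap in A (consume B column)
  Iy <- matrix(NEG, n + 1, m + 1)   # gap in B (consume A column)
  M[1, 1] <- 0
  Ix[1, ] <- c(NEG, -gap_open - ge * seq_len(m))
  Iy[, 1] <- c(NEG, -gap_open - ge * seq_len(n))
  for (i in seq_len(n)) {
    prev_best <- pmax(M[i, ], Ix[i, ], Iy[i, ])
    M[i + 1, 2:(m + 1)] <- S[i, ] + prev_best[1:m]
    Iy[i + 1, ] <- pmax(M[i, ] - go, Iy[i, ] - ge)
    # Ix along the row via cumulative max trick
    base <- pmax(M[i + 1, ], Iy[i + 1, ]) + ge * (0:m)
    Ix[i + 1, 2:(m + 1)] <- (cummax(base[1:m]) - go) - ge * (1:m)
  }
  # traceback
  i <- n; j <- m
  state <- which.max(c(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1]))
  stepA <- logical(0); stepB <- logical(0)
  while (i > 0 || j > 0) {
    if (state == 1 && i > 0 && j > 0) {
      stepA <- c(TRUE, stepA); stepB <- c(TRUE, stepB)
      prev <- c(M[i, j], Ix[i, j], Iy[i, j])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2 || i == 0) {   # gap in A: consume B
      stepA <- c(FALSE, stepA); stepB <- c(TRUE, stepB)
      if (i == 0) { j <- j - 1; state <- 2; next }
      from_m <- max(M[i + 1, j], Iy[i + 1, j]) - go
      from_x <- Ix[i + 1, j] - ge
      state <- if (from_m >= from_x) {
        if (M[i + 1, j] >= Iy[i + 1, j]) 1 else 3
      } else 2
      j <- j - 1
    } else {                              # gap in B: consume A
      stepA <- c(TRUE, stepA); stepB <- c(FALSE, stepB)
      if (j == 0) { i <- i - 1; state <- 3; next }
      state <- if (M[i, j + 1] - go >= Iy[i, j + 1] - ge) 1 else 3
      i <- i - 1
    }
  }
  list(stepA = stepA, stepB = stepB)
}

insert_gaps <- function(rows, step) {
  out <- matrix("-", nrow = nrow(rows), ncol = length(step))
  out[, step] <- rows
  out
}

#' Progressive protein multiple alignment
#'
#' Two sequences are aligned by optimal global pairwise alignment
#' (BLOSUM62, affine gaps).  Three or more are aligned progressively
#' along a UPGMA guide tree built on 3-mer cosine distances, merging
#' profiles by affine-gap dynamic programming on frequency-weighted
#' substitution scores.  Columns preserve the residue order of every
#' sequence.
#'
#' @param proteins Tibble with `id`, `seq` (>= 2 non-empty sequences).
#' @param substitution Substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend Positive affine gap costs.
#' @return Tibble with `id` and `seq` (aligned, equal lengths).
#' @export
progressive_align <- function(proteins, substitution = NULL,
                              gap_open = 10, gap_extend = 0.5) {
  stopifnot(nrow(proteins) >= 2)
  if (any(!nzchar(proteins$seq))) stop("empty sequence in alignment input")
  if (is.null(substitution)) substitution <- blosum62()
  ids <- proteins$id
  seqs <- toupper(proteins$seq)

  if (nrow(proteins) == 2) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::BString(seqs[1]), Biostrings::BString(seqs[2]),
      substitutionMatrix = substitution, gapOpening = gap_open,
      gapExtension = gap_extend, type = "global")
    return(tibble::tibble(
      id = ids,
      seq = c(as.character(Biostrings::alignedPattern(al)),
              as.character(Biostrings::alignedSubject(al)))))
  }

  alphabet <- rownames(substitution)
  # guide tree: UPGMA on 3-mer cosine distance
  km <- kmer_sets(seqs, 3)
  all_k <- sort(unique(unlist(km)))
  counts <- do.call(rbind, lapply(seqs, function(s) {
    n <- nchar(s)
    kms <- substring(s, 1:(n - 2), 3:n)
    as.numeric(table(factor(kms, levels = all_k)))
  }))
  norms <- sqrt(rowSums(counts^2))
  cosd <- 1 - (counts %*% t(counts)) / (norms %o% norms)
  hc <- stats::hclust(stats::as.dist(cosd), method = "average")

  profiles <- lapply(seqs, function(s) matrix(strsplit(s, "")[[1]], nrow = 1))
  members <- as.list(seq_along(seqs))
  merged <- vector("list", nrow(hc$merge))
  merged_members <- vector("list", nrow(hc$merge))
  get_node <- function(k) {
    if (k < 0) list(rows = profiles[[-k]], mem = members[[-k]])
    else list(rows = merged[[k]], mem = merged_members[[k]])
  }
  for (s in seq_len(nrow(hc$merge))) {
    a <- get_node(hc$merge[s, 1]); b <- get_node(hc$merge[s, 2])
    fa <- aa_freq_profile(a$rows, alphabet)
    fb <- aa_freq_profile(b$rows, alphabet)
    path <- align_profiles(fa, fb, substitution, gap_open, gap_extend)
    merged[[s]] <- rbind(insert_gaps(a$rows, path$stepA),
                         insert_gaps(b$rows, path$stepB))
    merged_members[[s]] <- c(a$mem, b$mem)
  }
  final <- merged[[nrow(hc$merge)]]
  ord <- merged_members[[nrow(hc$merge)]]
  aligned <- apply(final, 1, paste0, collapse = "")
  tibble::tibble(id = ids[ord], seq = aligned)[order(match(ids[ord], ids)), ]
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each residue column becomes the corresponding codon triplet of the
#' member's CDS; protein gaps become `---`.  Terminal stop codons are
#' stripped from the CDS first.  A CDS whose length is not three times
#' its protein length, whose translation does not match the ungapped
#' protein row, or which contains an internal stop codon, aborts with a
#' classed error (`orphanevo_backtranslate_error`) carrying the reason.
#'
#' @param msa Protein alignment tibble (`id`, `seq`).
#' @param cds Named character vector of coding sequences (names = ids).
#' @return Codon alignment tibble (`id`, `seq`), nucleotide length three
#'   times the protein alignment length.
#' @export
backtranslate <- function(msa, cds) {
  fail <- function(reason, id) {
    stop(structure(class = c("orphanevo_backtranslate_error", "error", "condition"),
                   list(message = sprintf("%s (member %s)", reason, id),
                        call = NULL, reason = reason, member = id)))
  }
  rows <- vapply(seq_len(nrow(msa)), function(i) {
    id <- msa$id[i]
    if (!id %in% names(cds)) fail("missing CDS", id)
    if (nchar(cds[[id]]) %% 3 != 0) fail("CDS length not a multiple of 3", id)
    cd <- strip_terminal_stop(toupper(cds[[id]]))
    if (has_internal_stop(paste0(cd, "TAA"))) fail("internal stop codon", id)
    aligned <- strsplit(msa$seq[i], "")[[1]]
    ungapped_len <- sum(aligned != "-")
    if (nchar(cd) != 3 * ungapped_len) fail("CDS / protein length mismatch", id)
    if (translate_cds(cd) != paste0(aligned[aligned != "-"], collapse = "")) {
      fail("translation mismatch", id)
    }
    codons <- split_codons(cd)
    out <- rep("---", length(aligned))
    out[aligned != "-"] <- codons
    paste0(out, collapse = "")
  }, character(1))
  tibble::tibble(id = msa$id, seq = rows)
}

#' Minimum codon-alignment length filter
#'
#' Keeps alignments with at least `min_nt` nucleotide columns (gap
#' columns included); shorter alignments are dropped.
#'
#' @param alignment Codon alignment tibble (`id`, `seq`).
#' @param min_nt Minimum number of alignment columns (default 150).
#' @return `TRUE` (keep) or `FALSE` (drop).
#' @export
filter_min_length <- function(alignment, min_nt = 150) {
  nchar(alignment$seq[1]) >= min_nt
}

#' Implant clade fixed differences into a reference CDS
#'
#' Maps genome-coordinate SNVs into CDS coordinates through the gene's
#' exon structure (alleles complemented for minus-strand genes) and
#' substitutes them, yielding the lineage allele of the gene.
#'
#' @param gene One gene-model row (tibble with `gene_id`, `contig`,
#'   `strand`, `cds`, `exons`).
#' @param variants Variant tibble (`contig`, `pos`, `ref`, `alt`,
#'   1-based genome coordinates).
#' @return The allele CDS (character scalar), differing from the
#'   reference exactly at the implanted positions.
#' @export
implant_variants <- function(gene, variants) {
  ex <- gene$exons[[1]]
  gpos <- unlist(lapply(seq_len(nrow(ex)), function(e) ex$start[e]:ex$end[e]))
  map <- if (gene$strand == "+") gpos else rev(gpos)
  v <- variants[variants$contig == gene$contig & variants$pos %in% map, , drop = FALSE]
  chars <- strsplit(gene$cds, "")[[1]]
  if (nrow(v) == 0) return(gene$cds)
  if (anyDuplicated(v$pos)) stop("overlapping variants at position ",
                                 v$pos[duplicated(v$pos)][1])
  idx <- match(v$pos, map)
  ref_cds <- if (gene$strand == "+") v$ref else complement_base(v$ref)
  alt_cds <- if (gene$strand == "+") v$alt else complement_base(v$alt)
  mismatch <- chars[idx] != ref_cds
  if (any(mismatch)) {
    stop("variant ref mismatch at ", gene$contig, ":", v$pos[mismatch][1],
         " (expected ", chars[idx][mismatch][1], ", got ", ref_cds[mismatch][1], ")")
  }
  chars[idx] <- alt_cds
  paste0(chars, collapse = "")
}
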