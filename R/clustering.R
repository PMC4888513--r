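# Homology clustering: all-vs-all local alignment similarity graph
# (k-mer prescreened), Markov clustering, and categorisation of clusters
# into the ortholog / paralog analysis datasets.

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score of two sequences under a substitution
#' matrix with affine gap costs.  By default proteins are scored with
#' BLOSUM62, gap open 10 and extension 0.5; pass `match`/`mismatch` for a
#' simple scoring scheme instead (with `gap_open = 0` the gap cost is
#' linear).
#'
#' @param a,b Sequences (character scalars).
#' @param match,mismatch Simple scoring scheme (used when
#'   `substitution` is `NULL` and either is given).
#' @param substitution Optional substitution matrix (defaults to BLOSUM62
#'   when no simple scheme is given).
#' @param gap_open,gap_extend Positive gap costs.
#' @return Non-negative alignment score (0 when nothing aligns
#'   positively).
#' @export
smith_waterman <- function(a, b, match = NULL, mismatch = NULL,
                           substitution = NULL, gap_open = 10, gap_extend = 0.5) {
  stopifnot(nzchar(a), nzchar(b))
  if (is.null(substitution)) {
    if (is.null(match)) {
      substitution <- blosum62()
    } else {
      alphabet <- sort(unique(strsplit(paste0(a, b), "")[[1]]))
      substitution <- matrix(mismatch, length(alphabet), length(alphabet),
                             dimnames = list(alphabet, alphabet))
      diag(substitution) <- match
    }
  }
  bad <- setdiff(unique(strsplit(paste0(a, b), "")[[1]]), rownames(substitution))
  if (length(bad) > 0) stop("unknown residue letter: ", bad[1])
  Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b),
    substitutionMatrix = substitution, gapOpening = gap_open,
    gapExtension = gap_extend, type = "local", scoreOnly = TRUE)
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# self-alignment score: sum of diagonal substitution scores
self_score <- function(seq, substitution) {
  chars <- strsplit(seq, "")[[1]]
  sum(diag(substitution)[chars])
}

kmer_sets <- function(seqs, k) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  })
}

#' Build the protein similarity graph
#'
#' Candidate pairs share at least one k-mer; each candidate pair is scored
#' by local alignment and normalised by the smaller self-score, giving a
#' similarity in \[0, 1\].  Edges keep pairs at or above
#' `min_normalized_score`.
#'
#' @param proteins Tibble with columns `id` and `seq` (ids unique,
#'   species-tagged as `species|gene` where relevant).
#' @param min_normalized_score Edge threshold in \[0, 1\].
#' @param kmer_k Prescreen word size.
#' @param gap_open,gap_extend Affine gap costs for the local alignment.
#' @return A list of class `similarity_graph`: `nodes` (character) and
#'   `edges` (tibble `from`, `to`, `weight`).
#' @export
build_graph <- function(proteins, min_normalized_score = 0.3, kmer_k = 4,
                        gap_open = 10, gap_extend = 0.5) {
  stopifnot(!anyDuplicated(proteins$id))
  n <- nrow(proteins)
  sub <- blosum62()
  selfs <- vapply(proteins$seq, self_score, numeric(1),
                  substitution = sub, USE.NAMES = FALSE)
  # inverted k-mer index -> candidate pairs
  km <- kmer_sets(proteins$seq, kmer_k)
  idx <- data.frame(kmer = unlist(km),
                    prot = rep(seq_len(n), lengths(km)))
  pairs <- unique(do.call(rbind, lapply(
    split(idx$prot, idx$kmer),
    function(p) if (length(p) > 1) t(utils::combn(sort(p), 2)) else NULL)))
  edges <- tibble::tibble(from = character(), to = character(), weight = numeric())
  if (!is.null(pairs) && nrow(pairs) > 0) {
    scores <- numeric(nrow(pairs))
    for (i in sort(unique(pairs[, 1]))) {
      rows <- which(pairs[, 1] == i)
      js <- pairs[rows, 2]
      scores[rows] <- Biostrings::pairwiseAlignment(
        Biostrings::BStringSet(proteins$seq[js]),
        Biostrings::BString(proteins$seq[i]),
        substitutionMatrix = sub, gapOpening = gap_open,
        gapExtension = gap_extend, type = "local", scoreOnly = TRUE)
    }
    wt <- pmax(scores, 0) / pmin(selfs[pairs[, 1]], selfs[pairs[, 2]])
    keep <- wt >= min_normalized_score & pairs[, 1] != pairs[, 2]
    edges <- tibble::tibble(from = proteins$id[pairs[keep, 1]],
                            to = proteins$id[pairs[keep, 2]],
                            weight = wt[keep])
  }
  structure(list(nodes = proteins$id, edges = edges),
            class = "similarity_graph")
}

union_find_components <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (length(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Markov clustering of a similarity graph
#'
#' Classic MCL: alternate expansion (matrix power) and inflation
#' (element-wise power with column renormalisation) on the column-
#' stochastic transition matrix of the weighted graph, with self-loops of
#' weight one (a sequence is fully similar to itself), pruning small
#' entries each iteration.  Clusters are the connected components of the
#' converged matrix; the result is a partition of the node set and is
#' deterministic for a fixed input.
#'
#' @param graph A `similarity_graph` from [build_graph()].
#' @param inflation Inflation power (> 1).
#' @param expansion Expansion power (integer >= 2).
#' @param prune Entries below this are zeroed each iteration.
#' @param max_iter Iteration cap; non-convergence gives a warning and a
#'   `converged = FALSE` attribute on the (still valid) partition.
#' @return Tibble with `cluster_id` and list-column `members`; cluster ids
#'   are assigned in order of each cluster's smallest member id.
#' @export
markov_cluster <- function(graph, inflation = 2, expansion = 2,
                           prune = 1e-5, max_iter = 100) {
  stopifnot(inherits(graph, "similarity_graph"), inflation > 1)
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0) stop("empty graph")
  i <- match(graph$edges$from, nodes)
  j <- match(graph$edges$to, nodes)
  M <- Matrix::sparseMatrix(
    i = c(i, j, seq_len(n)), j = c(j, i, seq_len(n)),
    x = c(graph$edges$weight, graph$edges$weight, rep(1, n)),
    dims = c(n, n))
  col_normalize <- function(M) {
    cs <- Matrix::colSums(M)
    cs[cs == 0] <- 1
    methods::as(M %*% Matrix::Diagonal(x = 1 / cs), "CsparseMatrix")
  }
  M <- col_normalize(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Mexp <- M
    for (e in seq_len(expansion - 1)) Mexp <- Mexp %*% M
    Minf <- methods::as(Mexp ^ inflation, "CsparseMatrix")
    Minf@x[Minf@x < prune] <- 0
    Minf <- Matrix::drop0(Minf)
    Minf <- col_normalize(Minf)
    delta <- max(abs(Minf - M))
    M <- Minf
    if (delta < 1e-8) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("Markov clustering did not converge within ", max_iter,
            " iterations; returning partial result", call. = FALSE)
  }
  Mt <- methods::as(Matrix::drop0(M), "TsparseMatrix")
  keep_nz <- Mt@x > prune
  nz <- cbind(Mt@i[keep_nz] + 1L, Mt@j[keep_nz] + 1L)
  comp <- union_find_components(n, nz)
  groups <- split(nodes, comp)
  groups <- lapply(groups, sort)
  anchor <- vapply(groups, function(m) sort(sub("^[^|]+\\|", "", m))[1], character(1))
  groups <- groups[order(anchor)]
  out <- tibble::tibble(
    cluster_id = sprintf("cl%04d", seq_along(groups)),
    members = unname(groups))
  attr(out, "converged") <- converged
  out
}

split_member_token <- function(tokens) {
  bad <- tokens[!grepl("^[^|]+\\|[^|]+$", tokens)]
  if (length(bad) > 0) stop("malformed member token: ", bad[1])
  tibble::tibble(species = sub("\\|.*$", "", tokens),
                 gene_id = sub("^[^|]+\\|", "", tokens))
}

#' Categorise homology clusters into analysis datasets
#'
#' Counts focal-species (ppa) orphan and conserved members and sister-
#' species (pex) members per cluster, assigns the category
#' (`orphan`, `conserved`, `hybrid`, `pex_specific`), and sets the dataset
#' flags: ortholog clusters have at least one member of each species,
#' paralog clusters at least two focal-species members (the paralog
#' dataset drops the sister-species genes).  Hybrid clusters (both orphan
#' and conserved focal members) and sister-species-specific clusters are
#' excluded from both datasets and listed in the exclusion report.
#'
#' @param clusters Tibble with `cluster_id` and `members` list-column of
#'   `species|gene` tokens.
#' @param labels Label tibble from [read_labels()] (focal-species genes).
#' @param focal,sister Species tags (defaults `"ppa"`, `"pex"`).
#' @return A list: `records` (one row per cluster with counts, category,
#'   `in_ortholog`, `in_paralog`, `paralog_members`) and `exclusions`
#'   (tibble `cluster_id`, `reason`).
#' @export
categorize_clusters <- function(clusters, labels, focal = "ppa", sister = "pex") {
  lab <- stats::setNames(labels$label, labels$gene_id)
  recs <- lapply(seq_len(nrow(clusters)), function(i) {
    mem <- split_member_token(clusters$members[[i]])
    ppa <- mem$gene_id[mem$species == focal]
    unknown <- ppa[!ppa %in% names(lab)]
    if (length(unknown) > 0) stop("unlabeled gene: ", unknown[1])
    n_orph <- sum(lab[ppa] == "orphan")
    n_cons <- sum(lab[ppa] == "conserved")
    n_pex <- sum(mem$species == sister)
    category <- if (n_orph >= 1 && n_cons >= 1) "hybrid"
      else if (length(ppa) == 0) "pex_specific"
      else if (n_orph >= 1) "orphan" else "conserved"
    excluded <- category %in% c("hybrid", "pex_specific")
    tibble::tibble(
      cluster_id = clusters$cluster_id[i],
      members = list(clusters$members[[i]]),
      n_ppa_orphan = n_orph, n_ppa_conserved = n_cons, n_pex = n_pex,
      category = category,
      in_ortholog = !excluded && length(ppa) >= 1 && n_pex >= 1,
      in_paralog = !excluded && length(ppa) >= 2,
      paralog_members = list(paste0(focal, "|", ppa)))
  })
  records <- dplyr::bind_rows(recs)
  exclusions <- records |>
    dplyr::filter(.data$category %in% c("hybrid", "pex_specific")) |>
    dplyr::transmute(.data$cluster_id, reason = .data$category)
  list(records = records, exclusions = exclusions)
}

#' Build the intra-species lineage-pair dataset
#'
#' For every focal-species gene, constructs the two lineage alleles by
#' implanting each clade's fixed differences into the reference CDS,
#' giving one size-two cluster per gene (including singletons that have no
#' homology-cluster membership).
#'
#' @param genes Gene-model tibble (needs `gene_id`, `cds`, `contig`,
#'   `strand`, `exons`, `valid`).
#' @param variants_a1,variants_a2 Variant tibbles ([read_variants()]).
#' @return Tibble with `gene_id`, `seq_a1`, `seq_a2`, `n_diff`.
#' @export
build_clade_pairs <- function(genes, variants_a1, variants_a2) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    a1 <- implant_variants(g, variants_a1)
    a2 <- implant_variants(g, variants_a2)
    tibble::tibble(
      gene_id = g$gene_id, seq_a1 = a1, seq_a2 = a2,
      n_diff = sum(strsplit(a1, "")[[1]] != strsplit(a2, "")[[1]]))
  })
  dplyr::bind_rows(rows)
}
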