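# Evidence integration: per-gene selection flags across datasets, Venn
# complementarity, the four gene classes, validation candidates, and
# per-class feature statistics.

#' Map cluster-level selection results onto genes
#'
#' Each gene inherits its cluster's dN/dS estimate, p and q in every
#' dataset it is covered by (a gene may belong to at most one cluster per
#' dataset).  The liberal flag is "omega below the liberal cutoff in any
#' dataset"; the conservative flag is "omega < 1 and q below alpha in any
#' dataset".
#'
#' @param selection A `selection_results` tibble (possibly several
#'   datasets stacked).
#' @param memberships Tibble `gene_id`, `dataset`, `cluster_id` mapping
#'   genes to the cluster that represents them in each dataset.
#' @param omega_liberal Liberal cutoff (default 0.6).
#' @param alpha FDR-adjusted significance level (default 0.05).
#' @return Tibble: `gene_id`, per-dataset `omega_*`/`q_*` columns,
#'   `omega_min`, `n_datasets`, `n_liberal_datasets`, `liberal`,
#'   `conservative`, `coverage`.
#' @export
gene_selection_evidence <- function(selection, memberships,
                                    omega_liberal = 0.6, alpha = 0.05) {
  dup <- memberships |>
    dplyr::count(.data$gene_id, .data$dataset) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("gene ", dup$gene_id[1], " is in two clusters of dataset ",
         dup$dataset[1])
  }
  joined <- memberships |>
    dplyr::inner_join(selection, by = c("dataset", "cluster_id"))
  wide <- joined |>
    dplyr::select("gene_id", "dataset", "omega", "q_value") |>
    tidyr::pivot_wider(names_from = "dataset",
                       values_from = c("omega", "q_value"))
  per_gene <- joined |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      omega_min = if (all(is.na(.data$omega))) NA_real_ else
        min(.data$omega, na.rm = TRUE),
      n_datasets = sum(!is.na(.data$omega)),
      n_liberal_datasets = sum(.data$omega < omega_liberal, na.rm = TRUE),
      liberal = any(.data$omega < omega_liberal, na.rm = TRUE),
      conservative = any(.data$omega < 1 & .data$q_value < alpha, na.rm = TRUE),
      .groups = "drop")
  out <- dplyr::left_join(per_gene, wide, by = "gene_id")
  dplyr::mutate(out, coverage = ifelse(.data$n_datasets == 0, "none", "some"))
}

#' Three-set Venn region counts
#'
#' @param sets Named list of three character vectors (gene-id sets).
#' @return Tibble with the seven region counts; region labels use
#'   the set names joined by `&`.
#' @export
venn3 <- function(sets) {
  stopifnot(length(sets) == 3, !is.null(names(sets)))
  nm <- names(sets)
  universe <- unique(unlist(sets))
  member <- sapply(sets, function(s) universe %in% s)
  if (length(universe) == 0) {
    member <- matrix(logical(0), 0, 3, dimnames = list(NULL, nm))
  }
  combos <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                        c = c(TRUE, FALSE))
  combos <- combos[rowSums(combos) > 0, ]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    mask <- unlist(combos[i, ])
    inregion <- if (length(universe) == 0) logical(0) else
      apply(member, 1, function(r) all(r == mask))
    tibble::tibble(region = paste(nm[mask], collapse = "&"),
                   n_sets = sum(mask), count = sum(inregion))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$n_sets, .data$region)
}

#' Classify genes into the four evidence classes
#'
#' Precedence (most to least specific evidence): conserved genes form
#' their own class; orphans with significant negative selection or
#' peptide evidence are `coding_orphan`; remaining orphans with robust
#' expression and no sign of strong negative selection are
#' `ncrna_candidate`; remaining orphans never reaching the expression
#' threshold and without strong negative selection are
#' `artifact_or_pseudogene`; everything else (e.g. weak expression only)
#' is `unassigned`.
#'
#' @param evidence Tibble with at least `gene_id`, `orphan`, `expressed`,
#'   `robust`, `liberal`, `conservative`, `peptide_hit`.
#' @param ncrna_rule `"liberal"` (default) or `"conservative"`: which
#'   selection rule defines "no sign of strong negative selection" for
#'   the non-coding and artifact classes.
#' @return The input with a `class` column added.
#' @export
classify_genes <- function(evidence, ncrna_rule = c("liberal", "conservative")) {
  ncrna_rule <- match.arg(ncrna_rule)
  no_sel <- if (ncrna_rule == "liberal") !evidence$liberal else
    !evidence$conservative
  cls <- dplyr::case_when(
    !evidence$orphan ~ "conserved",
    evidence$conservative | evidence$peptide_hit ~ "coding_orphan",
    evidence$robust & no_sel ~ "ncrna_candidate",
    !evidence$expressed & no_sel ~ "artifact_or_pseudogene",
    TRUE ~ "unassigned")
  dplyr::mutate(evidence, class = cls)
}

#' Select validation candidates
#'
#' Orphan genes with significant negative selection (conservative flag),
#' FPKM exactly zero in every sample, omega below the liberal cutoff in
#' at least two datasets, and strictly more than `min_exons` exons.
#'
#' @param evidence Classified evidence tibble (needs `orphan`,
#'   `conservative`, `zero_everywhere`, `n_liberal_datasets`, `n_exons`).
#' @param min_exons Exon threshold (candidates need more than this;
#'   default 2).
#' @return Character vector of candidate gene ids.
#' @export
select_validation_candidates <- function(evidence, min_exons = 2) {
  with(evidence, gene_id[
    orphan & conservative & zero_everywhere &
      n_liberal_datasets >= 2 & n_exons > min_exons])
}

#' Per-gene contig size percentile
#'
#' Percentile of the gene's contig when contigs are ranked by decreasing
#' length (ties share the minimum rank): the largest contig of 100 is
#' percentile 1, the smallest percentile 100.
#'
#' @param contigs Tibble `contig`, `length`.
#' @param gene_contig Tibble `gene_id`, `contig`.
#' @return Tibble `gene_id`, `contig_percentile`.
#' @export
contig_percentile <- function(contigs, gene_contig) {
  unknown <- setdiff(gene_contig$contig, contigs$contig)
  if (length(unknown) > 0) stop("gene on unknown contig: ", unknown[1])
  r <- rank(-contigs$length, ties.method = "min")
  pct <- stats::setNames(100 * r / nrow(contigs), contigs$contig)
  tibble::tibble(gene_id = gene_contig$gene_id,
                 contig_percentile = unname(pct[gene_contig$contig]))
}

#' Per-class feature distributions and rank-sum tests
#'
#' Compares transcript length, exon count, GC fraction and contig size
#' percentile across gene classes with two-sided Wilcoxon rank-sum tests
#' for every class pair (exact enumeration for small tie-free samples,
#' normal approximation with continuity and tie correction otherwise).
#'
#' @param evidence Classified evidence tibble with `class` and the
#'   feature columns.
#' @param features Feature column names.
#' @return A list: `summary` (per class x feature: n, median, quartiles)
#'   and `tests` (per feature x class pair: two-sided rank-sum p).
#' @export
feature_stats <- function(evidence,
                          features = c("transcript_length", "n_exons",
                                       "gc", "contig_percentile")) {
  classes <- sort(unique(evidence$class))
  summary <- evidence |>
    dplyr::select(dplyr::all_of(c("class", features))) |>
    tidyr::pivot_longer(dplyr::all_of(features), names_to = "feature") |>
    dplyr::group_by(.data$class, .data$feature) |>
    dplyr::summarise(n = dplyr::n(), q25 = stats::quantile(.data$value, 0.25),
                     median = stats::median(.data$value),
                     q75 = stats::quantile(.data$value, 0.75),
                     .groups = "drop")
  tests <- list()
  for (f in features) {
    for (i in seq_along(classes)) {
      for (j in seq_along(classes)) {
        if (j <= i) next
        x <- evidence[[f]][evidence$class == classes[i]]
        y <- evidence[[f]][evidence$class == classes[j]]
        if (length(x) == 0 || length(y) == 0) {
          tests[[length(tests) + 1]] <- tibble::tibble(
            feature = f, class_a = classes[i], class_b = classes[j],
            p_value = NA_real_, note = "empty class")
          next
        }
        exact <- length(x) * length(y) <= 400 &&
          !any(duplicated(c(x, y)))
        p <- suppressWarnings(stats::wilcox.test(
          x, y, exact = exact, correct = TRUE)$p.value)
        tests[[length(tests) + 1]] <- tibble::tibble(
          feature = f, class_a = classes[i], class_b = classes[j],
          p_value = p, note = "")
      }
    }
  }
  list(summary = summary, tests = dplyr::bind_rows(tests))
}

#' Cumulative proportion of clusters below omega thresholds
#'
#' For each dataset and cluster category, the cumulative proportion of
#' clusters whose estimated dN/dS falls at or below a grid of thresholds.
#'
#' @param selection Stacked `selection_results` with a `category` column
#'   (e.g. orphan / conserved).
#' @param thresholds Omega grid.
#' @return Tibble `dataset`, `category`, `threshold`, `proportion`.
#' @export
omega_cumulative <- function(selection,
                             thresholds = seq(0, 2, by = 0.05)) {
  selection |>
    dplyr::filter(!is.na(.data$omega)) |>
    dplyr::group_by(.data$dataset, .data$category) |>
    dplyr::reframe(threshold = thresholds,
                   proportion = vapply(thresholds,
                                       function(th) mean(.data$omega <= th),
                                       numeric(1)))
}

#' Summarise a pipeline run
#'
#' Collects every reported count from the evidence table so that each
#' printed number is re-derivable from it: class counts, expression
#' strata, Venn complementarity of the liberal and conservative gene
#' sets, validation-candidate count, and cumulative omega curves.
#'
#' @param evidence Classified evidence tibble.
#' @param selection Stacked selection results with `category`.
#' @param candidates Character vector from
#'   [select_validation_candidates()].
#' @return A list ready for JSON serialisation.
#' @export
summarize_run <- function(evidence, selection, candidates) {
  datasets <- unique(selection$dataset)
  lib_sets <- lapply(datasets, function(d) {
    col <- paste0("omega_", d)
    if (!col %in% names(evidence)) return(character(0))
    evidence$gene_id[!is.na(evidence[[col]]) & evidence[[col]] < 0.6 &
                       evidence$orphan]
  })
  names(lib_sets) <- datasets
  cons_sets <- lapply(datasets, function(d) {
    ocol <- paste0("omega_", d); qcol <- paste0("q_value_", d)
    if (!all(c(ocol, qcol) %in% names(evidence))) return(character(0))
    evidence$gene_id[!is.na(evidence[[ocol]]) & evidence[[ocol]] < 1 &
                       !is.na(evidence[[qcol]]) & evidence[[qcol]] < 0.05 &
                       evidence$orphan]
  })
  names(cons_sets) <- datasets
  list(
    n_genes = nrow(evidence),
    class_counts = as.list(table(evidence$class)),
    n_orphan = sum(evidence$orphan),
    n_expressed = sum(evidence$expressed),
    n_robust = sum(evidence$robust),
    n_zero_everywhere = sum(evidence$zero_everywhere),
    n_peptide = sum(evidence$peptide_hit),
    venn_liberal = if (length(datasets) == 3) venn3(lib_sets) else NULL,
    venn_conservative = if (length(datasets) == 3) venn3(cons_sets) else NULL,
    n_candidates = length(candidates),
    candidates = candidates,
    omega_curves = omega_cumulative(selection))
}
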