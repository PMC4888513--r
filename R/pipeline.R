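# End-to-end orchestration: from on-disk inputs to the classified
# evidence table, selection results and run summary.

read_pipeline_inputs <- function(input_dir) {
  p <- function(f) {
    path <- file.path(input_dir, f)
    if (!file.exists(path)) stop("missing input file: ", path)
    path
  }
  genes <- read_gff3(p("genes.gff3"), p("genome.fasta"))
  genome <- read_fasta(p("genome.fasta"))
  list(
    genes = genes,
    contigs = tibble::tibble(contig = genome$id, length = nchar(genome$seq)),
    labels = read_labels(p("labels.tsv")),
    prot_ppa = read_fasta(p("proteins_ppa.fasta")),
    prot_pex = read_fasta(p("proteins_pex.fasta")),
    cds_ppa = read_fasta(p("cds_ppa.fasta")),
    cds_pex = read_fasta(p("cds_pex.fasta")),
    expression = read_fpkm(p("fpkm.tsv")),
    de_sets = read_de_sets(p("de_sets.tsv")),
    peptides = dplyr::rename(read_fasta(p("peptides.fasta")), peptide_id = "id"),
    variants_a1 = read_variants(p("variants_A1.tsv")),
    variants_a2 = read_variants(p("variants_A2.tsv")))
}

# align one cluster's members and back-translate; NULL + reason on failure
cluster_codon_alignment <- function(member_ids, proteins, cds, cfg) {
  prot <- tibble::tibble(id = member_ids, seq = proteins[member_ids])
  if (any(is.na(prot$seq))) return(list(alignment = NULL, reason = "missing_protein"))
  if (nrow(prot) < 2) return(list(alignment = NULL, reason = "singleton"))
  msa <- progressive_align(prot, gap_open = cfg$gap_open,
                           gap_extend = cfg$gap_extend)
  aln <- tryCatch(backtranslate(msa, cds[member_ids]),
                  orphanevo_backtranslate_error = function(e) e)
  if (inherits(aln, "condition")) {
    return(list(alignment = NULL, reason = aln$reason %||% conditionMessage(aln)))
  }
  if (!filter_min_length(aln, cfg$min_alignment_nt)) {
    return(list(alignment = NULL, reason = "below_min_length"))
  }
  list(alignment = aln, reason = NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the evidence-integration pipeline
#'
#' Reads a dataset directory (the layout written by [generate_dataset()]),
#' clusters the two proteomes, builds the ortholog / paralog /
#' lineage-pair datasets, aligns and fits every qualifying cluster,
#' gathers expression and peptide evidence, classifies every
#' focal-species gene and writes result tables.
#'
#' @param input_dir Directory with the input files.
#' @param config A [run_config()].
#' @param out_dir Optional output directory for result tables
#'   (`evidence.tsv`, `selection.tsv`, `clusters.txt`, `exclusions.tsv`,
#'   `drops.tsv`, `saturation.tsv`, `de_saturation.tsv`, `summary.json`).
#' @param stage One of `"all"`, `"cluster"`, `"express"`, `"peptides"`:
#'   how far to run.
#' @return A list with the computed tables (see Details in the package
#'   vignette).
#' @export
run_pipeline <- function(input_dir, config = run_config(), out_dir = NULL,
                         stage = c("all", "cluster", "express", "peptides")) {
  stage <- match.arg(stage)
  cfg <- config
  inp <- read_pipeline_inputs(input_dir)
  out <- list(config = cfg, genes = inp$genes)

  if (stage %in% c("express")) {
    out$expression_flags <- expressed_flags(inp$expression,
                                            c(cfg$fpkm_expressed, cfg$fpkm_robust))
    out$saturation <- saturation(inp$expression, inp$labels,
                                 c(cfg$fpkm_expressed, cfg$fpkm_robust),
                                 n_perm = cfg$n_perm, seed = cfg$seed)
    out$de_saturation <- de_saturation(inp$de_sets, inp$labels,
                                       n_perm = cfg$n_perm, seed = cfg$seed)
    if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
    return(out)
  }
  if (stage == "peptides") {
    pep <- match_peptides(inp$peptides, inp$prot_ppa)
    out$peptide_hits <- pep$hits
    out$peptide_flags <- pep$gene_flags
    if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
    return(out)
  }

  ## clustering ------------------------------------------------------------
  proteins <- dplyr::bind_rows(
    dplyr::mutate(inp$prot_ppa, id = paste0("ppa|", .data$id)),
    dplyr::mutate(inp$prot_pex, id = paste0("pex|", .data$id)))
  graph <- build_graph(proteins, min_normalized_score = cfg$edge_threshold,
                       kmer_k = cfg$kmer_k, gap_open = cfg$gap_open,
                       gap_extend = cfg$gap_extend)
  clusters <- markov_cluster(graph, inflation = cfg$inflation,
                             expansion = cfg$expansion, prune = cfg$mcl_prune,
                             max_iter = cfg$mcl_max_iter)
  cat_res <- categorize_clusters(clusters, inp$labels)
  out$graph_n_edges <- nrow(graph$edges)
  out$clusters <- clusters
  out$cluster_records <- cat_res$records
  out$exclusions <- cat_res$exclusions
  if (stage == "cluster") {
    if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
    return(out)
  }

  ## codon alignments and selection fits -----------------------------------
  cds <- c(stats::setNames(inp$cds_ppa$seq, paste0("ppa|", inp$cds_ppa$id)),
           stats::setNames(inp$cds_pex$seq, paste0("pex|", inp$cds_pex$id)))
  prot_named <- stats::setNames(proteins$seq, proteins$id)
  valid_ppa <- paste0("ppa|", inp$genes$gene_id[inp$genes$valid])
  recs <- out$cluster_records

  drops <- list()
  collect_alignments <- function(rec_subset, members_col) {
    alns <- list()
    for (i in seq_len(nrow(rec_subset))) {
      cid <- rec_subset$cluster_id[i]
      mem <- rec_subset[[members_col]][[i]]
      mem <- mem[mem %in% c(valid_ppa, names(prot_named)[startsWith(names(prot_named), "pex|")])]
      if (length(mem) < 2) {
        drops[[length(drops) + 1]] <<- tibble::tibble(
          cluster_id = cid, reason = "fewer_than_two_valid_members")
        next
      }
      res <- cluster_codon_alignment(mem, prot_named, cds, cfg)
      if (is.null(res$alignment)) {
        drops[[length(drops) + 1]] <<- tibble::tibble(
          cluster_id = cid, reason = res$reason)
      } else {
        alns[[cid]] <- res$alignment
      }
    }
    alns
  }
  orth <- collect_alignments(recs[recs$in_ortholog, ], "members")
  para <- collect_alignments(recs[recs$in_paralog, ], "paralog_members")

  clade_pairs <- build_clade_pairs(inp$genes[inp$genes$valid, ],
                                   inp$variants_a1, inp$variants_a2)
  clade_alns <- list()
  for (i in seq_len(nrow(clade_pairs))) {
    aln <- tibble::tibble(
      id = c("A1", "A2"),
      seq = c(strip_terminal_stop(clade_pairs$seq_a1[i]),
              strip_terminal_stop(clade_pairs$seq_a2[i])))
    if (!filter_min_length(aln, cfg$min_alignment_nt)) {
      drops[[length(drops) + 1]] <- tibble::tibble(
        cluster_id = clade_pairs$gene_id[i], reason = "below_min_length")
      next
    }
    clade_alns[[clade_pairs$gene_id[i]]] <- aln
  }
  out$drops <- if (length(drops) > 0) dplyr::bind_rows(drops) else
    tibble::tibble(cluster_id = character(), reason = character())

  sel_orth <- run_dataset(orth, "ortholog", cfg$omega_bounds)
  sel_para <- run_dataset(para, "paralog", cfg$omega_bounds)
  sel_clade <- run_dataset(clade_alns, "cladeAB", cfg$omega_bounds)
  lab <- stats::setNames(inp$labels$label, inp$labels$gene_id)
  cat_of <- stats::setNames(recs$category, recs$cluster_id)
  selection <- dplyr::bind_rows(sel_orth, sel_para, sel_clade) |>
    dplyr::mutate(category = dplyr::case_when(
      .data$dataset == "cladeAB" ~ unname(lab[.data$cluster_id]),
      TRUE ~ unname(cat_of[.data$cluster_id])))
  out$selection <- selection

  ## per-gene dataset memberships ------------------------------------------
  mem_rows <- list()
  for (i in seq_len(nrow(recs))) {
    toks <- split_member_token(recs$members[[i]])
    ppa <- toks$gene_id[toks$species == "ppa"]
    if (recs$in_ortholog[i] && recs$cluster_id[i] %in% names(orth)) {
      mem_rows[[length(mem_rows) + 1]] <- tibble::tibble(
        gene_id = ppa, dataset = "ortholog", cluster_id = recs$cluster_id[i])
    }
    if (recs$in_paralog[i] && recs$cluster_id[i] %in% names(para)) {
      mem_rows[[length(mem_rows) + 1]] <- tibble::tibble(
        gene_id = ppa, dataset = "paralog", cluster_id = recs$cluster_id[i])
    }
  }
  mem_rows[[length(mem_rows) + 1]] <- tibble::tibble(
    gene_id = names(clade_alns), dataset = "cladeAB",
    cluster_id = names(clade_alns))
  memberships <- dplyr::bind_rows(mem_rows)
  out$memberships <- memberships

  ## expression, peptides, integration -------------------------------------
  expr_flags <- expressed_flags(inp$expression,
                                c(cfg$fpkm_expressed, cfg$fpkm_robust))
  out$expression_flags <- expr_flags
  out$saturation <- saturation(inp$expression, inp$labels,
                               c(cfg$fpkm_expressed, cfg$fpkm_robust),
                               n_perm = cfg$n_perm, seed = cfg$seed)
  out$de_saturation <- de_saturation(inp$de_sets, inp$labels,
                                     n_perm = cfg$n_perm, seed = cfg$seed)
  pep <- match_peptides(inp$peptides, inp$prot_ppa)
  out$peptide_hits <- pep$hits

  sel_ev <- gene_selection_evidence(selection, memberships,
                                    omega_liberal = cfg$omega_liberal,
                                    alpha = cfg$alpha)
  pct <- contig_percentile(inp$contigs,
                           dplyr::select(inp$genes, "gene_id", "contig"))
  evidence <- inp$genes |>
    dplyr::select("gene_id", "contig", "n_exons", "transcript_length",
                  "gc", "valid") |>
    dplyr::left_join(dplyr::select(inp$labels, "gene_id", "label", "orphan"),
                     by = "gene_id") |>
    dplyr::left_join(expr_flags, by = "gene_id") |>
    dplyr::left_join(pct, by = "gene_id") |>
    dplyr::mutate(
      in_de_set = .data$gene_id %in% inp$de_sets$gene_id,
      peptide_hit = .data$gene_id %in% pep$hits$protein_id) |>
    dplyr::left_join(sel_ev, by = "gene_id") |>
    dplyr::mutate(
      n_datasets = tidyr::replace_na(.data$n_datasets, 0L),
      n_liberal_datasets = tidyr::replace_na(.data$n_liberal_datasets, 0L),
      liberal = tidyr::replace_na(.data$liberal, FALSE),
      conservative = tidyr::replace_na(.data$conservative, FALSE),
      coverage = tidyr::replace_na(.data$coverage, "none"))
  evidence <- classify_genes(evidence, ncrna_rule = cfg$ncrna_rule)
  out$evidence <- evidence
  out$candidates <- select_validation_candidates(evidence,
                                                 min_exons = cfg$min_candidate_exons)
  out$feature_stats <- feature_stats(evidence)
  out$summary <- summarize_run(evidence, selection, out$candidates)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # atomic writes: emit to a temporary name, then rename into place
  atomically <- function(f, writer) {
    path <- file.path(out_dir, f)
    tmp <- paste0(path, ".tmp")
    writer(tmp)
    file.rename(tmp, path)
  }
  if (!is.null(out$evidence)) {
    atomically("evidence.tsv", function(f)
      readr::write_tsv(dplyr::select(out$evidence, -dplyr::any_of("exons")), f))
  }
  if (!is.null(out$selection)) {
    atomically("selection.tsv", function(f) readr::write_tsv(out$selection, f))
  }
  if (!is.null(out$clusters)) {
    atomically("clusters.txt", function(f) write_groups(out$clusters, f))
  }
  if (!is.null(out$exclusions)) {
    atomically("exclusions.tsv", function(f) readr::write_tsv(out$exclusions, f))
  }
  if (!is.null(out$drops)) {
    atomically("drops.tsv", function(f) readr::write_tsv(out$drops, f))
  }
  if (!is.null(out$saturation)) {
    atomically("saturation.tsv", function(f) readr::write_tsv(out$saturation, f))
  }
  if (!is.null(out$de_saturation)) {
    atomically("de_saturation.tsv", function(f)
      readr::write_tsv(out$de_saturation, f))
  }
  if (!is.null(out$summary)) {
    atomically("summary.json", function(f)
      jsonlite::write_json(out$summary, f, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, na = "null"))
  }
  # figures for the report
  save_plot <- function(f, plot) {
    tryCatch(suppressMessages(ggplot2::ggsave(
      file.path(out_dir, f), plot, width = 7, height = 5, dpi = 120)),
      error = function(e) invisible(NULL))
  }
  if (!is.null(out$saturation)) {
    save_plot("saturation.png", plot_saturation(out$saturation))
  }
  if (!is.null(out$summary)) {
    save_plot("omega_cumulative.png",
              plot_omega_cumulative(out$summary$omega_curves))
  }
  if (!is.null(out$evidence)) {
    save_plot("class_features.png", plot_class_features(out$evidence))
  }
  invisible(out_dir)
}
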