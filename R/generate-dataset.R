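# Full synthetic dataset with known ground truth: a two-species gene
# catalogue evolved under known dN/dS, a focal-species genome with exon
# structure, an FPKM matrix, DE gene sets, peptides, and fixed-difference
# variant tables for two intra-species clades.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# split L nucleotides into n exon pieces, each >= min_len
split_exon_lengths <- function(L, n, min_len = 10L) {
  n <- max(1L, min(n, L %/% min_len))
  if (n == 1) return(L)
  extra <- L - n * min_len
  cuts <- sort(sample.int(extra + n - 1, n - 1))
  sizes <- diff(c(0L, cuts, extra + n)) - 1L + min_len
  stopifnot(sum(sizes) == L, all(sizes >= min_len))
  sizes
}

# newick for a cluster of 1-2 focal genes plus optionally one sister gene
cluster_newick <- function(ppa_ids, pex_id, t_inter, t_par) {
  if (length(ppa_ids) == 1 && is.null(pex_id)) {
    return(NULL)  # singleton: no tree
  }
  if (length(ppa_ids) == 1) {
    return(sprintf("(%s:%g,%s:%g);", ppa_ids[1], t_inter / 2, pex_id, t_inter / 2))
  }
  if (is.null(pex_id)) {
    return(sprintf("(%s:%g,%s:%g);", ppa_ids[1], t_par / 2, ppa_ids[2], t_par / 2))
  }
  x <- t_par / 2
  y <- max(0.01, (t_inter - t_par) / 2)
  z <- max(0.01, t_inter - x - y)
  sprintf("((%s:%g,%s:%g):%g,%s:%g);", ppa_ids[1], x, ppa_ids[2], x, y, pex_id, z)
}

#' Generate a complete synthetic input dataset with known truth
#'
#' Produces everything the downstream pipeline consumes: a focal-species
#' gene catalogue (genome FASTA + GFF3 with exon structure), CDS and
#' protein FASTA for both species, orphan/conserved labels, an FPKM
#' expression matrix, differentially-expressed gene sets, a peptide list
#' with decoys, fixed-difference variant tables for two intra-species
#' clades, the true homology clusters, and a per-gene truth table (true
#' class, cluster, dN/dS).  All randomness derives from `config$seed`;
#' identical configurations give byte-identical files.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Optional directory; when given, all files are written
#'   there (see Details) and paths returned in `$paths`.
#' @return A list with tibbles `genes` (focal gene models), `pex_genes`,
#'   `labels`, `clusters_true`, `truth`, `expression`, `de_sets`,
#'   `peptides`, `variants` (list with `A1`, `A2`), and `paths`.
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  validate_sim_config(config)
  cfg <- config
  withr::with_seed(cfg$seed, generate_dataset_impl(cfg, out_dir))
}

draw_law <- function(law, n) {
  if (is.function(law)) law(n) else rep(law, n)
}

generate_dataset_impl <- function(cfg, out_dir) {
  n_ppa <- cfg$n_conserved + cfg$n_orphan
  classes <- character(n_ppa)
  classes[seq_len(cfg$n_conserved)] <- "conserved"
  if (cfg$n_orphan > 0) {
    k <- floor(cfg$orphan_class_fractions * cfg$n_orphan)
    k["coding"] <- cfg$n_orphan - sum(k[c("ncrna", "artifact")])
    orphan_classes <- sample(rep(names(k), k))
    classes[cfg$n_conserved + seq_len(cfg$n_orphan)] <- orphan_classes
  }
  gene_id <- sprintf("g%04d", seq_len(n_ppa))
  label <- ifelse(classes == "conserved", "conserved", "orphan")

  ## ---- cluster assembly -------------------------------------------------
  # hybrid clusters pair a conserved with a coding orphan gene
  hybrid_cons <- hybrid_orph <- integer(0)
  n_hyb <- min(cfg$n_hybrid, cfg$n_conserved, sum(classes == "coding"))
  if (n_hyb > 0) {
    hybrid_cons <- sample(which(classes == "conserved"), n_hyb)
    hybrid_orph <- sample(which(classes == "coding"), n_hyb)
  }
  in_hybrid <- c(hybrid_cons, hybrid_orph)

  # paralog pairing within class among the remaining genes
  paired_with <- rep(NA_integer_, n_ppa)
  for (cl in names(cfg$paralog_fraction)) {
    pool <- setdiff(which(classes == cl), in_hybrid)
    n_pairs <- floor(length(pool) * cfg$paralog_fraction[[cl]] / 2)
    if (n_pairs > 0) {
      chosen <- sample(pool, 2 * n_pairs)
      a <- chosen[seq_len(n_pairs)]
      b <- chosen[n_pairs + seq_len(n_pairs)]
      paired_with[a] <- b
      paired_with[b] <- a
    }
  }

  # build cluster member lists
  cluster_members <- list()   # list of integer vectors (ppa indices)
  cluster_class <- character(0)
  seen <- rep(FALSE, n_ppa)
  for (h in seq_along(hybrid_cons)) {
    cluster_members[[length(cluster_members) + 1L]] <-
      c(hybrid_cons[h], hybrid_orph[h])
    cluster_class <- c(cluster_class, "conserved")  # sequence law of the anchor
    seen[c(hybrid_cons[h], hybrid_orph[h])] <- TRUE
  }
  for (i in seq_len(n_ppa)) {
    if (seen[i]) next
    mem <- i
    if (!is.na(paired_with[i])) {
      mem <- sort(c(i, paired_with[i]))
      seen[paired_with[i]] <- TRUE
    }
    seen[i] <- TRUE
    cluster_members[[length(cluster_members) + 1L]] <- mem
    cluster_class <- c(cluster_class, classes[mem[1]])
  }
  n_clusters <- length(cluster_members)

  # sister-species ortholog presence per cluster
  has_pex <- vapply(seq_len(n_clusters), function(ci) {
    stats::runif(1) < cfg$ortholog_fraction[[cluster_class[ci]]]
  }, logical(1))
  # hybrid clusters always get a sister member so they would qualify as
  # ortholog clusters were they not excluded
  if (n_hyb > 0) has_pex[seq_len(n_hyb)] <- TRUE

  t_inter <- 3 * cfg$interspecies_divergence    # codon-site units
  t_intra <- 3 * cfg$intraclade_divergence

  ## ---- sequence simulation per cluster ---------------------------------
  cluster_omega <- numeric(n_clusters)
  for (cl in unique(cluster_class)) {
    idx <- which(cluster_class == cl)
    cluster_omega[idx] <- draw_law(cfg$omega_law[[cl]], length(idx))
  }
  cluster_len <- integer(n_clusters)
  for (cl in unique(cluster_class)) {
    idx <- which(cluster_class == cl)
    cluster_len[idx] <- draw_law(cfg$codon_length_law[[cl]], length(idx))
  }
  cluster_seed <- sample.int(.Machine$integer.max - 1L, n_clusters + n_ppa + cfg$n_pex_specific)

  cds <- character(n_ppa)
  pex_counter <- 0L
  pex_id <- character(0); pex_cds <- character(0); pex_cluster <- integer(0)
  cluster_tree <- character(n_clusters)
  gene_cluster <- integer(n_ppa)

  for (ci in seq_len(n_clusters)) {
    mem <- cluster_members[[ci]]
    gene_cluster[mem] <- ci
    xid <- NULL
    if (has_pex[ci]) {
      pex_counter <- pex_counter + 1L
      xid <- sprintf("x%04d", pex_counter)
    }
    t_par <- t_inter * stats::runif(1, 0.4, 1.2)
    nwk <- cluster_newick(gene_id[mem], xid, t_inter, t_par)
    if (is.null(nwk)) {   # singleton: draw a lone sequence from the root law
      states <- withr::with_seed(cluster_seed[ci],
        sample.int(61, cluster_len[ci], replace = TRUE))
      cds[mem] <- paste0(codon_tables$sense[states], collapse = "")
      cluster_tree[ci] <- NA_character_
    } else {
      tr <- ape::read.tree(text = nwk)
      aln <- simulate_codon_msa(tr, omega = cluster_omega[ci], kappa = cfg$kappa,
                                n_codons = cluster_len[ci],
                                seed = cluster_seed[ci])
      for (j in seq_along(mem)) {
        cds[mem[j]] <- aln$seq[aln$id == gene_id[mem[j]]]
      }
      if (!is.null(xid)) {
        pex_id <- c(pex_id, xid)
        pex_cds <- c(pex_cds, aln$seq[aln$id == xid])
        pex_cluster <- c(pex_cluster, ci)
      }
      cluster_tree[ci] <- nwk
    }
  }

  # sister-species-specific genes (no focal member)
  if (cfg$n_pex_specific > 0) {
    for (k in seq_len(cfg$n_pex_specific)) {
      pex_counter <- pex_counter + 1L
      len <- draw_law(cfg$codon_length_law$conserved, 1)
      states <- withr::with_seed(cluster_seed[n_clusters + n_ppa + k],
        sample.int(61, len, replace = TRUE))
      pex_id <- c(pex_id, sprintf("x%04d", pex_counter))
      pex_cds <- c(pex_cds, paste0(codon_tables$sense[states], collapse = ""))
      pex_cluster <- c(pex_cluster, NA_integer_)
    }
  }

  # append terminal stops; proteins exclude the terminal stop
  stops <- sample(STOP_CODONS, n_ppa, replace = TRUE)
  cds_full <- paste0(cds, stops)
  protein <- translate_cds(cds)
  pex_cds_full <- paste0(pex_cds, sample(STOP_CODONS, length(pex_cds), replace = TRUE))
  pex_protein <- translate_cds(pex_cds)

  ## ---- genome layout ----------------------------------------------------
  n_exons <- integer(n_ppa)
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    n_exons[idx] <- pmax(1L, draw_law(cfg$exon_law[[cl]], length(idx)))
  }
  # contig weights: long-tailed so a few large contigs hold most genes
  w <- exp(stats::rnorm(cfg$n_contigs, 0, 1.5))
  gene_contig <- sample.int(cfg$n_contigs, n_ppa, replace = TRUE, prob = w)
  strand <- sample(c("+", "-"), n_ppa, replace = TRUE)

  contig_seq <- vector("list", cfg$n_contigs)
  gene_exons <- vector("list", n_ppa)   # per gene: tibble(start, end)
  cds_map <- vector("list", n_ppa)      # genome coordinate of CDS position i
  for (k in seq_len(cfg$n_contigs)) {
    genes_here <- which(gene_contig == k)
    pos <- sample(100:400, 1)
    pieces <- list(paste0(sample(c("A", "C", "G", "T"), pos, replace = TRUE), collapse = ""))
    for (i in genes_here) {
      L <- nchar(cds_full[i])
      ex_len <- split_exon_lengths(L, n_exons[i])
      n_exons[i] <- length(ex_len)
      intr <- if (length(ex_len) > 1) sample(40:300, length(ex_len) - 1, replace = TRUE) else integer(0)
      # genomic layout left to right
      starts <- pos + 1 + cumsum(c(0, head(ex_len, -1) + intr))
      ends <- starts + ex_len - 1
      gene_exons[[i]] <- tibble::tibble(start = starts, end = ends)
      gpos <- unlist(lapply(seq_along(starts), function(e) starts[e]:ends[e]))
      if (strand[i] == "+") {
        cds_map[[i]] <- gpos
        placed <- strsplit(cds_full[i], "")[[1]]
      } else {
        cds_map[[i]] <- rev(gpos)
        placed <- rev(strsplit(complement_base(cds_full[i]), "")[[1]])
      }
      gene_len <- max(ends) - pos
      block <- sample(c("A", "C", "G", "T"), gene_len, replace = TRUE)
      block[gpos - pos] <- placed
      pieces[[length(pieces) + 1L]] <- paste0(block, collapse = "")
      pos <- max(ends) + sample(100:500, 1)
      pieces[[length(pieces) + 1L]] <- paste0(
        sample(c("A", "C", "G", "T"), pos - max(ends), replace = TRUE), collapse = "")
    }
    contig_seq[[k]] <- paste0(unlist(pieces), collapse = "")
  }
  contig_name <- sprintf("Contig%d", seq_len(cfg$n_contigs))
  names(contig_seq) <- contig_name

  ## ---- clade alleles and variant tables ---------------------------------
  clade_tree <- ape::read.tree(text = sprintf("(A1:%g,A2:%g);", t_intra / 2, t_intra / 2))
  var_rows <- list(A1 = list(), A2 = list())
  for (i in seq_len(n_ppa)) {
    aln <- simulate_codon_msa(clade_tree, omega = cluster_omega[gene_cluster[i]],
                              kappa = cfg$kappa, seed = cluster_seed[n_clusters + i],
                              root_seq = cds[i])
    ref_chars <- strsplit(cds[i], "")[[1]]
    for (clade in c("A1", "A2")) {
      allele <- strsplit(aln$seq[aln$id == clade], "")[[1]]
      d <- which(allele != ref_chars)
      if (length(d) == 0) next
      gpos <- cds_map[[i]][d]
      if (strand[i] == "+") {
        ref_a <- ref_chars[d]; alt_a <- allele[d]
      } else {
        ref_a <- complement_base(ref_chars[d]); alt_a <- complement_base(allele[d])
      }
      var_rows[[clade]][[length(var_rows[[clade]]) + 1L]] <- tibble::tibble(
        contig = contig_name[gene_contig[i]], pos = gpos, ref = ref_a, alt = alt_a)
    }
  }
  variants <- lapply(var_rows, function(x) {
    if (length(x) == 0) {
      tibble::tibble(contig = character(), pos = integer(),
                     ref = character(), alt = character())
    } else {
      dplyr::arrange(dplyr::bind_rows(x), .data$contig, .data$pos)
    }
  })

  ## ---- expression matrix -------------------------------------------------
  fpkm <- matrix(0, nrow = n_ppa, ncol = cfg$n_samples,
                 dimnames = list(gene_id, sprintf("S%02d", seq_len(cfg$n_samples))))
  for (i in seq_len(n_ppa)) {
    cl <- classes[i]
    if (stats::runif(1) < cfg$expressed_fraction[[cl]]) {
      k <- 1 + stats::rbinom(1, cfg$n_samples - 1, 0.5)
      cols <- sample.int(cfg$n_samples, k)
      fpkm[i, cols] <- round(stats::rlnorm(k, cfg$fpkm_meanlog[[cl]], cfg$fpkm_sdlog[[cl]]), 3)
    }
  }

  ## ---- DE gene sets ------------------------------------------------------
  expressed_any <- rowSums(fpkm) > 0
  de_sets <- dplyr::bind_rows(lapply(seq_len(cfg$n_de_sets), function(s) {
    p <- ifelse(label == "conserved", cfg$de_rate[["conserved"]], cfg$de_rate[["orphan"]])
    inc <- expressed_any & stats::runif(n_ppa) < p
    tibble::tibble(set_id = sprintf("DE%d", s), gene_id = gene_id[inc])
  }))

  ## ---- peptides ----------------------------------------------------------
  pep_rows <- list()
  for (i in seq_len(n_ppa)) {
    cl <- classes[i]
    if (cfg$peptide_coverage[[cl]] > 0 && stats::runif(1) < cfg$peptide_coverage[[cl]]) {
      n_pep <- sample(1:3, 1)
      for (p in seq_len(n_pep)) {
        len <- sample(7:25, 1)
        if (nchar(protein[i]) < len) len <- nchar(protein[i])
        start <- sample.int(nchar(protein[i]) - len + 1, 1)
        pep_rows[[length(pep_rows) + 1L]] <- substr(protein[i], start, start + len - 1)
      }
    }
  }
  peptide_seq <- unlist(pep_rows)
  n_decoy <- ceiling(0.1 * length(peptide_seq))
  decoys <- character(0)
  if (n_decoy > 0 && length(peptide_seq) > 0) {
    src <- sample(peptide_seq, n_decoy, replace = TRUE)
    all_prot <- c(protein, pex_protein)
    decoys <- vapply(src, function(s) {
      for (try in 1:20) {
        d <- paste0(sample(strsplit(s, "")[[1]]), collapse = "")
        if (!any(stringr::str_detect(all_prot, stringr::fixed(d)))) return(d)
      }
      paste0(paste0(rep("W", 3), collapse = ""), d)  # force a miss
    }, character(1), USE.NAMES = FALSE)
  }
  peptides <- tibble::tibble(
    peptide_id = c(sprintf("pep%04d", seq_along(peptide_seq)),
                   sprintf("decoy%03d", seq_along(decoys))),
    seq = c(peptide_seq, decoys),
    decoy = c(rep(FALSE, length(peptide_seq)), rep(TRUE, length(decoys)))
  )

  ## ---- assemble outputs --------------------------------------------------
  contig_len <- nchar(unlist(contig_seq))
  genes <- tibble::tibble(
    gene_id = gene_id, species = "ppa", contig = contig_name[gene_contig],
    strand = strand, n_exons = n_exons,
    cds = cds_full, protein = protein,
    transcript_length = nchar(cds_full),
    orphan = label == "orphan", label = label,
    exons = gene_exons, gc = vapply(cds_full, gc_fraction, numeric(1), USE.NAMES = FALSE)
  )
  pex_genes <- tibble::tibble(
    gene_id = pex_id, species = "pex", cds = pex_cds_full, protein = pex_protein,
    cluster_index = pex_cluster
  )

  # cluster ids named by smallest member id (deterministic)
  all_members <- lapply(seq_len(n_clusters), function(ci) {
    m <- paste0("ppa|", gene_id[cluster_members[[ci]]])
    if (has_pex[ci]) m <- c(m, paste0("pex|", pex_id[match(ci, pex_cluster)]))
    sort(m)
  })
  # pex-specific singleton clusters
  pex_only <- which(is.na(pex_cluster))
  all_members <- c(all_members, lapply(pex_only, function(k) paste0("pex|", pex_id[k])))
  anchor <- vapply(all_members, function(m) sort(sub("^...\\|", "", m))[1], character(1))
  ord <- order(anchor)
  cluster_id_of <- integer(length(all_members)); cluster_id_of[ord] <- seq_along(ord)
  cl_ids <- sprintf("cl%04d", cluster_id_of)
  clusters_true <- tibble::tibble(
    cluster_id = cl_ids,
    members = all_members,
    omega = c(cluster_omega, rep(NA_real_, length(pex_only))),
    tree = c(cluster_tree, rep(NA_character_, length(pex_only)))
  ) |> dplyr::arrange(.data$cluster_id)

  truth <- tibble::tibble(
    gene_id = gene_id, class = classes,
    cluster_id = cl_ids[gene_cluster],
    omega = cluster_omega[gene_cluster]
  )

  expression <- tibble::as_tibble(fpkm, rownames = "gene_id")
  labels <- tibble::tibble(gene_id = gene_id, label = label)

  out <- list(
    config = cfg, genes = genes, pex_genes = pex_genes, labels = labels,
    clusters_true = clusters_true, truth = truth, expression = expression,
    de_sets = de_sets, peptides = peptides, variants = variants,
    contigs = tibble::tibble(contig = contig_name, length = contig_len),
    contig_seq = unlist(contig_seq), paths = NULL
  )
  if (!is.null(out_dir)) out$paths <- write_dataset(out, out_dir)
  out
}

#' Write a generated dataset to disk
#'
#' Emits genome FASTA, GFF3, per-species CDS/protein FASTA, label TSV,
#' FPKM matrix, DE sets, peptide FASTA, clade variant TSVs, true groups
#' file and a JSON truth table.
#'
#' @param ds A dataset from [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of file paths (invisibly).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  paths <- c(
    genome = p("genome.fasta"), gff = p("genes.gff3"),
    cds_ppa = p("cds_ppa.fasta"), prot_ppa = p("proteins_ppa.fasta"),
    cds_pex = p("cds_pex.fasta"), prot_pex = p("proteins_pex.fasta"),
    labels = p("labels.tsv"), fpkm = p("fpkm.tsv"), de = p("de_sets.tsv"),
    peptides = p("peptides.fasta"), var_a1 = p("variants_A1.tsv"),
    var_a2 = p("variants_A2.tsv"), groups = p("clusters_true.txt"),
    truth = p("truth.json")
  )
  write_fasta(tibble::tibble(id = names(ds$contig_seq), seq = unname(ds$contig_seq)),
              paths["genome"])
  write_gff3(ds$genes, paths["gff"])
  write_fasta(dplyr::select(ds$genes, id = "gene_id", seq = "cds"), paths["cds_ppa"])
  write_fasta(dplyr::select(ds$genes, id = "gene_id", seq = "protein"), paths["prot_ppa"])
  write_fasta(dplyr::select(ds$pex_genes, id = "gene_id", seq = "cds"), paths["cds_pex"])
  write_fasta(dplyr::select(ds$pex_genes, id = "gene_id", seq = "protein"), paths["prot_pex"])
  readr::write_tsv(ds$labels, paths["labels"])
  readr::write_tsv(ds$expression, paths["fpkm"])
  readr::write_tsv(ds$de_sets, paths["de"])
  write_fasta(dplyr::select(ds$peptides, id = "peptide_id", seq = "seq"), paths["peptides"])
  readr::write_tsv(ds$variants$A1, paths["var_a1"])
  readr::write_tsv(ds$variants$A2, paths["var_a2"])
  write_groups(ds$clusters_true, paths["groups"])
  jsonlite::write_json(
    list(genes = ds$truth,
         clusters = dplyr::select(ds$clusters_true, "cluster_id", "omega", "tree")),
    paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(paths)
}
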