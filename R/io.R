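# Readers and writers for every on-disk format.  All coordinates are
# 1-based inclusive on disk (GFF3, variant tables) and are converted to
# internal representations exactly once, at parse time.

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header) and `seq` (uppercased).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) stop("empty FASTA record: ", ids[!nzchar(seqs)][1])
  tibble::tibble(id = ids, seq = unname(seqs))
}

#' Write a FASTA file
#'
#' @param records Tibble/data frame with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  if (anyDuplicated(records$id)) {
    stop("duplicate FASTA id: ", records$id[duplicated(records$id)][1])
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    s <- records$seq[i]
    n <- nchar(s)
    starts <- seq(1, max(n, 1), by = width)
    writeLines(c(paste0(">", records$id[i]),
                 substring(s, starts, pmin(starts + width - 1, n))), con)
  }
  invisible(path)
}

# phase of CDS pieces given their lengths in translation order
cds_phases <- function(lengths) {
  c(0, cumsum(lengths)[-length(lengths)]) %% 3
}

#' Write gene models as GFF3
#'
#' One gene/mRNA pair per gene with exon and CDS features (here exons and
#' CDS coincide: models are CDS-only).  Coordinates 1-based inclusive.
#'
#' @param genes Gene-model tibble with columns `gene_id`, `contig`,
#'   `strand`, `exons` (list of tibbles with `start`, `end`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- g$exons[[1]]
    gid <- g$gene_id; tid <- paste0(gid, ".t1")
    lines <- c(
      sprintf("%s\torphanevo\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$contig, min(ex$start), max(ex$end), g$strand, gid),
      sprintf("%s\torphanevo\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$contig, min(ex$start), max(ex$end), g$strand, tid, gid)
    )
    # translation order: ascending for +, descending for -
    ord <- if (g$strand == "+") order(ex$start) else order(-ex$start)
    ph <- cds_phases(ex$end[ord] - ex$start[ord] + 1)
    lines <- c(lines,
      sprintf("%s\torphanevo\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
              g$contig, ex$start, ex$end, g$strand, tid),
      sprintf("%s\torphanevo\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds-%s;Parent=%s",
              g$contig, ex$start[ord], ex$end[ord], g$strand, ph, gid, tid))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read gene models from GFF3 + genome FASTA
#'
#' Parses gene/mRNA/exon/CDS features, splices the CDS (reverse-
#' complementing minus-strand genes), translates it, and counts exons.
#' Genes whose CDS length is not a multiple of three, or that contain an
#' internal stop codon, are kept but flagged `valid = FALSE` (they are
#' excluded from selection analysis downstream).
#'
#' @param gff_path GFF3 file.
#' @param genome_path Genome FASTA with the contigs named in the GFF3.
#' @return A gene-model tibble: `gene_id`, `contig`, `strand`, `n_exons`,
#'   `cds`, `protein`, `transcript_length`, `gc`, `exons` (list-column of
#'   1-based inclusive ranges), `valid`, `flag`.
#' @export
read_gff3 <- function(gff_path, genome_path) {
  for (pth in c(gff_path, genome_path)) {
    if (!file.exists(pth)) stop("file not found: ", pth)
  }
  genome <- read_fasta(genome_path)
  gseq <- stats::setNames(genome$seq, genome$id)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  df <- as.data.frame(gr)
  mrna <- df[df$type == "mRNA", ]
  cds <- df[df$type == "CDS", ]
  exon <- df[df$type == "exon", ]
  cds$parent <- vapply(cds$Parent, function(x) x[1], character(1))
  exon$parent <- vapply(exon$Parent, function(x) x[1], character(1))
  if (anyNA(cds$parent)) stop("CDS feature without Parent")
  known <- c(mrna$ID, df$ID[df$type == "gene"])
  orphan_feat <- setdiff(c(cds$parent, exon$parent), known)
  if (length(orphan_feat) > 0) stop("orphaned features with Parent ", orphan_feat[1])

  cds_by_tx <- split(cds, cds$parent)
  exon_count <- table(exon$parent)
  rows <- lapply(seq_len(nrow(mrna)), function(i) {
    tid <- mrna$ID[i]
    gid <- vapply(mrna$Parent[i], function(x) x[1], character(1))
    cc <- cds_by_tx[[tid]]
    if (is.null(cc)) stop("mRNA without CDS: ", tid)
    cc <- cc[order(cc$start), ]
    contig <- as.character(cc$seqnames[1])
    strand <- as.character(cc$strand[1])
    if (!contig %in% names(gseq)) stop("unknown contig in GFF3: ", contig)
    spliced <- paste0(substring(gseq[[contig]], cc$start, cc$end), collapse = "")
    if (strand == "-") spliced <- revcomp(spliced)
    len <- nchar(spliced)
    flag <- ""
    valid <- TRUE
    if (len %% 3 != 0) {
      warning("CDS of ", gid, " not a multiple of 3; flagged", call. = FALSE)
      valid <- FALSE; flag <- "cds_not_mod3"
    } else if (has_internal_stop(spliced)) {
      valid <- FALSE; flag <- "internal_stop"
    }
    tibble::tibble(
      gene_id = gid, contig = contig, strand = strand,
      n_exons = max(exon_count[tid], nrow(cc), na.rm = TRUE),
      cds = spliced, transcript_length = len,
      gc = gc_fraction(spliced),
      exons = list(tibble::tibble(start = cc$start, end = cc$end)),
      valid = valid, flag = flag)
  })
  out <- dplyr::bind_rows(rows)
  # translate all in-frame models in one pass
  out$protein <- NA_character_
  ok <- out$transcript_length %% 3 == 0
  if (any(ok)) out$protein[ok] <- sub("\\*$", "", translate_cds(out$cds[ok]))
  dplyr::relocate(out, "protein", .after = "cds")
}

#' Read / write homology groups (OrthoMCL groups dialect)
#'
#' Format: one cluster per line, `clusterid: species|gene species|gene ...`.
#'
#' @param path Groups file.
#' @return A tibble with `cluster_id` and list-column `members`
#'   (`species|gene` tokens).
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ":", fixed = TRUE)
  ids <- vapply(parts, function(x) trimws(x[1]), character(1))
  members <- lapply(parts, function(x) {
    toks <- strsplit(trimws(x[2]), "\\s+")[[1]]
    bad <- toks[!grepl("^[^|]+\\|[^|]+$", toks)]
    if (length(bad) > 0) stop("malformed member token: ", bad[1])
    toks
  })
  tibble::tibble(cluster_id = ids, members = members)
}

#' @rdname read_groups
#' @param clusters Tibble with `cluster_id` and `members` list-column.
#' @export
write_groups <- function(clusters, path) {
  lines <- vapply(seq_len(nrow(clusters)), function(i) {
    paste0(clusters$cluster_id[i], ": ",
           paste(clusters$members[[i]], collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an FPKM expression matrix
#'
#' @param path TSV with a `gene_id` column and one numeric column per
#'   sample.
#' @return Tibble; negative values are rejected.
#' @export
read_fpkm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readr::read_tsv(path, show_col_types = FALSE)
  vals <- as.matrix(x[, -1])
  if (any(vals < 0)) stop("negative FPKM values in ", path)
  x
}

#' Read orphan/conserved labels
#'
#' @param path TSV with columns `gene_id`, `label`.
#' @return Tibble with an additional logical `orphan` column.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("gene_id", "label") %in% names(x)))
  bad <- setdiff(unique(x$label), c("orphan", "conserved"))
  if (length(bad) > 0) stop("unknown label: ", bad[1])
  dplyr::mutate(x, orphan = .data$label == "orphan")
}

#' Read differentially-expressed gene sets
#'
#' @param path TSV with columns `set_id`, `gene_id`.
#' @return Tibble.
#' @export
read_de_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Read a fixed-difference variant table
#'
#' Biallelic SNV rows, 1-based genome coordinates, columns
#' `contig`, `pos`, `ref`, `alt`.
#'
#' @param path TSV file.
#' @return Tibble.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("contig", "pos", "ref", "alt") %in% names(x)))
  ok <- x$ref %in% c("A", "C", "G", "T") & x$alt %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("non-SNV variant row at line ", which(!ok)[1])
  x
}
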