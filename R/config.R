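# Configuration objects: simulation conditions and pipeline thresholds.

#' Simulation configuration
#'
#' Defines the synthetic study conditions: catalogue sizes, per-class
#' distributions of the dN/dS ratio and of gene structure, the two
#' divergence scales (sister species at ~10 % nucleotide divergence,
#' intra-species lineage pair at ~1 %), expression and peptide coverage
#' per class, and the seed that fully determines every output.
#'
#' Orphan genes are planted in three ground-truth subclasses: `coding`
#' (under purifying selection, translated), `ncrna` (neutral, robustly
#' transcribed), and `artifact` (neutral, never expressed).  Conserved
#' genes form the fourth class.
#'
#' @param n_conserved,n_orphan Number of conserved / orphan focal-species
#'   genes.
#' @param orphan_class_fractions Named fractions (`coding`, `ncrna`,
#'   `artifact`) summing to 1.
#' @param omega_law Named list giving, per class, either a fixed dN/dS
#'   value or a function `function(n)` returning `n` positive draws.
#' @param kappa Transition/transversion rate ratio used in all simulations.
#' @param codon_length_law Named list of functions `function(n)` returning
#'   codons-per-gene counts (all >= 50).
#' @param exon_law Named list of functions returning exon counts (>= 1).
#' @param interspecies_divergence Expected nucleotide substitutions/site
#'   between the two species (default 0.10).
#' @param intraclade_divergence Expected nucleotide divergence between the
#'   two intra-species clades (default 0.01).
#' @param ortholog_fraction,paralog_fraction Named per-class probabilities
#'   that a gene has a sister-species ortholog / a within-species paralog.
#' @param n_samples Number of RNA-seq samples in the expression matrix.
#' @param expressed_fraction,peptide_coverage Named per-class fractions.
#' @param fpkm_meanlog,fpkm_sdlog Log-normal parameters of non-zero FPKM
#'   values, per class.
#' @param n_de_sets Number of differentially-expressed gene sets.
#' @param de_rate Named per-label (`conserved`, `orphan`) inclusion
#'   probability per DE set (conserved enriched about two-fold).
#' @param n_contigs Number of assembly contigs.
#' @param n_hybrid Number of planted hybrid clusters (one conserved + one
#'   orphan member of the focal species).
#' @param n_pex_specific Number of sister-species-specific genes without a
#'   focal-species cluster member.
#' @param seed Integer seed; identical configurations give byte-identical
#'   outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_conserved = 350,
                       n_orphan = 150,
                       orphan_class_fractions = c(coding = 0.6, ncrna = 0.2, artifact = 0.2),
                       omega_law = list(
                         conserved = function(n) pmin(exp(stats::rnorm(n, log(0.12), 0.35)), 0.8),
                         coding = function(n) pmin(exp(stats::rnorm(n, log(0.18), 0.3)), 0.8),
                         ncrna = 1,
                         artifact = 1
                       ),
                       kappa = 2,
                       codon_length_law = list(
                         conserved = function(n) 50 + stats::rnbinom(n, mu = 200, size = 3),
                         coding = function(n) 50 + stats::rnbinom(n, mu = 90, size = 2),
                         ncrna = function(n) 50 + stats::rnbinom(n, mu = 70, size = 2),
                         artifact = function(n) 50 + stats::rnbinom(n, mu = 70, size = 2)
                       ),
                       exon_law = list(
                         conserved = function(n) 1 + stats::rpois(n, 5),
                         coding = function(n) 1 + stats::rpois(n, 2),
                         ncrna = function(n) 1 + stats::rpois(n, 1),
                         artifact = function(n) 1 + stats::rpois(n, 1)
                       ),
                       interspecies_divergence = 0.10,
                       intraclade_divergence = 0.01,
                       ortholog_fraction = c(conserved = 0.9, coding = 0.85, ncrna = 0.6, artifact = 0.6),
                       paralog_fraction = c(conserved = 0.11, coding = 0.15, ncrna = 0.15, artifact = 0.15),
                       n_samples = 14,
                       expressed_fraction = c(conserved = 0.9, coding = 0.8, ncrna = 1, artifact = 0),
                       peptide_coverage = c(conserved = 0.5, coding = 0.35, ncrna = 0, artifact = 0),
                       fpkm_meanlog = c(conserved = log(20), coding = log(8), ncrna = log(40), artifact = 0),
                       fpkm_sdlog = c(conserved = 1.2, coding = 1.0, ncrna = 0.8, artifact = 0),
                       n_de_sets = 6,
                       de_rate = c(conserved = 0.08, orphan = 0.04),
                       n_contigs = 25,
                       n_hybrid = 5,
                       n_pex_specific = 10,
                       seed = 1L) {
  cfg <- list(
    n_conserved = as.integer(n_conserved), n_orphan = as.integer(n_orphan),
    orphan_class_fractions = orphan_class_fractions, omega_law = omega_law,
    kappa = kappa, codon_length_law = codon_length_law, exon_law = exon_law,
    interspecies_divergence = interspecies_divergence,
    intraclade_divergence = intraclade_divergence,
    ortholog_fraction = ortholog_fraction, paralog_fraction = paralog_fraction,
    n_samples = as.integer(n_samples),
    expressed_fraction = expressed_fraction,
    peptide_coverage = peptide_coverage,
    fpkm_meanlog = fpkm_meanlog, fpkm_sdlog = fpkm_sdlog,
    n_de_sets = as.integer(n_de_sets), de_rate = de_rate,
    n_contigs = as.integer(n_contigs),
    n_hybrid = as.integer(n_hybrid), n_pex_specific = as.integer(n_pex_specific),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_conserved >= 0, cfg$n_orphan >= 0,
    cfg$n_conserved + cfg$n_orphan > 0,
    abs(sum(cfg$orphan_class_fractions) - 1) < 1e-8,
    all(cfg$orphan_class_fractions >= 0),
    cfg$kappa > 0,
    cfg$interspecies_divergence > 0, cfg$intraclade_divergence > 0,
    all(cfg$ortholog_fraction >= 0 & cfg$ortholog_fraction <= 1),
    all(cfg$paralog_fraction >= 0 & cfg$paralog_fraction <= 1),
    cfg$n_samples >= 1,
    all(cfg$expressed_fraction >= 0 & cfg$expressed_fraction <= 1),
    all(cfg$peptide_coverage >= 0 & cfg$peptide_coverage <= 1),
    cfg$n_contigs >= 1,
    length(cfg$seed) == 1, is.finite(cfg$seed)
  )
  invisible(cfg)
}

#' Pipeline run configuration
#'
#' Thresholds of the evidence-integration pipeline.  Defaults are the
#' study's published values: expression thresholds FPKM >= 1 (expressed)
#' and FPKM >= 10 (robust), liberal purifying-selection cutoff
#' omega < 0.6, significance level 0.05 on FDR-adjusted LRT p-values, a
#' 150-nucleotide minimum codon-alignment length, and a minimum of more
#' than 2 exons for validation candidates.
#'
#' @param fpkm_expressed,fpkm_robust Inclusive FPKM thresholds.
#' @param omega_liberal Liberal dN/dS cutoff for "strong negative
#'   selection".
#' @param alpha FDR-adjusted significance level of the LRT.
#' @param min_alignment_nt Minimum codon-alignment length in nucleotide
#'   columns (gap columns included).
#' @param min_candidate_exons Validation candidates require strictly more
#'   exons than this.
#' @param ncrna_rule Which selection rule defines "no sign of strong
#'   negative selection" for the non-coding-RNA class: `"liberal"`
#'   (omega < 0.6 in any dataset) or `"conservative"`.
#' @param edge_threshold Minimum normalised local-alignment score for a
#'   similarity-graph edge.
#' @param kmer_k Word size of the shared-k-mer prescreen before alignment.
#' @param inflation,expansion,mcl_prune,mcl_max_iter Markov-clustering
#'   parameters.
#' @param gap_open,gap_extend Affine gap penalties (positive costs) used
#'   for protein alignment.
#' @param omega_bounds Search interval for the dN/dS estimate.
#' @param n_perm Number of sample-order permutations in saturation
#'   analysis.
#' @param seed Integer seed for the pipeline's stochastic steps.
#' @return A list of class `run_config`.
#' @export
run_config <- function(fpkm_expressed = 1, fpkm_robust = 10,
                       omega_liberal = 0.6, alpha = 0.05,
                       min_alignment_nt = 150, min_candidate_exons = 2,
                       ncrna_rule = c("liberal", "conservative"),
                       edge_threshold = 0.3, kmer_k = 4,
                       inflation = 2, expansion = 2,
                       mcl_prune = 1e-5, mcl_max_iter = 100,
                       gap_open = 10, gap_extend = 0.5,
                       omega_bounds = c(1e-4, 10),
                       n_perm = 10, seed = 1L) {
  ncrna_rule <- match.arg(ncrna_rule)
  cfg <- list(
    fpkm_expressed = fpkm_expressed, fpkm_robust = fpkm_robust,
    omega_liberal = omega_liberal, alpha = alpha,
    min_alignment_nt = min_alignment_nt,
    min_candidate_exons = min_candidate_exons,
    ncrna_rule = ncrna_rule,
    edge_threshold = edge_threshold, kmer_k = as.integer(kmer_k),
    inflation = inflation, expansion = expansion,
    mcl_prune = mcl_prune, mcl_max_iter = as.integer(mcl_max_iter),
    gap_open = gap_open, gap_extend = gap_extend,
    omega_bounds = omega_bounds, n_perm = as.integer(n_perm),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$fpkm_expressed > 0, cfg$fpkm_robust >= cfg$fpkm_expressed,
    cfg$omega_liberal > 0, cfg$alpha > 0, cfg$alpha < 1,
    cfg$min_alignment_nt > 0, cfg$inflation > 1,
    cfg$omega_bounds[1] > 0, cfg$omega_bounds[2] > cfg$omega_bounds[1]
  )
  structure(cfg, class = "run_config")
}

#' Read a flat key-value configuration file
#'
#' Each non-comment line is `key = value`; values are parsed as numbers
#' where possible.  Unknown keys are rejected.  Returns a [run_config()]
#' with the file's overrides applied.
#'
#' @param path Path to the configuration file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    args[[key]] <- if (is.na(num)) val else num
  }
  allowed <- names(formals(run_config))
  bad <- setdiff(names(args), allowed)
  if (length(bad) > 0) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, args)
}
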