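# Expression evidence: per-gene FPKM threshold flags and permutation-based
# saturation analysis of expressed genes and DE gene sets.

#' Per-gene expression flags
#'
#' A gene is `expressed` when its maximum FPKM over samples is at least
#' the lower threshold, `robust` at the upper threshold (both inclusive),
#' and `zero_everywhere` when every sample is exactly zero.
#'
#' @param expression Tibble with `gene_id` and one numeric column per
#'   sample.
#' @param thresholds Numeric vector `c(expressed, robust)` (default
#'   `c(1, 10)`).
#' @return Tibble: `gene_id`, `max_fpkm`, `expressed`, `robust`,
#'   `zero_everywhere`.
#' @export
expressed_flags <- function(expression, thresholds = c(1, 10)) {
  vals <- as.matrix(expression[, setdiff(names(expression), "gene_id")])
  stopifnot(all(vals >= 0))
  mx <- apply(vals, 1, max)
  tibble::tibble(
    gene_id = expression$gene_id,
    max_fpkm = mx,
    expressed = mx >= thresholds[1],
    robust = mx >= thresholds[2],
    zero_everywhere = apply(vals, 1, function(r) all(r == 0)))
}

#' Expression saturation by sample permutation
#'
#' For each of `n_perm` random permutations of the sample order, counts
#' the genes whose maximum FPKM over the first k samples reaches each
#' threshold, for k = 1 .. n_samples, per gene class; summarised as
#' minimum, quartiles, median and maximum over permutations.
#'
#' @param expression Expression tibble (`gene_id` + sample columns).
#' @param labels Label tibble (`gene_id`, `label`).
#' @param thresholds FPKM thresholds (inclusive).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; the permutation list is stored in the
#'   `permutations` attribute.
#' @return A `saturation_curve` tibble: `label`, `threshold`, `k`,
#'   `min`, `q25`, `median`, `q75`, `max`.
#' @export
saturation <- function(expression, labels, thresholds = c(1, 10),
                       n_perm = 10, seed = 1L) {
  samples <- setdiff(names(expression), "gene_id")
  n_s <- length(samples)
  if (n_s == 0) stop("expression matrix has no sample columns")
  stopifnot(n_perm >= 1)
  vals <- as.matrix(expression[, samples])
  lab <- stats::setNames(labels$label, labels$gene_id)[expression$gene_id]
  perms <- withr::with_seed(seed, {
    lapply(seq_len(n_perm), function(i) sample.int(n_s))
  })
  rows <- list()
  for (p in seq_len(n_perm)) {
    v <- vals[, perms[[p]], drop = FALSE]
    cummx <- if (ncol(v) == 1) v else t(apply(v, 1, cummax))
    for (th in thresholds) {
      hit <- cummx >= th
      for (lb in unique(lab)) {
        counts <- colSums(hit[lab == lb, , drop = FALSE])
        rows[[length(rows) + 1]] <- tibble::tibble(
          perm = p, label = lb, threshold = th, k = seq_len(n_s), count = counts)
      }
    }
  }
  curve <- dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$label, .data$threshold, .data$k) |>
    dplyr::summarise(
      min = min(.data$count), q25 = stats::quantile(.data$count, 0.25),
      median = stats::median(.data$count),
      q75 = stats::quantile(.data$count, 0.75), max = max(.data$count),
      .groups = "drop")
  attr(curve, "permutations") <- perms
  class(curve) <- c("saturation_curve", class(curve))
  curve
}

#' Differential-expression saturation
#'
#' Cumulative number of distinct genes covered as DE gene sets are added
#' in permuted orders, per gene class.
#'
#' @param de_sets Tibble with `set_id`, `gene_id`.
#' @param labels Label tibble (`gene_id`, `label`); genes absent from it
#'   are dropped with a warning.
#' @param n_perm Number of set-order permutations.
#' @param seed Integer seed.
#' @return A `saturation_curve` tibble: `label`, `k` (number of sets),
#'   `min`, `q25`, `median`, `q75`, `max` of the cumulative distinct-gene
#'   count.
#' @export
de_saturation <- function(de_sets, labels, n_perm = 10, seed = 1L) {
  unknown <- setdiff(unique(de_sets$gene_id), labels$gene_id)
  if (length(unknown) > 0) {
    warning("ignoring ", length(unknown), " unknown gene id(s) in DE sets",
            call. = FALSE)
    de_sets <- de_sets[!de_sets$gene_id %in% unknown, ]
  }
  lab <- stats::setNames(labels$label, labels$gene_id)
  sets <- split(de_sets$gene_id, de_sets$set_id)
  n_sets <- length(sets)
  perms <- withr::with_seed(seed, {
    lapply(seq_len(n_perm), function(i) sample.int(n_sets))
  })
  rows <- list()
  for (p in seq_len(n_perm)) {
    ordered <- sets[perms[[p]]]
    for (lb in unique(lab)) {
      seen <- character(0)
      for (k in seq_len(n_sets)) {
        genes_k <- ordered[[k]]
        seen <- union(seen, genes_k[lab[genes_k] == lb])
        rows[[length(rows) + 1]] <- tibble::tibble(
          perm = p, label = lb, k = k, count = length(seen))
      }
    }
  }
  curve <- dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$label, .data$k) |>
    dplyr::summarise(
      min = min(.data$count), q25 = stats::quantile(.data$count, 0.25),
      median = stats::median(.data$count),
      q75 = stats::quantile(.data$count, 0.75), max = max(.data$count),
      .groups = "drop")
  class(curve) <- c("saturation_curve", class(curve))
  curve
}
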