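# Selection inference: Nei-Gojobori counting (the independent oracle),
# neighbor-joining cluster trees, Felsenstein pruning log-likelihood under
# the GY94 M0 model, maximum-likelihood fitting of omega with a
# likelihood-ratio test against the neutral model (omega = 1), and
# Benjamini-Hochberg FDR control across a dataset.

# ---- codon alignment utilities -------------------------------------------

# alignment tibble -> integer state matrix (taxa x codons); NA = gap/other
alignment_states <- function(alignment) {
  rows <- lapply(alignment$seq, function(s) codon_index(split_codons(toupper(s))))
  out <- do.call(rbind, rows)
  rownames(out) <- alignment$id
  out
}

# site-pattern compression
pattern_compress <- function(states) {
  key <- apply(states, 2, paste0, collapse = ",")
  tab <- table(key)
  first <- match(names(tab), key)
  list(patterns = states[, first, drop = FALSE], counts = as.numeric(tab))
}

# ---- Nei-Gojobori 1986 counting ------------------------------------------

# per-codon synonymous site counts (stop-codon targets excluded)
ng86_sites_for_codon <- function(ci) {
  ct <- codon_tables
  codon <- ct$codon_nt[ci, ]
  nt <- c("A", "C", "G", "T")
  s <- 0; valid <- 0
  for (p in 1:3) {
    for (b in setdiff(nt, codon[p])) {
      alt <- codon; alt[p] <- b
      alt_str <- paste0(alt, collapse = "")
      j <- match(alt_str, ct$sense)
      if (is.na(j)) next                     # stop target: excluded
      valid <- valid + 1
      if (ct$aa[j] == ct$aa[ci]) s <- s + 1
    }
  }
  c(syn = s / 3, total = valid / 3)
}

ng86_sites_table <- local({
  m <- t(vapply(1:61, ng86_sites_for_codon, numeric(2)))
  colnames(m) <- c("syn", "total")
  m
})

# average syn/nonsyn differences between two codons over substitution
# pathways that avoid stop codons
ng86_pair_diffs <- function(ci, cj) {
  ct <- codon_tables
  a <- ct$codon_nt[ci, ]; b <- ct$codon_nt[cj, ]
  pos <- which(a != b)
  if (length(pos) == 0) return(c(syn = 0, nonsyn = 0))
  paths <- if (length(pos) == 1) matrix(pos, 1, 1) else
    do.call(rbind, combinat_permutations(pos))
  count_path <- function(order) {
    cur <- a; s <- 0; n <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- b[p]
      i1 <- match(paste0(cur, collapse = ""), ct$sense)
      i2 <- match(paste0(nxt, collapse = ""), ct$sense)
      if (is.na(i2)) return(NULL)            # path through a stop codon
      if (ct$aa[i1] == ct$aa[i2]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s, n)
  }
  res <- lapply(seq_len(nrow(paths)), function(k) count_path(paths[k, ]))
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) {
    # all pathways cross a stop: fall back to averaging over all of them,
    # scoring the stop-crossing steps as nonsynonymous
    res <- lapply(seq_len(nrow(paths)), function(k) {
      cur <- a; s <- 0; n <- 0
      for (p in paths[k, ]) {
        nxt <- cur; nxt[p] <- b[p]
        i1 <- match(paste0(cur, collapse = ""), codon_tables$sense)
        i2 <- match(paste0(nxt, collapse = ""), codon_tables$sense)
        if (!is.na(i1) && !is.na(i2) && codon_tables$aa[i1] == codon_tables$aa[i2])
          s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      c(s, n)
    })
  }
  avg <- Reduce(`+`, res) / length(res)
  c(syn = avg[1], nonsyn = avg[2])
}

combinat_permutations <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_permutations(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

#' Nei-Gojobori (1986) pairwise dN/dS
#'
#' Counting estimate of synonymous and nonsynonymous substitution rates
#' for a pairwise codon alignment: fractional site counts per codon (stop
#' targets excluded), pathway-averaged difference counts, and
#' Jukes-Cantor multiple-hit correction.  Columns with gaps or
#' non-sense codons are masked.  Used as the independent counting oracle
#' for the maximum-likelihood engine.
#'
#' @param alignment Codon alignment tibble with exactly two rows.
#' @return A list: `dn`, `ds`, `omega` (`NA` when `ds` is 0 or
#'   undefined), `pn`, `ps`, `n_sites`, `s_sites`, `flags`.
#' @export
ng86_dnds <- function(alignment) {
  stopifnot(nrow(alignment) == 2)
  st <- alignment_states(alignment)
  keep <- !is.na(st[1, ]) & !is.na(st[2, ])
  if (sum(keep) < 1) stop("alignment shorter than one comparable codon")
  a <- st[1, keep]; b <- st[2, keep]
  sites <- (ng86_sites_table[a, , drop = FALSE] +
            ng86_sites_table[b, , drop = FALSE]) / 2
  S <- sum(sites[, "syn"])
  N <- sum(sites[, "total"] - sites[, "syn"])
  diff_idx <- which(a != b)
  sd <- nd <- 0
  for (k in diff_idx) {
    d <- ng86_pair_diffs(a[k], b[k])
    sd <- sd + d["syn"]; nd <- nd + d["nonsyn"]
  }
  ps <- if (S > 0) sd / S else 0
  pn <- if (N > 0) nd / N else 0
  jc <- function(p) {
    if (p >= 0.75) return(Inf)
    -0.75 * log(1 - 4 * p / 3)
  }
  ds <- jc(ps); dn <- jc(pn)
  flags <- character(0)
  if (!is.finite(ds) || !is.finite(dn)) flags <- c(flags, "saturated")
  omega <- if (ds == 0 || !is.finite(ds)) {
    if (is.infinite(ds) && is.finite(dn)) dn / ds else NA_real_
  } else dn / ds
  if (ds == 0) flags <- c(flags, "ds_zero")
  list(dn = unname(dn), ds = unname(ds), omega = unname(omega),
       pn = unname(pn), ps = unname(ps),
       n_sites = unname(N), s_sites = unname(S), flags = flags)
}

# ---- neighbor-joining tree -----------------------------------------------

# pairwise Jukes-Cantor corrected distances in codon-substitution units
codon_pair_distance <- function(si, sj) {
  keep <- !is.na(si) & !is.na(sj)
  if (sum(keep) == 0) return(NA_real_)
  ct <- codon_tables
  ai <- ct$codon_nt[si[keep], , drop = FALSE]
  aj <- ct$codon_nt[sj[keep], , drop = FALSE]
  p <- mean(ai != aj)
  if (p >= 0.75) return(Inf)
  3 * (-0.75 * log(1 - 4 * p / 3))
}

#' Neighbor-joining tree for a codon alignment
#'
#' Two taxa give the single edge with length equal to their corrected
#' distance; three give the star tree solved from the three pairwise
#' distances; four or more are joined by neighbor joining ([ape::nj()]).
#' Saturated (undefined) distances fall back to the maximum finite
#' distance and set the `saturated` attribute.
#'
#' @param alignment Codon alignment tibble (`id`, `seq`, >= 2 rows).
#' @return An [ape::phylo] with branch lengths in codon substitutions per
#'   site and attribute `saturated`.
#' @export
nj_tree <- function(alignment) {
  st <- alignment_states(alignment)
  n <- nrow(st)
  stopifnot(n >= 2)
  D <- matrix(0, n, n, dimnames = list(alignment$id, alignment$id))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- codon_pair_distance(st[i, ], st[j, ])
  }
  saturated <- any(!is.finite(D))
  if (saturated) {
    mx <- max(D[is.finite(D)], 0.5)
    D[!is.finite(D)] <- mx
  }
  tr <- if (n == 2) {
    ape::read.tree(text = sprintf("(%s:%.15g,%s:%.15g);", alignment$id[1],
                                  D[1, 2] / 2, alignment$id[2], D[1, 2] / 2))
  } else if (n == 3) {
    x <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
    y <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
    z <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
    ape::read.tree(text = sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                                  alignment$id[1], x, alignment$id[2], y,
                                  alignment$id[3], z))
  } else {
    tr <- ape::nj(stats::as.dist(D))
    tr$edge.length <- pmax(tr$edge.length, 1e-6)
    tr
  }
  attr(tr, "saturated") <- saturated
  tr
}

# ---- pruning likelihood ---------------------------------------------------

prepared_tree <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = po$edge, edge_order = seq_len(nrow(po$edge)),
       n_tip = ape::Ntip(po), n_node = max(po$edge),
       root = po$edge[nrow(po$edge), 1], tip_label = po$tip.label,
       edge_length = po$edge.length)
}

# core pruning likelihood: patterns (taxa x npat), counts, prepared tree,
# decomposition, per-edge branch lengths, pi
pruning_core <- function(pat, counts, pt, dec, b, pi) {
  n_states <- length(pi)
  npat <- ncol(pat)
  tip_idx <- match(pt$tip_label, rownames(pat))
  cond <- vector("list", pt$n_node)
  scale_log <- 0
  for (k in seq_along(tip_idx)) {
    m <- matrix(0, n_states, npat)
    s <- pat[tip_idx[k], ]
    obs <- !is.na(s)
    m[cbind(s[obs], which(obs))] <- 1
    if (any(!obs)) m[, !obs] <- 1
    cond[[k]] <- m
  }
  for (e in seq_len(nrow(pt$edge))) {
    par <- pt$edge[e, 1]; child <- pt$edge[e, 2]
    P <- transition_prob(dec, b[e])
    contrib <- P %*% cond[[child]]
    if (is.null(cond[[par]])) {
      cond[[par]] <- contrib
    } else {
      cond[[par]] <- cond[[par]] * contrib
      mx <- apply(cond[[par]], 2, max)
      mx[mx <= 0] <- 1
      cond[[par]] <- sweep(cond[[par]], 2, mx, "/")
      scale_log <- scale_log + sum(counts * log(mx))
    }
  }
  site <- colSums(pi * cond[[pt$root]])
  site[site <= 0] <- .Machine$double.xmin
  sum(counts * log(site)) + scale_log
}

#' Felsenstein pruning log-likelihood under the GY94 M0 model
#'
#' Post-order pruning over the 61 sense-codon states with per-node
#' rescaling; gap codons contribute partial likelihood one (missing
#' data).
#'
#' @param alignment Codon alignment tibble (`id`, `seq`).
#' @param tree An [ape::phylo] whose tip labels match alignment ids;
#'   branch lengths in codon substitutions per site.
#' @param omega,kappa,pi Model parameters (see [gy94_rate_matrix()]).
#' @return The log-likelihood (scalar).
#' @export
pruning_loglik <- function(alignment, tree, omega, kappa,
                           pi = f3x4_frequencies(alignment$seq)) {
  st <- alignment_states(alignment)
  stopifnot(setequal(tree$tip.label, alignment$id))
  pc <- pattern_compress(st)
  pt <- prepared_tree(tree)
  dec <- decompose_rate_matrix(gy94_rate_matrix(omega, kappa, pi), pi)
  pruning_core(pc$patterns, pc$counts, pt, dec, pt$edge_length, pi)
}

# ---- M0 maximum-likelihood fit -------------------------------------------

#' Fit the M0 codon model by maximum likelihood
#'
#' Estimates a single dN/dS ratio for the whole cluster tree, together
#' with the transition/transversion ratio and all branch lengths, by
#' cyclic coordinate ascent with bounded scalar optimisation per
#' parameter.  Codon frequencies are F3x4 estimates from the alignment.
#' With `fix_omega` set, the ratio is pinned (the null model re-optimises
#' the nuisance parameters, a proper nested fit).  The free fit restarts
#' from three initial ratios and polishes the best.
#'
#' @param alignment Codon alignment tibble (`id`, `seq`).
#' @param tree Optional [ape::phylo]; defaults to [nj_tree()] on the
#'   alignment.
#' @param fix_omega Optional fixed dN/dS (e.g. 1 for the neutral null).
#' @param omega_bounds Search interval for the ratio.
#' @param kappa_bounds,branch_bounds Search intervals for nuisance
#'   parameters.
#' @param tol Convergence threshold on the log-likelihood gain of a full
#'   parameter sweep.
#' @param max_sweeps Sweep cap.
#' @return An object of class `m0_fit`: `omega`, `kappa`,
#'   `branch_lengths`, `tree`, `loglik`, `pi`, `n_codons`, `converged`,
#'   `flags`, `fixed_omega`.
#' @export
fit_m0 <- function(alignment, tree = NULL, fix_omega = NULL,
                   omega_bounds = c(1e-4, 10), kappa_bounds = c(0.1, 20),
                   branch_bounds = c(1e-6, 10), tol = 1e-6, max_sweeps = 50) {
  st <- alignment_states(alignment)
  pc <- pattern_compress(st)
  pi <- f3x4_frequencies(alignment$seq)
  n_codons <- ncol(st)
  flags <- character(0)

  identical_seqs <- all(apply(pc$patterns, 2, function(col) {
    v <- col[!is.na(col)]
    length(unique(v)) <= 1
  }))

  if (is.null(tree)) tree <- nj_tree(alignment)
  if (isTRUE(attr(tree, "saturated"))) flags <- c(flags, "saturated")
  pt <- prepared_tree(tree)

  if (identical_seqs) {
    b0 <- rep(branch_bounds[1], nrow(pt$edge))
    dec <- decompose_rate_matrix(gy94_rate_matrix(1, 2, pi), pi)
    ll <- pruning_core(pc$patterns, pc$counts, pt, dec, b0, pi)
    return(structure(list(
      omega = if (is.null(fix_omega)) NA_real_ else fix_omega,
      kappa = 2, branch_lengths = b0, tree = tree, loglik = ll, pi = pi,
      n_codons = n_codons, converged = TRUE,
      flags = c(flags, "identical_sequences"),
      fixed_omega = fix_omega), class = "m0_fit"))
  }

  # a two-taxon tree has one identifiable path length: collapse it onto
  # the first edge and pin the second at the lower bound
  nb <- nrow(pt$edge)
  pair_tree <- ape::Ntip(tree) == 2
  b_init <- pmax(pmin(pt$edge_length, branch_bounds[2]), branch_bounds[1])
  if (pair_tree) {
    b_init <- c(min(sum(pt$edge_length), branch_bounds[2]),
                rep(branch_bounds[1], nb - 1))
  }
  branch_free <- if (pair_tree) 1L else seq_len(nb)

  # memoise the eigendecomposition on (omega, kappa): branch-length moves
  # (most optimiser evaluations) reuse it
  memo_key <- NULL; memo_dec <- NULL
  get_dec <- function(omega, kappa) {
    key <- c(omega, kappa)
    if (!identical(key, memo_key)) {
      memo_dec <<- decompose_rate_matrix(gy94_rate_matrix(omega, kappa, pi), pi)
      memo_key <<- key
    }
    memo_dec
  }

  if (pair_tree) {
    # closed-form pair likelihood: sum_p n_p log(pi_a P_ab(t))
    a_st <- pc$patterns[1, ]; b_st <- pc$patterns[2, ]
    both <- !is.na(a_st) & !is.na(b_st)
    const <- sum(pc$counts[!both & !is.na(a_st)] * log(pi[a_st[!both & !is.na(a_st)]])) +
      sum(pc$counts[!both & !is.na(b_st)] * log(pi[b_st[!both & !is.na(b_st)]]))
    ab_idx <- cbind(a_st[both], b_st[both])
    wts <- pc$counts[both]
    pia <- pi[a_st[both]]
    ll_fun <- function(omega, kappa, b) {
      P <- transition_prob(get_dec(omega, kappa), sum(b))
      const + sum(wts * log(pmax(pia * P[ab_idx], 1e-300)))
    }
  } else {
    ll_fun <- function(omega, kappa, b) {
      pruning_core(pc$patterns, pc$counts, pt, get_dec(omega, kappa), b, pi)
    }
  }

  run_ascent <- function(omega, kappa, b, sweeps, sweep_tol) {
    ll <- ll_fun(omega, kappa, b)
    ll_start <- ll
    for (s in seq_len(sweeps)) {
      ll_start <- ll
      if (is.null(fix_omega)) {
        o <- stats::optimize(function(x) ll_fun(x, kappa, b),
                             interval = omega_bounds, maximum = TRUE, tol = 1e-4)
        if (o$objective > ll) { omega <- o$maximum; ll <- o$objective }
      }
      o <- stats::optimize(function(x) ll_fun(omega, x, b),
                           interval = kappa_bounds, maximum = TRUE, tol = 1e-4)
      if (o$objective > ll) { kappa <- o$maximum; ll <- o$objective }
      for (e in branch_free) {
        o <- stats::optimize(function(x) {
          bb <- b; bb[e] <- x
          ll_fun(omega, kappa, bb)
        }, interval = branch_bounds, maximum = TRUE, tol = 1e-5)
        if (o$objective > ll) { b[e] <- o$maximum; ll <- o$objective }
      }
      if (ll - ll_start < sweep_tol) break
    }
    list(omega = omega, kappa = kappa, b = b, ll = ll,
         converged = (ll - ll_start) < sweep_tol)
  }

  # joint bounded quasi-Newton fit on log-parameters; the coordinate-
  # ascent sweep above verifies (and if needed repairs) the optimum
  run_lbfgs <- function(omega0, kappa0, b0) {
    free_omega <- is.null(fix_omega)
    k <- length(branch_free)
    par0 <- log(c(b0[branch_free], kappa0, if (free_omega) omega0))
    lower <- log(c(rep(branch_bounds[1], k), kappa_bounds[1],
                   if (free_omega) omega_bounds[1]))
    upper <- log(c(rep(branch_bounds[2], k), kappa_bounds[2],
                   if (free_omega) omega_bounds[2]))
    bb <- b0
    negll <- function(par) {
      p <- exp(par)
      bb[branch_free] <- p[seq_len(k)]
      -ll_fun(if (free_omega) p[k + 2] else fix_omega, p[k + 1], bb)
    }
    o <- tryCatch(
      stats::optim(par0, negll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 200, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(o) || !is.finite(o$value)) return(NULL)
    p <- exp(o$par)
    bb[branch_free] <- p[seq_len(k)]
    list(omega = if (free_omega) p[k + 2] else fix_omega,
         kappa = p[k + 1], b = bb, ll = -o$value,
         converged = o$convergence == 0)
  }

  omega0 <- if (!is.null(fix_omega)) fix_omega else {
    og <- tryCatch(if (nrow(alignment) == 2) ng86_dnds(alignment)$omega else NA_real_,
                   error = function(e) NA_real_)
    if (is.na(og) || !is.finite(og)) 0.5 else
      min(max(og, omega_bounds[1] * 2), omega_bounds[2] / 2)
  }
  fit <- run_lbfgs(omega0, 2, b_init)
  if (!is.null(fit) && is.null(fix_omega) &&
      (fit$omega <= omega_bounds[1] * 1.05 || fit$omega >= omega_bounds[2] * 0.95)) {
    alt <- run_lbfgs(1, fit$kappa, fit$b)
    if (!is.null(alt) && alt$ll > fit$ll + 1e-9) fit <- alt
  }
  if (is.null(fit)) {
    fit <- run_ascent(omega0, 2, b_init, max_sweeps, tol)
  } else if (!fit$converged) {
    fit <- run_ascent(if (is.null(fix_omega)) fit$omega else fix_omega,
                      fit$kappa, fit$b, max_sweeps, tol)
  } else {
    fit$converged <- TRUE
  }
  if (!fit$converged) flags <- c(flags, "not_converged")
  if (is.null(fix_omega)) {
    if (fit$omega <= omega_bounds[1] * 1.05 || fit$omega >= omega_bounds[2] * 0.95) {
      flags <- c(flags, "omega_boundary")
    }
    # dS ~ 0: negligible synonymous divergence makes omega unreliable
    ng_flag <- tryCatch({
      if (nrow(alignment) == 2) {
        ng <- ng86_dnds(alignment)
        if (!is.na(ng$ds) && ng$ds == 0 && ng$dn > 0) "ds_zero" else NULL
      } else NULL
    }, error = function(e) NULL)
    flags <- c(flags, ng_flag)
  }
  structure(list(
    omega = fit$omega, kappa = fit$kappa, branch_lengths = fit$b,
    tree = tree, loglik = fit$ll, pi = pi, n_codons = n_codons,
    converged = fit$converged, flags = flags, fixed_omega = fix_omega),
    class = "m0_fit")
}

#' @export
print.m0_fit <- function(x, ...) {
  cat("M0 codon model fit\n")
  cat(sprintf("  omega: %s%s\n",
              format(x$omega, digits = 4),
              if (!is.null(x$fixed_omega)) " (fixed)" else ""))
  cat(sprintf("  kappa: %s   lnL: %s   codons: %d\n",
              format(x$kappa, digits = 4), format(x$loglik, digits = 8),
              x$n_codons))
  if (length(x$flags) > 0) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Likelihood-ratio test of negative selection
#'
#' Statistic `2 (lnL_HA - lnL_H0)`, clipped at zero (a warning is issued
#' for materially negative differences), referred to the chi-squared
#' distribution with one degree of freedom.
#'
#' @param lnl_ha,lnl_h0 Log-likelihoods of the free-omega and
#'   omega-fixed-at-1 fits.
#' @return A list with `statistic` and `p_value`.
#' @export
lrt <- function(lnl_ha, lnl_h0) {
  stopifnot(is.finite(lnl_ha), is.finite(lnl_h0))
  delta <- 2 * (lnl_ha - lnl_h0)
  if (delta < -1e-6) {
    warning("alternative log-likelihood below null (", format(delta),
            "); statistic clipped at 0", call. = FALSE)
  }
  stat <- max(0, delta)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment; monotone, capped at one.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return q-values of the same length.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  stats::p.adjust(p, method = "BH")
}

#' Run selection inference over a dataset of codon alignments
#'
#' Fits the free and neutral M0 models per cluster, computes the LRT and
#' adjusts p-values by Benjamini-Hochberg within the dataset.  Clusters
#' of identical sequences are flagged and get p = 1; per-cluster failures
#' are recorded as flags and never abort the dataset.
#'
#' @param alignments Named list of codon alignment tibbles (names are
#'   cluster ids).
#' @param dataset Dataset tag (e.g. `"ortholog"`, `"paralog"`,
#'   `"cladeAB"`).
#' @param omega_bounds Search interval for the ratio.
#' @return A `selection_results` tibble: `cluster_id`, `dataset`,
#'   `omega`, `lnl_ha`, `lnl_h0`, `statistic`, `p_value`, `q_value`,
#'   `flags`.
#' @export
run_dataset <- function(alignments, dataset, omega_bounds = c(1e-4, 10)) {
  rows <- lapply(names(alignments), function(cid) {
    aln <- alignments[[cid]]
    res <- tryCatch({
      ha <- fit_m0(aln, omega_bounds = omega_bounds)
      if ("identical_sequences" %in% ha$flags) {
        tibble::tibble(cluster_id = cid, dataset = dataset,
                       omega = NA_real_, lnl_ha = ha$loglik, lnl_h0 = ha$loglik,
                       statistic = 0, p_value = 1,
                       flags = paste(ha$flags, collapse = ";"))
      } else {
        h0 <- fit_m0(aln, tree = ha$tree, fix_omega = 1,
                     omega_bounds = omega_bounds)
        lr <- lrt(max(ha$loglik, h0$loglik), h0$loglik)
        tibble::tibble(cluster_id = cid, dataset = dataset,
                       omega = ha$omega, lnl_ha = ha$loglik, lnl_h0 = h0$loglik,
                       statistic = lr$statistic, p_value = lr$p_value,
                       flags = paste(union(ha$flags, h0$flags), collapse = ";"))
      }
    }, error = function(e) {
      tibble::tibble(cluster_id = cid, dataset = dataset, omega = NA_real_,
                     lnl_ha = NA_real_, lnl_h0 = NA_real_, statistic = NA_real_,
                     p_value = NA_real_, flags = paste0("error:", conditionMessage(e)))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- bh_fdr(out$p_value)
  out <- dplyr::relocate(out, "q_value", .after = "p_value")
  class(out) <- c("selection_results", class(out))
  out
}

# ---- broom-style accessors -----------------------------------------------

#' Tidy an M0 fit
#'
#' @param x An `m0_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`omega`, `kappa`, one row
#'   per branch length).
#' @export
tidy.m0_fit <- function(x, ...) {
  tibble::tibble(
    term = c("omega", "kappa", paste0("branch_", seq_along(x$branch_lengths))),
    estimate = c(x$omega, x$kappa, x$branch_lengths),
    fixed = c(!is.null(x$fixed_omega), FALSE, rep(FALSE, length(x$branch_lengths))))
}

#' Glance at an M0 fit
#'
#' @param x An `m0_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `omega`, `kappa`, `n_codons`,
#'   `n_taxa`, `converged`, `flags`.
#' @export
glance.m0_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, omega = x$omega, kappa = x$kappa,
    n_codons = x$n_codons, n_taxa = ape::Ntip(x$tree),
    converged = x$converged,
    flags = paste(x$flags, collapse = ";"))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
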