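# Independent brute-force oracles used to freeze expected values.

# naive Smith-Waterman DP (linear or affine-as-linear gap per gap column)
sw_oracle <- function(a, b, match, mismatch, gap) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (a[i] == b[j]) match else mismatch
    H[i + 1, j + 1] <- max(0, H[i, j] + s, H[i, j + 1] - gap, H[i + 1, j] - gap)
  }
  max(H)
}

# naive global Needleman-Wunsch with linear gap
nw_oracle <- function(a, b, match, mismatch, gap) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  H[, 1] <- -gap * (0:n); H[1, ] <- -gap * (0:m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (a[i] == b[j]) match else mismatch
    H[i + 1, j + 1] <- max(H[i, j] + s, H[i, j + 1] - gap, H[i + 1, j] - gap)
  }
  H[n + 1, m + 1]
}

# Benjamini-Hochberg by the min-over-tail definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    tail_vals <- vapply(rank_i:m, function(k) min(1, m * p[o[k]] / k), numeric(1))
    q[i] <- min(tail_vals)
  }
  q
}

# naive quadratic substring scan
peptide_scan_oracle <- function(peptides, proteins) {
  hits <- list()
  for (p in seq_along(peptides)) {
    for (r in seq_along(proteins)) {
      lp <- nchar(peptides[p]); lr <- nchar(proteins[r])
      if (lp > lr) next
      for (s in 1:(lr - lp + 1)) {
        if (substr(proteins[r], s, s + lp - 1) == peptides[p]) {
          hits[[length(hits) + 1]] <- c(p, r, s - 1)
        }
      }
    }
  }
  if (length(hits) == 0) return(matrix(numeric(0), 0, 3))
  do.call(rbind, hits)
}

# adjusted Rand index between two partitions (vectors of labels)
adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * cc / choose(n, 2)
  mx <- (b + cc) / 2
  if (mx == expected) return(1)
  (a - expected) / (mx - expected)
}

# dense-matrix Markov clustering oracle (expansion/inflation to fixpoint)
mcl_oracle <- function(adj, inflation = 2, expansion = 2) {
  n <- nrow(adj)
  diag(adj) <- 1
  M <- sweep(adj, 2, colSums(adj), "/")
  for (it in 1:200) {
    M2 <- M
    for (e in seq_len(expansion - 1)) M2 <- M2 %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    if (max(abs(M2 - M)) < 1e-10) { M <- M2; break }
    M <- M2
  }
  reach <- (M > 1e-5) | t(M > 1e-5)
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, which(reach[v, ] & comp == 0))
    }
  }
  comp
}

# shared small synthetic dataset, generated once per test session
test_dataset_env <- new.env()
small_test_dataset <- function() {
  if (is.null(test_dataset_env$ds)) {
    dir <- file.path(tempdir(), "orphanevo_test_ds")
    cfg <- sim_config(n_conserved = 25, n_orphan = 15, n_hybrid = 2,
                      n_pex_specific = 2, n_contigs = 8, seed = 2024L)
    test_dataset_env$ds <- generate_dataset(cfg, out_dir = dir)
    test_dataset_env$dir <- dir
  }
  list(ds = test_dataset_env$ds, dir = test_dataset_env$dir)
}
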