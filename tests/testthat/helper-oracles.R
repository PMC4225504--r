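# Independent oracles used across the suite.  These deliberately avoid the
# package's internal code paths: naive per-site loops, a literal O(n^4)
# neighbor-joining translation, matrix exponentials via Matrix::expm, and
# plain grid search.

# Naive per-site DNA pair counting (unambiguous symbols only).
oracle_count_pair <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  res <- c(valid = 0, matches = 0, ts_AG = 0, ts_CT = 0, tv = 0)
  for (s in seq_along(av)) {
    x <- av[s]; y <- bv[s]
    if (!x %in% c("A", "C", "G", "T") || !y %in% c("A", "C", "G", "T")) next
    res["valid"] <- res["valid"] + 1
    if (x == y) res["matches"] <- res["matches"] + 1
    else if (all(c(x, y) %in% c("A", "G"))) res["ts_AG"] <- res["ts_AG"] + 1
    else if (all(c(x, y) %in% c("C", "T"))) res["ts_CT"] <- res["ts_CT"] + 1
    else res["tv"] <- res["tv"] + 1
  }
  res
}

# Literal neighbor joining: recompute all row sums and the full criterion
# table from scratch each iteration (O(n^4) total), identical tie-breaking
# (smallest original-index pair).  Returns a phylo built through ape.
oracle_nj <- function(D) {
  n <- nrow(D)
  sub <- as.list(rownames(D))           # newick fragments
  ids <- seq_len(n)                     # creation-order node ids (tie-break)
  next_id <- n
  W <- D
  while (length(ids) > 3) {
    m <- length(ids)
    best <- NULL; best_s <- Inf
    for (ii in 1:(m - 1)) for (jj in (ii + 1):m) {
      R_i <- sum(W[ii, ]); R_j <- sum(W[jj, ])
      s <- (m - 2) * W[ii, jj] - R_i - R_j
      fi <- sort(c(ids[ii], ids[jj]))
      if (s < best_s ||
          (s == best_s && (fi[1] < best$fi[1] ||
                           (fi[1] == best$fi[1] && fi[2] < best$fi[2])))) {
        best_s <- s; best <- list(i = ii, j = jj, fi = fi)
      }
    }
    i <- best$i; j <- best$j
    if (ids[i] > ids[j]) { tmp <- i; i <- j; j <- tmp }
    R_i <- sum(W[i, ]); R_j <- sum(W[j, ])
    li <- W[i, j] / 2 + (R_i - R_j) / (2 * (m - 2))
    lj <- W[i, j] - li
    fmt <- function(x) formatC(x, digits = 15, format = "g", width = 1)
    merged <- paste0("(", sub[[i]], ":", fmt(li), ",", sub[[j]], ":",
                     fmt(lj), ")")
    duk <- (W[i, -c(i, j)] + W[j, -c(i, j)] - W[i, j]) / 2
    W <- W[-c(i, j), -c(i, j), drop = FALSE]
    W <- rbind(cbind(W, duk), c(duk, 0))
    sub <- c(sub[-c(i, j)], merged)
    next_id <- next_id + 1
    ids <- c(ids[-c(i, j)], next_id)
  }
  fmt <- function(x) formatC(x, digits = 15, format = "g", width = 1)
  la <- (W[1, 2] + W[1, 3] - W[2, 3]) / 2
  lb <- (W[1, 2] + W[2, 3] - W[1, 3]) / 2
  lc <- (W[1, 3] + W[2, 3] - W[1, 2]) / 2
  txt <- paste0("(", sub[[1]], ":", fmt(la), ",", sub[[2]], ":", fmt(lb),
                ",", sub[[3]], ":", fmt(lc), ");")
  ape::read.tree(text = txt)
}

# Random symmetric dissimilarity matrix with zero diagonal.
random_dm <- function(n, seed) {
  set.seed(seed)
  D <- matrix(0, n, n, dimnames = list(paste0("x", 1:n), paste0("x", 1:n)))
  D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.05, 2)
  D + t(D)
}

# Leaf-to-leaf path distance comparison of two trees on a common taxon set.
tree_metric_gap <- function(t1, t2) {
  taxa <- t1$tip.label
  max(abs(stats::cophenetic(t1)[taxa, taxa] - stats::cophenetic(t2)[taxa, taxa]))
}

make_dna_counts <- function(valid, matches, ts_AG, ts_CT, tv,
                            freq = c(A = 1, C = 1, G = 1, T = 1)) {
  freq <- freq / sum(freq) * 2 * valid
  structure(list(valid_sites = valid, matches = matches, ts_AG = ts_AG,
                 ts_CT = ts_CT, tv = tv, freq = freq),
            class = "pair_counts_dna")
}

# Two-taxon alignment evolved at a given true distance.
evolve_pair <- function(d, L, model, seed, ...) {
  tr <- structure(list(edge = rbind(c(3L, 1L), c(3L, 2L)),
                       edge.length = c(d / 2, d / 2),
                       tip.label = c("a", "b"), Nnode = 1L),
                  class = "phylo")
  evolve_sequences(tr, L, model, seed = seed, ...)
}
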