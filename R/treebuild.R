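# Distance-based tree reconstruction: canonical Neighbor-Joining, Fast
# Neighbor-Joining with a visibility set (quadratic total work), and BioNJ
# (variance-weighted reduction).  All three share the NJ selection
# criterion S(i,j) = (m-2) D(i,j) - R(i) - R(j) (lower is better, R the row
# sums over active nodes), identical branch-length conventions, and exact
# lexicographic tie-breaking on original node indices, so on additive
# matrices all three reproduce the generating tree exactly.

#' NJ selection criterion
#'
#' `S(i, j) = (m - 2) D(i, j) - R(i) - R(j)` where `m` is the number of
#' active nodes and `R` the row sums of the working matrix.  The pair
#' minimising `S` is joined next.
#'
#' @param D symmetric working distance matrix over active nodes.
#' @param i,j distinct 1-based node indices.
#' @return The criterion value (a real; lower is better).
#' @examples
#' D <- matrix(1, 3, 3); diag(D) <- 0
#' nj_selection(D, 1, 2)
#' @export
nj_selection <- function(D, i, j) {
  m <- nrow(D)
  R <- rowSums(D)
  (m - 2) * D[i, j] - R[i] - R[j]
}

validate_dm_input <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("input error: distance matrix must be square")
  if (nrow(D) < 2L) stop("input error: need at least 2 taxa")
  if (any(!is.finite(D)))
    stop("input error: non-finite distance entry; substitute saturated ",
         "entries first (saturation_distance)")
  if (max(abs(D - t(D))) > 1e-8)
    stop("input error: distance matrix is not symmetric")
  if (is.null(rownames(D)))
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  D
}

#' Distance-matrix tree reconstruction
#'
#' `nj_tree` is canonical Neighbor-Joining (Saitou-Nei/Studier-Keppler
#' form): at each step the globally minimal pair under [nj_selection()] is
#' joined; the new node `u` replacing `(i, j)` gets branch lengths
#' `l_i = D(i,j)/2 + (R(i) - R(j)) / (2 (m - 2))`, `l_j = D(i,j) - l_i`, and
#' reduced distances `D(u, k) = (D(i,k) + D(j,k) - D(i,j)) / 2`.
#'
#' `fnj_tree` restricts the pair search to a visibility set — one stored
#' candidate partner per active node, chosen by a full scan when the node is
#' created and opportunistically improved as new nodes appear — which brings
#' the total number of selection-criterion evaluations down to `O(n^2)`
#' (exposed as attribute `s_evaluations` on the result).  The joined pair is
#' always a member of the visible set.
#'
#' `bionj_tree` selects pairs and assigns branch lengths exactly as NJ but
#' propagates a variance matrix (initialised to `D`) and uses the
#' variance-weighted reduction of Gascuel (1997):
#' `D(u,k) = lambda (D(i,k) - l_i) + (1 - lambda) (D(j,k) - l_j)` with
#' `lambda = 1/2 + sum_k (V(j,k) - V(i,k)) / (2 (m - 2) V(i,j))` clamped to
#' `[0, 1]`.
#'
#' All methods finish at three remaining nodes with the closed-form
#' three-point branch lengths and return an unrooted tree with a trifurcate
#' serialization root (for `n = 2`, the single edge is split over the two
#' tips).  Negative branch lengths are kept unless `min_branch_length` is
#' given, in which case shorter branches are raised to it and the deficit
#' transferred to the adjacent edge.  Exact ties in the selection criterion
#' break to the lexicographically smallest pair of original node indices.
#'
#' @param D symmetric distance matrix with finite entries; rownames are the
#'   taxon labels.
#' @param min_branch_length optional lower clamp for branch lengths.
#' @return An [ape::phylo] tree; `fnj_tree` results carry an
#'   `s_evaluations` attribute counting selection-criterion evaluations.
#' @examples
#' D <- matrix(c(0,5,7,8, 5,0,8,9, 7,8,0,9, 8,9,9,0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' write_newick(nj_tree(D), precision = 6)
#' @export
nj_tree <- function(D, min_branch_length = NULL)
  agglomerate(D, method = "nj", min_branch_length = min_branch_length)

#' @rdname nj_tree
#' @export
fnj_tree <- function(D, min_branch_length = NULL)
  agglomerate(D, method = "fnj", min_branch_length = min_branch_length)

#' @rdname nj_tree
#' @export
bionj_tree <- function(D, min_branch_length = NULL)
  agglomerate(D, method = "bionj", min_branch_length = min_branch_length)

# Shared agglomeration engine.  Slots 1..n are leaves; each join creates a
# new slot.  `active` indexes live slots; D/V are (2n-1)^2 working stores.
agglomerate <- function(D, method = c("nj", "fnj", "bionj"),
                        min_branch_length = NULL) {
  method <- match.arg(method)
  D <- validate_dm_input(D)
  taxa <- rownames(D)
  n <- nrow(D)
  if (n == 2L)
    return(finish_tree(rbind(c(3L, 1L), c(3L, 2L)),
                       c(D[1L, 2L] / 2, D[1L, 2L] / 2),
                       taxa, root_slot = 3L, slot_of = c(1L, 2L, 3L),
                       min_branch_length))
  nslots <- 2L * n - 2L
  W <- matrix(0, nslots, nslots)
  W[1:n, 1:n] <- D
  V <- if (method == "bionj") W
  active <- seq_len(n)
  is_active <- logical(nslots + 1L)
  is_active[active] <- TRUE
  R <- rowSums(D)                    # over active slots only
  edges <- matrix(0L, 2L * n - 3L, 2L)
  elen <- numeric(2L * n - 3L)
  ne <- 0L
  new_slot <- n
  s_evals <- 0L

  # visibility set (fnj): best-known partner per active slot
  vis <- integer(nslots)
  if (method == "fnj") {
    for (i in active) {
      s_best <- Inf; p <- 0L
      for (j in active) if (j != i) {
        s <- (n - 2) * W[i, j] - R[i] - R[j]; s_evals <- s_evals + 1L
        if (s < s_best - 0) { s_best <- s; p <- j }
      }
      vis[i] <- p
    }
  }

  m <- n
  while (m > 3L) {
    if (method == "fnj") {
      # evaluate S over visible pairs, refreshing stale partners to the
      # newest node; re-scan the winner until it survives its own refresh
      cand_s <- rep(Inf, length(active))
      for (t in seq_along(active)) {
        i <- active[t]
        if (vis[i] == 0L || !is_active[vis[i]] || vis[i] == i)
          vis[i] <- new_slot
        j <- vis[i]
        cand_s[t] <- (m - 2) * W[i, j] - R[i] - R[j]
        s_evals <- s_evals + 1L
      }
      repeat {
        t_star <- best_candidate(cand_s, active, vis)
        i <- active[t_star]
        s_best <- Inf; p <- 0L
        for (j in active) if (j != i) {
          s <- (m - 2) * W[i, j] - R[i] - R[j]; s_evals <- s_evals + 1L
          if (s < s_best || (s == s_best && pair_lt(i, j, i, p))) {
            s_best <- s; p <- j
          }
        }
        changed <- p != vis[i]
        vis[i] <- p
        cand_s[t_star] <- s_best
        if (!changed) break
        if (best_candidate(cand_s, active, vis) == t_star) break
      }
      t_star <- best_candidate(cand_s, active, vis)
      i <- active[t_star]; j <- vis[i]
      if (pair_lt(j, i, i, j)) { tmp <- i; i <- j; j <- tmp }
    } else {
      # full scan over active pairs, vectorised
      Ra <- R[active]
      S <- (m - 2) * W[active, active] - outer(Ra, Ra, "+")
      diag(S) <- Inf
      s_min <- min(S)
      hits <- which(S == s_min, arr.ind = TRUE)
      hits <- cbind(active[hits[, 1L]], active[hits[, 2L]])
      hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
      hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
      i <- hits[1L, 1L]; j <- hits[1L, 2L]
    }

    # branch lengths for the joined pair
    li <- W[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- W[i, j] - li
    u <- new_slot <- new_slot + 1L
    edges[ne + 1L, ] <- c(u, i); elen[ne + 1L] <- li
    edges[ne + 2L, ] <- c(u, j); elen[ne + 2L] <- lj
    ne <- ne + 2L

    rest <- active[active != i & active != j]
    dik <- W[i, rest]; djk <- W[j, rest]
    if (method == "bionj") {
      vij <- V[i, j]
      lambda <- if (vij > 0 && m > 3L)
        0.5 + sum(V[j, rest] - V[i, rest]) / (2 * (m - 2) * vij)
      else 0.5
      lambda <- min(max(lambda, 0), 1)
      duk <- lambda * (dik - li) + (1 - lambda) * (djk - lj)
      vuk <- lambda * V[i, rest] + (1 - lambda) * V[j, rest] -
        lambda * (1 - lambda) * vij
      V[u, rest] <- vuk; V[rest, u] <- vuk
    } else {
      duk <- (dik + djk - W[i, j]) / 2
    }
    W[u, rest] <- duk; W[rest, u] <- duk
    R[rest] <- R[rest] + duk - dik - djk
    R[u] <- sum(duk)
    is_active[i] <- FALSE; is_active[j] <- FALSE; is_active[u] <- TRUE
    active <- c(rest, u)
    m <- m - 1L

    if (method == "fnj" && m > 3L) {
      # creation scan for the new node's partner; opportunistically adopt u
      # as the stored partner of any node it beats
      s_best <- Inf; p <- 0L
      for (k in rest) {
        s_uk <- (m - 2) * W[u, k] - R[u] - R[k]; s_evals <- s_evals + 1L
        if (s_uk < s_best || (s_uk == s_best && pair_lt(u, k, u, p))) {
          s_best <- s_uk; p <- k
        }
        jk <- vis[k]
        if (jk != 0L && is_active[jk] && jk != u) {
          s_kv <- (m - 2) * W[k, jk] - R[k] - R[jk]; s_evals <- s_evals + 1L
          if (s_uk < s_kv) vis[k] <- u
        } else vis[k] <- u
      }
      vis[u] <- p
    }
  }

  # three-point termination: closed-form star lengths
  a <- active[1L]; b <- active[2L]; c <- active[3L]
  root <- new_slot + 1L
  la <- (W[a, b] + W[a, c] - W[b, c]) / 2
  lb <- (W[a, b] + W[b, c] - W[a, c]) / 2
  lc <- (W[a, c] + W[b, c] - W[a, b]) / 2
  edges[ne + 1L, ] <- c(root, a); elen[ne + 1L] <- la
  edges[ne + 2L, ] <- c(root, b); elen[ne + 2L] <- lb
  edges[ne + 3L, ] <- c(root, c); elen[ne + 3L] <- lc
  ne <- ne + 3L

  tree <- finish_tree(edges[seq_len(ne), , drop = FALSE], elen[seq_len(ne)],
                      taxa, root, slot_of = NULL, min_branch_length)
  if (method == "fnj") attr(tree, "s_evaluations") <- s_evals
  tree
}

best_candidate <- function(cand_s, active, vis) {
  s_min <- min(cand_s)
  hits <- which(cand_s == s_min)
  if (length(hits) == 1L) return(hits)
  # lexicographic tie-break on the (min, max) original-index pair
  best <- hits[1L]
  for (h in hits[-1L]) {
    if (pair_lt(active[h], vis[active[h]], active[best], vis[active[best]]))
      best <- h
  }
  best
}

pair_lt <- function(i1, j1, i2, j2) {
  a1 <- min(i1, j1); b1 <- max(i1, j1)
  a2 <- min(i2, j2); b2 <- max(i2, j2)
  a1 < a2 || (a1 == a2 && b1 < b2)
}

# Convert slot-indexed edges to a valid phylo: tips 1..n keep their slots,
# the root becomes n+1, remaining internal slots follow in creation order.
finish_tree <- function(edges, elen, taxa, root_slot, slot_of,
                        min_branch_length = NULL) {
  n <- length(taxa)
  internal <- sort(unique(edges[, 1L]))
  internal <- c(root_slot, setdiff(internal, root_slot))
  map <- integer(max(c(edges, root_slot)))
  map[seq_len(n)] <- seq_len(n)
  map[internal] <- n + seq_along(internal)
  edge <- cbind(map[edges[, 1L]], map[edges[, 2L]])
  tree <- structure(list(edge = edge, edge.length = elen,
                         tip.label = taxa, Nnode = length(internal)),
                    class = "phylo")
  attr(tree, "order") <- NULL
  tree <- ape::reorder.phylo(tree, "cladewise")
  if (!is.null(min_branch_length))
    tree <- clamp_branch_lengths(tree, min_branch_length)
  tree
}

# Kuhner-Felsenstein style: raise short branches to the floor and transfer
# the deficit to the adjacent (parent-side sibling or parent) edge.
clamp_branch_lengths <- function(tree, floor_len) {
  for (pass in seq_len(10L * length(tree$edge.length))) {
    short <- which(tree$edge.length < floor_len)
    if (!length(short)) break
    e <- short[1L]
    deficit <- floor_len - tree$edge.length[e]
    tree$edge.length[e] <- floor_len
    parent <- tree$edge[e, 1L]
    up <- which(tree$edge[, 2L] == parent)
    if (length(up)) tree$edge.length[up] <- tree$edge.length[up] - deficit
    else {
      sib <- setdiff(which(tree$edge[, 1L] == parent), e)
      tree$edge.length[sib] <- tree$edge.length[sib] - deficit / length(sib)
    }
  }
  tree
}
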