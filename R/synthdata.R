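# Synthetic data: random unrooted trees, additive (path-length) matrices,
# and sequences evolved site-independently under the supported DNA models
# (JC, K2P, TN93) or any bundled amino-acid model.  Every generator takes a
# mandatory seed so fixtures are reproducible.

#' Random unrooted binary tree
#'
#' Topology by sequential random edge attachment (uniform over labelled
#' unrooted binary topologies); branch lengths i.i.d. exponential.
#'
#' @param n_taxa number of leaves, `>= 2`.
#' @param mean_branch_length mean of the exponential branch-length
#'   distribution, in expected substitutions per site.
#' @param seed integer RNG seed (mandatory: fixtures must be reproducible).
#' @param labels optional leaf labels (default `t1..tn`).
#' @return An [ape::phylo] tree (trifurcate root for `n_taxa >= 3`).
#' @examples
#' tr <- random_tree(8, seed = 1)
#' ape::Ntip(tr)
#' @export
random_tree <- function(n_taxa, mean_branch_length = 0.1, seed,
                        labels = paste0("t", seq_len(n_taxa))) {
  if (n_taxa < 2L) stop("argument error: need n_taxa >= 2")
  stopifnot(mean_branch_length > 0)
  set.seed(seed)
  if (n_taxa == 2L) {
    tree <- structure(list(edge = rbind(c(3L, 1L), c(3L, 2L)),
                           edge.length = stats::rexp(2L, 1 / mean_branch_length),
                           tip.label = labels, Nnode = 1L), class = "phylo")
    return(ape::reorder.phylo(tree, "cladewise"))
  }
  # grow an unrooted topology: start from the 3-leaf star, then attach each
  # new leaf to a uniformly chosen existing edge
  topo <- ape::read.tree(text = paste0("(", labels[1L], ",", labels[2L], ",",
                                       labels[3L], ");"))
  topo$edge.length <- rep(1, nrow(topo$edge))
  if (n_taxa > 3L) {
    for (k in 4:n_taxa) {
      e <- sample.int(nrow(topo$edge), 1L)
      topo <- ape::bind.tree(
        topo,
        structure(list(edge = rbind(c(2L, 1L)), edge.length = 1,
                       tip.label = labels[k], Nnode = 1L), class = "phylo"),
        where = topo$edge[e, 2L], position = 0.5)
      topo$edge.length[] <- 1
    }
  }
  topo <- ape::unroot(topo)
  topo$edge.length <- stats::rexp(nrow(topo$edge), 1 / mean_branch_length)
  ape::reorder.phylo(topo, "cladewise")
}

#' Additive (path-length) distance matrix of a tree
#'
#' Entries are sums of branch lengths along leaf-to-leaf paths; the result
#' satisfies the four-point condition, and Neighbor-Joining reconstructs the
#' generating tree from it exactly.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @return A symmetric named matrix in `tree$tip.label` order.
#' @export
additive_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  D <- stats::cophenetic(tree)
  D[tree$tip.label, tree$tip.label]
}

# Normalised (rate 1) DNA generators.
dna_rate_matrix <- function(model = c("JC", "K2P", "TN93"), kappa = 2,
                            pi = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                            alpha1 = 2, alpha2 = 2, beta = 1) {
  model <- match.arg(model)
  bases <- c("A", "C", "G", "T")
  pi <- pi[bases] / sum(pi)
  Q <- matrix(0, 4L, 4L, dimnames = list(bases, bases))
  is_ts <- function(x, y) (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
  for (x in bases) for (y in bases) if (x != y) {
    rate <- switch(model,
      JC = 1,
      K2P = if (is_ts(x, y)) kappa else 1,
      TN93 = if (x %in% c("A", "G") && y %in% c("A", "G")) alpha1
             else if (x %in% c("C", "T") && y %in% c("C", "T")) alpha2
             else beta)
    Q[x, y] <- rate * (if (model == "TN93") pi[[y]] else 0.25)
  }
  diag(Q) <- -rowSums(Q)
  pi_eff <- if (model == "TN93") pi else rep(0.25, 4L)
  Q / -sum(pi_eff * diag(Q))
}

transition_probs <- function(Q, t) {
  eig <- eigen(Q)
  Re(eig$vectors %*% diag(exp(eig$values * t)) %*% solve(eig$vectors))
}

#' Evolve sequences along a tree
#'
#' The root sequence is drawn from the model's stationary frequencies; each
#' edge applies its transition matrix `expm(Q * length)` site-independently.
#' DNA supports JC, K2P (`kappa`) and TN93 (`pi`, `alpha1`, `alpha2`,
#' `beta`); protein supports the bundled empirical models.  Optionally, DNA
#' bases are replaced at rate `ambiguity_rate` by a random IUPAC ambiguity
#' code compatible with the true base.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param n_sites sequence length.
#' @param model `"JC"`, `"K2P"`, `"TN93"`, or an amino-acid model name
#'   (`"WAG"`, `"JTT"`, `"DAY"`, `"MVR"`, `"LG"`).
#' @param seed integer RNG seed (mandatory).
#' @param kappa,pi,alpha1,alpha2,beta DNA model parameters.
#' @param ambiguity_rate per-site probability of masking a DNA base with a
#'   compatible ambiguity code.
#' @return An [alignment] over the tree's tip labels.
#' @examples
#' tr <- random_tree(4, seed = 1)
#' evolve_sequences(tr, 100, "JC", seed = 2)
#' @export
evolve_sequences <- function(tree, n_sites, model = "K2P", seed,
                             kappa = 2,
                             pi = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                             alpha1 = 2, alpha2 = 2, beta = 1,
                             ambiguity_rate = 0) {
  stopifnot(inherits(tree, "phylo"), n_sites >= 1)
  model_up <- toupper(model)
  dna <- model_up %in% c("JC", "K2P", "TN93")
  if (!dna && !model_up %in% .aa_model_names)
    stop("argument error: unknown model '", model, "'")
  set.seed(seed)
  if (dna) {
    Q <- dna_rate_matrix(model_up, kappa = kappa, pi = pi,
                         alpha1 = alpha1, alpha2 = alpha2, beta = beta)
    root_freq <- if (model_up == "TN93") pi[c("A", "C", "G", "T")] / sum(pi)
                 else rep(0.25, 4L)
    symbols <- c("A", "C", "G", "T")
  } else {
    m <- aa_model(model_up)
    Q <- m$generator
    root_freq <- m$frequencies
    symbols <- .aa_residues
  }
  k <- length(symbols)
  n <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "cladewise")
  states <- vector("list", n + tree$Nnode)
  root <- n + 1L
  states[[root]] <- sample.int(k, n_sites, replace = TRUE, prob = root_freq)
  for (e in seq_len(nrow(tree$edge))) {     # cladewise: parents before kids
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    P <- transition_probs(Q, tree$edge.length[e])
    P[P < 0] <- 0
    ps <- states[[par]]
    cs <- integer(n_sites)
    for (s in seq_len(k)) {
      idx <- which(ps == s)
      if (length(idx))
        cs[idx] <- sample.int(k, length(idx), replace = TRUE,
                              prob = P[s, ] / sum(P[s, ]))
    }
    states[[child]] <- cs
  }
  rows <- vapply(seq_len(n), function(i)
    paste0(symbols[states[[i]]], collapse = ""), "")
  if (dna && ambiguity_rate > 0) {
    # ambiguity codes (code index 5..15) containing each base
    compat <- lapply(1:4, function(b)
      which(vapply(.dna_sets, function(s) b %in% s, TRUE) &
              lengths(.dna_sets) > 1L))
    mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    mask <- matrix(stats::runif(length(mat)) < ambiguity_rate, nrow(mat))
    for (idx in which(mask)) {
      b <- match(mat[idx], symbols)
      mat[idx] <- .dna_syms[sample(compat[[b]], 1L)]
    }
    rows <- apply(mat, 1L, paste0, collapse = "")
  }
  alignment(tree$tip.label, rows, if (dna) "dna" else "protein")
}
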