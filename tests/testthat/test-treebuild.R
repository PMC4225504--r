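# The worked additive example: tree ((A:2,B:3):1,C:4,D:5) gives pairwise
# path lengths AB=5 AC=7 AD=8 BC=8 BD=9 CD=9.
worked_matrix <- function() {
  matrix(c(0, 5, 7, 8, 5, 0, 8, 9, 7, 8, 0, 9, 8, 9, 9, 0), 4, 4,
         dimnames = list(LETTERS[1:4], LETTERS[1:4]))
}

test_that("the NJ selection criterion picks the cherry pairs of the worked matrix", {
  D <- worked_matrix()
  S <- outer(1:4, 1:4, Vectorize(function(i, j)
    if (i == j) Inf else nj_selection(D, i, j)))
  # for four taxa the two cherries of the split tie at the minimum
  expect_equal(S[1, 2], -32)
  expect_equal(S[3, 4], -32)
  expect_equal(min(S), -32)
  expect_true(all(S[cbind(c(1, 1, 2, 2), c(3, 4, 3, 4))] == -30))

  # equidistant taxa: all pairs equal
  E <- matrix(1, 3, 3); diag(E) <- 0
  vals <- c(nj_selection(E, 1, 2), nj_selection(E, 1, 3), nj_selection(E, 2, 3))
  expect_equal(length(unique(vals)), 1L)
})

test_that("the selection order is invariant to adding a constant to off-diagonals", {
  D <- random_dm(8, 401)
  Dc <- D + 0.7; diag(Dc) <- 0
  pairs <- t(combn(8, 2))
  s1 <- apply(pairs, 1, function(p) nj_selection(D, p[1], p[2]))
  s2 <- apply(pairs, 1, function(p) nj_selection(Dc, p[1], p[2]))
  expect_equal(order(s1), order(s2))
})

test_that("NJ reconstructs the worked 4-taxon tree with exact branch lengths", {
  tr <- nj_tree(worked_matrix())
  want <- ape::read.tree(text = "((A:2,B:3):1,C:4,D:5);")
  expect_equal(phangorn::RF.dist(tr, want), 0)
  expect_lt(tree_metric_gap(tr, want), 1e-12)
})

test_that("a 2-taxon matrix yields a single edge of the full length", {
  D <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  tr <- nj_tree(D)
  expect_equal(sum(tr$edge.length), 0.4)
  expect_setequal(tr$tip.label, c("a", "b"))
})

test_that("all three methods exactly recover generating trees from additive matrices", {
  for (s in 1:10) {
    tr <- random_tree(10, seed = 410 + s)
    D <- additive_matrix(tr)
    for (build in list(nj_tree, fnj_tree, bionj_tree)) {
      got <- build(D)
      expect_equal(phangorn::RF.dist(got, tr), 0)
      expect_lt(tree_metric_gap(got, tr), 1e-10)
      expect_equal(nrow(got$edge), 2 * 10 - 3)
      expect_setequal(got$tip.label, tr$tip.label)
    }
  }
})

test_that("NJ equals the literal O(n^4) reference on random non-additive matrices", {
  for (s in 1:8) {
    n <- sample(4:12, 1)
    D <- random_dm(n, 420 + s)
    got <- nj_tree(D)
    want <- oracle_nj(D)
    expect_equal(phangorn::RF.dist(got, want), 0)
    expect_lt(tree_metric_gap(got, want), 1e-9)
  }
})

test_that("NJ and BioNJ are invariant to input taxon order; FNJ on additive inputs", {
  tr <- random_tree(12, seed = 430)
  D <- additive_matrix(tr)
  set.seed(431)
  perm <- sample(12)
  Dp <- D[perm, perm]
  for (build in list(nj_tree, bionj_tree, fnj_tree)) {
    expect_equal(phangorn::RF.dist(build(D), build(Dp)), 0)
    expect_lt(tree_metric_gap(build(D), build(Dp)), 1e-10)
  }
  # order invariance on a non-additive matrix for NJ/BioNJ
  Dr <- random_dm(9, 432)
  p2 <- sample(9)
  Drp <- Dr[p2, p2]
  expect_equal(phangorn::RF.dist(nj_tree(Dr), nj_tree(Drp)), 0)
  expect_equal(phangorn::RF.dist(bionj_tree(Dr), bionj_tree(Drp)), 0)
})

test_that("NJ agrees with ape's independent implementation on additive matrices", {
  for (s in 1:5) {
    tr <- random_tree(15, seed = 440 + s)
    D <- additive_matrix(tr)
    got <- nj_tree(D)
    ref <- ape::nj(D)
    expect_equal(phangorn::RF.dist(got, ref), 0)
    expect_lt(tree_metric_gap(got, ref), 1e-8)
  }
})

test_that("FNJ does quadratic selection work and matches NJ on perturbed matrices too", {
  evals <- vapply(c(40, 80, 160), function(n) {
    D <- additive_matrix(random_tree(n, seed = n + 450))
    attr(fnj_tree(D), "s_evaluations")
  }, 0)
  expect_true(all(evals <= 4 * c(40, 80, 160)^2))
  # noisy (near-additive) matrices: FNJ still produces a valid tree
  D <- additive_matrix(random_tree(20, seed = 451))
  set.seed(452)
  noise <- matrix(rnorm(400, 0, 0.01), 20, 20)
  noise <- (noise + t(noise)) / 2; diag(noise) <- 0
  tr <- fnj_tree(pmax(D + noise, 1e-6))
  expect_equal(nrow(tr$edge), 37)
})

test_that("BioNJ lambda stays within [0,1] and improves on noisy matrices on average", {
  # lambda clamping is structural: reconstruct from random matrices
  for (s in 1:5) {
    D <- random_dm(10, 460 + s)
    tr <- bionj_tree(D)      # would error/NaN if lambda escaped the clamp
    expect_true(all(is.finite(tr$edge.length)))
  }
  # distance-proportional noise: BioNJ topology accuracy is not worse than NJ
  rf_nj <- rf_bionj <- numeric(30)
  for (s in 1:30) {
    tr <- random_tree(20, seed = 470 + s)
    D <- additive_matrix(tr)
    set.seed(500 + s)
    eps <- matrix(rnorm(400, 0, 0.2), 20, 20) * D
    eps <- (eps + t(eps)) / 2; diag(eps) <- 0
    Dn <- pmax(D + eps, 1e-6); diag(Dn) <- 0
    rf_nj[s] <- phangorn::RF.dist(nj_tree(Dn), tr)
    rf_bionj[s] <- phangorn::RF.dist(bionj_tree(Dn), tr)
  }
  delta <- rf_bionj - rf_nj
  expect_lte(mean(delta), 3 * stats::sd(delta) / sqrt(length(delta)))
})

test_that("degenerate inputs are rejected with clear errors", {
  D <- matrix(c(0, NA, NA, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(D), "non-finite")
  expect_error(nj_tree(matrix(0, 1, 1)), "at least 2")
})

test_that("branch-length clamping transfers the deficit to adjacent edges", {
  D <- random_dm(8, 480)
  tr <- nj_tree(D)
  if (any(tr$edge.length < 0)) {
    cl <- nj_tree(D, min_branch_length = 0)
    expect_true(all(cl$edge.length >= 0))
    # total tree length is preserved by the transfer
    expect_equal(sum(cl$edge.length), sum(tr$edge.length), tolerance = 1e-9)
  } else succeed("no negative branches in this draw")
})
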