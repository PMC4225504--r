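test_that("protein pair counting excludes gap/X sites and matches a per-site oracle", {
  cc <- count_pair_protein("AR", "AR")
  expect_equal(cc$table["A", "A"], 1)
  expect_equal(cc$table["R", "R"], 1)
  expect_equal(cc$valid_sites, 2)
  expect_equal(count_pair_protein("A-X", "AAA")$valid_sites, 1)

  set.seed(201)
  res <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  a <- sample(c(res, "X", "-"), 350, TRUE)
  b <- sample(c(res, "X", "-"), 350, TRUE)
  got <- count_pair_protein(paste0(a, collapse = ""), paste0(b, collapse = ""))
  want <- matrix(0, 20, 20, dimnames = list(res, res))
  for (s in seq_along(a))
    if (a[s] %in% res && b[s] %in% res)
      want[a[s], b[s]] <- want[a[s], b[s]] + 1
  expect_equal(unname(got$table), unname(want))
})

test_that("every bundled model is a valid reversible rate-1 generator", {
  for (nm in c("WAG", "JTT", "DAY", "MVR", "LG")) {
    m <- aa_model(nm)
    expect_equal(sum(m$frequencies), 1, tolerance = 1e-9)
    expect_lt(max(abs(rowSums(m$generator))), 1e-10)
    expect_equal(-sum(m$frequencies * diag(m$generator)), 1, tolerance = 1e-9)
    flux <- diag(m$frequencies) %*% m$generator
    expect_lt(max(abs(flux - t(flux))), 1e-10)          # detailed balance
    expect_true(all(m$eigenvalues < 1e-8))
    expect_equal(sum(abs(m$eigenvalues) < 1e-8), 1)     # one zero eigenvalue
    # spectrum reconstructs the generator
    Q_back <- m$A %*% (m$eigenvalues * m$B)
    expect_lt(max(abs(Q_back - m$generator)), 1e-10)
  }
})

test_that("P(d) is stochastic, satisfies the semigroup property, and tends to pi", {
  m <- aa_model("LG")
  for (d in c(0.01, 0.1, 1, 10)) {
    P <- phylodist:::aa_transition(m, d)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P > -1e-12))
  }
  P_s <- phylodist:::aa_transition(m, 0.4)
  P_t <- phylodist:::aa_transition(m, 0.9)
  P_st <- phylodist:::aa_transition(m, 1.3)
  expect_lt(max(abs(P_s %*% P_t - P_st)), 1e-8)
  P_inf <- phylodist:::aa_transition(m, 500)
  expect_lt(max(abs(sweep(P_inf, 2, m$frequencies))), 1e-10)
})

test_that("pair log-likelihood matches an independent matrix-exponential oracle", {
  m <- aa_model("WAG")
  aln <- evolve_pair(0.7, 350, "WAG", seed = 202)
  cc <- count_pair_protein(aln$rows[1], aln$rows[2])
  d <- 0.7
  P_oracle <- as.matrix(Matrix::expm(m$generator * d))
  ll_oracle <- sum(cc$table * log(m$frequencies * P_oracle))
  expect_equal(pair_log_likelihood(cc, m, d), ll_oracle, tolerance = 1e-8)
  # P(0) = identity: identical sequences score sum N_aa log pi_a
  id_cc <- count_pair_protein(aln$rows[1], aln$rows[1])
  expect_equal(pair_log_likelihood(id_cc, m, 0),
               sum(diag(id_cc$table) * log(m$frequencies)))
  expect_error(pair_log_likelihood(cc, m, -0.1), "domain error")
})

test_that("ML distance matches a grid-search oracle and handles the boundaries", {
  m <- aa_model("WAG")
  for (s in 1:3) {
    aln <- evolve_pair(c(0.1, 0.5, 1.2)[s], 350, "WAG", seed = 210 + s)
    cc <- count_pair_protein(aln$rows[1], aln$rows[2])
    est <- ml_distance(cc, m)
    coarse <- seq(1e-6, 10, length.out = 1e4)
    ll <- vapply(coarse, function(d) pair_log_likelihood(cc, m, d), 0)
    d0 <- coarse[which.max(ll)]
    fine <- seq(max(1e-6, d0 - 2e-3), d0 + 2e-3, length.out = 1e4)
    llf <- vapply(fine, function(d) pair_log_likelihood(cc, m, d), 0)
    expect_lt(abs(est - fine[which.max(llf)]), 1e-4)
  }
  # identical pair: likelihood decreasing in d from the start
  id_cc <- count_pair_protein(strrep("A", 350), strrep("A", 350))
  expect_equal(ml_distance(id_cc, m), 1e-6)
})

test_that("expected distance: two-point prior midpoint, posterior concentration, fine-grid oracle", {
  m <- aa_model("WAG")
  # symmetric two-point prior with equal likelihoods (zero counts)
  cc0 <- count_pair_protein("", "")
  cc0$table[] <- 0
  cc0$valid_sites <- 1  # bypass the empty-overlap guard; likelihood is flat
  pr <- distance_prior(grid = c(0.2, 0.8), weights = c(0.5, 0.5))
  expect_equal(expected_distance(cc0, m, pr), 0.5)

  # large alignments: posterior mean approaches the ML point estimate
  aln <- evolve_pair(0.3, 1e4, "WAG", seed = 220)
  cc <- count_pair_protein(aln$rows[1], aln$rows[2])
  expect_lt(abs(expected_distance(cc, m) - ml_distance(cc, m)), 0.01)

  # independent quadrature over the same prior, likelihoods via Matrix::expm
  aln2 <- evolve_pair(0.5, 350, "WAG", seed = 221)
  cc2 <- count_pair_protein(aln2$rows[1], aln2$rows[2])
  pr2 <- distance_prior()
  ll <- vapply(pr2$grid, function(d)
    sum(cc2$table * log(m$frequencies *
                          as.matrix(Matrix::expm(m$generator * d)))), 0)
  w <- pr2$weights * exp(ll - max(ll))
  expect_equal(expected_distance(cc2, m, pr2), sum(pr2$grid * w) / sum(w),
               tolerance = 1e-4)

  # extending a flat prior's support never shrinks a saturated estimate
  sat <- count_pair_protein(paste0(rep(c("A", "R"), 50), collapse = ""),
                            paste0(rep(c("R", "A"), 50), collapse = ""))
  e1 <- expected_distance(sat, m, distance_prior(
    grid = exp(seq(log(1e-4), log(5), length.out = 200))))
  e2 <- expected_distance(sat, m, distance_prior(
    grid = exp(seq(log(1e-4), log(10), length.out = 200))))
  expect_gte(e2, e1)
})

test_that("protein corrections match frozen closed-form evaluations", {
  expect_equal(jc20_distance(0), 0)
  expect_equal(kimura_protein_distance(0), 0)
  expect_equal(jc20_distance(0.5), 0.70985368173871003, tolerance = 1e-12)
  expect_equal(kimura_protein_distance(0.5), 0.79850769621777162,
               tolerance = 1e-12)
  expect_true(is.na(jc20_distance(0.96)))  # beyond the 19/20 domain bound
})

test_that("the protein matrix builder exposes exactly seven estimators", {
  expect_length(phylodist:::.protein_estimators, 7L)
  aln <- alignment(c("a", "b"), c("ARND", "ARND"), "protein")
  expect_error(protein_distance_matrix(aln, estimator = "pam"),
               "jc, jck, wag, jtt, day, mvr, lg")
  expect_true(all(protein_distance_matrix(aln, "jc") == 0))
  expect_true(all(protein_distance_matrix(aln, "jck") == 0))
})

test_that("protein streaming equals the in-memory matrix bit-for-bit", {
  tr <- random_tree(10, seed = 230)
  aln <- evolve_sequences(tr, 120, "LG", seed = 231)
  M <- protein_distance_matrix(aln, "lg", method = "ml")
  rows <- list()
  protein_distance_matrix(aln, "lg", method = "ml",
                          row_sink = function(i, r) rows[[i]] <<- r)
  n <- length(aln$taxa)
  R <- matrix(0, n, n, dimnames = dimnames(M))
  for (i in seq_len(n - 1)) {
    R[i, (i + 1):n] <- rows[[i]]
    R[(i + 1):n, i] <- rows[[i]]
  }
  expect_identical(R, M)
})
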