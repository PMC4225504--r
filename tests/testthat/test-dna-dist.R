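test_that("pair counting matches hand categories and the per-site oracle", {
  cc <- count_pair("ACGT", "ACGA")
  expect_equal(cc$valid_sites, 4)
  expect_equal(cc$matches, 3)
  expect_equal(cc$tv, 1)          # T vs A is a transversion
  expect_equal(cc$ts_AG + cc$ts_CT, 0)

  cc <- count_pair("AN-T", "AC-T", ambiguity = FALSE)
  expect_equal(cc$valid_sites, 2)
  expect_equal(cc$matches, 2)

  set.seed(101)
  for (rep in 1:5) {
    a <- paste0(sample(c("A", "C", "G", "T", "-"), 300, TRUE), collapse = "")
    b <- paste0(sample(c("A", "C", "G", "T", "-"), 300, TRUE), collapse = "")
    got <- count_pair(a, b, ambiguity = FALSE)
    want <- oracle_count_pair(a, b)
    expect_equal(got$valid_sites, unname(want["valid"]))
    expect_equal(got$matches, unname(want["matches"]))
    expect_equal(got$ts_AG, unname(want["ts_AG"]))
    expect_equal(got$ts_CT, unname(want["ts_CT"]))
    expect_equal(got$tv, unname(want["tv"]))
  }
})

test_that("ambiguity weighting is the uniform expectation over candidate sets", {
  cc <- count_pair("A", "R")
  expect_equal(cc$valid_sites, 1)
  expect_equal(cc$matches, 0.5)
  expect_equal(cc$ts_AG, 0.5)

  # N vs C: candidates {A,C,G,T} x {C}: one match, one ts (T/C), two tv
  cc <- count_pair("N", "C")
  expect_equal(cc$matches, 0.25)
  expect_equal(cc$ts_CT, 0.25)
  expect_equal(cc$tv, 0.5)
})

test_that("category conservation and frequency normalisation hold with and without ambiguity", {
  set.seed(102)
  syms <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N", "-")
  for (rep in 1:10) {
    a <- paste0(sample(syms, 200, TRUE), collapse = "")
    b <- paste0(sample(syms, 200, TRUE), collapse = "")
    for (amb in c(TRUE, FALSE)) {
      cc <- count_pair(a, b, ambiguity = amb)
      expect_equal(cc$matches + cc$ts_AG + cc$ts_CT + cc$tv, cc$valid_sites,
                   tolerance = 1e-9)
      expect_equal(sum(cc$freq), 2 * cc$valid_sites, tolerance = 1e-9)
    }
    # symmetry
    cc_ab <- count_pair(a, b); cc_ba <- count_pair(b, a)
    expect_equal(cc_ab$valid_sites, cc_ba$valid_sites)
    expect_equal(cc_ab$matches, cc_ba$matches)
    expect_equal(cc_ab$tv, cc_ba$tv)
  }
})

test_that("ambiguity mode on unambiguous input equals non-ambiguity mode exactly", {
  tr <- random_tree(6, seed = 51)
  aln <- evolve_sequences(tr, 400, "K2P", seed = 52)
  expect_identical(distance_matrix(aln, "k2p", ambiguity = TRUE),
                   distance_matrix(aln, "k2p", ambiguity = FALSE))
})

test_that("closed-form corrections match frozen high-precision values", {
  expect_equal(p_distance(make_dna_counts(4, 4, 0, 0, 0)), 0)
  expect_equal(p_distance(make_dna_counts(4, 3, 0, 0, 1)), 0.25)
  expect_equal(jc_distance(make_dna_counts(4, 3, 0, 0, 1)),
               0.30409883108112329, tolerance = 1e-12)
  expect_true(is.na(jc_distance(make_dna_counts(4, 1, 1, 1, 1))))  # p = 0.75
  cc <- make_dna_counts(20, 17, 1, 1, 1)               # P = 0.1, Q = 0.05
  expect_equal(k2p_distance(cc), 0.17018116514034703, tolerance = 1e-12)
  expect_equal(k2p_distance(make_dna_counts(9, 9, 0, 0, 0)), 0)
})

test_that("K2P collapses to JC and TN93 collapses to K2P on the reduction grids", {
  for (p in seq(0.03, 0.72, by = 0.03)) {
    # equal-rate differences: P = p/3, Q = 2p/3 (counts on 3 sites)
    cj <- make_dna_counts(3, 3 - 3 * p, p / 2, p / 2, 2 * p)
    expect_equal(k2p_distance(cj), jc_distance(cj), tolerance = 1e-12)
  }
  for (P in c(0.02, 0.1, 0.2)) for (Q in c(0.02, 0.1, 0.2)) {
    cc <- make_dna_counts(1, 1 - P - Q, P / 2, P / 2, Q)
    expect_equal(tn93_distance(cc), k2p_distance(cc), tolerance = 1e-12)
  }
})

test_that("estimators are monotone in their difference proportions", {
  jc_vals <- vapply(seq(0, 0.7, 0.05), function(p)
    jc_distance(make_dna_counts(1, 1 - p, p / 3, p / 3, p / 3)), 0)
  expect_true(all(diff(jc_vals) > 0))
  k2p_P <- vapply(seq(0, 0.35, 0.05), function(P)
    k2p_distance(make_dna_counts(1, 1 - P - 0.1, P / 2, P / 2, 0.1)), 0)
  expect_true(all(diff(k2p_P) > 0))
})

test_that("identical sequences give a zero matrix; default model is K2P", {
  aln <- alignment(c("a", "b", "c"), rep("ACGTACGT", 3), "dna")
  expect_true(all(distance_matrix(aln) == 0))
  tr <- random_tree(5, seed = 61)
  aln2 <- evolve_sequences(tr, 200, "K2P", seed = 62)
  expect_identical(distance_matrix(aln2), distance_matrix(aln2, model = "k2p"))
})

test_that("saturated entries are flagged NA and can be substituted", {
  aln <- alignment(c("a", "b"), c("AAAACCCC", "CCCCAAAA"), "dna")  # p = 1
  D <- distance_matrix(aln, model = "jc")
  expect_true(is.na(D["a", "b"]))
  D2 <- distance_matrix(aln, model = "jc", saturation_distance = 9.9)
  expect_equal(D2["a", "b"], 9.9)
})

test_that("streamed rows reassemble to the in-memory matrix bit-for-bit", {
  tr <- random_tree(30, seed = 71)
  aln <- evolve_sequences(tr, 300, "TN93", seed = 72,
                          pi = c(A = 0.35, C = 0.15, G = 0.25, T = 0.25))
  M <- distance_matrix(aln, "tn93", ambiguity = FALSE)
  rows <- list()
  distance_matrix(aln, "tn93", ambiguity = FALSE,
                  row_sink = function(i, r) rows[[i]] <<- r)
  n <- length(aln$taxa)
  R <- matrix(0, n, n, dimnames = dimnames(M))
  for (i in seq_len(n - 1)) {
    R[i, (i + 1):n] <- rows[[i]]
    R[(i + 1):n, i] <- rows[[i]]
  }
  expect_identical(R, M)
})

test_that("streaming with ambiguity is rejected as an unsupported combination", {
  aln <- alignment(c("a", "b"), c("ACGT", "ACGA"), "dna")
  expect_error(distance_matrix(aln, row_sink = function(i, r) NULL),
               "unsupported combination")
})

test_that("row partitioning covers the rows disjointly and balances pair workload", {
  expect_equal(partition_rows(4, 1), list(c(0, 4)))
  pr <- partition_rows(10, 3)
  got <- unlist(lapply(pr, function(r) seq(r[1], r[2] - 1)))
  expect_equal(sort(got), 0:9)
  expect_error(partition_rows(4, 5), "blocks")

  n <- 1000
  pr <- partition_rows(n, 8)
  loads <- vapply(pr, function(r)
    sum((n - 1) - seq(r[1], r[2] - 1)), 0)
  expect_lt(max(loads) - min(loads), n)  # within the largest single row
})
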