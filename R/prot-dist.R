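# Protein distance estimation: correction formulas on the proportion of
# differing sites (JC-20, Kimura), and model-based pairwise maximum
# likelihood / posterior expectation under the bundled empirical models.

encode_protein <- function(s) {
  x <- match(strsplit(s, "", fixed = TRUE)[[1L]], c(.aa_residues, "X", "-"))
  if (anyNA(x))
    stop("alphabet error: non-amino-acid character in protein sequence")
  x[x > 20L] <- 0L           # X and gap are excluded from counting
  x
}

#' Residue pair counts for two aligned protein sequences
#'
#' Tallies aligned residue pairs into a 20 x 20 table `N[a, b]` (residue
#' order `ARNDCQEGHILKMFPSTWYV`); sites where either sequence has a gap or
#' `X` are excluded.
#'
#' @param row_a,row_b character scalars (aligned protein sequences).
#' @return A list of class `pair_counts_protein` with fields `table`
#'   (20 x 20) and `valid_sites`.
#' @examples
#' count_pair_protein("AR", "AR")$valid_sites
#' @export
count_pair_protein <- function(row_a, row_b) {
  a <- if (is.character(row_a)) encode_protein(toupper(row_a)) else row_a
  b <- if (is.character(row_b)) encode_protein(toupper(row_b)) else row_b
  if (length(a) != length(b))
    stop("alignment shape error: sequence lengths ", length(a), " and ",
         length(b), " differ")
  keep <- a > 0L & b > 0L
  a <- a[keep]; b <- b[keep]
  N <- matrix(tabulate((a - 1L) * 20L + b, nbins = 400L), 20L, 20L,
              byrow = TRUE, dimnames = list(.aa_residues, .aa_residues))
  structure(list(table = N, valid_sites = sum(N)),
            class = "pair_counts_protein")
}

#' Pairwise log-likelihood of an aligned protein pair at distance d
#'
#' Returns `sum_ab N[a,b] log(pi_a P_ab(d))` with `P(d) = expm(Q d)`
#' evaluated through the model's spectral decomposition.  As `d` grows,
#' `P_ab(d)` tends to `pi_b` (stationarity).
#'
#' @param c a `pair_counts_protein`.
#' @param m an [aa_model].
#' @param d distance, `d >= 0`, in expected substitutions per site.
#' @return The log-likelihood (a real scalar).
#' @export
pair_log_likelihood <- function(c, m, d) {
  if (d < 0) stop("domain error: distance must be non-negative")
  P <- aa_transition(m, d)
  P[P < 1e-300] <- 1e-300
  sum(c$table * (log(m$frequencies) + log(P)))
}

# First/second derivative of the log-likelihood in d, from the spectrum.
pair_ll_deriv <- function(c, m, d) {
  P <- aa_transition(m, d)
  P[P < 1e-300] <- 1e-300
  P1 <- aa_transition(m, d, deriv = 1L)
  P2 <- aa_transition(m, d, deriv = 2L)
  r <- P1 / P
  list(d1 = sum(c$table * r),
       d2 = sum(c$table * (P2 / P - r * r)))
}

#' Maximum-likelihood pairwise protein distance
#'
#' Maximises [pair_log_likelihood()] over `d` in `[d_min, d_max]` by
#' Newton-Raphson on the analytic first derivative (analytic second
#' derivative, spectrum-based), falling back to golden-section search when
#' the iteration leaves the bracket or fails to converge.  An all-identical
#' pair returns `d_min`; a likelihood still increasing at `d_max` returns
#' `d_max` carrying a `saturated` attribute.
#'
#' @param c a `pair_counts_protein` with `valid_sites > 0`.
#' @param m an [aa_model].
#' @param d_min,d_max search bracket (expected substitutions per site).
#' @param tol convergence tolerance on the derivative step.
#' @param max_iter Newton-Raphson iteration cap.
#' @return The ML distance estimate.
#' @export
ml_distance <- function(c, m, d_min = 1e-6, d_max = 10, tol = 1e-8,
                        max_iter = 50L) {
  if (c$valid_sites <= 0) stop("no overlapping sites: ML distance undefined")
  g <- function(d) pair_ll_deriv(c, m, d)
  if (g(d_min)$d1 <= 0) return(d_min)           # decreasing from the start
  if (g(d_max)$d1 >= 0)
    return(structure(d_max, saturated = TRUE))  # still increasing at d_max
  p <- 1 - sum(diag(c$table)) / c$valid_sites
  d <- kimura_protein_distance(p)
  if (is.na(d) || d <= d_min || d >= d_max) d <- min(max(p, d_min * 10), d_max / 2)
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    dv <- g(d)
    if (dv$d2 >= 0) break                       # not locally concave: bail out
    step <- dv$d1 / dv$d2
    d_new <- d - step
    if (d_new <= d_min || d_new >= d_max) break # left the bracket
    d <- d_new
    if (abs(step) < tol) { ok <- TRUE; break }
  }
  if (ok) return(d)
  golden_max(function(x) pair_log_likelihood(c, m, x), d_min, d_max,
             tol = 1e-10)
}

# Golden-section maximisation of a unimodal function on [a, b].
golden_max <- function(f, a, b, tol = 1e-10) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol * (1 + abs(a) + abs(b))) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  (a + b) / 2
}

#' Prior over distances for the posterior-expected estimator
#'
#' The default is a flat prior on a 400-point geometric grid over
#' `[1e-4, 10]` expected substitutions per site.
#'
#' @param grid strictly increasing positive distance values.
#' @param weights prior mass per grid point; normalised to sum to 1.
#' @return A list of class `distance_prior`.
#' @export
distance_prior <- function(grid = exp(seq(log(1e-4), log(10), length.out = 400L)),
                           weights = NULL) {
  if (any(diff(grid) <= 0) || any(grid <= 0))
    stop("prior grid must be strictly increasing and positive")
  if (is.null(weights)) weights <- rep(1 / length(grid), length(grid))
  if (length(weights) != length(grid) || any(weights < 0))
    stop("prior weights must be non-negative, one per grid point")
  structure(list(grid = grid, weights = weights / sum(weights)),
            class = "distance_prior")
}

#' Posterior-expected pairwise protein distance
#'
#' Returns `E[d | a, b]` under the given prior: the likelihood-weighted mean
#' of the prior grid, computed with a log-sum-exp shift for numerical
#' safety.
#'
#' @param c a `pair_counts_protein` with `valid_sites > 0`.
#' @param m an [aa_model].
#' @param prior a [distance_prior].
#' @return The posterior mean distance.
#' @export
expected_distance <- function(c, m, prior = distance_prior()) {
  if (c$valid_sites <= 0) stop("no overlapping sites: distance undefined")
  ll <- vapply(prior$grid, function(d) pair_log_likelihood(c, m, d), 0)
  keep <- prior$weights > 0
  shift <- max(ll[keep])
  w <- prior$weights[keep] * exp(ll[keep] - shift)
  if (!any(w > 0)) stop("degenerate posterior: zero mass everywhere")
  sum(prior$grid[keep] * w) / sum(w)
}

#' Protein distance corrections on the proportion of differing sites
#'
#' `jc20_distance` is the 20-state Jukes-Cantor correction
#' `d = -(19/20) log(1 - 20 p / 19)`; `kimura_protein_distance` the Kimura
#' correction `d = -log(1 - p - 0.2 p^2)`.  Out-of-domain `p` returns `NA`
#' (saturation).
#'
#' @param p proportion of differing sites, in `[0, 1]`.
#' @return Distance in expected substitutions per site, or `NA`.
#' @examples
#' jc20_distance(0.5)
#' kimura_protein_distance(0.5)
#' @export
jc20_distance <- function(p) {
  w <- 1 - 20 * p / 19
  ifelse(w <= 0, NA_real_, -(19 / 20) * log(w))
}

#' @rdname jc20_distance
#' @export
kimura_protein_distance <- function(p) {
  w <- 1 - p - 0.2 * p * p
  ifelse(w <= 0, NA_real_, -log(w))
}

.protein_estimators <- c("jc", "jck", "wag", "jtt", "day", "mvr", "lg")

#' Pairwise distance matrix from a protein alignment
#'
#' Seven selectable distance functions: the `jc` and `jck` corrections on
#' the observed proportion of differing sites, and the five empirical
#' models `wag`, `jtt`, `day`, `mvr`, `lg` used with either the
#' maximum-likelihood (`method = "ml"`, default) or the posterior-expected
#' (`method = "expected"`) estimator.  The streaming contract matches
#' [distance_matrix()]: with `row_sink` given, one row is retained at a
#' time and streamed values equal in-memory values bit-for-bit.
#'
#' @param aln a protein [alignment] with at least 2 taxa.
#' @param estimator one of `"jc"`, `"jck"`, `"wag"` (default), `"jtt"`,
#'   `"day"`, `"mvr"`, `"lg"`.
#' @param method `"ml"` or `"expected"` (model-based estimators only).
#' @param prior a [distance_prior] for `method = "expected"`.
#' @param row_sink optional `function(i, row)` row consumer (streaming).
#' @param saturation_distance substitute for saturated entries (default NA).
#' @return A symmetric named matrix, or `NULL` in streaming mode.
#' @export
protein_distance_matrix <- function(aln, estimator = "wag",
                                    method = c("ml", "expected"),
                                    prior = distance_prior(),
                                    row_sink = NULL,
                                    saturation_distance = NA_real_) {
  stopifnot(inherits(aln, "alignment"))
  if (aln$alphabet != "protein")
    stop("protein_distance_matrix expects a protein alignment")
  estimator <- tolower(estimator)
  if (!estimator %in% .protein_estimators)
    stop("unknown estimator '", estimator, "'; valid: ",
         paste(.protein_estimators, collapse = ", "))
  method <- match.arg(method)
  n <- length(aln$taxa)
  if (n < 2L) stop("need at least 2 taxa")
  model <- if (estimator %in% c("wag", "jtt", "day", "mvr", "lg"))
    aa_model(estimator)
  enc <- lapply(aln$rows, encode_protein)
  pair_dist <- function(i, j) {
    cc <- count_pair_protein(enc[[i]], enc[[j]])
    if (cc$valid_sites == 0) return(NA_real_)
    if (is.null(model)) {
      p <- 1 - sum(diag(cc$table)) / cc$valid_sites
      if (estimator == "jc") jc20_distance(p) else kimura_protein_distance(p)
    } else if (method == "ml") {
      as.numeric(ml_distance(cc, model))
    } else {
      expected_distance(cc, model, prior)
    }
  }
  streaming <- !is.null(row_sink)
  D <- if (!streaming)
    matrix(0, n, n, dimnames = list(aln$taxa, aln$taxa))
  for (i in seq_len(n - 1L)) {
    row <- numeric(n - i)
    for (j in (i + 1L):n) {
      d <- pair_dist(i, j)
      if (is.na(d)) d <- saturation_distance
      row[j - i] <- d
    }
    if (streaming) row_sink(i, row)
    else { D[i, (i + 1L):n] <- row; D[(i + 1L):n, i] <- row }
  }
  if (streaming) invisible(NULL) else D
}
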