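# Nucleotide distance estimation: sufficient statistics per pair
# (match / A<->G transition / C<->T transition / transversion tallies and
# base-frequency weights), then the p, JC, K2P and TN93 corrections.
#
# IUPAC ambiguity codes are handled by fractional counting: a site pairing
# symbols with candidate sets S_a, S_b contributes weight 1/(|S_a||S_b|) to
# the substitution category of every (x, y) in S_a x S_b, and counts as one
# valid site.  With unambiguous input this reduces exactly to integer
# counting.

# symbol codes: gap=0, A=1, C=2, G=3, T=4, ambiguity codes 5..15
.dna_syms <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")
.dna_sets <- list(1L, 2L, 3L, 4L,
                  c(1L, 3L), c(2L, 4L), c(2L, 3L), c(1L, 4L), c(3L, 4L),
                  c(1L, 2L), c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L),
                  c(1L, 2L, 3L), 1:4)

# Category of an unambiguous ordered base pair (1..4, 1..4):
# 1 match, 2 ts A<->G, 3 ts C<->T, 4 transversion.
.base_category <- local({
  m <- matrix(4L, 4L, 4L)
  diag(m) <- 1L
  m[1L, 3L] <- m[3L, 1L] <- 2L
  m[2L, 4L] <- m[4L, 2L] <- 3L
  m
})

# Precomputed weight tables over the 15 x 15 IUPAC code pairs:
# .pair_cat_w[p, k] is the fractional weight code-pair p contributes to
# category k; .pair_freq_w[p, b] its contribution to base-frequency tallies
# (both sequences, so each row sums to 2).
.pair_tables <- local({
  cat_w <- matrix(0, 225L, 4L)
  freq_w <- matrix(0, 225L, 4L)
  for (a in 1:15) for (b in 1:15) {
    p <- (a - 1L) * 15L + b
    Sa <- .dna_sets[[a]]; Sb <- .dna_sets[[b]]
    w <- 1 / (length(Sa) * length(Sb))
    for (x in Sa) for (y in Sb)
      cat_w[p, .base_category[x, y]] <- cat_w[p, .base_category[x, y]] + w
    for (x in Sa) freq_w[p, x] <- freq_w[p, x] + 1 / length(Sa)
    for (y in Sb) freq_w[p, y] <- freq_w[p, y] + 1 / length(Sb)
  }
  list(cat = cat_w, freq = freq_w)
})

encode_dna <- function(s) {
  x <- match(strsplit(s, "", fixed = TRUE)[[1L]], c(.dna_syms, "-"))
  if (anyNA(x))
    stop("alphabet error: non-IUPAC character in DNA sequence")
  x[x == 16L] <- 0L
  x
}

#' Pair counts for two aligned DNA sequences
#'
#' Computes the sufficient statistics for the nucleotide distance
#' estimators: the effective number of comparable sites, the match weight,
#' the two transition-class weights (A/G and C/T), the transversion weight,
#' and per-base frequency tallies.  Sites where either sequence has a gap
#' are excluded (pairwise deletion).  With `ambiguity = FALSE` sites holding
#' any non-ACGT symbol are excluded too; with `ambiguity = TRUE` ambiguous
#' sites contribute fractionally (uniform expectation over the candidate-set
#' product).
#'
#' @param row_a,row_b character scalars (aligned DNA sequences) or integer
#'   codes from the internal encoder.
#' @param ambiguity logical; count IUPAC-ambiguous sites fractionally.
#' @return A list of class `pair_counts_dna` with fields `valid_sites`,
#'   `matches`, `ts_AG`, `ts_CT`, `tv` and `freq` (named length-4 vector
#'   summing to twice `valid_sites`).
#' @examples
#' count_pair("ACGT", "ACGA")
#' count_pair("A", "R", ambiguity = TRUE)
#' @export
count_pair <- function(row_a, row_b, ambiguity = TRUE) {
  a <- if (is.character(row_a)) encode_dna(toupper(row_a)) else row_a
  b <- if (is.character(row_b)) encode_dna(toupper(row_b)) else row_b
  if (length(a) != length(b))
    stop("alignment shape error: sequence lengths ", length(a), " and ",
         length(b), " differ")
  keep <- a > 0L & b > 0L
  if (!ambiguity) keep <- keep & a <= 4L & b <= 4L
  a <- a[keep]; b <- b[keep]
  tab <- tabulate((a - 1L) * 15L + b, nbins = 225L)
  cats <- as.numeric(crossprod(tab, .pair_tables$cat))
  freq <- as.numeric(crossprod(tab, .pair_tables$freq))
  names(freq) <- c("A", "C", "G", "T")
  structure(list(valid_sites = sum(tab), matches = cats[1L],
                 ts_AG = cats[2L], ts_CT = cats[3L], tv = cats[4L],
                 freq = freq),
            class = "pair_counts_dna")
}

# Saturated / undefined corrections are flagged as NA_real_; the matrix
# builder can substitute a fixed distance (saturation_distance).
.saturated <- function() structure(NA_real_, saturated = TRUE)

#' Nucleotide distance estimators
#'
#' `p_distance` is the proportion of differing sites; `jc_distance` the
#' Jukes-Cantor correction `-(3/4) log(1 - 4p/3)`; `k2p_distance` the Kimura
#' two-parameter correction `-(1/2) log(1-2P-Q) - (1/4) log(1-2Q)` with `P`
#' the transition and `Q` the transversion proportion; `tn93_distance` the
#' Tamura-Nei (1993) correction using the two transition classes and
#' per-pair base frequencies.  Out-of-domain proportions (a logarithm
#' argument at or below zero) return `NA` — a saturation flag — rather than
#' an error.
#'
#' @param c a `pair_counts_dna` from [count_pair()].
#' @return The distance in expected substitutions per site, or `NA` when
#'   saturated / undefined.
#' @examples
#' cc <- count_pair("ACGT", "ACGA")
#' p_distance(cc)
#' k2p_distance(cc)
#' @export
p_distance <- function(c) {
  if (c$valid_sites <= 0) return(.saturated())
  (c$valid_sites - c$matches) / c$valid_sites
}

#' @rdname p_distance
#' @export
jc_distance <- function(c) {
  p <- p_distance(c)
  if (is.na(p) || p >= 0.75) return(.saturated())
  -0.75 * log1p(-4 * p / 3)
}

#' @rdname p_distance
#' @export
k2p_distance <- function(c) {
  if (c$valid_sites <= 0) return(.saturated())
  P <- (c$ts_AG + c$ts_CT) / c$valid_sites
  Q <- c$tv / c$valid_sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(.saturated())
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' @rdname p_distance
#' @export
tn93_distance <- function(c) {
  if (c$valid_sites <= 0) return(.saturated())
  pi_ <- c$freq / sum(c$freq)
  if (any(pi_ <= 0))
    stop("degenerate composition: a base class has zero frequency; ",
         "TN93 is undefined")
  pR <- pi_[["A"]] + pi_[["G"]]
  pY <- pi_[["C"]] + pi_[["T"]]
  P1 <- c$ts_AG / c$valid_sites
  P2 <- c$ts_CT / c$valid_sites
  Q <- c$tv / c$valid_sites
  k1 <- 2 * pi_[["A"]] * pi_[["G"]] / pR
  k2 <- 2 * pi_[["T"]] * pi_[["C"]] / pY
  k3 <- 2 * (pR * pY - pi_[["A"]] * pi_[["G"]] * pY / pR -
               pi_[["T"]] * pi_[["C"]] * pR / pY)
  w1 <- 1 - P1 / k1 - Q / (2 * pR)
  w2 <- 1 - P2 / k2 - Q / (2 * pY)
  w3 <- 1 - Q / (2 * pR * pY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(.saturated())
  -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
}

.dna_estimators <- c("p", "jc", "k2p", "tn93")

dna_estimate <- function(counts, model) {
  switch(model,
         p = p_distance(counts),
         jc = jc_distance(counts),
         k2p = k2p_distance(counts),
         tn93 = tn93_distance(counts),
         stop("unknown DNA estimator '", model, "'; valid: ",
              paste(.dna_estimators, collapse = ", ")))
}

#' Pairwise distance matrix from a DNA alignment
#'
#' Computes the upper triangle row by row.  In streaming mode (`row_sink`
#' given) each finished row is handed to the consumer and discarded, so the
#' peak retained matrix state is a single row; streamed and in-memory modes
#' run the identical arithmetic and agree bit-for-bit.  The streaming
#' (memory-efficient / binary) pathway does not support ambiguity counting;
#' requesting both is an error.
#'
#' @param aln a DNA [alignment] with at least 2 taxa.
#' @param model `"p"`, `"jc"`, `"k2p"` (default) or `"tn93"`.
#' @param ambiguity count IUPAC-ambiguous sites fractionally (default TRUE;
#'   must be FALSE in streaming mode).
#' @param row_sink optional `function(i, row)` receiving, for each row `i`
#'   (1-based), the `n - i` upper-triangle entries; when given, no matrix is
#'   materialised and `NULL` is returned invisibly.
#' @param saturation_distance value substituted for saturated/undefined
#'   entries; default `NA` leaves them flagged missing.
#' @return A symmetric named matrix (zero diagonal), or `NULL` in streaming
#'   mode.
#' @examples
#' aln <- alignment(c("a", "b", "c"), c("ACGTACGT", "ACGAACGT", "ACTAACGA"), "dna")
#' distance_matrix(aln, model = "jc")
#' @export
distance_matrix <- function(aln, model = "k2p", ambiguity = TRUE,
                            row_sink = NULL, saturation_distance = NA_real_) {
  stopifnot(inherits(aln, "alignment"))
  if (aln$alphabet != "dna") stop("distance_matrix expects a DNA alignment")
  n <- length(aln$taxa)
  if (n < 2L) stop("need at least 2 taxa")
  model <- match.arg(model, .dna_estimators)
  streaming <- !is.null(row_sink)
  if (streaming && ambiguity)
    stop("unsupported combination: streaming (one-row-in-memory) mode ",
         "does not support ambiguity counting")
  enc <- lapply(aln$rows, encode_dna)
  D <- if (!streaming)
    matrix(0, n, n, dimnames = list(aln$taxa, aln$taxa))
  for (i in seq_len(n - 1L)) {
    row <- numeric(n - i)
    for (j in (i + 1L):n) {
      d <- dna_estimate(count_pair(enc[[i]], enc[[j]], ambiguity), model)
      if (is.na(d)) d <- saturation_distance
      row[j - i] <- d
    }
    if (streaming) row_sink(i, row)
    else { D[i, (i + 1L):n] <- row; D[(i + 1L):n, i] <- row }
  }
  if (streaming) invisible(NULL) else D
}

#' Balanced row partitioning of the upper-triangle workload
#'
#' Splits the `n` matrix rows into `blocks` contiguous half-open ranges
#' whose upper-triangle workloads (row `i`, 0-based, costs `n - 1 - i` pair
#' computations) are balanced to within the largest single row.  This is the
#' hook for trivially parallelising distance-matrix computation across
#' external jobs.
#'
#' @param n taxon count.
#' @param blocks number of ranges, `1 <= blocks <= n`.
#' @return A list of integer vectors `c(begin, end)` (0-based, half-open),
#'   disjoint and covering `[0, n)`.
#' @examples
#' partition_rows(10, 3)
#' @export
partition_rows <- function(n, blocks) {
  n <- as.integer(n); blocks <- as.integer(blocks)
  if (blocks < 1L || blocks > n)
    stop("blocks must be between 1 and n (= ", n, ")")
  work <- (n - 1L):0L           # cost of row i (0-based) is n-1-i pairs
  cum <- c(0, cumsum(work))     # cum[i+1] = work of rows [0, i)
  out <- vector("list", blocks)
  begin <- 0L
  for (b in seq_len(blocks)) {
    if (b == blocks) { out[[b]] <- c(begin, n); break }
    target <- cum[begin + 1L] + (cum[n + 1L] - cum[begin + 1L]) / (blocks - b + 1L)
    # stop at the cut whose cumulative workload is closest to the target,
    # taking at least one row and leaving one per remaining block
    lo <- begin + 1L
    hi <- n - (blocks - b)
    cand <- lo:hi
    end <- cand[which.min(abs(cum[cand + 1L] - target))]
    out[[b]] <- c(begin, end)
    begin <- end
  }
  out
}
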