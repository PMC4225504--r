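# Column-resampling bootstrap.  Replicate r draws its RNG state from
# (seed, r) alone — replicate_seed(seed, r) — so any replicate can be
# recomputed independently (e.g. one replicate per external job) and the
# full stream is byte-reproducible from the seed.

replicate_seed <- function(seed, r) {
  (as.double(seed) + 1000003 * as.double(r)) %% 2147483647
}

#' Resample alignment columns with replacement
#'
#' One bootstrap draw: columns are sampled i.i.d. uniformly with
#' replacement; taxa and site count are unchanged.
#'
#' @param aln an [alignment] with `n_sites >= 1`.
#' @return A resampled [alignment].
#' @export
resample_columns <- function(aln) {
  stopifnot(inherits(aln, "alignment"))
  if (aln$n_sites < 1L) stop("input error: empty alignment")
  m <- as_char_matrix(aln)
  idx <- sample.int(aln$n_sites, aln$n_sites, replace = TRUE)
  char_matrix_to_alignment(m[, idx, drop = FALSE], aln$alphabet)
}

#' Bootstrap replicate distance matrices
#'
#' Emits the original-data distance matrix first (unless
#' `keep_original = FALSE`, the `-k` behaviour), then `replicates` matrices
#' computed on column-resampled alignments.  Replicate `r` is reproducible
#' from `(seed, r)` alone.  When no seed is given, a clock-derived seed is
#' drawn and reported via a message.
#'
#' @param aln an [alignment] (DNA or protein).
#' @param replicates number of bootstrap replicates `B >= 0`.
#' @param keep_original emit the original-data matrix first (default TRUE).
#' @param seed integer seed; `NULL` draws one from the clock (reported).
#' @param estimator passed to [distance_matrix()] (DNA `model`) or
#'   [protein_distance_matrix()] (`estimator`).
#' @param ... further arguments for the underlying matrix builder.
#' @return A list of `B + keep_original` symmetric matrices, carrying the
#'   seed used as attribute `seed`.
#' @export
bootstrap_matrices <- function(aln, replicates = 0L, keep_original = TRUE,
                               seed = NULL, estimator = NULL, ...) {
  stopifnot(inherits(aln, "alignment"), replicates >= 0L)
  if (is.null(seed)) {
    seed <- as.integer(as.numeric(Sys.time()) %% 2147483647)
    message("bootstrap: using clock-derived seed ", seed)
  }
  compute <- function(a) {
    if (a$alphabet == "dna")
      distance_matrix(a, model = if (is.null(estimator)) "k2p" else estimator,
                      ...)
    else
      protein_distance_matrix(a, estimator = if (is.null(estimator)) "wag"
                                             else estimator, ...)
  }
  out <- vector("list", replicates + as.integer(keep_original))
  k <- 0L
  if (keep_original) { k <- 1L; out[[1L]] <- compute(aln) }
  for (r in seq_len(replicates)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(replicate_seed(seed, r))
    rep_aln <- resample_columns(aln)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    out[[k + r]] <- compute(rep_aln)
  }
  attr(out, "seed") <- seed
  out
}
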