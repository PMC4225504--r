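# Empirical amino-acid replacement models.  Each model is a symmetric
# exchangeability table S and stationary frequencies pi; the rate generator
# is Q[i,j] = S[i,j] * pi[j] (i != j), diagonal chosen so rows sum to zero,
# globally rescaled so the expected substitution rate at stationarity,
# -sum_i pi_i Q[i,i], equals 1 — distances are then in expected
# substitutions per site.  The transition matrix P(d) = expm(Q d) and its
# derivatives come from the spectral decomposition of the symmetrised
# generator  X = diag(sqrt(pi)) Q diag(1/sqrt(pi)),
# giving  P(d) = A exp(L d) B  with A = diag(1/sqrt(pi)) U,
# B = t(U) diag(sqrt(pi)), X = U L t(U).

.aa_residues <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]
.aa_model_names <- c("WAG", "JTT", "DAY", "MVR", "LG")
.aa_model_cache <- new.env(parent = emptyenv())

#' Load an empirical amino-acid substitution model
#'
#' Bundled models: `WAG` (Whelan-Goldman 2001), `JTT` (Jones-Taylor-Thornton
#' 1992), `DAY` (Dayhoff 1978), `MVR` (the Mueller-Vingron VT model, 2000)
#' and `LG` (Le-Gascuel 2008).  Tables are shipped as plain-text files
#' (lower-triangle exchangeabilities plus frequencies, residue order
#' `ARNDCQEGHILKMFPSTWYV`); loading validates symmetry, frequency
#' normalisation, detailed balance and the spectrum (all eigenvalues real
#' and non-positive, exactly one zero).
#'
#' @param name one of `"WAG"`, `"JTT"`, `"DAY"`, `"MVR"`, `"LG"`
#'   (case-insensitive).
#' @return An object of class `aa_model`: list with `name`,
#'   `exchangeabilities` (20 x 20 symmetric), `frequencies` (sums to 1),
#'   `generator` (rate-1 normalised Q), and the spectral factors
#'   `eigenvalues`, `A`, `B` with `P(d) = A diag(exp(eigenvalues * d)) B`.
#' @examples
#' m <- aa_model("WAG")
#' range(rowSums(m$generator))
#' @export
aa_model <- function(name) {
  key <- toupper(name)
  if (!key %in% .aa_model_names)
    stop("unknown amino-acid model '", name, "'; bundled models: ",
         paste(.aa_model_names, collapse = ", "))
  if (!is.null(.aa_model_cache[[key]])) return(.aa_model_cache[[key]])
  path <- system.file("extdata", "models", paste0(tolower(key), ".dat"),
                      package = "phylodist", mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  nums <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  if (length(nums) != 20L)
    stop("model file ", path, ": expected 19 triangle rows + 1 frequency row")
  S <- matrix(0, 20L, 20L, dimnames = list(.aa_residues, .aa_residues))
  for (i in 2:20) {
    if (length(nums[[i - 1L]]) != i - 1L)
      stop("model file ", path, ": triangle row ", i, " malformed")
    S[i, 1:(i - 1L)] <- nums[[i - 1L]]
  }
  S <- S + t(S)
  pi_ <- nums[[20L]]
  if (length(pi_) != 20L || any(pi_ <= 0))
    stop("model file ", path, ": bad frequency row")
  pi_ <- pi_ / sum(pi_)
  names(pi_) <- .aa_residues
  m <- build_aa_model(key, S, pi_)
  .aa_model_cache[[key]] <- m
  m
}

build_aa_model <- function(name, S, pi_) {
  stopifnot(isSymmetric(S), abs(sum(pi_) - 1) < 1e-9)
  Q <- S * rep(pi_, each = 20L)        # Q[i,j] = S[i,j] * pi[j]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi_ * diag(Q))            # expected rate at stationarity
  Q <- Q / mu
  # detailed balance must hold by construction: pi_i Q_ij == pi_j Q_ji
  flux <- diag(pi_) %*% Q
  if (max(abs(flux - t(flux))) > 1e-10)
    stop("model ", name, ": detailed balance violated")
  sq <- sqrt(pi_)
  X <- diag(sq) %*% Q %*% diag(1 / sq)
  X <- (X + t(X)) / 2
  eig <- eigen(X, symmetric = TRUE)
  lam <- eig$values
  if (any(lam > 1e-8) || sum(abs(lam) < 1e-8) != 1L)
    stop("model ", name, ": spectrum must be non-positive with one zero")
  A <- diag(1 / sq) %*% eig$vectors
  B <- t(eig$vectors) %*% diag(sq)
  structure(list(name = name, exchangeabilities = S, frequencies = pi_,
                 generator = Q, eigenvalues = lam, A = A, B = B),
            class = "aa_model")
}

#' @export
print.aa_model <- function(x, ...) {
  cat("aa_model ", x$name, ": 20x20 reversible generator, rate 1 at d = 1\n",
      sep = "")
  invisible(x)
}

# Transition matrix P(d) and its first two derivatives in d.
aa_transition <- function(m, d, deriv = 0L) {
  e <- exp(m$eigenvalues * d)
  if (deriv == 1L) e <- e * m$eigenvalues
  if (deriv == 2L) e <- e * m$eigenvalues^2
  m$A %*% (e * m$B)
}
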