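#' Multiple sequence alignment container
#'
#' An `alignment` is the package's central sequence container: an ordered set
#' of equal-length sequences over a declared alphabet.  DNA alignments may
#' contain the IUPAC ambiguity codes (`RYSWKMBDHVN`) and the gap symbol `-`;
#' protein alignments the 20 standard residues plus `X` and `-`.  Sequences
#' are stored upper-case; `U` is normalised to `T` on construction.
#'
#' @param taxa character vector of unique, non-empty identifiers.
#' @param rows character vector of sequences, one per taxon, equal lengths.
#' @param alphabet `"dna"` or `"protein"`.
#' @return An object of class `alignment`: a list with elements `taxa`,
#'   `rows`, `alphabet` and `n_sites`.
#' @examples
#' aln <- alignment(c("a", "b"), c("ACGT", "ACGA"), "dna")
#' aln$n_sites
#' @export
alignment <- function(taxa, rows, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  taxa <- as.character(taxa)
  rows <- toupper(as.character(rows))
  if (length(taxa) != length(rows))
    stop("alignment: ", length(taxa), " identifiers but ", length(rows), " sequences")
  if (any(!nzchar(taxa)))
    stop("alignment: empty taxon identifier")
  if (anyDuplicated(taxa))
    stop("identifier collision: duplicate taxon '",
         taxa[duplicated(taxa)][1L], "'")
  if (alphabet == "dna")
    rows <- gsub("U", "T", rows, fixed = TRUE)
  w <- nchar(rows)
  if (length(unique(w)) > 1L) {
    bad <- which(w != w[1L])[1L]
    stop("alignment shape error: sequence '", taxa[bad], "' has length ",
         w[bad], ", expected ", w[1L])
  }
  ok <- alphabet_symbols(alphabet)
  for (i in seq_along(rows)) {
    ch <- unique(strsplit(rows[i], "", fixed = TRUE)[[1L]])
    bad <- setdiff(ch, ok)
    if (length(bad))
      stop("alphabet error: sequence '", taxa[i], "' contains symbol '",
           bad[1L], "' not in the ", alphabet, " alphabet")
  }
  structure(list(taxa = taxa, rows = rows, alphabet = alphabet,
                 n_sites = if (length(w)) w[1L] else 0L),
            class = "alignment")
}

alphabet_symbols <- function(alphabet) {
  if (alphabet == "dna")
    c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
      "B", "D", "H", "V", "N", "-")
  else
    c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]], "X", "-")
}

#' @export
print.alignment <- function(x, ...) {
  cat("alignment: ", length(x$taxa), " ", x$alphabet, " sequences, ",
      x$n_sites, " sites\n", sep = "")
  invisible(x)
}

format.alignment <- function(x, ...) {
  paste0("alignment(", length(x$taxa), " x ", x$n_sites, ", ", x$alphabet, ")")
}

# Character matrix view (taxa x sites); used by the bootstrap resampler.
as_char_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  rownames(m) <- aln$taxa
  m
}

char_matrix_to_alignment <- function(m, alphabet) {
  alignment(rownames(m), apply(m, 1L, paste0, collapse = ""), alphabet)
}

# Guess the alphabet from observed symbols.  Sequences over ACGTU + IUPAC
# codes + gap are called DNA; anything else protein.
detect_alphabet <- function(rows) {
  ch <- unique(strsplit(paste(toupper(rows), collapse = ""), "")[[1L]])
  dna <- c(alphabet_symbols("dna"), "U")
  if (all(ch %in% dna)) "dna" else "protein"
}
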