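#' Read a FASTA alignment
#'
#' Parses FASTA via [Biostrings::readBStringSet()] and validates the result as
#' an alignment.  The identifier is the header text up to the first
#' whitespace; sequence case is normalised to upper (and `U` to `T` for DNA).
#' Record order is preserved.
#'
#' @param file path to a FASTA file, or a connection; `"-"` reads stdin.
#' @param alphabet `"auto"` (default), `"dna"` or `"protein"`.  With
#'   `"auto"`, sequences whose symbols all fall in the IUPAC nucleotide set
#'   are treated as DNA.
#' @return An [alignment].
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT", ">b", "ACGA"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(file, alphabet = c("auto", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  file <- slurp_to_path(file)
  if (file.size(file) == 0L)
    stop("empty input: no FASTA records found")
  set <- tryCatch(Biostrings::readBStringSet(file),
                  error = function(e) stop("FASTA parse error: ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) < 1L)
    stop("empty input: no FASTA records found")
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("identifier collision: duplicate record '",
         ids[duplicated(ids)][1L], "'")
  w <- Biostrings::width(set)
  if (length(unique(w)) > 1L) {
    bad <- which(w != w[1L])[1L]
    stop("alignment shape error: record '", ids[bad], "' has length ",
         w[bad], ", expected ", w[1L])
  }
  rows <- as.character(set)
  if (alphabet == "auto") alphabet <- detect_alphabet(rows)
  alignment(ids, rows, alphabet)
}

#' Write a FASTA alignment
#'
#' @param aln an [alignment].
#' @param file output path or connection; `"-"` writes to stdout.
#' @param width characters per sequence line.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(aln, file, width = 60L) {
  stopifnot(inherits(aln, "alignment"))
  out <- character(0L)
  for (i in seq_along(aln$taxa)) {
    s <- aln$rows[i]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    out <- c(out, paste0(">", aln$taxa[i]),
             substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }
  writeLines(out, con_for_write(file))
  invisible(file)
}

# Accept a path, "-" (stdin) or a connection; return a local file path.
slurp_to_path <- function(file) {
  if (inherits(file, "connection")) {
    tmp <- tempfile()
    writeLines(readLines(file, warn = FALSE), tmp)
    return(tmp)
  }
  if (identical(file, "-")) {
    tmp <- tempfile()
    writeLines(readLines(base::file("stdin"), warn = FALSE), tmp)
    return(tmp)
  }
  if (!file.exists(file)) stop("cannot open input: ", file)
  file
}

con_for_write <- function(file) {
  if (inherits(file, "connection")) file
  else if (identical(file, "-")) stdout()
  else file
}
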