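#' Read a PHYLIP alignment
#'
#' Supports sequential and interleaved layouts (auto-detected by line
#' accounting) in two name dialects: `strict` (fixed 10-character name
#' field, as classic PHYLIP tools write) and `relaxed` (whitespace-delimited
#' names of any length).
#'
#' Auto-detection: if the first block of `n` lines already yields
#' full-length sequences the file is sequential; if the line count is a
#' whole number of `n`-line blocks it is read as interleaved; otherwise it
#' is read as sequential with wrapped sequence lines.
#'
#' @param file path, connection, or `"-"` for stdin.
#' @param dialect `"relaxed"` (default) or `"strict"`.
#' @param alphabet `"auto"`, `"dna"` or `"protein"`.
#' @return An [alignment].
#' @export
read_phylip_alignment <- function(file, dialect = c("relaxed", "strict"),
                                  alphabet = c("auto", "dna", "protein")) {
  dialect <- match.arg(dialect)
  alphabet <- match.arg(alphabet)
  lines <- readLines(slurp_to_path(file), warn = FALSE)
  if (!length(lines)) stop("empty input: no PHYLIP header")
  first <- which(nzchar(trimws(lines)))[1L]
  if (is.na(first)) stop("empty input: no PHYLIP header")
  hdr <- strsplit(trimws(lines[first]), "\\s+")[[1L]]
  if (length(hdr) < 2L || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
    stop("parse error at line ", first, ": expected 'n n_sites' header")
  n <- as.integer(hdr[1L]); L <- as.integer(hdr[2L])
  body <- lines[-seq_len(first)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n)
    stop("parse error: header announces ", n, " taxa but only ",
         length(body), " sequence lines follow (line ",
         first + length(body), ")")

  split_record <- function(line) {
    if (dialect == "strict") {
      if (nchar(line) < 10L)
        stop("parse error: strict record line shorter than the ",
             "10-character name field: '", line, "'")
      list(name = trimws(substr(line, 1L, 10L)),
           seq = gsub("\\s", "", substring(line, 11L)))
    } else {
      m <- regexpr("^\\S+", line <- trimws(line))
      list(name = regmatches(line, m),
           seq = gsub("\\s", "", substring(line, attr(m, "match.length") + 1L)))
    }
  }

  rec <- lapply(body[seq_len(n)], split_record)
  names_ <- vapply(rec, `[[`, "", "name")
  chunks <- vapply(rec, `[[`, "", "seq")

  if (all(nchar(chunks) == L) && length(body) == n) {
    rows <- chunks                                   # sequential, one line each
  } else if (length(body) %% n == 0L && length(body) > n &&
             all(nchar(chunks) < L)) {
    rows <- chunks                                   # interleaved blocks
    k <- length(body) / n
    for (b in seq_len(k - 1L)) {
      blk <- body[(b * n + 1L):((b + 1L) * n)]
      rows <- paste0(rows, gsub("\\s", "", blk))
    }
  } else {                                           # sequential, wrapped
    rows <- character(n); i <- 1L; pos <- 1L
    while (i <= n && pos <= length(body)) {
      r <- split_record(body[pos]); pos <- pos + 1L
      names_[i] <- r$name; acc <- r$seq
      while (nchar(acc) < L) {
        if (pos > length(body))
          stop("parse error at line ", first + pos,
               ": sequence '", r$name, "' ends at ", nchar(acc),
               " of ", L, " sites")
        acc <- paste0(acc, gsub("\\s", "", body[pos])); pos <- pos + 1L
      }
      if (nchar(acc) > L)
        stop("parse error: sequence '", r$name, "' has ", nchar(acc),
             " sites, header says ", L)
      rows[i] <- acc; i <- i + 1L
    }
    if (i <= n)
      stop("parse error: header announces ", n, " taxa, found ", i - 1L)
  }

  if (any(nchar(rows) != L))
    stop("parse error: sequence '", names_[which(nchar(rows) != L)[1L]],
         "' has ", nchar(rows[which(nchar(rows) != L)[1L]]),
         " sites, header says ", L)
  if (anyDuplicated(names_))
    stop("identifier collision: duplicate name '",
         names_[duplicated(names_)][1L], "'",
         if (dialect == "strict") " (strict 10-character truncation)" else "")
  if (alphabet == "auto") alphabet <- detect_alphabet(rows)
  alignment(names_, rows, alphabet)
}

#' Write a PHYLIP alignment
#'
#' @param aln an [alignment].
#' @param file output path, connection, or `"-"` for stdout.
#' @param dialect `"relaxed"` (whitespace-delimited names, the default) or
#'   `"strict"` (names padded/truncated to 10 characters).
#' @param interleaved write interleaved blocks instead of sequential lines.
#' @param block_width sites per line in interleaved layout.
#' @return `file`, invisibly.
#' @export
write_phylip_alignment <- function(aln, file, dialect = c("relaxed", "strict"),
                                   interleaved = FALSE, block_width = 60L) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(aln, "alignment"))
  nm <- if (dialect == "strict")
    formatC(substr(aln$taxa, 1L, 10L), width = -10L)
  else paste0(aln$taxa, " ")
  if (dialect == "strict" && anyDuplicated(trimws(nm)))
    stop("identifier collision: names not unique after 10-character truncation")
  out <- paste(length(aln$taxa), aln$n_sites)
  if (!interleaved) {
    out <- c(out, paste0(nm, aln$rows))
  } else {
    starts <- seq(1L, max(aln$n_sites, 1L), by = block_width)
    for (b in seq_along(starts)) {
      chunk <- substring(aln$rows, starts[b],
                         pmin(starts[b] + block_width - 1L, aln$n_sites))
      out <- c(out, if (b == 1L) paste0(nm, chunk) else chunk, "")
    }
    out <- out[-length(out)]
  }
  writeLines(out, con_for_write(file))
  invisible(file)
}
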