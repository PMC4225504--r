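# Distance-matrix I/O: PHYLIP text (square and upper-triangular), and a
# compact streaming binary format holding the strict upper triangle in
# little-endian IEEE-754 single precision.
#
# Binary layout (self-defined, versioned):
#   magic  "FPB1"                      4 bytes
#   version 0x01                       1 byte
#   n      unsigned 32-bit LE          4 bytes
#   ids    n x (uint16 LE byte length + UTF-8 bytes)
#   payload row-major upper triangle, row i (0-based) holds n-1-i floats,
#           4 bytes each, little-endian; diagonal (identically 0) omitted.

.dm_magic <- charToRaw("FPB1")
.dm_version <- as.raw(1L)

#' Predict the on-disk size of a binary distance matrix
#'
#' `header + 4 n (n - 1) / 2` bytes: the header is 9 fixed bytes plus, per
#' identifier, a 2-byte length prefix and its UTF-8 bytes; the payload
#' stores the strict upper triangle in 4-byte single precision.
#'
#' @param n taxon count (`n >= 2`).
#' @param taxa identifiers (length `n`), or a single representative
#'   identifier assumed for all `n` taxa.
#' @return Predicted byte count (a double, exact for all practical `n`).
#' @examples
#' predict_binary_size(2, c("a", "b"))
#' @export
predict_binary_size <- function(n, taxa) {
  if (n < 2L) stop("need n >= 2")
  id_bytes <- vapply(enc2utf8(as.character(taxa)), function(s)
    length(charToRaw(s)), 0L)
  if (length(id_bytes) == 1L) id_bytes <- rep(id_bytes, n)
  if (length(id_bytes) != n) stop("taxa must have length n (or 1)")
  9 + sum(2 + id_bytes) + 4 * n * (n - 1) / 2
}

#' Write a distance matrix in the streaming binary format
#'
#' Accepts either a full symmetric matrix or an ordered list of
#' upper-triangle rows (row `i`, 1-based, holds `n - i` entries), so a
#' one-row-in-memory producer can stream straight to disk.  Entries are
#' quantized to IEEE-754 single precision on write.
#'
#' @param rows a symmetric named matrix, or a list of numeric vectors (the
#'   upper-triangle rows in order).
#' @param taxa identifiers; defaults to the matrix rownames.
#' @param sink output file path or writable binary connection.
#' @return Total bytes written (equals [predict_binary_size()]).
#' @export
write_binary_dm <- function(rows, taxa = NULL, sink) {
  if (is.matrix(rows)) {
    if (is.null(taxa)) taxa <- rownames(rows)
    n <- nrow(rows)
    rows <- lapply(seq_len(n - 1L), function(i) rows[i, (i + 1L):n])
  } else {
    n <- length(rows) + 1L
  }
  if (is.null(taxa) || length(taxa) != n)
    stop("need one identifier per taxon (", n, ")")
  con <- if (inherits(sink, "connection")) sink else {
    f <- file(sink, "wb"); on.exit(close(f)); f
  }
  writeBin(.dm_magic, con)
  writeBin(.dm_version, con)
  writeBin(as.integer(n), con, size = 4L, endian = "little")
  bytes <- 9
  for (t in enc2utf8(as.character(taxa))) {
    raw_id <- charToRaw(t)
    writeBin(as.integer(length(raw_id)), con, size = 2L, endian = "little")
    writeBin(raw_id, con)
    bytes <- bytes + 2 + length(raw_id)
  }
  for (i in seq_along(rows)) {
    r <- as.numeric(rows[[i]])
    if (length(r) != n - i)
      stop("shape error: row ", i, " has ", length(r), " entries, expected ",
           n - i)
    if (any(!is.finite(r)))
      stop("encoding error: non-finite entry in row ", i,
           "; substitute saturated entries first (saturation_distance)")
    writeBin(r, con, size = 4L, endian = "little")
    bytes <- bytes + 4 * length(r)
  }
  bytes
}

#' Read a binary distance matrix
#'
#' Verifies magic and version before touching the payload.  Either
#' materialises the full symmetric matrix, or — with `row_handler` — streams
#' the upper-triangle rows one at a time without holding the payload.
#'
#' @param stream input file path or readable binary connection.
#' @param row_handler optional `function(i, row)` called per upper-triangle
#'   row (1-based); when given, the return value is the taxon vector.
#' @return A symmetric named matrix, or (with `row_handler`) the taxa.
#' @export
read_binary_dm <- function(stream, row_handler = NULL) {
  con <- if (inherits(stream, "connection")) stream else {
    if (!file.exists(stream)) stop("cannot open input: ", stream)
    f <- file(stream, "rb"); on.exit(close(f)); f
  }
  magic <- readBin(con, "raw", 4L)
  if (length(magic) < 4L || !identical(magic, .dm_magic))
    stop("format error: bad magic; not a binary distance-matrix stream")
  version <- readBin(con, "raw", 1L)
  if (!identical(version, .dm_version))
    stop("format error: unsupported version ",
         if (length(version)) as.integer(version) else "(truncated)")
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!length(n) || n < 2L) stop("format error: bad taxon count")
  taxa <- character(n)
  for (i in seq_len(n)) {
    len <- readBin(con, "integer", 1L, size = 2L, endian = "little",
                   signed = FALSE)
    if (!length(len)) stop("length error: truncated identifier block")
    raw_id <- readBin(con, "raw", len)
    if (length(raw_id) < len) stop("length error: truncated identifier block")
    taxa[i] <- rawToChar(raw_id)
  }
  Encoding(taxa) <- "UTF-8"
  D <- if (is.null(row_handler))
    matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    k <- n - i
    r <- readBin(con, "double", k, size = 4L, endian = "little")
    if (length(r) < k)
      stop("length error: expected ", 4 * k, " payload bytes for row ", i,
           ", got ", 4 * length(r))
    if (is.null(row_handler)) {
      D[i, (i + 1L):n] <- r
      D[(i + 1L):n, i] <- r
    } else row_handler(i, r)
  }
  if (is.null(row_handler)) D else invisible(taxa)
}

#' Write / read PHYLIP distance matrices
#'
#' `write_phylip_dm` emits the classic layout: an `n` header line then one
#' row per taxon, either the full square matrix or the upper triangle.
#' Names are 10-character padded in the `strict` dialect, whitespace-
#' delimited in `relaxed` (the default).  `read_phylip_dm` auto-detects
#' square vs upper-triangular rows.
#'
#' @param m symmetric named matrix with finite entries.
#' @param file output (or input) path, connection, or `"-"`.
#' @param layout `"square"` (default) or `"upper"`.
#' @param dialect `"relaxed"` or `"strict"` names.
#' @param precision decimal places printed.
#' @return `write_phylip_dm`: `file`, invisibly.  `read_phylip_dm`: a
#'   symmetric named matrix.
#' @export
write_phylip_dm <- function(m, file, layout = c("square", "upper"),
                            dialect = c("relaxed", "strict"),
                            precision = 6L) {
  layout <- match.arg(layout)
  dialect <- match.arg(dialect)
  if (any(!is.finite(m)))
    stop("encoding error: non-finite entry; substitute saturated entries ",
         "first (saturation_distance)")
  taxa <- rownames(m)
  n <- nrow(m)
  nm <- if (dialect == "strict") formatC(substr(taxa, 1L, 10L), width = -10L)
        else paste0(taxa, " ")
  out <- character(n + 1L)
  out[1L] <- paste0(n)
  for (i in seq_len(n)) {
    vals <- if (layout == "square") m[i, ]
            else if (i < n) m[i, (i + 1L):n] else numeric(0L)
    out[i + 1L] <- paste0(nm[i], paste(formatC(vals, format = "f",
                                               digits = precision),
                                       collapse = " "))
  }
  writeLines(out, con_for_write(file))
  invisible(file)
}

#' @rdname write_phylip_dm
#' @export
read_phylip_dm <- function(file) {
  lines <- readLines(slurp_to_path(file), warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty input: no PHYLIP matrix header")
  n <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]][1L]))
  if (is.na(n) || n < 1L)
    stop("parse error at line 1: expected taxon count")
  if (length(lines) - 1L < n)
    stop("parse error: header announces ", n, " rows, found ",
         length(lines) - 1L)
  taxa <- character(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
    taxa[i] <- tok[1L]
    rows[[i]] <- suppressWarnings(as.numeric(tok[-1L]))
    if (anyNA(rows[[i]]))
      stop("parse error at line ", i + 1L, ": non-numeric entry")
  }
  len <- lengths(rows)
  D <- matrix(0, n, n)
  if (all(len == n)) {                      # square
    for (i in seq_len(n)) D[i, ] <- rows[[i]]
    D <- (D + t(D)) / 2
  } else if (all(len == n - seq_len(n))) {  # upper triangle
    for (i in seq_len(n - 1L)) {
      D[i, (i + 1L):n] <- rows[[i]]
      D[(i + 1L):n, i] <- rows[[i]]
    }
  } else {
    bad <- which(len != n & len != n - seq_len(n))[1L]
    stop("parse error at line ", bad + 1L, ": row has ", len[bad],
         " entries; expected ", n, " (square) or ", n - bad, " (upper)")
  }
  dimnames(D) <- list(taxa, taxa)
  D
}
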