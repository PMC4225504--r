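#' Serialize a tree to Newick
#'
#' Emits standard Newick for an [ape::phylo] tree, branch lengths formatted
#' to `precision` significant digits, terminated by `";"`.  Labels containing
#' Newick metacharacters (`(),:;[]'` or whitespace) are single-quoted with
#' internal quotes doubled.
#'
#' @param tree a `phylo` object.
#' @param precision significant digits for branch lengths.
#' @param file optional output path/connection; if `NULL` the Newick string
#'   is returned.
#' @return The Newick string (invisibly when `file` is given).
#' @examples
#' tr <- ape::read.tree(text = "(A:1,B:2,C:3);")
#' write_newick(tr)
#' @export
write_newick <- function(tree, precision = 10L, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt <- function(x) formatC(x, digits = precision, format = "g", width = 1L)
  lab <- function(s) {
    if (grepl("[\\s(),:;\\[\\]']", s, perl = TRUE))
      paste0("'", gsub("'", "''", s, fixed = TRUE), "'")
    else s
  }
  rec <- function(node) {
    kid_edges <- children[[as.character(node)]]
    if (is.null(kid_edges)) return(lab(tree$tip.label[node]))
    parts <- vapply(kid_edges, function(e) {
      child <- tree$edge[e, 2L]
      paste0(rec(child), ":", fmt(tree$edge.length[e]))
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- n + 1L
  txt <- paste0(rec(root), ";")
  if (is.null(file)) return(txt)
  writeLines(txt, con_for_write(file))
  invisible(txt)
}
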