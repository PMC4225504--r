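#' The suite's XML dialect
#'
#' A minimal, self-describing XML format for alignments, distance matrices
#' and trees.  Identifiers of arbitrary length round-trip losslessly, which
#' the fixed-width PHYLIP name field cannot offer.  The document element is
#' `<run>`, holding one of:
#'
#' * `<alignment alphabet="dna|protein">` with one `<seq id="...">` per taxon;
#' * `<matrix>` with a `<taxa>` block (one `<taxon id="..."/>` per taxon, in
#'   matrix order) followed by one `<row>` per upper-triangle row, entries
#'   whitespace-separated (`n-1-i` values for row `i`, 0-based);
#' * `<tree>` holding a Newick string.
#'
#' [print_schema()] emits the embedded RELAX NG compact schema text.
#'
#' @name xml_dialect
NULL

xml_schema_text <- paste(
  "# RELAX NG compact schema for the phylodist XML dialect",
  "start = element run {",
  "  element alignment {",
  "    attribute alphabet { \"dna\" | \"protein\" },",
  "    element seq { attribute id { text }, text }+",
  "  }",
  "  | element matrix {",
  "    element taxa { element taxon { attribute id { text } }+ },",
  "    element row { text }*   # row i holds n-1-i whitespace-separated reals",
  "  }",
  "  | element tree { text }   # Newick",
  "}",
  sep = "\n")

#' Print the embedded XML schema
#'
#' @param file output path/connection, default stdout.
#' @return The schema text, invisibly.
#' @export
print_schema <- function(file = "-") {
  writeLines(xml_schema_text, con_for_write(file))
  invisible(xml_schema_text)
}

xml_fail <- function(node, msg)
  stop("XML validation error at ", xml2::xml_path(node), ": ", msg,
       call. = FALSE)

#' Read an XML document in the suite's dialect
#'
#' @param file path, connection, or `"-"` for stdin.
#' @return An [alignment] or a distance matrix (named symmetric base
#'   matrix), depending on the document content.
#' @export
read_xml_input <- function(file) {
  doc <- xml2::read_xml(slurp_to_path(file))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "run")
    xml_fail(root, "document element must be <run>")
  kids <- xml2::xml_children(root)
  if (length(kids) != 1L)
    xml_fail(root, "expected exactly one child of <run>")
  node <- kids[[1L]]
  switch(xml2::xml_name(node),
    alignment = xml_to_alignment(node),
    matrix = xml_to_matrix(node),
    xml_fail(node, "unknown element; expected <alignment> or <matrix>"))
}

xml_to_alignment <- function(node) {
  alphabet <- xml2::xml_attr(node, "alphabet")
  if (is.na(alphabet) || !alphabet %in% c("dna", "protein"))
    xml_fail(node, "alphabet attribute must be \"dna\" or \"protein\"")
  seqs <- xml2::xml_children(node)
  if (!length(seqs)) xml_fail(node, "alignment has no <seq> children")
  for (s in seqs)
    if (xml2::xml_name(s) != "seq") xml_fail(s, "expected <seq>")
  ids <- vapply(seqs, function(s) xml2::xml_attr(s, "id"), "")
  if (anyNA(ids)) xml_fail(node, "<seq> without id attribute")
  rows <- vapply(seqs, function(s) gsub("\\s", "", xml2::xml_text(s)), "")
  alignment(ids, rows, alphabet)
}

xml_to_matrix <- function(node) {
  kids <- xml2::xml_children(node)
  if (!length(kids) || xml2::xml_name(kids[[1L]]) != "taxa")
    xml_fail(node, "first child of <matrix> must be <taxa>")
  taxa_node <- kids[[1L]]
  taxa <- vapply(xml2::xml_children(taxa_node), function(t) {
    if (xml2::xml_name(t) != "taxon") xml_fail(t, "expected <taxon>")
    id <- xml2::xml_attr(t, "id")
    if (is.na(id)) xml_fail(t, "<taxon> without id attribute")
    id
  }, "")
  n <- length(taxa)
  rows <- kids[-1L]
  if (length(rows) != max(n - 1L, 0L))
    xml_fail(node, paste0("expected ", n - 1L, " <row> elements, found ",
                          length(rows)))
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (xml2::xml_name(r) != "row") xml_fail(r, "expected <row>")
    v <- as.numeric(strsplit(trimws(xml2::xml_text(r)), "\\s+")[[1L]])
    if (length(v) != n - i)
      xml_fail(r, paste0("row ", i - 1L, " holds ", length(v),
                         " entries, expected ", n - i))
    D[i, (i + 1L):n] <- v
    D[(i + 1L):n, i] <- v
  }
  D
}

#' Write an alignment, distance matrix or tree as XML
#'
#' @param object an [alignment], a named symmetric distance matrix, or a
#'   `phylo` tree.
#' @param file output path/connection, `"-"` for stdout.
#' @param precision significant digits for matrix entries / branch lengths.
#' @return `file`, invisibly.
#' @export
write_xml_output <- function(object, file = "-", precision = 10L) {
  doc <- xml2::xml_new_root("run")
  if (inherits(object, "alignment")) {
    a <- xml2::xml_add_child(doc, "alignment", alphabet = object$alphabet)
    for (i in seq_along(object$taxa))
      xml2::xml_add_child(a, "seq", object$rows[i], id = object$taxa[i])
  } else if (is.matrix(object)) {
    m <- xml2::xml_add_child(doc, "matrix")
    tx <- xml2::xml_add_child(m, "taxa")
    taxa <- rownames(object)
    for (t in taxa) xml2::xml_add_child(tx, "taxon", id = t)
    n <- nrow(object)
    for (i in seq_len(max(n - 1L, 0L)))
      xml2::xml_add_child(m, "row",
        paste(formatC(object[i, (i + 1L):n], digits = precision, format = "g",
                      width = 1L),
              collapse = " "))
  } else if (inherits(object, "phylo")) {
    xml2::xml_add_child(doc, "tree", write_newick(object, precision))
  } else stop("write_xml_output: unsupported object of class ",
              paste(class(object), collapse = "/"))
  txt <- as.character(doc)
  writeLines(txt, con_for_write(file))
  invisible(file)
}
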