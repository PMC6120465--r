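# Readers for JATS/NLM XML articles and plain-text files.

#' Read a JATS/NLM XML article
#'
#' Extracts the article title, abstract paragraphs and body paragraphs of a
#' full-text article in the JATS (PubMed Central) dialect, in document
#' order, and tokenizes the result. Reference lists, tables and figure
#' captions are excluded by default: citation boilerplate would otherwise
#' dominate collocation windows.
#'
#' @param xml_source Path to a JATS XML file, or a string of XML.
#' @param doc_id Document identifier; defaults to the first
#'   \code{<article-id>} element, else the file name without extension.
#' @param include_refs,include_tables,include_captions Widen the extraction
#'   to reference lists, table contents and figure captions.
#' @return A \code{corpus_document}.
#' @seealso [read_plaintext()], [build_index()]
#' @export
read_jats <- function(xml_source, doc_id = NULL,
                      include_refs = FALSE, include_tables = FALSE,
                      include_captions = FALSE) {
  src_label <- if (is.character(xml_source) && length(xml_source) == 1L &&
                   file.exists(xml_source)) xml_source else "<xml string>"
  doc <- tryCatch(
    xml2::read_xml(xml_source),
    error = function(e) stop("cannot parse JATS XML from '", src_label,
                             "': ", conditionMessage(e), call. = FALSE)
  )

  # collect optional sections before pruning them from the tree
  extra <- character()
  grab <- function(xpath) {
    vapply(xml2::xml_find_all(doc, xpath), xml2::xml_text, character(1))
  }
  if (include_refs)     extra <- c(extra, grab(".//ref-list"))
  if (include_tables)   extra <- c(extra, grab(".//table-wrap"))
  if (include_captions) extra <- c(extra, grab(".//fig//caption"))

  # prune floats and citations so body paragraphs stay clean prose
  drop <- c(".//ref-list", ".//table-wrap", ".//table", ".//fig")
  if (!include_refs) drop <- c(drop, ".//xref")
  for (xp in drop) {
    nodes <- xml2::xml_find_all(doc, xp)
    if (length(nodes)) xml2::xml_remove(nodes)
  }

  title    <- xml2::xml_find_all(doc, ".//front//title-group/article-title")
  abstract <- xml2::xml_find_all(doc, ".//front//abstract//p")
  body     <- xml2::xml_find_all(doc, ".//body//p")
  pieces <- c(vapply(c(title, abstract, body), xml2::xml_text, character(1)),
              extra)

  if (is.null(doc_id)) {
    id_node <- xml2::xml_find_first(doc, ".//front//article-id")
    doc_id <- if (!inherits(id_node, "xml_missing")) {
      trimws(xml2::xml_text(id_node))
    } else if (file.exists(src_label)) {
      tools::file_path_sans_ext(basename(src_label))
    } else "article"
  }

  if (length(pieces) == 0L) {
    warning("JATS article '", doc_id, "' has no title, abstract or body; ",
            "document is empty", call. = FALSE)
  }
  new_document(doc_id, "jats_xml", tokenize(paste(pieces, collapse = "\n")))
}

#' Read a plain-text article
#'
#' Reads a UTF-8 text file (with latin-1 fallback for files that do not
#' decode as UTF-8) and tokenizes its full content.
#'
#' @param text_source Path to a text file.
#' @param doc_id Document identifier; defaults to the file name without
#'   extension.
#' @return A \code{corpus_document}.
#' @export
read_plaintext <- function(text_source, doc_id = NULL) {
  raw <- readBin(text_source, what = "raw", n = file.size(text_source))
  if (any(raw == as.raw(0L))) {
    stop("cannot decode '", text_source, "': embedded NUL bytes ",
         "(binary file?)", call. = FALSE)
  }
  txt <- rawToChar(raw)
  if (validUTF8(txt)) {
    Encoding(txt) <- "UTF-8"
  } else {
    txt <- iconv(txt, from = "latin1", to = "UTF-8")
    if (is.na(txt)) stop("cannot decode '", text_source,
                         "' as UTF-8 or latin-1", call. = FALSE)
  }
  if (is.null(doc_id)) doc_id <- tools::file_path_sans_ext(basename(text_source))
  new_document(doc_id, "plaintext", tokenize(txt))
}
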