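ALIGN_NS <- "http://knowledgeweb.semanticweb.org/heterogeneity/alignment"

#' Read an alignment from the RDF Alignment (Alignment API) XML format
#'
#' Parses the INRIA Alignment API serialization: an \code{Alignment} element
#' holding \code{map/Cell} children, each with \code{entity1},
#' \code{entity2}, a \code{relation} symbol (\code{"="}, \code{"<"},
#' \code{">"}) and a \code{measure} (the confidence). Duplicate cells are
#' collapsed by canonicalization.
#'
#' @param path path to an RDF Alignment XML file, or a literal XML string.
#' @param system_name,family labels for the resulting [alignment()].
#' @return an [alignment()].
#' @export
parse_rdf_alignment <- function(path, system_name = "unnamed",
                                family = system_name) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop("malformed RDF Alignment XML: ",
                         conditionMessage(e), call. = FALSE))
  onto <- function(which) {
    node <- xml2::xml_find_first(doc, sprintf("//*[local-name()='%s']", which))
    if (inherits(node, "xml_missing")) return(NA_character_)
    res <- xml2::xml_find_first(
      node, ".//*[local-name()='Ontology']|.//*[local-name()='location']")
    id <- if (!inherits(res, "xml_missing"))
      xml2::xml_attr(res, "about") else NA_character_
    txt <- trimws(xml2::xml_text(node))
    if (!is.na(id) && nzchar(id)) id
    else if (nzchar(txt)) txt
    else NA_character_
  }
  cells <- xml2::xml_find_all(doc, "//*[local-name()='Cell']")
  ent <- function(cell, which) {
    node <- xml2::xml_find_first(cell,
      sprintf(".//*[local-name()='%s']", which))
    if (inherits(node, "xml_missing")) return(NA_character_)
    res <- xml2::xml_attr(node, "resource")
    if (!is.na(res) && nzchar(res)) res else trimws(xml2::xml_text(node))
  }
  e1 <- vapply(cells, ent, character(1), which = "entity1")
  e2 <- vapply(cells, ent, character(1), which = "entity2")
  rel <- vapply(cells, ent, character(1), which = "relation")
  meas <- vapply(cells, ent, character(1), which = "measure")
  if (length(cells) > 0) {
    if (anyNA(e1) || anyNA(e2))
      stop("Cell without entity1/entity2 (cell #",
           which(is.na(e1) | is.na(e2))[1], ")", call. = FALSE)
    rel[is.na(rel) | !nzchar(rel)] <- "="
    known <- tolower(trimws(rel)) %in% names(.rel_aliases)
    if (any(!known)) {
      i <- which(!known)[1]
      stop(sprintf("unknown relation symbol '%s' in cell <%s, %s>",
                   rel[i], e1[i], e2[i]), call. = FALSE)
    }
    conf <- suppressWarnings(as.numeric(meas))
    conf[is.na(meas)] <- 1.0
    if (anyNA(conf))
      stop("non-numeric measure in cell <", e1[which(is.na(conf))[1]], ">",
           call. = FALSE)
  } else conf <- numeric()
  alignment(data.frame(source = e1, target = e2, relation = rel,
                       confidence = conf, stringsAsFactors = FALSE),
            system_name = system_name, family = family,
            ontology1_id = onto("onto1"), ontology2_id = onto("onto2"))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

#' Write an alignment in the RDF Alignment XML format
#'
#' Cells are emitted in lexicographic (source, target, relation) order so
#' output is deterministic; relation symbols \code{<} and \code{>} are
#' XML-escaped as the format requires.
#'
#' @param x an [alignment()].
#' @param path output file path, or \code{NULL} to return the XML as a
#'   single string.
#' @return the XML string, invisibly when written to a file.
#' @export
write_rdf_alignment <- function(x, path = NULL) {
  stopifnot(inherits(x, "alignment"))
  m <- x$mappings
  hdr <- c(
    '<?xml version="1.0" encoding="utf-8"?>',
    sprintf('<rdf:RDF xmlns="%s"', ALIGN_NS),
    '         xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '         xmlns:xsd="http://www.w3.org/2001/XMLSchema#">',
    "<Alignment>",
    "  <xml>yes</xml>",
    "  <level>0</level>",
    "  <type>??</type>")
  if (!is.na(x$ontology1_id))
    hdr <- c(hdr, sprintf("  <onto1>%s</onto1>", xml_escape(x$ontology1_id)))
  if (!is.na(x$ontology2_id))
    hdr <- c(hdr, sprintf("  <onto2>%s</onto2>", xml_escape(x$ontology2_id)))
  cells <- if (nrow(m) == 0) character() else sprintf(
    paste0("  <map>\n    <Cell>\n",
           '      <entity1 rdf:resource="%s"/>\n',
           '      <entity2 rdf:resource="%s"/>\n',
           '      <measure rdf:datatype="xsd:float">%s</measure>\n',
           "      <relation>%s</relation>\n",
           "    </Cell>\n  </map>"),
    xml_escape(m$source), xml_escape(m$target),
    format(m$confidence, trim = TRUE, scientific = FALSE),
    xml_escape(m$relation))
  out <- paste(c(hdr, cells, "</Alignment>", "</rdf:RDF>", ""),
               collapse = "\n")
  if (is.null(path)) return(out)
  writeLines(out, path, sep = "")
  invisible(out)
}

#' Read an alignment from tab-separated text
#'
#' Dialect: UTF-8, tab-separated, \code{#} comment lines ignored, optional
#' auto-detected header. Columns are \code{source}, \code{target},
#' \code{relation} (optional, default equivalence) and \code{confidence}
#' (optional, default 1).
#'
#' @inheritParams parse_rdf_alignment
#' @param path path to a TSV file or a character vector of lines.
#' @return an [alignment()].
#' @export
parse_tsv_alignment <- function(path, system_name = "unnamed",
                                family = system_name) {
  lines <- if (length(path) == 1 && file.exists(path))
    readLines(path, warn = FALSE) else path
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) == 0)
    return(alignment(empty_mappings(), system_name, family))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  # header if the first row names the columns
  first <- tolower(trimws(parts[[1]]))
  if (length(first) >= 2 && first[1] %in% c("source", "entity1") &&
      first[2] %in% c("target", "entity2")) {
    parts <- parts[-1]; lineno <- lineno[-1]
  }
  if (length(parts) == 0)
    return(alignment(empty_mappings(), system_name, family))
  nf <- lengths(parts)
  if (any(nf < 2 | nf > 4))
    stop("line ", lineno[which(nf < 2 | nf > 4)[1]],
         ": expected 2-4 tab-separated fields", call. = FALSE)
  get <- function(i, default) vapply(parts, function(p)
    if (length(p) >= i && nzchar(trimws(p[i]))) trimws(p[i]) else default,
    character(1))
  conf <- suppressWarnings(as.numeric(get(4, "1.0")))
  if (anyNA(conf))
    stop("line ", lineno[which(is.na(conf))[1]],
         ": non-numeric confidence", call. = FALSE)
  alignment(data.frame(source = get(1, NA_character_),
                       target = get(2, NA_character_),
                       relation = get(3, "="), confidence = conf,
                       stringsAsFactors = FALSE),
            system_name = system_name, family = family)
}

#' Write an alignment as tab-separated text
#'
#' @param x an [alignment()].
#' @param path output path, or \code{NULL} to return the lines.
#' @export
write_tsv_alignment <- function(x, path = NULL) {
  stopifnot(inherits(x, "alignment"))
  m <- x$mappings
  lines <- c("source\ttarget\trelation\tconfidence",
             sprintf("%s\t%s\t%s\t%s", m$source, m$target, m$relation,
                     format(m$confidence, trim = TRUE, scientific = FALSE)))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
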