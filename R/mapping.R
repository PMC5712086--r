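#' @importFrom stats setNames
#' @importFrom utils head read.delim
NULL

# Relation codes used throughout:
#   "<"  source is subsumed by target   (subClassOf)
#   ">"  source subsumes target         (superClassOf)
#   "="  equivalence
REL_CODES <- c("<", ">", "=")

.rel_aliases <- c(
  "<" = "<", ">" = ">", "=" = "=",
  "subclassof" = "<", "superclassof" = ">", "equivalent" = "=",
  "subsumedby" = "<", "subsumes" = ">", "equiv" = "="
)

normalize_relation <- function(r) {
  key <- tolower(trimws(r))
  out <- unname(.rel_aliases[key])
  if (anyNA(out)) {
    bad <- unique(r[is.na(out)])
    stop("unknown relation symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Construct a canonical mapping table
#'
#' A mapping is a correspondence \eqn{\langle e, e', r, c \rangle} between an
#' entity of one ontology and an entity of another, with a semantic relation
#' (subsumed-by \code{"<"}, subsumes \code{">"}, or equivalence \code{"="})
#' and a confidence in \eqn{(0, 1]}. A mapping set is a data frame with
#' columns \code{source}, \code{target}, \code{relation}, \code{confidence}.
#'
#' Canonicalization trims identifiers, validates the relation symbol and
#' confidence range, and collapses duplicate \code{(source, target,
#' relation)} triples keeping the maximum confidence. The cross-ontology
#' orientation is always preserved: \code{source} stays on the first
#' ontology's side and the subsumption direction is carried in
#' \code{relation}, so \code{A > B} ("A subsumes B") is the same assertion
#' as "B subClassOf A" without swapping the columns. Mapping identity
#' (set membership, intersections) never involves the confidence.
#'
#' @param source,target character vectors of entity identifiers (IRIs or
#'   CURIEs); compared as exact strings after trimming.
#' @param relation relation symbols; \code{"<"}, \code{">"}, \code{"="} or
#'   the aliases \code{subClassOf}, \code{superClassOf}, \code{equivalent}.
#' @param confidence numeric in \eqn{(0, 1]}; out-of-range values are an
#'   error, never clamped.
#' @return a canonical mapping data frame, rows sorted by
#'   (source, target, relation).
#' @export
mapping_set <- function(source = character(), target = character(),
                        relation = character(), confidence = numeric()) {
  n <- length(source)
  if (n == 0) {
    return(data.frame(source = character(), target = character(),
                      relation = character(), confidence = numeric(),
                      stringsAsFactors = FALSE))
  }
  source <- trimws(as.character(source))
  target <- trimws(as.character(target))
  if (length(relation) == 0) relation <- rep("=", n)
  if (length(relation) == 1) relation <- rep(relation, n)
  if (length(confidence) == 0) confidence <- rep(1.0, n)
  if (length(confidence) == 1) confidence <- rep(confidence, n)
  stopifnot(length(target) == n, length(relation) == n,
            length(confidence) == n)
  relation <- normalize_relation(relation)
  if (any(!nzchar(source)) || any(!nzchar(target)))
    stop("empty entity identifier in mapping set", call. = FALSE)
  if (any(source == target))
    stop("mapping with identical source and target: ",
         source[source == target][1], call. = FALSE)
  confidence <- as.numeric(confidence)
  bad <- !is.finite(confidence) | confidence <= 0 | confidence > 1
  if (any(bad))
    stop("confidence outside (0, 1]: ",
         paste(format(confidence[bad][seq_len(min(3, sum(bad)))]),
               collapse = ", "), call. = FALSE)
  df <- data.frame(source = source, target = target, relation = relation,
                   confidence = confidence, stringsAsFactors = FALSE)
  # collapse duplicates, keep the highest confidence seen for a triple
  key <- mapping_key(df)
  if (anyDuplicated(key)) {
    keep <- tapply(df$confidence, key, max)
    df <- df[!duplicated(key), , drop = FALSE]
    df$confidence <- as.numeric(keep[mapping_key(df)])
  }
  df <- df[order(df$source, df$target, df$relation), , drop = FALSE]
  rownames(df) <- NULL
  df
}

mapping_key <- function(m) paste(m$source, m$target, m$relation, sep = "\r")

empty_mappings <- function() mapping_set()

#' Create an alignment object
#'
#' An alignment is one matching system's set of mappings between a fixed
#' pair of ontologies, tagged with the system's name and family (a family
#' groups variants of one tool so that their agreeing mappings count as a
#' single consensus vote).
#'
#' @param mappings a mapping data frame (canonicalized via
#'   [mapping_set()] if not already).
#' @param system_name system identifier.
#' @param family system family; defaults to the system's own name.
#' @param ontology1_id,ontology2_id identifiers of the aligned ontologies.
#' @return an object of class \code{alignment}.
#' @export
alignment <- function(mappings, system_name = "unnamed",
                      family = system_name,
                      ontology1_id = NA_character_,
                      ontology2_id = NA_character_) {
  if (!is.data.frame(mappings))
    stop("mappings must be a data frame", call. = FALSE)
  m <- mapping_set(mappings$source, mappings$target,
                   if (is.null(mappings$relation)) character() else mappings$relation,
                   if (is.null(mappings$confidence)) numeric() else mappings$confidence)
  structure(
    list(system_name = system_name, family = family,
         ontology1_id = ontology1_id, ontology2_id = ontology2_id,
         mappings = m),
    class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %s (family %s): %d mappings [%s vs %s]\n",
              x$system_name, x$family, nrow(x$mappings),
              x$ontology1_id, x$ontology2_id))
  rel <- table(factor(x$mappings$relation, levels = REL_CODES))
  cat(sprintf("  subsumed-by: %d  subsumes: %d  equivalence: %d\n",
              rel[["<"]], rel[[">"]], rel[["="]]))
  invisible(x)
}

#' @export
length.alignment <- function(x) nrow(x$mappings)

as_mappings <- function(x) {
  if (inherits(x, "alignment")) x$mappings
  else if (is.data.frame(x)) mapping_set(x$source, x$target, x$relation,
                                         if (is.null(x$confidence)) numeric() else x$confidence)
  else stop("expected an alignment or mapping data frame", call. = FALSE)
}

#' Set operations on mapping tables
#'
#' Intersection and difference of mapping sets by the
#' \code{(source, target, relation)} triple; confidences are ignored for
#' identity, and the left operand's confidences are retained.
#'
#' @param a,b alignments or mapping data frames.
#' @return a mapping data frame.
#' @export
mapping_intersect <- function(a, b) {
  ma <- as_mappings(a); mb <- as_mappings(b)
  ma[mapping_key(ma) %in% mapping_key(mb), , drop = FALSE]
}

#' @rdname mapping_intersect
#' @export
mapping_setdiff <- function(a, b) {
  ma <- as_mappings(a); mb <- as_mappings(b)
  ma[!(mapping_key(ma) %in% mapping_key(mb)), , drop = FALSE]
}

same_ontology_pair <- function(a, b) {
  ok <- function(x, y) is.na(x) || is.na(y) || identical(x, y)
  ok(a$ontology1_id, b$ontology1_id) && ok(a$ontology2_id, b$ontology2_id)
}
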