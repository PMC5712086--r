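#' Split equivalence mappings into their two subsumption directions
#'
#' Each equivalence mapping is replaced by the pair of directed subsumption
#' mappings it abbreviates (source subsumed-by target, and source subsumes
#' target); subsumption mappings pass through. The result is deduplicated.
#' Semantic precision and recall are computed on split sets, which keeps
#' both fractions well behaved when an aligned ontology entails one
#' direction of an equivalence but not the other.
#'
#' @param m an [alignment()] or mapping data frame.
#' @return a mapping data frame containing only \code{"<"} and \code{">"}
#'   rows.
#' @export
split_equivalence <- function(m) {
  m <- as_mappings(m)
  eq <- m[m$relation == "=", , drop = FALSE]
  sub <- m[m$relation != "=", , drop = FALSE]
  if (nrow(eq)) {
    lt <- eq; lt$relation <- "<"
    gt <- eq; gt$relation <- ">"
    sub <- rbind(sub, lt, gt)
  }
  mapping_set(sub$source, sub$target, sub$relation, sub$confidence)
}

#' Build an entailment index over the aligned ontology
#'
#' Merges the two input ontologies with an alignment (equivalences split
#' into directed subsumptions) into one directed graph of told subsumption
#' edges, contracts strongly connected components (mutual subsumption,
#' i.e. equivalence, collapses to a single node), and answers entailment
#' queries by graph reachability over the condensation. This structural
#' closure computes the atomic-subsumption entailments of the merged
#' taxonomy; the \eqn{\models} interface is deliberately narrow so a full
#' OWL 2 reasoner could be substituted where ontologies carry richer
#' axioms.
#'
#' Mappings naming classes absent from both ontologies are accepted: the
#' unknown classes become isolated nodes and a single warning is emitted.
#'
#' @param o1,o2 [ontology()] objects.
#' @param m an [alignment()] or mapping data frame (may be empty).
#' @return an object of class \code{entailment_index}.
#' @export
build_index <- function(o1, o2, m = empty_mappings()) {
  m <- as_mappings(m)
  classes <- unique(c(o1$classes, o2$classes))
  unknown <- setdiff(unique(c(m$source, m$target)), classes)
  if (length(unknown)) {
    warning(length(unknown), " mapped class(es) not present in either ",
            "ontology; treated as isolated nodes (e.g. ", unknown[1], ")",
            call. = FALSE)
    classes <- c(classes, unknown)
  }
  sm <- split_equivalence(m)
  # edge u -> v means "u is subsumed by v"
  edges <- rbind(
    data.frame(from = o1$subsumptions$child, to = o1$subsumptions$parent,
               stringsAsFactors = FALSE),
    data.frame(from = o2$subsumptions$child, to = o2$subsumptions$parent,
               stringsAsFactors = FALSE),
    data.frame(from = c(o1$equivalences$a, o1$equivalences$b),
               to   = c(o1$equivalences$b, o1$equivalences$a),
               stringsAsFactors = FALSE),
    data.frame(from = c(o2$equivalences$a, o2$equivalences$b),
               to   = c(o2$equivalences$b, o2$equivalences$a),
               stringsAsFactors = FALSE),
    data.frame(from = ifelse(sm$relation == "<", sm$source, sm$target),
               to   = ifelse(sm$relation == "<", sm$target, sm$source),
               stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = classes))
  scc <- igraph::components(g, mode = "strong")
  comp <- scc$membership                     # class -> component id
  cedges <- unique(data.frame(from = comp[edges$from], to = comp[edges$to]))
  cedges <- cedges[cedges$from != cedges$to, , drop = FALSE]
  cg <- igraph::graph_from_data_frame(
    data.frame(from = as.character(cedges$from),
               to = as.character(cedges$to)),
    directed = TRUE,
    vertices = data.frame(name = as.character(seq_len(scc$no))))
  dis <- rbind(o1$disjointness, o2$disjointness)
  structure(
    list(comp = comp, graph = cg, n_comp = scc$no,
         classes = classes, disjointness = dis,
         cache = new.env(parent = emptyenv())),
    class = "entailment_index")
}

#' @export
print.entailment_index <- function(x, ...) {
  cat(sprintf(
    "<entailment_index> %d classes in %d components, %d condensed edges, %d disjointness pairs\n",
    length(x$classes), x$n_comp, igraph::ecount(x$graph),
    nrow(x$disjointness)))
  invisible(x)
}

# component ids reachable from component `c` (inclusive), memoized
reach_up <- function(index, c) {
  key <- as.character(c)
  hit <- index$cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- as.integer(names(igraph::subcomponent(index$graph, key,
                                             mode = "out")))
  assign(key, r, envir = index$cache)
  r
}

#' Entailment of mappings by the aligned ontology
#'
#' A subsumption \code{source < target} is entailed when the target's
#' component is reachable from the source's component in the contracted
#' subsumption graph; an equivalence is entailed when both directions are.
#' Every mapping asserted when building the index is entailed by it
#' (reflexivity of \eqn{\models} on asserted axioms); unknown identifiers
#' are never entailed.
#'
#' @param index an [build_index()] result.
#' @param m an [alignment()] or mapping data frame.
#' @return a logical vector, one element per mapping row.
#' @export
entails <- function(index, m) {
  m <- as_mappings(m)
  n <- nrow(m)
  if (n == 0) return(logical(0))
  cs <- index$comp[m$source]
  ct <- index$comp[m$target]
  out <- logical(n)
  known <- !is.na(cs) & !is.na(ct)
  up <- function(a, b) {           # comp a subsumed by comp b?
    mapply(function(x, y) x == y || y %in% reach_up(index, x), a, b)
  }
  idx <- which(known)
  if (length(idx)) {
    rel <- m$relation[idx]
    a <- cs[idx]; b <- ct[idx]
    res <- logical(length(idx))
    lt <- rel == "<"; gt <- rel == ">"; eq <- rel == "="
    if (any(lt)) res[lt] <- up(a[lt], b[lt])
    if (any(gt)) res[gt] <- up(b[gt], a[gt])
    if (any(eq)) res[eq] <- up(a[eq], b[eq]) & up(b[eq], a[eq])
    out[idx] <- res
  }
  out
}

#' Coherence check of an aligned ontology
#'
#' A class is unsatisfiable when it is subsumed (through the closure) by
#' both members of a declared disjoint pair, or when a disjoint pair has
#' been collapsed into one equivalence component. With no disjointness
#' axioms the aligned ontology is trivially coherent — the situation the
#' phenotype/disease hierarchies are in.
#'
#' @param index an [build_index()] result.
#' @return a list with \code{coherent}, \code{unsatisfiable} (class
#'   identifiers) and \code{witnesses} (named list: one disjoint ancestor
#'   pair per unsatisfiable class).
#' @export
check_coherence <- function(index) {
  dis <- index$disjointness
  unsat_comp <- integer(0)
  witness <- list()
  if (nrow(dis) > 0) {
    da <- index$comp[dis$a]; db <- index$comp[dis$b]
    for (i in seq_len(nrow(dis))) {
      if (is.na(da[i]) || is.na(db[i])) next
      below_a <- as.integer(names(igraph::subcomponent(
        index$graph, as.character(da[i]), mode = "in")))
      below_b <- as.integer(names(igraph::subcomponent(
        index$graph, as.character(db[i]), mode = "in")))
      clash <- if (da[i] == db[i]) below_a else intersect(below_a, below_b)
      for (cpt in clash) {
        if (!as.character(cpt) %in% names(witness))
          witness[[as.character(cpt)]] <- c(dis$a[i], dis$b[i])
      }
      unsat_comp <- union(unsat_comp, clash)
    }
  }
  unsat_classes <- sort(index$classes[index$comp[index$classes] %in% unsat_comp])
  wit <- setNames(
    lapply(unsat_classes,
           function(cl) witness[[as.character(index$comp[[cl]])]]),
    unsat_classes)
  list(coherent = length(unsat_classes) == 0,
       unsatisfiable = unsat_classes,
       witnesses = wit)
}
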