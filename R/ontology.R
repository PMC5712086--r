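#' Construct an ontology (labeled class hierarchy with told axioms)
#'
#' The evaluation only needs each input ontology's class hierarchy: a set of
#' classes, told atomic subsumptions (a DAG — multiple parents and multiple
#' roots are allowed, as in HP/MP/DOID/ORDO), optional equivalence pairs and
#' optional disjointness pairs. Logical axioms beyond these (existential
#' restrictions, cross-products) are out of scope.
#'
#' @param ontology_id identifier for the ontology.
#' @param classes character vector of class identifiers; classes mentioned
#'   only in axioms are added automatically.
#' @param subsumptions data frame with columns \code{child}, \code{parent}.
#' @param equivalences data frame with columns \code{a}, \code{b}
#'   (unordered pairs).
#' @param disjointness data frame with columns \code{a}, \code{b}
#'   (unordered pairs).
#' @param labels named character vector, identifier to human-readable name.
#' @param check validate acyclicity of the told hierarchy after contracting
#'   equivalence pairs (default \code{TRUE}).
#' @return an object of class \code{ontology}.
#' @export
ontology <- function(ontology_id, classes = character(),
                     subsumptions = NULL, equivalences = NULL,
                     disjointness = NULL, labels = character(),
                     check = TRUE) {
  pairdf <- function(x, n1, n2) {
    if (is.null(x) || nrow(as.data.frame(x)) == 0)
      return(setNames(data.frame(a = character(), b = character(),
                                 stringsAsFactors = FALSE), c(n1, n2)))
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    out <- data.frame(trimws(as.character(x[[1]])),
                      trimws(as.character(x[[2]])),
                      stringsAsFactors = FALSE)
    names(out) <- c(n1, n2)
    out[!duplicated(out), , drop = FALSE]
  }
  subs <- pairdf(subsumptions, "child", "parent")
  eqs  <- pairdf(equivalences, "a", "b")
  dis  <- pairdf(disjointness, "a", "b")
  if (any(subs$child == subs$parent))
    stop("self-loop in told subsumptions: ",
         subs$child[subs$child == subs$parent][1], call. = FALSE)
  if (any(dis$a == dis$b))
    stop("class declared disjoint with itself: ",
         dis$a[dis$a == dis$b][1], call. = FALSE)
  classes <- sort(unique(c(trimws(classes), subs$child, subs$parent,
                           eqs$a, eqs$b, dis$a, dis$b)))
  classes <- classes[nzchar(classes)]
  o <- structure(
    list(ontology_id = ontology_id, classes = classes,
         labels = labels, subsumptions = subs,
         equivalences = eqs, disjointness = dis),
    class = "ontology")
  if (check) validate_ontology(o)
  o
}

#' Validate that the told hierarchy is acyclic
#'
#' Equivalence pairs are contracted first (an equivalence class is one
#' node); a directed cycle among the remaining told subsumptions is an
#' error, and one witness cycle is reported.
#'
#' @param o an [ontology()].
#' @return \code{o}, invisibly.
#' @export
validate_ontology <- function(o) {
  if (nrow(o$subsumptions) == 0) return(invisible(o))
  comp <- eq_components(o$classes, o$equivalences)
  g <- igraph::graph_from_data_frame(
    data.frame(from = comp[o$subsumptions$child],
               to = comp[o$subsumptions$parent]),
    directed = TRUE)
  g <- igraph::simplify(g, remove.loops = FALSE)
  loops <- igraph::which_loop(g)
  if (any(loops) || !igraph::is_dag(igraph::simplify(g))) {
    cyc <- if (any(loops))
      igraph::ends(g, igraph::E(g)[loops][1])[1, 1]
    else {
      scc <- igraph::components(g, mode = "strong")
      big <- which(scc$csize > 1)[1]
      paste(names(scc$membership)[scc$membership == big], collapse = " -> ")
    }
    stop("cycle in told subsumption hierarchy of ", o$ontology_id,
         " (after equivalence contraction): ", cyc, call. = FALSE)
  }
  invisible(o)
}

# map each class to a canonical representative of its equivalence component
eq_components <- function(classes, equivalences) {
  if (nrow(equivalences) == 0) return(setNames(classes, classes))
  g <- igraph::graph_from_data_frame(equivalences, directed = FALSE,
                                     vertices = data.frame(name = classes))
  memb <- igraph::components(g)$membership
  reps <- tapply(names(memb), memb, function(v) sort(v)[1])
  setNames(unname(reps[as.character(memb)]), names(memb))
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf(
    "<ontology> %s: %d classes, %d subsumptions, %d equivalences, %d disjointness pairs\n",
    x$ontology_id, length(x$classes), nrow(x$subsumptions),
    nrow(x$equivalences), nrow(x$disjointness)))
  invisible(x)
}

#' Read an OBO flat file into an ontology
#'
#' Supports the OBO 1.2/1.4 subset the evaluation needs: \code{[Term]}
#' stanzas with \code{id}, \code{name}, \code{is_a}, \code{equivalent_to},
#' \code{disjoint_from} and \code{is_obsolete}. Obsolete terms are dropped
#' together with every axiom mentioning them.
#'
#' @param path path to an OBO file or a character vector of lines.
#' @param ontology_id identifier; defaults to the header's \code{ontology:}
#'   tag or the file name.
#' @return an [ontology()].
#' @export
parse_obo <- function(path, ontology_id = NULL) {
  lines <- if (length(path) == 1 && file.exists(path))
    readLines(path, warn = FALSE) else path
  lines <- sub("!.*$", "", lines)          # trailing OBO comments
  lines <- trimws(lines)
  stanza_starts <- grep("^\\[", lines)
  if (is.null(ontology_id)) {
    hdr_end <- if (length(stanza_starts)) stanza_starts[1] - 1 else length(lines)
    ont_tag <- grep("^ontology:", head(lines, hdr_end), value = TRUE)
    ontology_id <- if (length(ont_tag)) trimws(sub("^ontology:", "", ont_tag[1]))
      else if (length(path) == 1 && file.exists(path)) basename(path)
      else "obo"
  }
  term_idx <- which(lines[stanza_starts] == "[Term]")
  ids <- character(); names_ <- character()
  isa_child <- character(); isa_parent <- character()
  eq_a <- character(); eq_b <- character()
  dj_a <- character(); dj_b <- character()
  obsolete <- character()
  bounds <- c(stanza_starts, length(lines) + 1)
  for (k in term_idx) {
    i0 <- stanza_starts[k] + 1
    i1 <- bounds[k + 1] - 1
    body <- lines[seq(i0, max(i0, i1))]
    tagval <- function(tag) {
      v <- grep(paste0("^", tag, ":"), body, value = TRUE)
      trimws(sub(paste0("^", tag, ":"), "", v))
    }
    id <- tagval("id")
    if (length(id) == 0 || !nzchar(id[1]))
      stop("OBO [Term] stanza #", which(term_idx == k),
           " is missing an id", call. = FALSE)
    id <- id[1]
    if (any(tolower(tagval("is_obsolete")) == "true")) {
      obsolete <- c(obsolete, id)
      next
    }
    ids <- c(ids, id)
    nm <- tagval("name")
    if (length(nm)) names_[id] <- nm[1]
    # axiom values may carry an inline name after the id; keep token one
    tok1 <- function(v) vapply(strsplit(v, "\\s+"), `[`, character(1), 1)
    for (p in tok1(tagval("is_a"))) {
      isa_child <- c(isa_child, id); isa_parent <- c(isa_parent, p)
    }
    for (p in tok1(tagval("equivalent_to"))) {
      eq_a <- c(eq_a, id); eq_b <- c(eq_b, p)
    }
    for (p in tok1(tagval("disjoint_from"))) {
      dj_a <- c(dj_a, id); dj_b <- c(dj_b, p)
    }
  }
  drop_obs <- function(a, b) !(a %in% obsolete | b %in% obsolete)
  k1 <- drop_obs(isa_child, isa_parent)
  k2 <- drop_obs(eq_a, eq_b)
  k3 <- drop_obs(dj_a, dj_b)
  ontology(ontology_id, classes = ids,
           subsumptions = data.frame(child = isa_child[k1],
                                     parent = isa_parent[k1]),
           equivalences = data.frame(a = eq_a[k2], b = eq_b[k2]),
           disjointness = data.frame(a = dj_a[k3], b = dj_b[k3]),
           labels = names_)
}

#' Read an ontology from a subsumption edge list
#'
#' TSV rows \code{child<TAB>parent} assert subsumption; an optional third
#' column \code{equiv} or \code{disjoint} reinterprets the pair. Lines
#' starting with \code{#} are ignored.
#'
#' @param path path or character vector of lines.
#' @param ontology_id identifier for the resulting ontology.
#' @return an [ontology()].
#' @export
parse_edgelist <- function(path, ontology_id = "ontology") {
  lines <- if (length(path) == 1 && file.exists(path))
    readLines(path, warn = FALSE) else path
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) return(ontology(ontology_id))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2 | nf > 3))
    stop("edge list row with ", nf[which(nf < 2 | nf > 3)[1]],
         " fields; expected 2 or 3", call. = FALSE)
  a <- vapply(parts, `[`, character(1), 1)
  b <- vapply(parts, `[`, character(1), 2)
  kind <- vapply(parts, function(p)
    if (length(p) >= 3) tolower(trimws(p[3])) else "subsumption",
    character(1))
  kind[!nzchar(kind)] <- "subsumption"
  bad <- !kind %in% c("subsumption", "is_a", "equiv", "disjoint")
  if (any(bad))
    stop("unknown edge kind '", kind[bad][1], "'", call. = FALSE)
  is_sub <- kind %in% c("subsumption", "is_a")
  ontology(ontology_id,
           subsumptions = data.frame(child = a[is_sub], parent = b[is_sub]),
           equivalences = data.frame(a = a[kind == "equiv"],
                                     b = b[kind == "equiv"]),
           disjointness = data.frame(a = a[kind == "disjoint"],
                                     b = b[kind == "disjoint"]))
}

#' Write an ontology as a subsumption edge list
#'
#' Inverse of [parse_edgelist()]; rows are sorted for deterministic output.
#' Isolated classes (no axioms) are not representable in this format and
#' are dropped with a warning.
#'
#' @param o an [ontology()].
#' @param path output path, or \code{NULL} to return the lines.
#' @export
write_edgelist <- function(o, path = NULL) {
  rows <- c(sprintf("%s\t%s", o$subsumptions$child, o$subsumptions$parent),
            sprintf("%s\t%s\tequiv", o$equivalences$a, o$equivalences$b),
            sprintf("%s\t%s\tdisjoint", o$disjointness$a, o$disjointness$b))
  mentioned <- unique(c(o$subsumptions$child, o$subsumptions$parent,
                        o$equivalences$a, o$equivalences$b,
                        o$disjointness$a, o$disjointness$b))
  lost <- setdiff(o$classes, mentioned)
  if (length(lost))
    warning(length(lost), " isolated class(es) not representable in the ",
            "edge-list format", call. = FALSE)
  rows <- sort(rows)
  if (is.null(path)) return(rows)
  writeLines(rows, path)
  invisible(rows)
}

#' Hierarchy metrics: class count, maximum depth, average children
#'
#' Depth counts nodes on the longest child-to-root path (a root alone has
#' depth 1); with multiple roots the maximum over roots is taken. Average
#' number of children is the mean out-degree (children per class) over
#' non-leaf classes only; an ontology with no non-leaf class reports 0.
#'
#' @param o an acyclic [ontology()].
#' @return a list with \code{n_classes}, \code{max_depth},
#'   \code{avg_children}.
#' @export
compute_metrics <- function(o) {
  validate_ontology(o)
  n <- length(o$classes)
  if (n == 0) return(list(n_classes = 0, max_depth = 0, avg_children = 0))
  comp <- eq_components(o$classes, o$equivalences)
  nodes <- unique(unname(comp))
  subs <- unique(data.frame(child = comp[o$subsumptions$child],
                            parent = comp[o$subsumptions$parent],
                            stringsAsFactors = FALSE))
  subs <- subs[subs$child != subs$parent, , drop = FALSE]
  # longest path via DP in topological order over child->parent edges
  depth <- setNames(rep(1L, length(nodes)), nodes)
  if (nrow(subs) > 0) {
    g <- igraph::graph_from_data_frame(subs, directed = TRUE,
                                       vertices = data.frame(name = nodes))
    ord <- names(igraph::topo_sort(g, mode = "in"))  # parents before children
    for (v in ord) {
      ps <- names(igraph::neighbors(g, v, mode = "out"))
      if (length(ps)) depth[v] <- max(depth[ps]) + 1L
    }
  }
  nchild <- table(factor(subs$parent, levels = nodes))
  nonleaf <- nchild[nchild > 0]
  list(n_classes = n,
       max_depth = max(depth),
       avg_children = if (length(nonleaf)) mean(as.numeric(nonleaf)) else 0)
}
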