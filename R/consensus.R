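#' Aggregate system alignments into a family vote table
#'
#' Each (source, target) pair accumulates one vote per system family that
#' proposed it, so several variants of the same tool cannot inflate a
#' mapping's support. Within a family, an equivalence proposal absorbs any
#' subsumption proposal for the same pair; a family proposing both
#' subsumption directions without equivalence is resolved to equivalence
#' (the precedence rule's spirit) and reported as a conflict message.
#'
#' @param alignments list of [alignment()] objects sharing one ontology
#'   pair and orientation.
#' @param equivalence_only restrict voting to equivalence mappings before
#'   aggregation.
#' @return a data frame with columns \code{source}, \code{target},
#'   \code{family}, \code{relation} (one row per family vote), carrying the
#'   full family roster as attribute \code{"families"}.
#' @export
build_vote_table <- function(alignments, equivalence_only = FALSE) {
  stopifnot(is.list(alignments), length(alignments) >= 1)
  for (a in alignments[-1]) {
    if (!same_ontology_pair(alignments[[1]], a))
      stop("alignments reference different ontology pairs: ",
           a$system_name, call. = FALSE)
  }
  fams <- sort(unique(vapply(alignments, `[[`, character(1), "family")))
  rows <- do.call(rbind, lapply(alignments, function(a) {
    m <- a$mappings
    if (equivalence_only) m <- m[m$relation == "=", , drop = FALSE]
    if (nrow(m) == 0) return(NULL)
    data.frame(source = m$source, target = m$target, relation = m$relation,
               family = a$family, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(source = character(), target = character(),
                       relation = character(), family = character(),
                       stringsAsFactors = FALSE)
  rows <- rows[!duplicated(rows[c("source", "target", "relation", "family")]),
               , drop = FALSE]
  # resolve one relation per family per pair
  key <- paste(rows$family, rows$source, rows$target, sep = "\r")
  rel <- tapply(rows$relation, key, function(r) {
    if ("=" %in% r) "="
    else if (all(c("<", ">") %in% r)) "conflict"
    else r[1]
  })
  first <- rows[!duplicated(key), c("source", "target", "family"),
                drop = FALSE]
  first$relation <- unname(rel[paste(first$family, first$source,
                                     first$target, sep = "\r")])
  ncf <- sum(first$relation == "conflict")
  if (ncf > 0) {
    message(ncf, " within-family subsumption direction conflict(s) ",
            "resolved to equivalence")
    first$relation[first$relation == "conflict"] <- "="
  }
  first <- first[order(first$source, first$target, first$family),
                 , drop = FALSE]
  rownames(first) <- NULL
  attr(first, "families") <- fams
  attr(first, "ontology1_id") <- alignments[[1]]$ontology1_id
  attr(first, "ontology2_id") <- alignments[[1]]$ontology2_id
  first
}

#' Consensus (silver standard) alignment at a vote threshold
#'
#' Keeps the mappings supported by at least \code{min_votes} system
#' families. If any voting family proposed equivalence for a pair, all of
#' the pair's family votes pool together and the consensus relation is
#' equivalence; otherwise each subsumption direction is counted as its own
#' proposal. The consensus confidence is the vote fraction (votes divided
#' by the number of contributing families).
#'
#' @param table a [build_vote_table()] result.
#' @param min_votes minimum number of supporting families (\eqn{\ge 1}).
#' @return an [alignment()] named \code{consensus-v<min_votes>}.
#' @export
consensus <- function(table, min_votes) {
  stopifnot(is.numeric(min_votes), min_votes >= 1)
  fams <- attr(table, "families")
  nfam <- max(length(fams), 1L)
  out <- list()
  if (nrow(table) > 0) {
    key <- paste(table$source, table$target, sep = "\r")
    for (grp in split(table, key)) {
      if (any(grp$relation == "=")) {
        votes <- length(unique(grp$family))
        if (votes >= min_votes)
          out[[length(out) + 1]] <- data.frame(
            source = grp$source[1], target = grp$target[1], relation = "=",
            confidence = votes / nfam, stringsAsFactors = FALSE)
      } else {
        for (d in unique(grp$relation)) {
          votes <- length(unique(grp$family[grp$relation == d]))
          if (votes >= min_votes)
            out[[length(out) + 1]] <- data.frame(
              source = grp$source[1], target = grp$target[1], relation = d,
              confidence = votes / nfam, stringsAsFactors = FALSE)
        }
      }
    }
  }
  m <- if (length(out)) do.call(rbind, out) else empty_mappings()
  alignment(m, system_name = sprintf("consensus-v%d", as.integer(min_votes)),
            family = "consensus",
            ontology1_id = attr(table, "ontology1_id"),
            ontology2_id = attr(table, "ontology2_id"))
}

#' Consensus size at every vote threshold
#'
#' Sizes of the consensus alignment for \code{min_votes} from 1 up to the
#' number of contributing families; the curve is monotone non-increasing.
#'
#' @param table a [build_vote_table()] result.
#' @return a data frame with columns \code{min_votes}, \code{n_mappings}.
#' @export
threshold_sweep <- function(table) {
  nfam <- max(length(attr(table, "families")), 1L)
  sizes <- vapply(seq_len(nfam),
                  function(v) nrow(consensus(table, v)$mappings), integer(1))
  data.frame(min_votes = seq_len(nfam), n_mappings = sizes)
}
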