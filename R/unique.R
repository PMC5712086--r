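#' Unique mappings of a system
#'
#' A mapping is unique to a system when no other participating system
#' proposed the same (source, target, relation) triple explicitly, and the
#' aligned ontology built from the vote-2 consensus does not entail it.
#' The default restricts to equivalence mappings, since matchers that emit
#' large subsumption sets would otherwise swamp the assessment; uniqueness
#' is checked against every individual system, including same-family
#' variants (use \code{family_exclusive} to exempt a system's own family).
#'
#' @param system the [alignment()] under assessment.
#' @param others list of the other systems' [alignment()]s.
#' @param consensus2_index [build_index()] over O1, O2 and the vote-2
#'   consensus alignment.
#' @param equivalence_only keep only equivalence mappings (default
#'   \code{TRUE}).
#' @param family_exclusive ignore proposals from the system's own family
#'   when testing explicit suggestion (default \code{FALSE}).
#' @param relation_loose treat an equivalence proposal elsewhere as also
#'   covering a subsumption proposal on the same pair (default strict).
#' @return a list with \code{system_name}, \code{mappings} (mapping data
#'   frame) and \code{note}.
#' @export
unique_mappings <- function(system, others, consensus2_index,
                            equivalence_only = TRUE,
                            family_exclusive = FALSE,
                            relation_loose = FALSE) {
  m <- system$mappings
  if (equivalence_only) m <- m[m$relation == "=", , drop = FALSE]
  if (family_exclusive)
    others <- Filter(function(a) !identical(a$family, system$family), others)
  if (nrow(m) > 0 && length(others) > 0) {
    other_m <- do.call(rbind, lapply(others, function(a) a$mappings))
    seen <- mapping_key(m) %in% mapping_key(other_m)
    if (relation_loose) {
      pair <- function(x) paste(x$source, x$target, sep = "\r")
      eq_pairs <- pair(other_m[other_m$relation == "=", , drop = FALSE])
      seen <- seen | (m$relation != "=" & pair(m) %in% eq_pairs)
    }
    m <- m[!seen, , drop = FALSE]
  }
  if (nrow(m) > 0) m <- m[!entails(consensus2_index, m), , drop = FALSE]
  rownames(m) <- NULL
  list(system_name = system$system_name, mappings = m,
       note = sprintf("unique %smappings vs %d other systems + vote-2 consensus entailment",
                      if (equivalence_only) "equivalence " else "",
                      length(others)))
}

#' Draw a manual-assessment sample from a unique-mapping set
#'
#' Uniform sample without replacement of up to \code{cap} mappings (the
#' review workload cap; 30 by default), deterministic for a given seed and
#' independent of the caller's RNG state.
#'
#' @param u a [unique_mappings()] result or mapping data frame.
#' @param cap maximum sample size.
#' @param seed integer seed.
#' @return a mapping data frame of \code{min(cap, n)} rows.
#' @export
sample_for_assessment <- function(u, cap = 30, seed = 1) {
  stopifnot(cap >= 1)
  m <- if (is.data.frame(u)) u else u$mappings
  if (nrow(m) <= cap) return(m)
  idx <- with_local_seed(seed, sample.int(nrow(m), cap))
  out <- m[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# evaluate expr under a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write a review sheet for manual assessment
#'
#' TSV with the mapped identifiers, their labels where the ontologies
#' provide one, the relation, and an empty \code{verdict} column for the
#' assessor to fill with \code{correct} or \code{incorrect}.
#'
#' @param m mapping data frame (typically a [sample_for_assessment()]
#'   draw).
#' @param o1,o2 optional [ontology()] objects supplying labels.
#' @param path output path, or \code{NULL} to return the lines.
#' @export
write_review_sheet <- function(m, o1 = NULL, o2 = NULL, path = NULL) {
  lab <- function(ids, o) {
    if (is.null(o) || length(o$labels) == 0) return(rep("", length(ids)))
    l <- unname(o$labels[ids]); l[is.na(l)] <- ""; l
  }
  lines <- c("source\tsource_label\ttarget\ttarget_label\trelation\tverdict",
             sprintf("%s\t%s\t%s\t%s\t%s\t", m$source, lab(m$source, o1),
                     m$target, lab(m$target, o2), m$relation))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read verdicts back from a completed review sheet
#'
#' @param path review-sheet TSV with a filled \code{verdict} column.
#' @return a list with \code{n_sampled} (verdicts present) and
#'   \code{n_correct}.
#' @export
read_review_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  v <- tolower(trimws(as.character(df$verdict)))
  v <- v[nzchar(v) & !is.na(v)]
  bad <- setdiff(v, c("correct", "incorrect"))
  if (length(bad))
    stop("unrecognized verdict(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  list(n_sampled = length(v), n_correct = sum(v == "correct"))
}

#' Positive and negative contributions of unique mappings
#'
#' For system \eqn{i} with \eqn{n_i} unique mappings and assessed precision
#' \eqn{p_i}, the positive contribution is \eqn{n_i p_i / \sum_j n_j} and
#' the negative contribution \eqn{n_i (1 - p_i) / \sum_j n_j}: the system's
#' share of the pooled unique mappings, split into its correct and
#' incorrect parts. Across systems the two columns always sum to 1.
#'
#' @param records data frame with columns \code{system_name},
#'   \code{n_unique} and \code{precision_est} (per-system assessed
#'   precision; \code{NA} allowed when \code{n_unique} is 0).
#' @param totals_row append an aggregate row: total uniques, mean assessed
#'   precision over the systems that had unique mappings, and the summed
#'   contributions, as the assessment tables print.
#' @return a data frame with \code{positive_contribution} and
#'   \code{negative_contribution} columns (fractions, not percentages).
#' @export
contributions <- function(records, totals_row = FALSE) {
  stopifnot(all(c("system_name", "n_unique", "precision_est") %in%
                  names(records)))
  n <- as.numeric(records$n_unique)
  p <- as.numeric(records$precision_est)
  if (any(n < 0) || any(!is.na(p) & (p < 0 | p > 1)))
    stop("invalid n_unique or precision_est", call. = FALSE)
  if (any(is.na(p) & n > 0))
    stop("precision_est missing for a system with unique mappings",
         call. = FALSE)
  total <- sum(n)
  if (total <= 0) stop("no unique mappings in the batch", call. = FALSE)
  pc <- ifelse(n > 0, n * p / total, 0)
  nc <- ifelse(n > 0, n * (1 - p) / total, 0)
  out <- data.frame(system_name = as.character(records$system_name),
                    n_unique = n, precision_est = p,
                    positive_contribution = pc,
                    negative_contribution = nc,
                    stringsAsFactors = FALSE)
  if (totals_row) {
    out <- rbind(out, data.frame(
      system_name = "Total", n_unique = total,
      precision_est = mean(p[n > 0]),
      positive_contribution = sum(pc),
      negative_contribution = sum(nc), stringsAsFactors = FALSE))
  }
  out
}
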