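#' Harmonic-mean F-measure
#'
#' \eqn{F = 2PR/(P+R)}, defined as 0 when both precision and recall are 0.
#'
#' @param p,r precision and recall in \eqn{[0,1]}.
#' @return F-measure in \eqn{[0,1]}.
#' @export
f_measure <- function(p, r) ifelse(p + r > 0, 2 * p * r / (p + r), 0)

#' Half-up rounding at a fixed number of decimals
#'
#' Report-level rounding (tables are printed at 2 decimals); metrics are
#' stored at full precision and only rounded for display.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Standard precision, recall and F-measure
#'
#' Set-based scoring: a system mapping is correct iff the same
#' (source, target, relation) triple appears in the reference; confidences
#' play no role. Precision over an empty system alignment is undefined and
#' reported as 0 with a note, so batch evaluation survives systems that
#' failed a task.
#'
#' @param system,reference [alignment()] objects over the same ontology
#'   pair.
#' @return a \code{metrics_report} list: \code{system_name},
#'   \code{reference_name}, \code{n_mappings}, \code{precision},
#'   \code{recall}, \code{f_measure}, \code{semantic}, \code{notes}.
#' @export
standard_prf <- function(system, reference) {
  stopifnot(inherits(system, "alignment"), inherits(reference, "alignment"))
  if (!same_ontology_pair(system, reference))
    stop("system and reference alignments are over different ontology pairs",
         call. = FALSE)
  inter <- nrow(mapping_intersect(system, reference))
  ns <- nrow(system$mappings); nr <- nrow(reference$mappings)
  notes <- character()
  p <- if (ns > 0) inter / ns else { notes <- "precision undefined (empty system alignment)"; 0 }
  r <- if (nr > 0) inter / nr else stop("empty reference alignment", call. = FALSE)
  report(system, reference, ns, p, r, semantic = FALSE, notes = notes)
}

report <- function(system, reference, n, p, r, semantic, notes = character()) {
  structure(list(system_name = system$system_name,
                 reference_name = reference$system_name,
                 n_mappings = n, precision = p, recall = r,
                 f_measure = f_measure(p, r),
                 semantic = semantic,
                 notes = paste(notes, collapse = "; ")),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s vs %s (%s): n=%d P=%.2f R=%.2f F=%.2f%s\n",
              x$system_name, x$reference_name,
              if (x$semantic) "semantic" else "standard",
              x$n_mappings, round_half_up(x$precision),
              round_half_up(x$recall), round_half_up(x$f_measure),
              if (nzchar(x$notes)) paste0(" [", x$notes, "]") else ""))
  invisible(x)
}

# entailment credit per correspondence: subsumptions score 0/1, an
# equivalence is split into its two directions and scores 1/2 each, so a
# half-derivable equivalence earns partial credit while every original
# correspondence weighs the same.
entailment_credit <- function(index, m) {
  m <- as_mappings(m)
  if (nrow(m) == 0) return(numeric(0))
  eq <- m$relation == "="
  credit <- numeric(nrow(m))
  if (any(!eq)) credit[!eq] <- as.numeric(entails(index, m[!eq, , drop = FALSE]))
  if (any(eq)) {
    fwd <- m[eq, , drop = FALSE]; fwd$relation <- "<"
    bwd <- m[eq, , drop = FALSE]; bwd$relation <- ">"
    credit[eq] <- (as.numeric(entails(index, fwd)) +
                     as.numeric(entails(index, bwd))) / 2
  }
  credit
}

#' Semantic precision
#'
#' Mean entailment credit of the system's mappings under the
#' reference-aligned ontology (the merge of both ontologies with the
#' reference alignment). Equivalences are split into their two subsumption
#' directions and earn half credit per entailed direction, so every
#' original correspondence weighs equally; since asserted mappings are
#' always entailed, semantic precision can never fall below standard
#' precision on the same inputs.
#'
#' @param system an [alignment()] or mapping data frame.
#' @param ref_index [build_index()] over O1, O2 and the reference
#'   alignment.
#' @return a fraction in \eqn{[0,1]}; 0 for an empty system alignment.
#' @export
semantic_precision <- function(system, ref_index) {
  sm <- as_mappings(system)
  if (nrow(sm) == 0) return(0)
  mean(entailment_credit(ref_index, sm))
}

#' Semantic recall
#'
#' Mean entailment credit of the reference's mappings under the
#' system-aligned ontology, with the same equivalence-splitting credit as
#' [semantic_precision()]. When scoring against a baseline (a precise but
#' highly incomplete mapping set, such as lexical closeMatch links), this
#' is the only meaningful number.
#'
#' @param reference an [alignment()] or mapping data frame (non-empty).
#' @param sys_index [build_index()] over O1, O2 and the system alignment.
#' @return a fraction in \eqn{[0,1]}.
#' @export
semantic_recall <- function(reference, sys_index) {
  rm <- as_mappings(reference)
  if (nrow(rm) == 0)
    stop("empty reference alignment: semantic recall undefined",
         call. = FALSE)
  mean(entailment_credit(sys_index, rm))
}

#' Evaluate a system alignment against a reference
#'
#' Modes: \code{"standard"} intersects mapping sets (Eq.-1-style P/R/F);
#' \code{"semantic"} scores by entailment over the two aligned ontologies,
#' with equivalences split into directed subsumptions; \code{"baseline"}
#' reports semantic recall only (precision and F against an incomplete
#' baseline are not meaningful and are returned as \code{NA}). In the
#' semantic modes the coherence of each aligned ontology is checked and an
#' incoherence warning is carried in the report notes — scoring an
#' incoherent merge can produce degenerate entailments and repair is out
#' of scope here.
#'
#' @param system,reference [alignment()] objects.
#' @param o1,o2 [ontology()] objects (required for the semantic modes).
#' @param mode \code{"standard"}, \code{"semantic"} or \code{"baseline"}.
#' @return a \code{metrics_report}.
#' @export
evaluate <- function(system, reference, o1 = NULL, o2 = NULL,
                     mode = c("standard", "semantic", "baseline")) {
  mode <- match.arg(mode)
  if (mode == "standard") return(standard_prf(system, reference))
  stopifnot(inherits(o1, "ontology"), inherits(o2, "ontology"))
  notes <- character()
  ref_index <- build_index(o1, o2, reference)
  sys_index <- build_index(o1, o2, system)
  if (!check_coherence(ref_index)$coherent)
    notes <- c(notes, "INCOHERENT reference-aligned ontology")
  if (!check_coherence(sys_index)$coherent)
    notes <- c(notes, "INCOHERENT system-aligned ontology")
  r <- semantic_recall(reference, sys_index)
  if (mode == "baseline") {
    rep <- report(system, reference, nrow(system$mappings),
                  NA_real_, r, semantic = TRUE,
                  notes = c(notes, "baseline mode: recall only"))
    rep$f_measure <- NA_real_
    return(rep)
  }
  p <- semantic_precision(system, ref_index)
  if (nrow(system$mappings) == 0)
    notes <- c(notes, "precision undefined (empty system alignment)")
  report(system, reference, nrow(system$mappings), p, r,
         semantic = TRUE, notes = notes)
}
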