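# deterministic sub-seed for a named component, kept within 32-bit range
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 2017L + as.integer(k) * 7919L
}

sample1 <- function(x) if (length(x) == 1) x else sample(x, 1)

# random rooted DAG grown top-down: each new class attaches below an
# existing class whose depth allows it; a fraction gets a second parent
# (multiple inheritance, as in real phenotype/disease hierarchies).
gen_dag <- function(n, max_depth, branching, prefix) {
  ids <- sprintf("%s:%04d", prefix, seq_len(n))
  depth <- integer(n); depth[1] <- 1L
  nchild <- integer(n)
  child <- character(0); parent <- character(0)
  if (n > 1) for (i in 2:n) {
    cand <- which(depth[seq_len(i - 1)] > 0 & depth[seq_len(i - 1)] < max_depth)
    if (length(cand) == 0) cand <- 1L
    w <- ifelse(nchild[cand] < branching, 1.0, 0.15)
    p1 <- if (length(cand) == 1) cand else sample(cand, 1, prob = w)
    child <- c(child, ids[i]); parent <- c(parent, ids[p1])
    nchild[p1] <- nchild[p1] + 1L
    depth[i] <- depth[p1] + 1L
    if (stats::runif(1) < 0.15) {
      cand2 <- setdiff(cand, p1)
      if (length(cand2)) {
        p2 <- sample1(cand2)
        child <- c(child, ids[i]); parent <- c(parent, ids[p2])
        nchild[p2] <- nchild[p2] + 1L
        depth[i] <- max(depth[i], depth[p2] + 1L)
      }
    }
  }
  list(ids = ids, depth = depth,
       edges = data.frame(child = child, parent = parent,
                          stringsAsFactors = FALSE))
}

#' Generate a toy ontology pair with a ground-truth alignment
#'
#' Builds a random DAG hierarchy for the first ontology, then derives the
#' second as a structurally perturbed copy (classes renamed into the second
#' namespace, a fraction deleted with their children re-attached upward,
#' fresh classes grafted on) so that the two hierarchies correspond without
#' being identical — the situation two independently curated vocabularies
#' of one domain are in. The ground-truth alignment links corresponding
#' classes: a configurable fraction as equivalences, the rest as
#' subsumptions of a class under the counterpart of one of its ancestors
#' (curated mapping sets contain both kinds, mostly subsumptions).
#'
#' @param n_classes classes in the first ontology (default 60).
#' @param max_depth target hierarchy depth (default 5).
#' @param branching soft cap on children per class before attachment
#'   elsewhere becomes preferred (default 3).
#' @param n_truth ground-truth mappings to sample (default 20).
#' @param equivalence_fraction fraction of truth mappings that are
#'   equivalences (default 0.7).
#' @param delete_fraction,extra_fraction perturbation intensity for the
#'   second ontology (defaults 0.1).
#' @param seed integer seed; the fixture is fully reproducible.
#' @param prefix1,prefix2 identifier namespaces (defaults \code{"O1"},
#'   \code{"O2"}).
#' @return a list with \code{o1}, \code{o2} ([ontology()]s), \code{truth}
#'   (an [alignment()]) and \code{counterpart} (named vector, O1 id to O2
#'   id for surviving classes).
#' @export
gen_ontology_pair <- function(n_classes = 60, max_depth = 5, branching = 3,
                              n_truth = 20, equivalence_fraction = 0.7,
                              delete_fraction = 0.1, extra_fraction = 0.1,
                              seed = 1, prefix1 = "O1", prefix2 = "O2") {
  stopifnot(n_classes >= 2, max_depth >= 1, n_truth >= 1,
            equivalence_fraction >= 0, equivalence_fraction <= 1)
  with_local_seed(derive_seed(seed, 1), {
    d1 <- gen_dag(n_classes, max_depth, branching, prefix1)
    o1 <- ontology(prefix1, classes = d1$ids, subsumptions = d1$edges,
                   labels = setNames(sprintf("%s term %s", prefix1,
                                             seq_along(d1$ids)), d1$ids))
    # mirrored copy in the second namespace
    rename <- setNames(sprintf("%s:%04d", prefix2, seq_len(n_classes)),
                       d1$ids)
    edges2 <- data.frame(child = unname(rename[d1$edges$child]),
                         parent = unname(rename[d1$edges$parent]),
                         stringsAsFactors = FALSE)
    ids2 <- unname(rename)
    # delete a fraction (never the root); re-attach orphaned children
    n_del <- floor(delete_fraction * n_classes)
    deleted <- if (n_del > 0) sample(ids2[-1], n_del) else character(0)
    if (length(deleted)) {
      for (dcl in deleted) {
        ups <- edges2$parent[edges2$child == dcl]
        downs <- edges2$child[edges2$parent == dcl]
        edges2 <- edges2[edges2$child != dcl & edges2$parent != dcl,
                         , drop = FALSE]
        if (length(downs) && length(ups))
          edges2 <- rbind(edges2,
                          expand.grid(child = downs, parent = ups,
                                      stringsAsFactors = FALSE))
      }
      ids2 <- setdiff(ids2, deleted)
    }
    # graft fresh classes with no counterpart
    n_extra <- floor(extra_fraction * n_classes)
    if (n_extra > 0) {
      extra <- sprintf("%s:X%03d", prefix2, seq_len(n_extra))
      edges2 <- rbind(edges2,
                      data.frame(child = extra,
                                 parent = vapply(seq_len(n_extra),
                                   function(i) sample1(ids2), character(1)),
                                 stringsAsFactors = FALSE))
      ids2 <- c(ids2, extra)
    }
    o2 <- ontology(prefix2, classes = ids2, subsumptions = edges2,
                   labels = setNames(sprintf("%s term %s", prefix2,
                                             seq_along(ids2)), ids2))
    surviving <- d1$ids[rename[d1$ids] %in% ids2]
    counterpart <- rename[surviving]
    if (n_truth > length(surviving))
      stop("infeasible fixture: ", n_truth, " truth mappings requested but ",
           "only ", length(surviving), " corresponding class pairs exist",
           call. = FALSE)
    picked <- sample(surviving, n_truth)
    n_eq <- round(equivalence_fraction * n_truth)
    rel <- c(rep("=", n_eq), rep("<", n_truth - n_eq))
    src <- picked
    tgt <- unname(counterpart[picked])
    # subsumption truths point at the counterpart of an ancestor
    if (n_truth > n_eq) {
      for (i in seq(n_eq + 1, n_truth)) {
        ups <- d1$edges$parent[d1$edges$child == src[i]]
        ups <- ups[ups %in% names(counterpart)]
        if (length(ups)) tgt[i] <- unname(counterpart[sample1(ups)])
        else rel[i] <- "="          # a root: keep the equivalence
      }
    }
    truth <- alignment(data.frame(source = src, target = tgt,
                                  relation = rel, confidence = 1,
                                  stringsAsFactors = FALSE),
                       system_name = "truth", family = "truth",
                       ontology1_id = prefix1, ontology2_id = prefix2)
    list(o1 = o1, o2 = o2, truth = truth, counterpart = counterpart)
  })
}

#' Simulate a matching system's alignment at target precision and recall
#'
#' Includes each ground-truth mapping independently with probability
#' \code{recall_target}, then adds false mappings until the expected
#' precision equals \code{precision_target}. False mappings are drawn as
#' structured near-misses with probability \code{confusability}: the target
#' of a true mapping is displaced to one of its hierarchy neighbours in the
#' second ontology, producing the plausible-but-wrong proposals real
#' matchers emit (and letting semantic scores diverge from standard ones);
#' the remainder are uniformly random cross-ontology pairs.
#'
#' @param pair a [gen_ontology_pair()] result.
#' @param precision_target,recall_target targets in \eqn{(0, 1]}.
#' @param seed integer seed.
#' @param confusability fraction of noise drawn near true matches
#'   (default 0.8).
#' @param system_name,family labels for the [alignment()].
#' @return an [alignment()] with a \code{bookkeeping} attribute recording
#'   the exact true/false mapping counts.
#' @export
gen_system_alignment <- function(pair, precision_target, recall_target,
                                 seed = 1, confusability = 0.8,
                                 system_name = "system",
                                 family = system_name) {
  stopifnot(precision_target > 0, precision_target <= 1,
            recall_target > 0, recall_target <= 1)
  truth <- pair$truth$mappings
  o2 <- pair$o2
  with_local_seed(derive_seed(seed, 2), {
    keep <- stats::runif(nrow(truth)) < recall_target
    kept <- truth[keep, , drop = FALSE]
    n_false <- round(nrow(kept) * (1 - precision_target) / precision_target)
    # exclude at the pair level so a "false" draw can never hit any truth
    taken <- new.env(parent = emptyenv())
    for (k in paste(truth$source, truth$target, sep = "\r"))
      assign(k, TRUE, envir = taken)
    false_rows <- list()
    neigh <- function(cl) unique(c(
      o2$subsumptions$parent[o2$subsumptions$child == cl],
      o2$subsumptions$child[o2$subsumptions$parent == cl]))
    guard <- 0
    while (length(false_rows) < n_false && guard < 50 * (n_false + 1)) {
      guard <- guard + 1
      if (stats::runif(1) < confusability && nrow(truth) > 0) {
        i <- sample1(seq_len(nrow(truth)))
        cand <- neigh(truth$target[i])
        # hop once more for variety
        if (length(cand) && stats::runif(1) < 0.3)
          cand <- unique(c(cand, unlist(lapply(cand, neigh))))
        cand <- setdiff(cand, truth$target[i])
        if (length(cand) == 0) next
        row <- c(truth$source[i], sample1(cand), truth$relation[i])
      } else {
        row <- c(sample1(pair$o1$classes), sample1(o2$classes), "=")
      }
      k <- paste(row[1], row[2], sep = "\r")
      if (!is.null(taken[[k]])) next
      assign(k, TRUE, envir = taken)
      false_rows[[length(false_rows) + 1]] <- row
    }
    fm <- if (length(false_rows)) {
      fr <- do.call(rbind, false_rows)
      data.frame(source = fr[, 1], target = fr[, 2], relation = fr[, 3],
                 confidence = round(stats::runif(nrow(fr), 0.5, 1), 3),
                 stringsAsFactors = FALSE)
    } else NULL
    m <- rbind(kept[c("source", "target", "relation", "confidence")], fm)
    a <- alignment(m, system_name = system_name, family = family,
                   ontology1_id = pair$o1$ontology_id,
                   ontology2_id = pair$o2$ontology_id)
    attr(a, "bookkeeping") <- list(n_true = nrow(kept),
                                   n_false = length(false_rows))
    a
  })
}

#' Generate a complete evaluation fixture
#'
#' A toy matching task: an ontology pair with ground truth plus a roster of
#' simulated systems at configured precision/recall, grouped into families.
#'
#' @param n_systems number of simulated systems (default 5).
#' @param precision_targets,recall_targets per-system targets, recycled to
#'   \code{n_systems} (defaults 0.8 and 0.8).
#' @param families per-system family labels; defaults to each system its
#'   own family.
#' @param seed integer seed.
#' @param ... passed to [gen_ontology_pair()].
#' @return a list with \code{o1}, \code{o2}, \code{truth}, \code{systems}
#'   (list of [alignment()]s) and \code{bookkeeping}.
#' @export
gen_fixture <- function(n_systems = 5, precision_targets = 0.8,
                        recall_targets = 0.8, families = NULL, seed = 1,
                        ...) {
  pair <- gen_ontology_pair(seed = derive_seed(seed, 10), ...)
  p <- rep_len(precision_targets, n_systems)
  r <- rep_len(recall_targets, n_systems)
  if (is.null(families)) families <- sprintf("sys%02d", seq_len(n_systems))
  systems <- lapply(seq_len(n_systems), function(i)
    gen_system_alignment(pair, p[i], r[i],
                         seed = derive_seed(seed, 100 + i),
                         system_name = sprintf("sys%02d", i),
                         family = families[i]))
  list(o1 = pair$o1, o2 = pair$o2, truth = pair$truth, systems = systems,
       bookkeeping = lapply(systems, attr, "bookkeeping"))
}
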