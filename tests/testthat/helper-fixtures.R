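# shared test utilities: tiny hand-built fixtures and independent oracles

# random canonical alignment for round-trip / set-semantics properties
random_alignment <- function(n = 10, name = "rand") {
  src <- sprintf("A:%03d", sample(500, n, replace = TRUE))
  tgt <- sprintf("B:%03d", sample(500, n, replace = TRUE))
  alignment(data.frame(source = src, target = tgt,
                       relation = sample(c("<", ">", "="), n, replace = TRUE),
                       confidence = round(runif(n, 0.01, 1), 3),
                       stringsAsFactors = FALSE),
            system_name = name)
}

# random directed acyclic subsumption graph as an ontology
random_ontology <- function(n = 10, p_edge = 0.2, id = "R",
                            n_equiv = 0, n_disjoint = 0) {
  ids <- sprintf("%s:%02d", id, seq_len(n))
  child <- character(0); parent <- character(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && runif(1) < p_edge) {    # edges only forward: acyclic
      child <- c(child, ids[i]); parent <- c(parent, ids[j])
    }
  }
  eq <- if (n_equiv > 0) {
    a <- sample(ids, n_equiv, replace = TRUE)
    b <- sample(ids, n_equiv, replace = TRUE)
    ok <- a != b
    data.frame(a = a[ok], b = b[ok], stringsAsFactors = FALSE)
  } else NULL
  dj <- if (n_disjoint > 0) {
    a <- sample(ids, n_disjoint, replace = TRUE)
    b <- sample(ids, n_disjoint, replace = TRUE)
    ok <- a != b
    data.frame(a = a[ok], b = b[ok], stringsAsFactors = FALSE)
  } else NULL
  tryCatch(
    ontology(id, classes = ids,
             subsumptions = data.frame(child = child, parent = parent,
                                       stringsAsFactors = FALSE),
             equivalences = eq, disjointness = dj),
    error = function(e) NULL)   # equivalences may close a cycle; redraw
}

# independent reachability oracle: boolean Floyd-Warshall transitive
# closure over the merged graph (told edges + equivalence both ways +
# split mapping edges), no component contraction
brute_closure <- function(o1, o2, m) {
  m <- split_equivalence(m)
  nodes <- unique(c(o1$classes, o2$classes, m$source, m$target))
  k <- length(nodes)
  R <- diag(TRUE, k)
  rownames(R) <- colnames(R) <- nodes
  add <- function(from, to) for (i in seq_along(from)) R[from[i], to[i]] <<- TRUE
  for (o in list(o1, o2)) {
    add(o$subsumptions$child, o$subsumptions$parent)
    add(o$equivalences$a, o$equivalences$b)
    add(o$equivalences$b, o$equivalences$a)
  }
  add(ifelse(m$relation == "<", m$source, m$target),
      ifelse(m$relation == "<", m$target, m$source))
  for (v in seq_len(k)) R <- R | (R[, v] %o% R[v, ])
  R
}

brute_entails <- function(R, source, target, relation) {
  if (!(source %in% rownames(R)) || !(target %in% rownames(R))) return(FALSE)
  switch(relation,
         "<" = R[source, target],
         ">" = R[target, source],
         "=" = R[source, target] && R[target, source])
}

# 4-node cross-ontology chain: a < b in O1, b = c mapping, c < d in O2
chain_fixture <- function() {
  o1 <- ontology("O1", subsumptions = data.frame(child = "a", parent = "b"))
  o2 <- ontology("O2", subsumptions = data.frame(child = "c", parent = "d"))
  m <- mapping_set("b", "c", "=")
  list(o1 = o1, o2 = o2, m = m)
}
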