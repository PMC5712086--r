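test_that("equivalence splitting replaces each = by both directions", {
  out <- split_equivalence(mapping_set("A", "B", "="))
  expect_setequal(out$relation, c("<", ">"))
  expect_equal(nrow(out), 2)

  sub <- mapping_set("A", "B", "<")
  expect_identical(split_equivalence(sub)[1:3], sub[1:3])

  # size arithmetic vs direct enumeration on random sets
  set.seed(21)
  for (i in 1:20) {
    m <- random_alignment(n = sample(1:12, 1))$mappings
    out <- split_equivalence(m)
    enum <- unique(do.call(rbind, lapply(seq_len(nrow(m)), function(i)
      if (m$relation[i] == "=")
        data.frame(source = m$source[i], target = m$target[i],
                   relation = c("<", ">"))
      else m[i, c("source", "target", "relation")])))
    expect_equal(nrow(out), nrow(enum))
  }
})

test_that("entailment follows chains through mapping bridges", {
  fx <- chain_fixture()
  idx <- build_index(fx$o1, fx$o2, fx$m)
  expect_true(entails(idx, mapping_set("a", "d", "<")))
  expect_true(entails(idx, mapping_set("b", "c", "=")))
  expect_false(entails(idx, mapping_set("d", "a", "<")))
  # with no mappings, only within-ontology ancestry is entailed
  idx0 <- build_index(fx$o1, fx$o2)
  expect_true(entails(idx0, mapping_set("a", "b", "<")))
  expect_false(entails(idx0, mapping_set("a", "d", "<")))
  # every asserted mapping is entailed by its own index
  expect_true(all(entails(idx, fx$m)))
})

test_that("entails agrees with Floyd-Warshall closure on random graphs", {
  set.seed(31)
  for (rep in 1:25) {
    o1 <- random_ontology(n = 8, p_edge = 0.2, id = "L", n_equiv = 1)
    o2 <- random_ontology(n = 8, p_edge = 0.2, id = "R", n_equiv = 1)
    if (is.null(o1) || is.null(o2)) next
    m <- mapping_set(sample(o1$classes, 3), sample(o2$classes, 3),
                     sample(c("<", ">", "="), 3, replace = TRUE))
    idx <- build_index(o1, o2, m)
    R <- brute_closure(o1, o2, m)
    nodes <- c(o1$classes, o2$classes)
    qs <- expand.grid(s = nodes, t = nodes, r = c("<", ">", "="),
                      stringsAsFactors = FALSE)
    qs <- qs[qs$s != qs$t, ]
    got <- entails(idx, mapping_set(qs$s, qs$t, qs$r))
    want <- mapply(brute_entails, qs$s, qs$t, qs$r,
                   MoreArgs = list(R = R))
    # entails() canonicalizes (sorts); align the query order the same way
    ord <- order(qs$s, qs$t, qs$r)
    expect_equal(got, unname(want[ord]))
  }
})

test_that("entailment is monotone in the mapping set", {
  set.seed(41)
  for (rep in 1:10) {
    o1 <- random_ontology(n = 8, id = "L"); o2 <- random_ontology(n = 8, id = "R")
    m1 <- mapping_set(sample(o1$classes, 2), sample(o2$classes, 2), "=")
    extra <- mapping_set(sample(o1$classes, 2), sample(o2$classes, 2),
                         c("<", "="))
    m2 <- mapping_set(c(m1$source, extra$source), c(m1$target, extra$target),
                      c(m1$relation, extra$relation))
    qs <- mapping_set(rep(o1$classes, each = length(o2$classes)),
                      rep(o2$classes, times = length(o1$classes)), "<")
    e1 <- entails(build_index(o1, o2, m1), qs)
    e2 <- entails(build_index(o1, o2, m2), qs)
    expect_true(all(e2[e1]))
  }
})

test_that("equivalence contraction is order-independent", {
  set.seed(51)
  o1 <- random_ontology(n = 10, id = "L"); o2 <- random_ontology(n = 10, id = "R")
  m <- mapping_set(sample(o1$classes, 5), sample(o2$classes, 5),
                   sample(c("<", ">", "="), 5, replace = TRUE))
  perm <- m[sample(nrow(m)), ]
  qs <- mapping_set(rep(o1$classes, each = 10), rep(o2$classes, 10), "<")
  expect_identical(entails(build_index(o1, o2, m), qs),
                   entails(build_index(o1, o2, perm), qs))
})

test_that("coherence: disjoint ancestors make a class unsatisfiable", {
  # textbook clash: A below both B and C, B disjoint C
  o1 <- ontology("O1",
                 subsumptions = data.frame(child = c("A", "A"),
                                           parent = c("B", "C")),
                 disjointness = data.frame(a = "B", b = "C"))
  o2 <- ontology("O2", classes = "Z")
  rep <- check_coherence(build_index(o1, o2))
  expect_false(rep$coherent)
  expect_equal(rep$unsatisfiable, "A")
  expect_setequal(rep$witnesses[["A"]], c("B", "C"))

  # no disjointness axioms at all: trivially coherent
  fx <- chain_fixture()
  expect_true(check_coherence(build_index(fx$o1, fx$o2, fx$m))$coherent)

  # brute-force cross-check on random graphs with random disjointness
  set.seed(61)
  for (i in 1:15) {
    o <- random_ontology(n = 10, p_edge = 0.25, n_disjoint = 2)
    if (is.null(o)) next
    oB <- ontology("B2", classes = "zz")
    idx <- build_index(o, oB)
    R <- brute_closure(o, oB, empty_mappings())
    unsat <- Filter(function(cl) {
      any(apply(o$disjointness, 1, function(d)
        (R[cl, d[1]] || cl == d[1]) && (R[cl, d[2]] || cl == d[2])))
    }, o$classes)
    expect_setequal(check_coherence(idx)$unsatisfiable, unsat)
  }
})

test_that("unknown mapped classes warn and are never entailed", {
  fx <- chain_fixture()
  expect_warning(idx <- build_index(fx$o1, fx$o2,
                                    mapping_set("ghost", "c", "=")),
                 "not present")
  expect_true(entails(idx, mapping_set("ghost", "c", "=")))   # asserted
  expect_true(entails(idx, mapping_set("ghost", "d", "<")))   # via c
  # identifiers absent from the index are never entailed
  expect_false(entails(idx, mapping_set("phantom", "d", "<")))
})
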