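test_that("F-measure arithmetic matches hand calculation and rounding", {
  expect_equal(f_measure(1, 1), 1)
  expect_equal(f_measure(0, 0.5), 0)
  expect_equal(round_half_up(f_measure(1.00, 0.33)), 0.50)
  expect_equal(round_half_up(f_measure(1.00, 0.34)), 0.51)
  expect_equal(round_half_up(f_measure(0.99, 0.55)), 0.71)
  expect_equal(round_half_up(0.005), 0.01)       # half rounds up
})

test_that("standard P/R/F by set intersection, with enumeration oracle", {
  ref <- alignment(data.frame(source = sprintf("A%d", 1:4),
                              target = sprintf("B%d", 1:4),
                              relation = "=", confidence = 1), "ref")
  sys <- alignment(data.frame(source = c("A1", "A2", "A9"),
                              target = c("B1", "B2", "B9"),
                              relation = "=", confidence = 1), "sys")
  rep <- standard_prf(sys, ref)
  expect_equal(rep$precision, 2 / 3)
  expect_equal(rep$recall, 1 / 2)
  expect_equal(rep$f_measure, 4 / 7)

  self <- standard_prf(ref, ref)
  expect_equal(c(self$precision, self$recall, self$f_measure), c(1, 1, 1))

  # a shared pair with a different relation is not a match
  sys2 <- alignment(data.frame(source = "A1", target = "B1",
                               relation = "<", confidence = 1), "sys2")
  expect_equal(standard_prf(sys2, ref)$precision, 0)
})

test_that("empty system alignment: precision 0 with explicit note", {
  ref <- alignment(data.frame(source = "A", target = "B", relation = "=",
                              confidence = 1), "ref")
  sys <- alignment(empty_mappings(), "failed-system")
  rep <- standard_prf(sys, ref)
  expect_equal(rep$precision, 0)
  expect_match(rep$notes, "undefined")
})

test_that("semantic scores credit entailed near-misses", {
  # O1: a < p ; O2: b < q ; reference maps p = q.
  # A system proposing a < q is standard-wrong but semantically right.
  o1 <- ontology("O1", subsumptions = data.frame(child = "a", parent = "p"))
  o2 <- ontology("O2", subsumptions = data.frame(child = "b", parent = "q"))
  ref <- alignment(data.frame(source = "p", target = "q", relation = "=",
                              confidence = 1), "ref",
                   ontology1_id = "O1", ontology2_id = "O2")
  sys <- alignment(data.frame(source = "a", target = "q", relation = "<",
                              confidence = 1), "sys",
                   ontology1_id = "O1", ontology2_id = "O2")
  expect_equal(standard_prf(sys, ref)$precision, 0)
  sem <- evaluate(sys, ref, o1, o2, mode = "semantic")
  expect_equal(sem$precision, 1)

  # one direction of an equivalence derivable: half credit
  sys_eq <- alignment(data.frame(source = "a", target = "q", relation = "=",
                                 confidence = 1), "syseq",
                      ontology1_id = "O1", ontology2_id = "O2")
  expect_equal(semantic_precision(sys_eq, build_index(o1, o2, ref)), 0.5)

  # disconnected pair: no credit
  sys_far <- mapping_set("a", "b", "=")
  expect_equal(semantic_precision(sys_far, build_index(o1, o2, ref)), 0)
})

test_that("semantic self-evaluation is perfect; subset gives precision 1", {
  fx <- gen_fixture(n_systems = 2, seed = 13, n_classes = 40, n_truth = 12)
  self <- evaluate(fx$truth, fx$truth, fx$o1, fx$o2, mode = "semantic")
  expect_equal(c(self$precision, self$recall, self$f_measure), c(1, 1, 1))

  sub <- alignment(fx$truth$mappings[1:5, ], "subset",
                   ontology1_id = "O1", ontology2_id = "O2")
  expect_equal(semantic_precision(sub, build_index(fx$o1, fx$o2, fx$truth)),
               1)
})

test_that("semantic measures never fall below standard ones", {
  set.seed(91)
  for (rep in 1:20) {
    fx <- gen_fixture(n_systems = 1, seed = sample(10000, 1),
                      precision_targets = runif(1, 0.4, 1),
                      recall_targets = runif(1, 0.4, 1),
                      n_classes = 40, n_truth = 15)
    std <- standard_prf(fx$systems[[1]], fx$truth)
    sem <- evaluate(fx$systems[[1]], fx$truth, fx$o1, fx$o2,
                    mode = "semantic")
    expect_gte(sem$precision + 1e-12, std$precision)
    expect_gte(sem$recall + 1e-12, std$recall)
  }
})

test_that("baseline mode reports recall only", {
  fx <- gen_fixture(n_systems = 1, seed = 17, n_classes = 40, n_truth = 12)
  base <- alignment(fx$truth$mappings[1:4, ], "baseline",
                    ontology1_id = "O1", ontology2_id = "O2")
  rep <- evaluate(fx$systems[[1]], base, fx$o1, fx$o2, mode = "baseline")
  expect_true(is.na(rep$precision))
  expect_true(is.na(rep$f_measure))
  expect_true(rep$recall >= 0 && rep$recall <= 1)
  expect_match(rep$notes, "baseline")
})

test_that("incoherent aligned ontologies are flagged, not fatal", {
  o1 <- ontology("O1",
                 subsumptions = data.frame(child = "a", parent = "b"),
                 disjointness = data.frame(a = "b", b = "c"))
  o2 <- ontology("O2", subsumptions = data.frame(child = "x", parent = "y"))
  # mapping forces a under both b and (via x = a? no: a = x, x < y, y = c)
  ref <- alignment(data.frame(source = c("a", "c"), target = c("x", "y"),
                              relation = "=", confidence = 1), "ref",
                   ontology1_id = "O1", ontology2_id = "O2")
  sys <- alignment(data.frame(source = "a", target = "x", relation = "=",
                              confidence = 1), "sys",
                   ontology1_id = "O1", ontology2_id = "O2")
  rep <- evaluate(sys, ref, o1, o2, mode = "semantic")
  expect_match(rep$notes, "INCOHERENT reference")
})
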