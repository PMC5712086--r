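test_that("uniqueness excludes explicit proposals and consensus entailment", {
  fx <- chain_fixture()   # a < b (O1), c < d (O2)
  idx <- build_index(fx$o1, fx$o2, fx$m)   # consensus asserts b = c

  sys <- alignment(data.frame(source = c("a", "b"), target = c("c", "d"),
                              relation = c("=", "="), confidence = 1), "S1")
  twin <- alignment(data.frame(source = "a", target = "c", relation = "=",
                               confidence = 1), "S2")
  # a = c proposed by S2 too -> not unique; b = d: only one direction
  # (b below d) is consensus-entailed, so the equivalence stays unique
  u <- unique_mappings(sys, list(twin), idx)
  expect_equal(nrow(u$mappings), 1)
  expect_equal(u$mappings$source, "b")

  # a mapping fully entailed via the consensus chain is excluded even if
  # no other system proposed it
  sys2 <- alignment(data.frame(source = "b", target = "c", relation = "<",
                               confidence = 1), "S3")
  u2 <- unique_mappings(sys2, list(), idx, equivalence_only = FALSE)
  expect_equal(nrow(u2$mappings), 0)

  # identical systems have no unique mappings at all
  u3 <- unique_mappings(sys, list(sys), idx)
  expect_equal(nrow(u3$mappings), 0)
})

test_that("equivalence-only focus and the loose-relation flag", {
  fx <- chain_fixture()
  idx <- build_index(fx$o1, fx$o2, empty_mappings())
  sys <- alignment(data.frame(source = c("a", "a"), target = c("c", "d"),
                              relation = c("<", "="), confidence = 1), "S")
  other <- alignment(data.frame(source = "a", target = "c", relation = "=",
                                confidence = 1), "O")
  # default: only the = mapping is considered, and it is unique
  expect_equal(unique_mappings(sys, list(other), idx)$mappings$target, "d")
  # all relations, strict matching: a < c not blocked by the = elsewhere
  u <- unique_mappings(sys, list(other), idx, equivalence_only = FALSE)
  expect_equal(nrow(u$mappings), 2)
  # loose matching: the = proposal elsewhere covers the subsumption
  ul <- unique_mappings(sys, list(other), idx, equivalence_only = FALSE,
                        relation_loose = TRUE)
  expect_equal(ul$mappings$target, "d")
})

test_that("assessment sampling is capped, deterministic and uniform", {
  m <- mapping_set(sprintf("A%02d", 1:7), sprintf("B%02d", 1:7), "=")
  expect_equal(nrow(sample_for_assessment(m, cap = 30, seed = 1)), 7)

  big <- mapping_set(sprintf("A%03d", 1:100), sprintf("B%03d", 1:100), "=")
  s1 <- sample_for_assessment(big, cap = 30, seed = 9)
  s2 <- sample_for_assessment(big, cap = 30, seed = 9)
  expect_equal(nrow(s1), 30)
  expect_identical(s1, s2)
  expect_false(identical(s1, sample_for_assessment(big, cap = 30, seed = 10)))

  # inclusion frequency of each element of a 10-set at cap 3 is ~ 3/10
  ten <- mapping_set(sprintf("A%02d", 1:10), sprintf("B%02d", 1:10), "=")
  hits <- integer(10)
  n_draws <- 2000
  for (s in seq_len(n_draws)) {
    drawn <- sample_for_assessment(ten, cap = 3, seed = s)
    hits[match(drawn$source, ten$source)] <-
      hits[match(drawn$source, ten$source)] + 1L
  }
  p <- 3 / 10
  ci <- 4 * sqrt(p * (1 - p) / n_draws)
  expect_true(all(abs(hits / n_draws - p) < ci))
})

test_that("review sheets round-trip verdicts", {
  fx <- chain_fixture()
  m <- mapping_set(c("a", "b"), c("c", "d"), "=")
  sheet <- write_review_sheet(m, fx$o1, fx$o2)
  expect_equal(length(sheet), 3)
  tf <- tempfile(fileext = ".tsv")
  writeLines(c(sheet[1], paste0(sheet[2], "correct"),
               paste0(sheet[3], "incorrect")), tf)
  v <- read_review_sheet(tf)
  expect_equal(v, list(n_sampled = 2L, n_correct = 1L))
})

test_that("contribution statistics reproduce the published arithmetic", {
  # HP-MP assessment batch: 1225 pooled unique mappings
  hp <- data.frame(
    system_name = c("AML", "DiSMatch", "FCA-Map", "LYAM++", "LogMap",
                    "LogMapBio", "LogMapLt", "PhenoMF", "PhenoMM",
                    "PhenoMP", "XMap"),
    n_unique = c(122, 291, 26, 226, 130, 176, 0, 89, 85, 80, 0),
    precision_est = c(0.87, 0.83, 0.96, 0.70, 0.93, 0.93, NA, 1.00, 1.00,
                      1.00, NA))
  out <- contributions(hp, totals_row = TRUE)
  pct <- function(x) round_half_up(100 * x)
  expect_equal(pct(out$positive_contribution[out$system_name == "PhenoMF"]),
               7.27)
  expect_equal(pct(out$positive_contribution[out$system_name == "PhenoMP"]),
               6.53)
  expect_equal(out$negative_contribution[out$system_name == "PhenoMF"], 0)
  tot <- out[out$system_name == "Total", ]
  expect_equal(tot$n_unique, 1225)
  expect_equal(round_half_up(tot$precision_est), 0.91)
  expect_equal(pct(tot$positive_contribution) + pct(tot$negative_contribution),
               100)

  # DOID-ORDO batch: equal positive and negative share for a 50% system
  do <- data.frame(
    system_name = c("AML", "DiSMatch", "FCA-Map", "LogMap", "LogMapBio",
                    "LogMapLt", "PhenoMF", "XMap"),
    n_unique = c(308, 259, 61, 80, 144, 7, 3, 16),
    precision_est = c(0.87, 0.40, 0.83, 0.90, 0.97, 0.50, 1.00, 0.56))
  out2 <- contributions(do, totals_row = TRUE)
  lt <- out2[out2$system_name == "LogMapLt", ]
  expect_equal(pct(lt$positive_contribution), 0.40)
  expect_equal(pct(lt$negative_contribution), 0.40)
  expect_equal(pct(out2$positive_contribution[out2$system_name == "PhenoMF"]),
               0.34)
})

test_that("contributions conserve total mass and validate inputs", {
  set.seed(101)
  for (rep in 1:50) {
    k <- sample(2:8, 1)
    rec <- data.frame(system_name = paste0("s", 1:k),
                      n_unique = sample(0:200, k, replace = TRUE),
                      precision_est = round(runif(k), 2))
    if (sum(rec$n_unique) == 0) next
    out <- contributions(rec)
    expect_equal(sum(out$positive_contribution + out$negative_contribution),
                 1, tolerance = 1e-12)
  }
  expect_error(contributions(data.frame(system_name = "s", n_unique = 0,
                                        precision_est = NA)),
               "no unique mappings")
  expect_error(contributions(data.frame(system_name = "s", n_unique = 5,
                                        precision_est = 1.2)), "invalid")
})
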