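---
title: "Evaluating ontology alignments with consensus references and semantic measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating ontology alignments with consensus references and semantic measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aligneval)
```

## The evaluation model

A *mapping* is a 4-tuple ⟨e, e′, r, c⟩ linking a class of one ontology to a
class of another with a relation r ∈ {⊑, ⊒, ≡} and a confidence
c ∈ (0, 1]. An *alignment* is one system's mapping set. Two facts shape the
whole design. First, no complete gold standard exists for large biomedical
matching tasks, so references must be built from the systems' own outputs
by voting. Second, two correct alignments can disagree syntactically while
agreeing logically — one system may assert `a ⊑ q` where the reference
asserts `p ≡ q` with `a ⊑ p` told in the ontology — so set intersection
alone misjudges systems that emit logically entailed variants. The package
therefore scores both ways: *standard* precision/recall by set
intersection on (source, target, relation) triples, and *semantic*
precision/recall by entailment over the merged aligned ontology
O^M = O1 ∪ O2 ∪ M.

Mapping identity deliberately ignores confidence: two systems proposing the
same correspondence at different confidence agree on the correspondence.
Confidences are carried (and validated to lie in (0, 1] — never clamped)
but no operation filters on them.

## Entailment by structural closure

`build_index()` merges the two told hierarchies with an alignment whose
equivalences have been split into their two subsumption directions, then
contracts strongly connected components — mutual subsumption is exactly
equivalence — and answers `entails()` queries by reachability in the
condensation, memoized per queried component. For taxonomies (atomic
subsumption, equivalence, disjointness) this computes the same atomic
entailments a description-logic reasoner would; ontologies whose semantics
live in complex axioms (existential restrictions, logical definitions)
are outside this engine's reach, which is why the ⊨ interface is a narrow
seam where a full reasoner could be substituted. An equivalence query is
entailed only when both directions are reachable; since the splitting rule
turns asserted equivalences into both directed axioms, every asserted
mapping is entailed by its own index.

Coherence: a class is unsatisfiable when the closure places it beneath
both members of a declared disjoint pair. The hierarchies this evaluation
targets ship without disjointness, in which case the merge is trivially
coherent; when an incoherent merge does arise, the metrics still run and
the report carries a prominent note — surfacing, not repairing, because
repair is a different problem with its own literature.

## Consensus voting

`build_vote_table()` groups systems into *families* (variants of one tool)
and counts at most one vote per family per (source, target) pair.
Precedence rules, in decreasing strength:

* within a family, an equivalence proposal absorbs subsumption proposals
  for the pair;
* a family proposing both ⊑ and ⊒ without ≡ contributes one vote and is
  resolved to ≡ (mutual subsumption *is* equivalence); the event is
  reported as a conflict;
* across families, if any voter proposed ≡ the pair's votes pool and the
  consensus relation is ≡; otherwise each subsumption direction is its own
  proposal with its own count. Whether opposite directions from different
  families should pool is genuinely undecidable from the published
  evaluation; counting them separately was chosen because a ⊑ and its
  converse are different claims, and the ≡-precedence rule already covers
  the case where they meet.

Consensus confidence is the vote fraction (supporting families divided by
contributing families) — order-independent and informative, where any
aggregation of the systems' own confidences would be neither. The
`threshold_sweep()` curve is monotone non-increasing by construction.
Vote thresholds 2 and 3 are the defaults `run_track()` evaluates against:
vote 1 is every proposal, and thresholds of 4 and above are typically
precise but very incomplete unless many independent families contribute.

## Semantic measures and the equivalence-splitting choice

The published definitions split equivalences into two subsumption mappings
before computing semantic precision and recall, leaving open whether the
denominator counts split or unsplit sets. Counting the split set makes an
equivalence weigh twice as much as a subsumption, and mixing the two
relations can then push semantic recall *below* standard recall — violating
the principle the semantic measures exist for, namely that entailment
extends membership. This package instead scores **per correspondence**:
a subsumption earns 0 or 1, an equivalence earns ½ per entailed direction,
and the denominator is the unsplit set. The splitting rule is thereby
honored (a half-derivable equivalence earns partial credit) while every
correspondence weighs equally, and the inequalities
P_sem ≥ P_std, R_sem ≥ R_std hold provably: an explicitly matched mapping
is asserted in the other side's aligned ontology, hence fully entailed.

Other numerical conventions: F = 2PR/(P+R) with F = 0 when P = R = 0;
metrics are stored at full precision and rounded half-up to two decimals
only in reports; precision over an empty system alignment is reported as 0
with an explicit "undefined" note rather than raising, so a batch
evaluation survives systems that failed a task; an empty *reference* is an
error, because every denominator of recall vanishes.

## Unique mappings and contributions

A system's unique mappings are those no other participant proposed
explicitly — every individual system counts, including same-family
variants, since variants do produce distinct unique sets; a
`family_exclusive` flag offers the other reading — and that the vote-2
consensus-aligned ontology does not entail. The default restricts to
equivalence mappings because subsumption-heavy matchers would otherwise
swamp the pool. Strict relation matching is the default (an ≡ elsewhere
does not block a ⊑ candidate); `relation_loose` offers the alternative.

Assessment samples up to 30 mappings per system (uniform, seeded,
restorable RNG state), writes a review sheet with label columns and an
empty verdict column, and ingests "correct"/"incorrect" verdicts.
Contributions split each system's share of the pooled unique mappings into
its correct and incorrect parts; the two columns sum to 1 across systems
by algebra, and the totals row reports the *unweighted* mean of per-system
assessed precisions (the convention the published assessment tables
follow, verified against both printed batches).

## The simulated oracle

`make_oracle()` wraps a reference alignment as a domain expert with an
error rate: the true answer is reference membership of the canonicalized
triple, flipped independently with the configured probability on first
contact. Answers are cached per mapping — a consistent expert — while the
request counter counts every call, repeated or not, because requests are
the cost axis of interactive evaluation. All flips come from a private,
seed-derived RNG stream, so transcripts are reproducible and the caller's
RNG is untouched. Only the independent symmetric flip model is
implemented; modeling correlated or biased expert errors is out of scope.

## What the fixture generator emulates — and what it does not

`gen_ontology_pair()` grows a random DAG root-down (multiple inheritance at
rate 0.15, soft branching cap 3, depth capped at `max_depth`), then derives
the partner ontology as a perturbed copy: 10% of classes deleted with
children re-attached upward, 10% fresh classes grafted on, everything
renamed into a second namespace. Ground truth links corresponding classes,
70% as equivalences and the rest as subsumptions under an ancestor's
counterpart, mirroring curated mapping sets that contain both kinds.
`gen_system_alignment()` hits a recall target by Bernoulli inclusion and a
precision target by adding `round(kept·(1−p)/p)` false mappings, drawn
preferentially (confusability 0.8) as *near misses* — a true target
displaced to a hierarchy neighbour — because uniformly random noise would
never exercise the standard-vs-semantic divergence that motivates semantic
scoring. Bookkeeping records exact true/false counts, so parameter
recovery is testable: at 1,000 truth mappings the binomial standard error
of the recall estimate is about 0.015, hence the ±0.03 recovery tolerance.

What the generator does **not** emulate: lexical content (labels are
synthetic tokens, so nothing here validates string matchers), realistic
ontology scale (tests run at tens to a few hundred classes; the entailment
engine itself is near-linear per query and handles larger inputs),
non-taxonomic axioms, and annotator disagreement. Passing tests therefore
certify the evaluation machinery, not any claim about how real matchers
rank on real ontologies.

All randomness descends from one integer seed through per-component
derived streams, so a fixture, a sample or a whole `run_track()` bundle is
reproducible bit for bit; the track driver's reports avoid timestamps for
the same reason, and the manifest records input MD5 hashes instead.

## Problem sizes and tolerances used in the test suite

Entailment is cross-checked against a boolean Floyd–Warshall transitive
closure on 200 random 30-class instances over all pairs and all three
relations; contribution conservation on 1,000 random batches at 10⁻¹²;
the semantic-vs-standard inequalities and consensus monotonicity on 100
generated fixtures each; parameter recovery at 1,000 truth mappings within
±0.03; oracle flip frequency at 10⁴ queries within 3 binomial standard
errors. These sizes keep the full suite around a minute while leaving each
property's failure modes (cycle handling, component contraction, vote
pooling, seed plumbing) nowhere to hide.

## Known limitations

* Structural closure is blind to entailments that require reasoning over
  complex axioms; on richly axiomatized inputs semantic scores are lower
  bounds.
* OWL inputs must be pre-converted to OBO or edge lists; the package reads
  hierarchies, not full OWL 2.
* Consensus references inherit the systems' collective blind spots: a
  mapping every system misses cannot appear, and two systems agreeing on
  an error can. Consensus-based scores compare systems to each other, not
  to truth — which is why the unique-mapping assessment exists.
* The totals-row precision convention and the per-direction vote counting
  are documented choices among defensible alternatives; both are isolated
  behind flags or single functions.
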