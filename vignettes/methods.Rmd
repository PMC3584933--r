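---
title: "Three-level function prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-level function prediction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funclevels)
```

## The prediction model

`funclevels` assigns Gene Ontology (GO) terms to target proteins from three
progressively weaker kinds of evidence, each confined to its own confidence
interval so that stronger evidence always outranks weaker evidence:

| Level | Evidence | Score | Range |
|---|---|---|---|
| 1 | top profile-sequence hit, e ≤ 0.01 | 0.6 + 0.4·(−lg e)/200 | [0.6, 1.0] |
| 2 | detected domain families, p ≥ 80 | 0.3 + 0.3·p/100 | [0.54, 0.6] after the filter |
| 3 | network neighbor-counting | 0.3·f | (0, 0.3] |

The intervals encode an empirical ranking of evidence reliability; we take
the interval boundaries as given rather than refitting them. The level-1
divisor of 200 means the score saturates at e ≈ 10⁻²⁰⁰; e-values of 0
(reported by search tools for overwhelming hits) are mapped to 1.0 as an
explicit special case because the formula is singular there, and values
below the smallest positive double are treated as 0. "lg" is read as log₁₀
— the only reading under which the e = 0.01 cutoff contributes the
visible score increment 0.4·2/200; a `log_base` argument allows log₂ for
sensitivity analysis.

**Level 1.** Only the GO terms of the *single best* hit are transferred —
a deliberate high-precision choice; the pooled-hits alternative is exactly
predictor 3. Hits tying at the minimum e-value have their GO sets merged at
the shared score, which makes the operation independent of input order (a
"first of the ties" rule would not be).

**Level 2.** Each retained domain family contributes its annotated terms
at the score of its own probability; a term supported by several domains
keeps the maximum confidence. We merge rather than repeat duplicates
because predictions are per-term objects with a single confidence, and the
maximum preserves the strongest evidence.

**Level 3 (hard cases).** When neither level fires, the target is a *hard
case*. Two fallbacks apply. First, default-threshold (e ≤ 10) hits are
scored by the level-1 formula *without* its 0.6 floor, clipped to (0, 1]:
for e ≥ 1 this falls below 0.6, and over the whole default range it stays
within ±0.004 of the 0.6 boundary, so fallback transfers sit at the bottom
of, or just below, the genuine level-1 band. Second, the domain
co-occurrence network (DCN) of the most closely related species — the
species of the smallest-e-value fallback hit, ties broken by
lexicographically smallest species id for reproducibility — is searched
around *all* detected domains (any probability): the requirement p ≥ 80 is
deliberately dropped here because hard cases by definition have no strong
detections. Detected domains absent from that species' network are dropped
with a logged message.

**Neighbor counting.** The counting unit is the neighbor *domain*: a
domain annotated with term g adds 1 to g's count no matter how many
duplicate annotation rows it has, and f(g) divides by the total number of
distinct (domain, term) occurrences, so Σf = 1 and the level-3 confidences
sum to exactly 0.3. If no radius-one neighbor carries any annotation the
search widens to radius two, counting *only* the domains at distance
exactly two — the radius-one domains are known to contribute nothing, and
including them would only dilute the denominator with zeros. Centers are
always excluded from their own neighbor sets: function is transferred
*from* neighbors precisely because the centers are unannotated.

**Predictor 2** pools GO-term occurrence counts from all passing
profile-sequence hits (per hit, mirroring predictor 3's per-hit counting),
all retained domains, and the radius-one neighbor domains, with weights
4 : 2 : 1, and divides by the maximum weighted frequency. Normalizing by
the maximum (rather than the sum) keeps the best-supported term at exactly
1.0, matching the (0, 1] confidence semantics of assessment submissions.
Predictor 2 uses radius one only; the radius-two extension belongs to
predictor 1's hard-case path.

Each target's final list is de-duplicated (max confidence), sorted by
confidence descending with GO-id ascending as the universal tie-break, and
capped at 100 predictions; a tie group straddling the cap is truncated
within the group in GO-id order.

## The ontology layer

Parent edges are `is_a` only by default — the most conservative reading of
"paths toward the root" — with `part_of` includable via the `relations`
argument of `load_obo()`. The three namespaces stay separate: no artificial
super-root, and propagation, depth and similarity never cross namespaces
(cross-namespace similarity is defined as 0 with a warning, consistent with
assessments that evaluate namespaces separately).

Term **depth** counts nodes inclusive of both endpoints, so the root has
depth 1. In a DAG a term reaches the root by many paths; we default to the
*shortest* path and expose `convention = "longest"`, since the verbal
definition ("number of nodes from a term to the root") does not
disambiguate and published average-depth figures cannot either. Under the
shortest-path convention a child can be *shallower* than one of its
parents; the invariant that does hold (and is tested) is that every term
is at most one level deeper than at least one parent.

The **semantic similarity** of two terms realizes each root-path set rᵢ as
the full ancestor closure of the term (itself included) — terms generally
have many root paths, and the union over paths is the one set-valued object
consistent with treating rᵢ as a single path in the defining ratio
|r₁ ∩ r₂| / max(|r₁|, |r₂|). The score is symmetric, lies in [0, 1], is 1
iff the closures coincide, and is always strictly positive within a
namespace (the root is shared).

## Evaluation

Predicted and true term sets are propagated to the root before computing
per-target precision and recall; curves average the per-target values over
all targets with non-empty truth. Two selection schemes are provided:
top-*n* (n = 1..20), where tied confidence scores form groups and the n
best *groups* are selected, so more than n terms can enter; and a sliding
threshold (t = 0..1, step 0.01), where predictions with confidence ≥ t are
selected. We use ≥ (not strictly greater) so the t = 1 endpoint retains
confidence-1.0 predictions; a `strict` flag switches this. Targets with no
selected predictions contribute (0, 0) rather than being skipped, keeping
the averaging denominator fixed at the full target count; average
(fractional) ranks are computed for reporting but selection is purely by
score groups.

The **break-even** point is the grid point minimizing |P − R|, ties going
to the larger threshold, with no interpolation. On small synthetic worlds
this rule can be degenerate: if some threshold excludes every prediction,
that point has P = R = 0 and, being at larger t, wins the tie. This is the
documented contract of the grid rule, visible only when curves contain
exact ties — at realistic scale (hundreds of targets) P and R at high
thresholds are small but unequal, and the reported point is the genuine
crossing.

**Similarity curves**: for each selected (unpropagated — the similarity
itself already walks to the root) predicted term, the maximum similarity
over the true terms is taken; the *average* curve averages these over
predicted terms then over targets, the *best* curve takes each target's
maximum. Targets with nothing selected contribute 0 to both, mirroring the
(0, 0) convention above.

## The synthetic-data generator

`make_world()` emulates the *structure* of the prediction problem, not its
biology: a random single-namespace DAG grown by preferential attachment to
1–`branching` parents; three species whose proteomes (50 proteins each,
1–3 domain families per protein, 30 families) yield connected
co-occurrence networks; and targets planted in three strata matching the
architecture's regimes — easy (a dominant hit with e-value log-uniform in
10⁻¹⁰⁰..10⁻²⁰ plus decoys at 10⁻⁸..10⁻³, truth = the top subject's
annotations), mid (no sequence hits; domain detections at p = 85..100,
truth = the detected domains' annotations), hard (one weak species-tagged
hit at e = 0.1..10 to an unannotated subject, one sub-cutoff detection of
a deliberately unannotated family, truth = the annotations of that
family's radius-one network neighbors). Every proteome contains one
planted protein joining the hard-center family to two annotated neighbors,
so the hard stratum is feasible in every species' network. All randomness
flows from one explicit seed through locally scoped RNG state;
regeneration is byte-identical, and the emitted files use exactly the
dialects the parsers consume, doubling as format round-trip tests.

What the generator does **not** emulate: realistic GO topology (45 000
terms, heavy multiple parentage), realistic e-value/score joint
distributions, annotation biases (shallow, evidence-code-skewed truth),
inter-species network divergence, or contradictory evidence across levels.
Passing tests on these worlds therefore demonstrates correctness of the
machinery — filtering, scoring, aggregation, propagation, averaging — not
expected accuracy on real proteomes.

## Problem sizes and tolerances

Tests run the oracle-equivalence suites on 100 randomized worlds of up to
50 GO terms and 10 targets (curves on a 0.05-step threshold grid and
n = 1..10), and network oracles on random graphs of up to ~100 nodes —
sizes at which the brute-force oracles (explicit set arithmetic,
breadth-first search, exhaustive scans) are themselves trivially
verifiable. Formula endpoints are asserted exactly; floating-point curve
comparisons use `testthat`'s default numeric tolerance; monotonicity
checks allow 10⁻¹² of slack for accumulated rounding.

## Known limitations

* Scores are taken on trust from the hit tables; the package does not
  recompute alignments or calibrate e-values.
* The per-species network registry is in-memory; there is no lazy loading
  for hundreds of proteomes.
* Confidence intervals of the three levels are fixed design constants, not
  refit to data.
* The evaluation implements the tie-grouped top-n / threshold-sweep /
  break-even family only — not the later F-max/S-min assessment metrics.
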