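---
title: "In-context ontology and knowledge-graph extraction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-context ontology and knowledge-graph extraction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontokit)
```

## The model

`ontokit` treats an ontology as a computational approximation
{classes, relations, instances} rather than a description-logic artifact:
its backbone is a **taxonomy**, a rooted directed acyclic graph of
*isA* edges over lemma-normalized terms, with the universal concept "Thing"
as root. Taxonomy leaves — terms with no children — are the lowest-level
concepts and become knowledge-graph **instances**; non-leaf nodes are
**classes**; a leaf with several parents instantiates several classes.
Open-vocabulary subject–predicate–object triples between vocabulary terms
complete the knowledge graph. No upper-level ontology or OWL semantics are
involved; the package does not attempt axioms, reasoning, or re-parenting
of placed terms.

The extraction pipeline is zero-shot: a text-generation backend is prompted
per stage (sentence splitting, term/acronym extraction, category
generation/refinement, relationship queries, triple extraction), and the
pipeline's own filters — text verification, vocabulary membership, cycle
guarding, majority voting — carry the burden of correctness. Any engine
satisfying the `GenerationBackend` contract can be plugged in; the package
ships a scripted replay backend and a planted-world oracle so every stage
runs offline and deterministically.

## Stage design and the parameters that matter

**Vocabulary (stage 1).** Text is split into sentences by a deterministic,
abbreviation-aware rule splitter (an LLM-backed splitter can be substituted
via the `sentence_split` role; splitting can also be disabled entirely to
prompt with whole papers). Per sentence, proposed terms are kept only if
they occur in that sentence; matching is on normalized text (case-folded,
hyphens to spaces, whitespace collapsed) because hyphenation and casing
variants denote the same concept — a raw-substring mode is available.
`normalizeTerm()` lemmatizes: punctuation out, case folded, rule-based
English plural reduction with a small irregular map. It is deliberately
deterministic and idempotent; no statistical lemmatizer is involved, so
behaviour is reproducible across machines. Acronyms verified in the text
attach as *aliases* of their expansion's entry — they never become taxonomy
nodes — and the canonical surface form of an entry is the earliest one seen
in corpus order.

**Categories (stage 2).** The first taxonomy level cannot reliably be read
off single papers, so `SG` long-context samples are generated, each with an
independently shuffled paper order (long-context models are order
sensitive; shuffles are seeded and logged). Papers are truncated to a
character budget (default 4000 characters per paper) before prompting.
`SR` refinement samples are then majority-voted; candidates are ranked by
support so `curateCategories()` can truncate by explicit labels or top-k.
The refinement prompt receives the raw sample lists (not frequency
summaries); both are trivially derivable from the run artifacts.

**Self-consistency.** The vote threshold is *strict* majority (> m/2),
with `m` odd enforced — a threshold the aggregation needs but that the
method description leaves open; it is configurable. The calibration is
exact: an item retained per sample with probability p survives with
probability P(Bin(m, p) ≥ ⌈(m+1)/2⌉); at p = 0.7, m = 9 this is 0.9012,
and a spurious item at h = 0.3 survives with probability 0.0988. The test
suite verifies both by simulation against `pbinom`.

**Taxonomy (stage 3).** `K` full passes over the corpus; per paper, the
backend proposes (parent s, child t) pairs given the paper text, the
complete current taxonomy term inventory, and the paper vocabulary. Pairs
are contract-filtered (s must be a taxonomy node, t a vocabulary lemma) and
inserted as (child = t, parent = s) — top-down orientation, since the goal
is to place new terms under existing ones. The cycle guard rejects any edge
that would make the parent reachable downward from the child (self-pairs
included); a child already placed gains an *additional* parent, preserving
DAG structure rather than re-parenting. Within one paper's accepted set,
insertion order is canonicalized (parents already present first, then
lexicographic) so runs are reproducible; the underlying method leaves
intra-answer order unspecified. Terms unplaced after all passes are
reported by `unplacedTerms()`, never force-attached: attaching them to an
arbitrary category would fabricate structure the corpus does not support.
`K` is always honored; per-iteration growth statistics let users judge
convergence instead of an automatic stopping rule.

**KG (stages 4–5).** Instantiation is purely structural (leaves become
instances). Relation triples are vocabulary-filtered on both endpoints,
with acronym aliases resolved to their expansion's lemma; predicates are
open-vocabulary, normalized by case-folding and whitespace collapsing, and
only exact duplicates are removed — near-synonymous predicates are not
clustered. The merged export adds the isA backbone as edges labeled
`isA` with an `edge_type` attribute, additively when the sets are disjoint.

## The planted-world generator

The generator emulates the pipeline's intended setting: a corpus whose
papers each state a subset of isA assertions, define acronyms, and mention
terms — with a known ground truth behind it. Defaults mirror the package's
study conditions: depth 4, mean branching 3, ~60 terms, 10 papers, full
edge coverage. Pseudoword labels are drawn from a syllable pool and
constrained to be `normalizeTerm` fixpoints; a fraction of two-word terms
(default 25%) receive acronym aliases (skipping collisions with real term
keys). Assertable facts — all edges except the root's, since the builder
seeds categories itself — are dealt either randomly or **staged**: deepest
facts in the earliest papers, the adversarial order in which a single pass
can place only one level, so recovery genuinely requires the incremental
iterations. Noise is two-sided and per-sample: each true fact is dropped
with the omission rate, and members of a fixed per-paper pool of spurious
facts (random vocabulary pairs absent from the truth, fabricated strings
for term extraction) are injected with the hallucination rate.

What passing planted-world tests shows — and what it does not: the planted
corpus has clean sentence structure, unambiguous single-sense terms, and
facts stated in a fixed template. Real papers bring polysemy, anaphora,
facts stated only implicitly, and genuinely wrong statements; recovery of a
planted world therefore validates the *machinery* (verification, voting,
placement, metrics), not extraction quality on natural text, which depends
on the live generation model.

## Metric suite: concrete choices

The hierarchical metrics' published forms admit several readings; the
implemented defaults are: path node sets exclude the root and include the
endpoint; a ground-truth path whose endpoint is missing contributes 0 to
recall; precision is macro-averaged over matched paths only; hierarchical
accuracy counts a path as correct when its match shares at least one node
(equivalently, when the endpoint itself is recovered — which keeps
hierarchical accuracy close to term accuracy, as observed empirically when
both are reported side by side). All four choices, the micro-averaged
precision alternative, and a one-sided ancestor-error mode are exposed in
`metricOptions()` so alternative readings remain testable. Path-match
tie-breaking is total: maximal shared count, then shortest path, then
lexicographic node sequence. In DAGs the lowest common ancestor is a *set*
(common ancestors with no common-ancestor proper descendant, ancestor sets
reflexive); non-empty intersection between truth and reconstruction is the
preservation criterion. The whole suite is verified against a brute-force
path-enumeration oracle on random DAG pairs to 1e-9.

## Numerical and degenerate-input choices

- Seeds: a single user seed fans out into per-stage, per-paper, per-sample
  substreams via a 31-bit polynomial string hash, so stages are
  independently reproducible and all derived seeds stay below 2^31.
- Degenerate inputs: an empty corpus errors; a root-only taxonomy has the
  root as its only "leaf"; a reconstruction with no matched paths reports
  hP = 0 alongside a zero matched-path count rather than NaN; identity
  comparison yields 1.0 everywhere and AEC = 0.
- Duplicate edges are idempotent no-ops; serialization orders nodes and
  edges lexicographically so equal objects produce byte-identical files.
- Problem sizes in the shipped tests and acceptance script (≤ 12-node DAGs
  for oracle comparisons, 60-term planted worlds, 2000-trial calibrations)
  were chosen as the smallest sizes at which every property is
  non-trivially exercised.

## Known limitations

Verification is substring-based and lemma-exact: it cannot catch a real
term extracted from the wrong context, and synonym pairs that do not share
a lemma stay separate concepts (no embedding-based matching). The
lemmatizer handles English plurals, not derivational morphology. The
category stage's 131→12-style curation is explicit, not automatic
clustering. A live generation engine is attached by subclassing
`GenerationBackend` and providing a `generate` method (the natural fit is
an OpenAI-compatible chat endpoint returning line-delimited structured
answers); the package itself ships only the offline backends, which is what
keeps the full pipeline and its tests deterministic.
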