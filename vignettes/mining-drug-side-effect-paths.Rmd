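---
title: "Mining and ranking drug–protein–side effect paths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and ranking drug–protein–side effect paths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathseeker)
```

## The problem and the model

Adverse drug events are catalogued extensively (SIDER, FDA labels), but the
mechanistic chain from drug to side effect is usually unknown. `pathseeker`
treats the biomedical literature as a source of fragmentary assertions —
"sorafenib inhibits p38", "gastrin is associated with dyspepsia" — and
composes them, Swanson-ABC style, into candidate mechanistic paths
drug → protein^k → side effect with k ∈ {1, 2, 3} bridging proteins.
Proteins are the bridge type because most drug action and most
pathophysiology is protein-mediated.

The pipeline makes three modelling commitments worth stating explicitly:

* **Sentence-level, verb-mediated assertions.** A relation exists only when
  two typed entity mentions co-occur in one sentence with a biomedical verb
  between them. No coreference, no cross-sentence inference, no event
  structure beyond a binary directed link.
* **Dictionary NER.** Mentions are exact 1/2/3-gram matches against
  synonym-expanded lexicons. This trades recall (unseen surface forms are
  missed) for precision and auditability — every mention is traceable to a
  dictionary row.
* **Composition is hypothesis generation, not inference.** Two true edges
  do not make a true path; the ranking exists precisely because the
  composed path set is noisy.

## Extraction rules

For an ordered pair of non-overlapping mentions (m1 left of m2) in a tagged
sentence, each bio-verb token strictly between the spans yields a candidate
triple when the number of tokens strictly between the spans is at most the
window (default 6). "Strictly between" is a deliberate reading: the bound
is on the inter-entity gap, not on a window containing the entities, which
is the most permissive interpretation consistent with requiring the pair
and its verb to fall inside a window. Each qualifying verb yields its own
triple, so a pair linked by "inhibits and blocks" carries both lemmas.

Voice decides direction: a be/auxiliary form within two tokens before a
past-participle verb marks the passive, and the directed edge is reversed
("A is activated by B" ⇒ B → A); everything else is active, m1 → m2.
Negation is a cue word (`not`, `no`, `never`, `hardly`, `scarcely`,
`n't`, `neither`, `nor`, `without`) within three tokens before the verb.
Negated triples are *flagged and retained* in the triple stream but
excluded from graph construction by default (`keep_negated = FALSE`):
dropping a negated assertion is the conservative choice for hypothesis
generation, and keeping the flag lets users study them separately.

Only drug→protein, protein→protein and protein→side-effect triples are
kept; with directionality this makes drugs sources only, so drug–drug
edges and cycles through drugs are impossible by construction.

The POS tagging these rules need is coarse (bio-verbs, auxiliaries, the
rest), so the default tagger is a deterministic lexicon + suffix-rule
lemmatizer that runs offline; an adapter slot (`ps_tagger("external", ...)`)
accepts any statistical tagger that returns parallel lemma/POS vectors.
When only token patterns are available, voice and negation fire on those
patterns; a dependency parse (auxpass/neg arcs) would subsume them and can
be plugged in through the same adapter.

## Graph, paths, significance

Parallel triples merge into one edge holding the verb set, the union of
polarities and a support count. Support counts contributing triples (two
verbs in one sentence contribute two), so edge supports always sum to the
number of type-valid non-negated triples — a cheap integrity invariant the
tests exploit.

Path enumeration is exhaustive DFS over simple paths with the exact type
signature drug, protein × k, side effect; proteins may not repeat within a
path. Protein–protein edges are traversed only in their stated direction —
the voice rule exists to orient them, so no symmetric closure is applied.
Paths found at different depths are all kept; no de-duplication across k.
Output order is lexicographic, making enumeration invariant to triple
input order.

Two post-hoc screens follow. Paths ending in nodes whose name contains an
intended-effect term (default `tumor`, `tumour`, `cancer`, `carcinoma`,
`neoplasm`) describe therapy, not toxicity, and are removed. And a path is
significant only if its verbs "do something": by default every edge except
the terminal protein→side-effect edge must carry at least one verb of
INCREASE or DECREASE polarity. The terminal edge may be purely associative
because side-effect assertions in abstracts are overwhelmingly
associational ("gastrin is associated with dyspepsia"). The predicate is
replaceable (`significant =`) because no canonical verb list exists for
"represents a change".

## The ranking

Each consecutive pair (v_i, v_j) of a path terminating in side effect SE
is weighted

EntityPairWeight = α·COALS(v_i, v_j) + β·LocalFreq(v_i, v_j, SE)/MaxLocalFreq(SE) + γ·WuPalmer(v_i, v_j)

and the path score is the arithmetic mean of its pair weights (a path with
n nodes has n − 1 pairs, so depth-1 paths average 2 weights and depth-3
paths average 4). Defaults (α, β, γ) = (0.3, 0.4, 0.3); weights must be
non-negative and are renormalized to sum to 1 with a warning otherwise.
The three components capture three independent notions of relatedness:

* **COALS** — distributional similarity from the mined corpus itself.
  Co-occurrence counts use a ramped window (weight `window + 1 − d` at
  distance `d`, default window 4); each cell is replaced by the pairwise
  correlation of its row/column events; negatives are zeroed and positives
  square-rooted; similarity is the Pearson correlation of two such
  vectors clamped at 0. Entity mentions are collapsed to their canonical id
  as a single token before counting, so multi-word entities have
  well-defined vectors and synonym variants pool their evidence. No SVD is
  applied: on desk-scale corpora the truncated count vectors are exact,
  deterministic, and cheap; column truncation (`dim`) is available for
  large vocabularies and keeps the most frequent terms, ties alphabetical.
* **LocalFreq** — how often the pair occurs among the candidate paths of
  this particular side effect, normalized by the most frequent pair for
  that side effect. This is deliberately local: a pair that dominates one
  side effect's path population is informative for that side effect
  regardless of its global frequency. A side effect with no counted pairs
  defines the term as 0 rather than 0/0.
* **Wu–Palmer** — 2·depth(lcs)/(depth(a)+depth(b)) with root depth 1 on a
  user-supplied parent-child hierarchy (a generic stand-in for a licensed
  medical ontology). Wu–Palmer was chosen for being bounded, parameter-free
  and computable on any rooted DAG; a rescaled path-length variant
  (`method = "leacock"`) is provided for sensitivity checks. Unmapped ids
  score 0.

Baselines (`baseline_scores`): co-occurrence (mean over path edges of edge
support / maximum edge support — the one reading of an "average
co-occurrence degree" baseline that needs no extra graph statistic), COALS
only, hierarchy only. The latter two are bit-identical to the proposed
scorer with weights (1,0,0) and (0,0,1), which the tests assert.

Ranking is a stable descending sort with lexicographic tie-breaking by
(drug, proteins, side effect), so equal-scored rankings are reproducible.
Evaluation is precision-at-k over plausibility labels; the shipped
`cancer_top20()` example (20 ranked paths, three-level labels) yields
P@{5,10,15,20} = (0.60, 0.60, 0.40, 0.30) with TYPE1 as truth and
(0.80, 0.80, 0.733, 0.65) with TYPE1∪TYPE2, with 13/20 = 65% plausible —
numbers recomputed, not stored, by `scripts/acceptance.R`.

## The synthetic-data generator

`generate_corpus()` plants n chains of known depth, realizes each edge as
one or two template sentences (active, padded-active, passive,
padded-passive, with single- and multi-token, hyphenated entity surfaces),
distributes them over MEDLINE-XML abstracts with filler sentences, and
emits the matching lexicons, verb list, hierarchy and exact ground truth
(mentions with token spans, triples, paths). Distractors violate exactly
one rule each: a negated pair, a pair 7 tokens apart, a pair linked by a
non-bio-verb, a complete chain ending in a cancer-named node, and a chain
whose drug–protein edge is only associative. A correct pipeline therefore
recovers *exactly* the planted paths — precision = recall = 1 — and any
rule regression surfaces as a specific extra or missing path.

What the generator does not emulate: real PubMed syntax (subordinate
clauses, coordination, anaphora), ambiguous or nested entity names shared
across types, reporting bias, and the hub structure of real interaction
graphs. Passing the synthetic suite shows the rules are implemented as
specified, not that the rules suffice for real text — on real abstracts
dictionary NER misses surface variants and the sentence-level verb rule
both misses and over-generates relations.

Determinism: one integer seed drives depth assignment, template and verb
choice, and label assignment; regeneration is byte-identical and the
caller's RNG state is saved and restored.

## Numerical and degenerate-input choices

* Correlation cells with a zero denominator (empty row or column) are 0,
  as are similarities involving an all-zero vector; two bitwise-identical
  nonzero vectors score 1 even when constant (Pearson is undefined there,
  and identity is the stronger fact).
* `ranking_weights` rejects negative values, renormalizes non-unit sums
  with a warning, and rejects the all-zero vector.
* Lexicon synonym collisions within a type keep the first mapping and
  warn; duplicate canonical ids are an error. Same-span cross-type
  collisions resolve by a configurable priority, default
  PROTEIN > DRUG > SIDE_EFFECT. Matching is case-insensitive by default
  (drug names are routinely case-variant) with surfaces preserved.
* Sentence segmentation falls back to one sentence when no boundary is
  found; an abbreviation list (`e.g.`, `et al.`, ...) suppresses false
  splits. Titles are mined as sentence 0 by default
  (`include_title = FALSE` restricts to abstracts).
* Enumeration depth outside 1..3 and precision cutoffs outside the ranking
  length are argument errors, not silent clamps.

## Problem sizes

The test suite and acceptance script run on generated corpora of 10–100
chains (roughly 20–60 abstracts, 10²–10³ tokens of vocabulary), sizes at
which the exhaustive oracles — brute-force rule checking, igraph
simple-path enumeration, cell-by-cell COALS correlation, exhaustive LCS
search — are exact and fast, so implementation and oracle can be compared
in full rather than sampled. The implementation itself is vectorized only
where it matters (COALS normalization); clarity was preferred over
throughput elsewhere, and a corpus of millions of abstracts would need a
sparse co-occurrence accumulator and an indexed mention store before
anything else.

## Known limitations

* Relation recall is bounded by the dictionary and by single-sentence,
  verb-between-entities syntax; nominalizations ("inhibition of p38 by
  sorafenib") are missed.
* Token-pattern voice/negation detection approximates a dependency parse;
  garden-path constructions can flip direction or miss negation.
* The composed-path semantics are heuristic: edge polarities are carried
  but not composed (an inhibitor of an inhibitor is not resolved to a net
  activation).
* COALS vectors from small corpora are noisy; the α weight should be
  lowered when the mined corpus is tiny.
* The hierarchy is only as good as its curation; with a flat hierarchy the
  γ component degenerates to near-constant values.
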