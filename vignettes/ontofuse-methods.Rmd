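---
title: "Aligning and fusing cell ontologies with ontofuse"
author: "ontofuse authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning and fusing cell ontologies with ontofuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontofuse)
```

## The problem

Cell-type ontologies that back single-cell atlas curation are built by
different groups, with different naming conventions and different, partially
overlapping developmental hierarchies. Combining two of them by hand is slow
and irreproducible. `ontofuse` fuses two ontologies of the same knowledge
domain fully automatically: it aligns classes that denote the same concept,
unifies them, and appends everything that is genuinely new.

An ontology is represented as an `OntologyGraph`: classes with a unique id, a
display label and optional synonyms, plus directed parent-to-child subclass
edges. Well-formed ontologies are DAGs, but every operation tolerates the
ill-formed inputs that occur in practice (duplicate relations, disconnected
branches, even cycles): readers clean what can be cleaned and the graph
algorithms terminate regardless.

## The alignment model

Alignment combines two complementary sources of evidence.

**Name mapping.** For every class $i$ of ontology A and $j$ of B the scaled
Levenshtein similarity of the (preconditioned) labels is

$$S^{AB}(i,j) \;=\; 1 - \frac{\mathrm{lev}(L_i^A, L_j^B)}
{\max(|L_i^A|, |L_j^B|)} \in [0,1],$$

optionally maximised over the two synonym lists (each including the principal
label), which can only raise an entry. The full $a \times b$ matrix is
materialised: the local-name confirmation step later averages arbitrary
entries, so no pruning is possible. A pair is a *name match* when
$S^{AB}(i,j) > \theta_N$ (default 0.85, strict inequality).

**Structure mapping.** Classes left without a name assignment — the
*generator nodes* — are compared through the shape of their neighbourhoods.
Around each generator a window-W subgraph is extracted: all classes reachable
within $W$ edges traversed either all-upstream or all-downstream (mixed
paths are excluded deliberately; at $W = 1$ the window holds parents and
children but not siblings). The node order is deterministic — generator
first, then breadth-first distance, ties by id — so the derived binary
adjacency matrices are reproducible. Five metrics score a pair of subgraphs:

* **cosine / euclidean / pearson** (vectorial row convolution): every row of
  one adjacency matrix is slid over every row of the other at all
  $nc = |a_{Wi} - b_{Wj}| + 1$ offsets; each slide is scored with the vector
  metric and the best slide kept. Per-row maxima are averaged, in both
  directions, and the two means averaged again — this reduction is not fixed
  by the construction itself; the symmetric mean was chosen because it makes
  the score symmetric, penalises size mismatch, and gives exactly 1 for
  identical subgraphs.
* **constraint**: counts name matches between the two member sets and weighs
  each matched node $k$ by its proximity to the generator,
  $c_k = W + 1 - s_k$ with $s_k$ the shortest-path distance. The accumulated
  sum is normalised by the maximum attainable value
  $(\min(a_{Wi}, b_{Wj}) - 1)\,W$ and clamped to $[0,1]$.
* **blondel**: the iterative mutually-reinforcing vertex similarity
  $T_{k+1} = (B T_k A^t + B^t T_k A)/\lVert\cdot\rVert_F$ from the all-ones
  start, read out at the generator pair after convergence at an even step
  ($\lVert T_k - T_{k-2}\rVert_F < 10^{-6}$, cap 100 iterations).

**The cascade.** For each class $i$ of A the best name candidate $j$ is
selected from its row of $S^{AB}$ (ties break to the smallest B id). If
$S^{AB}(i,j) > \theta_N$, it is a name match. Otherwise the structure score
*of that same candidate* is consulted: the pair becomes a *structure match*
when both sides are generators, $T^{AB}(i,j) \ge \theta_T$, and the local
name comparison confirms it — the mean over members of $A_W(i)$ of their best
name score against $B_W(j)$ must strictly exceed $\theta_{LN}$ (default 0.7).
Everything else is non-matched. Matching is greedy and one-directional:
several A classes may legitimately share one B partner, as happens in real
cell ontologies where one atlas is coarser than the other.

## Merging

Matched B classes are unified with their A partners; their labels and
synonyms become synonyms of the A class. Unmatched B classes are appended
under fresh, deterministic, zero-padded ids, and every B relation is
re-expressed in merged ids and added, de-duplicating while preserving
first-seen order. When several A classes share one B partner the B class's
relations attach to the single best-scoring partner — replicating them onto
all partners would invent relations no input asserts. The conservation law
$|merged| = |A| + |B| - |\text{distinct matched B}|$ holds on every input
and is property-tested.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `W` | 4 | window radius (edges) of extracted subgraphs |
| `thetaN` | 0.85 | name-match threshold on scaled Levenshtein similarity |
| `thetaT` | 0.7 | structure-score threshold (no canonical value exists; set equal to `thetaLN`, user-overridable) |
| `thetaLN` | 0.7 | local-name confirmation threshold |
| `metric` | cosine | structure metric (five alternatives above) |
| `useSynonyms` | TRUE | maximise name similarity over synonym lists |
| `threads` | 1 | worker pool for the structure matrix; results are identical to serial |

All thresholds live on the common $[0,1]$ similarity scale. That drove two
numerical conversions: Euclidean distance between binary windows of length
$L$ is divided by its maximum $\sqrt{L}$ and subtracted from 1; Pearson
correlation is clamped at 0 (anti-correlated shapes carry no positive
evidence), with zero-variance windows scoring 1 if identical and 0 otherwise.
Cosine against a zero vector is 0 unless both windows are all-zero (then 1:
two childless rows are structurally indistinguishable). These degenerate
conventions keep self-similarity exactly 1 — at the price that very sparse
subgraphs can look alike, which is precisely why structure matches must also
pass the local-name confirmation.

## Label preconditioning

`normalizeLabel()` lowercases, replaces strip characters by a space
("yolk-sac" becomes "yolk sac", never "yolksac", because gluing words would
corrupt the Levenshtein similarity), removes stop words as whole tokens only
(removing "cell" must not damage "cellular"), and collapses whitespace; it is
idempotent. The automatic ontology editor applies scripted repairs before
alignment: select/deselect by case-insensitive substring (matched against
labels and synonyms), connect, merge two classes (the kept class inherits
edges and synonyms; the absorbed label becomes a synonym), and normalise all
labels. A label that would normalise to the empty string is kept unchanged
with a warning rather than silently destroying the class's identity.

## What the synthetic generator emulates

`generateBaseOntology()` grows a rooted breadth-first tree with
Poisson-distributed child counts plus a fraction of extra strictly-downward
edges, giving about 1.16 relations per class — the shape of mid-sized curated
cell ontologies (roughly 800 classes to 930 relations). Labels are unique
2–4 word phrases over a cell-biology vocabulary; ~30% of classes carry 1–2
synonyms. `deriveVariant()` then emulates how two ontologies of the same
domain diverge: per-character edits of word-internal letters (orthographic
variation: plural endings, hyphenation, typos), label/synonym swaps, dropped
classes with parents rewired to children, and grafted novel subtrees. The
ground truth maps every surviving base class to itself.

The study condition used throughout (`studyPair()`): 300 classes, edit rate
0.13 — chosen once so that the expected scaled similarity between a label
and its edited copy is about 0.9, given ~16 editable word-internal letters in
a ~21-character label — and six grafted subtrees (~10% novel classes). The
test suite runs 20 such seeds; the acceptance script 10.

What the generator does **not** emulate: real-world systematic vocabulary
differences (one ontology saying "erythroid progenitor" where the other says
"red blood cell precursor"), cross-species duplication, and annotation
errors that are not label-local. Passing the synthetic recovery tests
therefore shows that the cascade works when divergence is orthographic and
structural — it does not certify performance on ontologies whose labels
differ semantically, where only the structure and synonym machinery can
help and a manually built reference is needed to measure anything.

## Design choices made where the construction was open

* **Structure candidate**: the structure score consulted for an unmatched
  class is that of its best *name* candidate. The alternative — taking the
  best *structure* candidate — degenerates in tree-shaped ontologies, where
  many windowed subgraphs are exactly isomorphic (every deep leaf looks the
  same), producing massive argmax ties that no deterministic tie-break can
  resolve meaningfully.
* **Shortest paths** for the constraint metric are computed within the
  extracted subgraph, in the sweep orientation; whether a path may detour
  through the full graph is unobservable at the window boundary and the
  windowed choice keeps the metric local.
* **Select/deselect** match synonyms as well as labels; matching labels only
  would make the editor blind to the synonym lists it is meant to repair.
* **Inequalities** are strict for $\theta_N$ and $\theta_{LN}$ and non-strict
  for $\theta_T$, exactly as the thresholds are defined.
* **Parallelism** is restricted to the embarrassingly parallel structure
  matrix; columns are computed by forked workers and reassembled in order,
  so results are bit-identical to serial execution.

## Known limitations

* Greedy per-class matching performs no global one-to-one assignment; a
  systematically coarser B ontology absorbs many A classes by design.
* The vectorial metrics see only window-local adjacency rows: a chain
  compared with a single childless node can score 1 under cosine (both rows
  all-zero after the slide). The local-name confirmation exists to keep such
  coincidences out of the final alignment.
* No OWL reasoning: only named-class subclass axioms are read; restrictions
  and anonymous superclasses are counted and skipped.
* Evaluation counts id pairs; how a manual reference treats many-to-one
  matches is a convention the user must fix when building the reference.

## Problem sizes used in the shipped checks

The packaged fixture pair has 60 + 72 classes; the simulation study uses
300-class bases over 20 seeds (tests) or 10 seeds (acceptance script);
property tests run on random DAGs of up to 20 nodes against brute-force
oracles (path enumeration, textbook DP edit distance, Kronecker-form Blondel
iteration). These sizes exercise every code path — including multi-parent
classes, drops and grafts — while keeping a full run in the low minutes on
one CPU.
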