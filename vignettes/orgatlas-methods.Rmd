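---
title: "orgatlas: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{orgatlas: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
models and rules, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
numerical and design choices that were genuinely open.

## The inference chain

`orgatlas` reconstructs how plastid- and mitochondrion-associated protein
families were recruited across a phylogeny. The chain is: classify
orthogroups (protein families from an upstream clustering run) into green /
plastid / mitochondrial sets, annotate them by majority vote over member KO
ids, root the species tree, reconstruct ancestral presence/absence of each
family, call gains at named ancestors, and screen for RNA-metabolism domain
enrichment and N-terminal charge. Clustering itself, homology search and
database retrieval are out of scope: membership tables, domain-hit tables and
the tree are inputs.

## Classification rules

All rules count **species**, never proteins: a species contributing forty
paralogs to a family counts once. The rules and their boundary behavior:

* **GOG**: at least `min_green_species` (default 3) distinct Chloroplastida
  species *and* strictly fewer than `max_nongreen_species` (default 3)
  non-green species. Both bounds are read literally, so (3 green, 0) is in,
  (2, 0) is out, and (5, 3) is out.
* **Core GOG**: strictly more than `core_fraction` (default 0.90) of the
  green species *present in the analyzed matrix*. The denominator choice
  matters when matrices are subset; it is the matrix, not some external
  species list, and a family at exactly 90 % is not core.
* **POG / MOG**: at least one member protein appears in an experimentally
  verified plastid / mitochondrial proteome of a reference species. The two
  sets may overlap (dual-targeting candidates); provenance records which
  protein triggered membership. Experimental ids that match no family are
  reported, not fatal — reference proteomes routinely contain proteins the
  clustering dropped.

## Majority-rule annotation

Member proteins vote with their KO id; proteins without an annotation
abstain rather than voting a sentinel value (a literal "N/A" category would
otherwise win many votes). Ties are broken by the lexicographically smallest
KO id — the alternative (first-seen) would make results depend on input
order. Votes are per protein, not per species: annotation transfer happens at
the protein level. Raw BRITE categories pass through an editable override
table because some BRITE labels ("Enzymes", "Exosome") are too generic to be
informative; the shipped default is minimal and meant to be replaced by the
user's curation.

## MAD rooting

For a candidate root position $\rho$ on a branch, each tip pair $(b, c)$
contributes a relative deviation $|2\,d(a,b)/d(b,c) - 1|$, where $a$ is the
pair's ancestor induced by the candidate root; the candidate's score is the
root mean square over all pairs, and the root is the global minimizer. Pairs
on the same side of the branch have a $\rho$-free contribution; straddling
pairs make the squared score a quadratic in $\rho$, so the per-branch minimum
is solved in closed form and clamped to $[0,1]$. A dense-grid scanner (kept
in the test suite only) verifies the closed form to $10^{-6}$. On a perfectly
clocklike tree every deviation at the true root is zero, so recovering a
simulated clock root with score $< 10^{-9}$ is an exact expectation, not a
statistical one. Ties are broken by smallest (branch index, $\rho$).
Zero-length branches remain candidates evaluated at $\rho = 0$. Rooting at an
arbitrary point on an edge is rebuilt by traversal (no in-place surgery),
which preserves all pairwise tip distances to $10^{-9}$ by construction.

## Ancestral state reconstruction

Presence/absence of a family is a binary character evolving under the
equal-rates (ER) binary Mk model: one rate $q$ per unit branch length for
both gain and loss, transition probabilities
$P_{\text{stay}}(t) = \tfrac12(1 + e^{-2qt})$, stationary root prior
$(\tfrac12, \tfrac12)$. The likelihood is computed by Felsenstein pruning
with per-node rescaling; marginal posteriors combine the pruning partials
with an outside recursion, which is algebraically identical to re-rooting at
each node. An exhaustive enumeration oracle (all joint internal-state
assignments) pins both quantities to $10^{-10}$ on small trees in the tests.

Choices that were open:

* **Rate fitting**: per-family maximum likelihood on a log scale within
  `rate_bounds` (default $[10^{-6}, 100]$); a shared global rate is available
  via `rate_mode = "global"` for sparse matrices where per-family fits are
  noisy.
* **Constant characters**: the ML rate degenerates ($q \to 0$), so
  all-present / all-absent families get posteriors pinned to the observed
  state, $\hat q$ recorded as 0 with a `degenerate` flag — the limit
  behavior, without an optimizer failure.
* **Tips missing from the matrix** are scored absent (presence is defined by
  detection); matrix species missing from the tree are dropped with a
  warning.
* **Polytomies** are resolved into zero-length dichotomies deterministically
  given the input representation, with a warning; zero-length branches leave
  the likelihood unchanged.

## Gain calling

A family is newly recruited at ancestor $A$ when $P_A(\text{present}) >
\tau$ (strict; default $\tau = 0.75$, sweep 0.65/0.75/0.85) *and* it is
absent in $A$'s parent. "Absent" admits two readings and both are
implemented: the default **confident** reading requires
$P_{\text{parent}} < 1 - \tau$; the **lax** reading requires
$P_{\text{parent}} < \tau$. The default is the conservative one — at
$\tau = 0.75$ it demands positive evidence of absence rather than mere lack
of evidence of presence — and the rule used is serialized with every result.
The sweep is monotone by construction: gains at 0.85 are a subset of gains
at 0.75, which are a subset of gains at 0.65. The root has no preceding
ancestor, so families confidently present there are reported separately as
present-at-root, never as gains. Loss calling (the mirrored predicate) is
deliberately not part of the default outputs.

## Screens

A member protein is domain-positive on $\ge 1$ hit to any screen accession
(PF01535, PF12854, PF13041, PF13812 for PPR; PF02536 for mTERF);
score thresholds belong to the upstream search. A family is flagged when the
positive fraction exceeds `domain_fraction_threshold` (default 0.60)
strictly; because "more than 60 %" and "at least 60 %" both circulate as
phrasings of this rule, the comparator is a flag (`"gt"` default, `"ge"`
available) and the two differ only at exactly 0.60. The per-species domain
presence matrix deliberately differs from family presence: a species can
harbor the family while none of its members carries the domain.

N-terminal net charge is $(\#K + \#R) - (\#D + \#E)$ over the first
`nterm_window` = 20 residues (whole sequence when shorter), histidine
neutral, termini ignored, initiator methionine included. This is the
simplest fixed-pH-agnostic convention; it is a summary statistic for
dual-targeting candidates, not a targeting predictor.

The tblout reader implements a fixed whitespace-delimited dialect with the
target name in field 1 and the query accession in field 5, skipping `#`
comments; Pfam version suffixes are stripped on ingest so `PF01535.20`
equals `PF01535`.

## The synthetic world

`simulate_dataset()` generates the complete input set with known truth. What
it emulates, and the defaults chosen once:

* **Tree**: six lineages (4 outgroup eukaryotes, 3 rhodophytes, 2
  glaucophytes, 6 chlorophytes, 4 zygnematophyceae, 8 embryophytes; 27
  species) on a pectinate backbone with evenly spaced split depths and a
  seeded Yule clock subtree per lineage (crown depth = half the stem
  attachment depth). This gives monophyletic lineages, well-defined named
  ancestors (Chloroplastida, ZE, Archaeplastida, per-lineage crowns) and a
  green clade large enough for the GOG rules to have non-trivial boundaries,
  at a size where the full pipeline runs in seconds.
* **Characters**: 300 families, gain = loss = 0.2 per unit branch length on
  a depth-1 tree, root presence probability 0.5. Transitions use the exact
  exponential two-state probabilities — the same process family the ER-Mk
  reconstruction assumes — so parameter-recovery tests are meaningful. The
  larger validation world (64 tips, depth 5, 500 families) puts roughly one
  expected gain and one expected loss on a root-to-tip path, making
  characters informative but not saturated.
* **Copy numbers**: $1 + \text{Geom}(p = 0.5)$ given presence — a
  heavy-ish tail resembling real paralog counts; downstream logic only uses
  presence, so the exact distribution is immaterial.
* **Annotations**: 60 % of families carry a planted KO; each member protein
  is missing its label with probability 0.3 and votes a decoy with
  probability 0.1, exercising the abstention and plurality logic.
* **Sequences**: random amino acids with two controlled N-terminal classes —
  charge 0 (neutral first 20 residues) and charge +2 (two lysines planted) —
  assigned to dual/RNA families, so the charge screen has exact truth.
  Sequence evolution is *not* simulated.
* **Experimental proteomes**: every designated POG/MOG contributes at least
  one protein from a reference species (two embryophytes), so the classifier
  must recover the designated sets exactly — a set-equality test, not a
  statistical one.

What a green test does **not** establish: robustness to orthology-inference
errors, to annotation biases correlated with lineage, to non-clocklike rate
variation across families' detectability, or to the scale of hundreds of
proteomes. The generator's world is the model's home turf by design; tests
against it validate the inference machinery, not the biology.

## Numerical conventions

Integer tables round-trip bit-exactly through TSV; probabilities are written
with 15 significant digits and round-trip to $10^{-12}$. All output row
orders are lexicographic (radix/C collation, locale-independent), every
threshold and seed is serialized into `manifest.json`, and nothing is
timestamped — two runs with the same config are byte-identical, which the
tests assert with raw file comparison. Likelihood optimization tolerance is
$10^{-9}$ on the log scale; enumeration comparisons use $10^{-10}$, MAD grid
comparisons $10^{-6}$ (the grid, not the closed form, limits agreement).

## Known limitations

* The ER model is symmetric; asymmetric gain/loss rates and rate variation
  across branches are not modeled (and gains near the root are accordingly
  conservative).
* MAD rooting is quadratic in tips per branch; fine to a few hundred tips,
  not tuned beyond that.
* The annotation stage ships only a minimal BRITE-override table; real
  curation is the user's.
* The N-terminal charge is a screen, not a prediction of targeting.
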