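---
title: "Proteochemometric screening of nuclear receptor ligands: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteochemometric screening of nuclear receptor ligands: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The model

A (compound, receptor) pair is represented by a 217-dimensional feature
vector: a 30-dimensional protein block followed by a 187-dimensional ligand
block. A probability random forest maps this vector to an activity score in
[0, 1], interpreted as the probability that the compound binds the receptor
with EC50 at or below 1 µM. Scores are reported at three levels — high
(> 0.7), medium (0.5–0.7), low (≤ 0.5) — and screening supports a normal
(> 0.5) and a strict (> 0.7) positive cutoff.

The point of carrying a protein block at all is transfer: a receptor is
described only by its similarity to a fixed reference panel, so the fitted
model scores receptors that contributed no bioactivity data. One model
covers the family.

### Protein block

Each entry is the local-alignment similarity of the query receptor to one
panel member, normalized by the geometric mean of the two self-alignment
scores:

\[ p_i = \frac{SW(q, r_i)}{\sqrt{SW(q,q)\,SW(r_i,r_i)}} \in [0, 1]. \]

This normalization is symmetric, equals 1 exactly at identity (for a
substitution matrix whose diagonal dominates, as BLOSUM62's does), and 0
when no residue pair scores positively. An alternative query-self
normalization is selectable in `alignment_params()`. Alignment defaults are
BLOSUM62 with gap open 10 and gap extend 0.5 — the common protein
local-alignment defaults — under the convention that a gap of length $L$
costs $\mathrm{open} + L\cdot\mathrm{extend}$. Panel row order defines the
descriptor axes and is serialized with every model; ambiguity codes (B, Z,
X) are rejected by default and accepted only behind an explicit flag,
because a silently low-scoring residue would quietly distort a panel axis.

### Ligand block

The 187 ligand descriptors are two-dimensional (constitutional,
topological, and electrotopological) descriptors computed on the
implicit-hydrogen heavy-atom graph, plus eight Open Babel bulk properties
(MW, logP, TPSA, molar refractivity, H-bond donor/acceptor counts,
fluorine count). The registry covers atom/bond/ring/functional-group
counts, connectivity (chi, plain and valence) and shape (kappa) indices,
E-state summaries, distance-based indices (Wiener, Harary, Balaban J,
eccentric connectivity, walk counts), and Moreau–Broto / Moran / Geary
autocorrelations of atomic mass, electronegativity, polarizability and van
der Waals volume at topological lags 1–8. Three-dimensional descriptors
are deliberately absent, and so are hashed fingerprints (ECFP/MACCS):
descriptor inflation is not the goal, a compact physicochemical profile
is.

The exact descriptor list is a *manifest* — a plain-text file, one name per
line, frozen in C-locale sorted order and serialized with every trained
model — so a different 187-descriptor list can be substituted verbatim
without touching code. Descriptors that are undefined for a molecule
(autocorrelations beyond its diameter, Moran/Geary at zero property
variance) are imputed as 0 and counted in a message; a random forest is
insensitive to the particular sentinel. No scaling happens in this module;
standardization is a model-side concern.

### Labels, assembly, splitting

EC50 values are dichotomized at 1 µM, boundary inclusive (active iff
EC50 ≤ 1 µM); the boundary choice is configurable. The CSV reader converts
nM/µM/M units. Assembly joins each record's target to its protein block and
its compound to its ligand block, excludes unresolvable ids with a report
(never silently), and orders columns protein-then-ligand. Splits are
seeded and stratified by label within target by default, so every receptor
keeps both classes on both sides; record-level splitting is the default
(compound-level splitting is a stricter regime users can emulate by
splitting compounds upstream).

### Augmentation

Training data for receptor panels are heavily imbalanced. Each target's
classes are resampled with replacement to `n_per_target / 2` each, so every
target contributes the same, class-balanced row count. Originals pass
through untouched; only the resampled duplicates receive i.i.d. Gaussian
noise with scale σ = 0.1 *per standardized feature*, mapped back to the
feature scale. Standardizing first makes one σ meaningful across features
whose scales differ by orders of magnitude (a molecular weight versus a
ring count); the statistics are fitted on the pre-augmentation training
set and stored in the model (the MLP reapplies them at prediction time;
the forest consumes raw features, the noise having been injected in
standardized space). Constant features receive no noise. The operating
range for `n_per_target` is 1000–5000 in steps of 500; 5000 with a 0.85
train fraction is the best setting and the package default.

### Learners

The default classifier is a 500-tree probability random forest
(`ranger`, mtry = ⌊√217⌋ = 14, unlimited depth, single-threaded and seeded
for bit-reproducibility). The score is the fraction-of-trees probability
estimate. A feed-forward MLP baseline (5 × 300 ReLU hidden units, dropout
0.5, sigmoid output, Adam, early stopping on a 10% carve-out, at most 200
epochs) is implemented in plain matrix arithmetic and kept for comparison;
tree ensembles are the better fit for tabular physicochemical features and
are what ships.

## Evaluation protocol

ROC-AUC is computed exactly as the Mann–Whitney concordance probability
with ties counting one half (mid-ranks). Confusion metrics use the strict
positive rule `score > cutoff`, consistent with the tri-level wording;
undefined precision (no positive calls) is reported as 0 with a
`degenerate` flag rather than NaN. Best-balanced-accuracy cutoff selection
scans the exhaustive candidate set — midpoints between consecutive
distinct scores plus 0 and 1 — and breaks ties toward the smallest
qualifying cutoff. The evaluation grid refits one model per (train
fraction, oversampling) cell on a fresh seeded split; the best cell is
chosen by validation ROC-AUC with ties toward the larger fraction, then
the larger oversampling count. Each cell is a single seeded split by
default with a `repeats` option, since resampling repetition is cheap but
not always wanted. Ablations refit after restricting the feature columns
to the protein block (P), the ligand block (L) or both (P+L).

## Matched molecular pairs and the chemical-space network

Pair mining is single-cut: every acyclic (bridge) single bond is cut, the
two fragments are canonicalized with one dummy-atom attachment marker
(`*`), and the larger fragment is the core (ties broken by the smaller
canonical string). Substituents above 1/3 of the parent's heavy atoms or
above 13 heavy atoms are filtered — common MMP practice; both caps are
configurable. Two compounds sharing a canonical core with different
substituents form exactly one pair per shared core. Double cuts are out of
scope. The chemical-space network annotates each compound with its
argmax-score target (ties to the first target in table order), takes MMPs
as edges, and labels connected components — the package's operational
definition of a scaffold cluster, since no sharper cluster notion is
required by the downstream use. Export is GraphML plus an edge-list CSV.

## The synthetic-data generator

The generator exists so that every stage is testable without any external
database, and it plants exactly the structure the pipeline assumes:

* **Panel** — 30 sequences of length 120 in 4 families, each member a
  per-site mutation (rate 0.1) of its family ancestor. Rate 0.1 puts
  within-family normalized similarity far above between-family similarity
  while leaving members distinguishable.
* **Compounds** — 300 molecules from a small grammar: an alkyl chain of
  2–12 carbons, a benzene ring with probability 1/2, and a terminal group
  (none/carboxyl/amide/methoxy at 0.3/0.4/0.15/0.15). The grammar spans
  the long-chain-acid versus small-aromatic contrast the screen should
  separate, and guarantees valid SMILES.
* **Bioactivity** — five training targets (covering both rule groups) and
  two fully held-out targets from families seen in training, mirroring a
  modeling set over few receptors plus an external set on unseen ones.
  The planted rule couples ligand features to target family: odd families
  bind long-chain carboxylic acids (chain ≥ 7 and a carboxyl), even
  families bind aromatics. Labels flip independently with probability
  0.05; EC50s are sampled log-uniformly consistent with the label —
  actives in [0.001, 1] µM, inactives in (1, 100] µM — so the 1 µM
  dichotomy is exercised on both sides of its boundary.

Because the rule is family-conditional, the ligand block alone faces a
ceiling (it cannot know which predicate applies), the protein block alone
carries only base-rate signal (the two predicates have different
prevalences, ~22% vs ~50%, so target identity alone is slightly better
than chance — the regime one expects when activity is mostly
ligand-determined), and only the combined blocks recover the rule. The
label noise bounds achievable AUC near 0.95. What passing tests show is
that the pipeline recovers a planted interaction of exactly this shape;
real receptor–ligand data are messier in every direction (correlated
assays, activity cliffs, family structure that does not align with binding
site similarity), so fixture performance is a correctness check, not a
performance claim.

## Problem sizes and numerical choices

Test and acceptance runs use the full default study (30-member panel, 300
compounds, 1500 training records) with forest fits of 100 trees —
probability estimates from a 14-mtry forest are stable well below the
500-tree default — averaged over 5 seeds in the acceptance tests and 3 in
the acceptance script; ablation and transfer runs use oversampling 1000
per target, inside the stated operating range. The determinism check runs
the whole simulate→assemble→fit→predict→evaluate chain twice at a smaller
scale (60 compounds, 300 rows per target).

Numerical details worth knowing: alignment scores are floats (gap extend
0.5); the manifest order is C-locale (radix) sorted so it cannot drift
with the session locale; single-heavy-atom molecules take a formula-level
fallback for the Open Babel bulk properties (the SDF round trip does not
support them) with the remainder imputed as 0; predictions clamp to
[0, 1]; and all seeded paths (splitting, augmentation, forest growing, MLP
initialization and batching, the generator) run single-threaded from
explicit seeds, so fit→predict is bit-identical across runs.

## Known limitations

* The default reference panel in tests is synthetic; real use requires the
  user's own panel FASTA, and descriptor axes are only as meaningful as
  that panel.
* The 187-descriptor registry is this package's own deterministic
  selection; the manifest mechanism exists precisely so a transcribed
  external list can replace it, and models always embed the manifest they
  were trained with.
* Protein similarity is sequence-global; binding-site-local similarity
  would be sharper but requires structures, which are out of scope.
* MMP mining is single-cut and size-capped; ring-system replacements and
  double-cut pairs are not found.
* No probability recalibration is applied; scores are raw forest votes.
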