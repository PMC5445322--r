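---
title: "Ranking protein decoy models: methods and design notes"
author: "decoyrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking protein decoy models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decoyrank)
```

## The problem

A structure prediction run produces tens to hundreds of candidate 3-D
models (decoys) per target sequence. Model quality assessment (QA)
estimates, without the native structure, how good each decoy is —
ideally on the scale the community actually uses to judge predictions,
GDT_TS (the mean over 1/2/4/8 Å thresholds of the maximal percentage of
CA atoms superposable within the threshold). Three families of QA
methods exist: *single* methods score one model in isolation,
*clustering* (consensus) methods exploit the structure of the whole
decoy population, and *quasi-single* methods pick a few reference models
with a single method and score everything by similarity to the
references. Clustering methods win when decoys are plentiful and
mostly decent, but degrade badly when the pool is small or
quality-skewed; quasi-single methods inherit much of the consensus
accuracy while depending far less on the pool's quality distribution.

`decoyrank` implements a quasi-single pipeline whose reference selection
is a *learning-to-rank* model rather than a hand-tuned score.

## Stage 1: pairwise learning-to-rank

QA is naturally a ranking problem: what matters is the ordering of
decoys by their similarity to the (unknown) native. We use the pairwise
via-classification formulation. For a training target with native
available, each decoy has a true quality $q_i$ (GDT_TS to the native;
TM-score selectable). Every unordered within-target pair with
$|q_i - q_j| > \text{margin}$ becomes one instance: the feature
difference $x_i - x_j$ in canonical orientation (higher-quality model
first, label $+1$), with every second instance sign-flipped for class
balance. Pairs never cross targets — differences of feature vectors are
only meaningful within one decoy population.

A linear soft-margin classifier (C-classification, i.e. minimizing
L2-regularized hinge loss; solved by libsvm via e1071) on these
differences yields a weight vector $w$, and the **rank score** of any
decoy is $w \cdot \tilde x$ where $\tilde x$ is the z-scored feature
vector (normalization statistics are estimated on the training rows and
stored in the model, so any positive rescaling of a feature column
leaves the learned ordering unchanged). The bias is pinned at 0: a
ranking score is translation-free by construction. Ties in the final
ordering break lexicographically by model id, a documented, deterministic
and truth-blind rule.

Hyperparameters: tie margin 0 GDT_TS units, $C = 1$, per-target pair cap
50,000 (seeded subsampling) — all configurable; target-level
cross-validation (`cross_validate()`, splits by target, never by model)
is provided for selecting $C$ when wanted.

## The features

Two native energy features come from trainable knowledge-based
potentials (below). Four secondary-structure features measure agreement
between the model's geometry-assigned 3-state secondary structure and a
sequence-based prediction supplied by the user: per-element fractions
$\#\{i: a_i = p_i = e\}/L$ for $e \in \{H, E, C\}$ plus their sum, the
total agreement fraction. Two accessibility features compare the
model's relative solvent accessibility profile with a predicted profile
via Pearson correlation and the cosine of the two vectors (zero-variance
and zero-norm profiles yield 0, with a warning — a convention, since
real profiles essentially never hit it). Finally, arbitrary external
per-model score tables (delimited text with a `model_id` column) merge
in as additional columns, with per-column median imputation for decoys a
table does not cover; third-party QA programs thus plug in as features
without being re-implemented.

Secondary structure is assigned from backbone dihedrals (helical region
$\phi \in (-120°, -20°)$, $\psi \in (-80°, 30°)$; extended region
$\phi \in (-180°, -60°)$, $\psi > 60°$ or $\psi < -150°$; runs shorter
than 4 H / 3 E smoothed to coil), the standard 8→3 state collapse
applied to predictions (H/G/I→H, E/B→E, else C). Absolute
accessibility uses a deterministic Shrake–Rupley implementation
(golden-spiral point sets, probe 1.4 Å, 120 points/atom) converted to
relative values with the Tien et al. theoretical maximum-ASA table.
These replace the external DSSP/PSIPRED/ACCpro binaries a production
deployment might call; the feature contracts (two profiles in, agreement
numbers out) are independent of the profile source.

## The potentials

Both potentials use the inverse-Boltzmann log-ratio form with $kT$
folded into the (dimensionless) energy units — absolute scale is
irrelevant because the ranker learns the weights.

**Pair potential.** Heavy-atom pair distances up to
$r_{cut} = 14.5$ Å in $\Delta r = 0.5$ Å bins, excluding within-residue
pairs and backbone–backbone contacts of sequence-adjacent residues.
The reference state is DFIRE-style: the expected count in bin $r$ scales
down from the outermost bin as $(r/r_{cut})^{\alpha}$ with
$\alpha = 1.61$. Energies are
$-\ln[(N_{obs} + p)/(N_{exp} + p)]$ with pseudocount $p = 0.5$ guarding
$-\ln 0$ on small training sets; type pairs never observed score 0.
Atom typing is residue-specific: the full mode has the 167 heavy-atom
classes of the 20 amino acids (4 backbone + 87 side-chain atoms), and a
reduced 20-class CA-only mode supports fast scoring and backbone-only
synthetic structures. Scoring uses a cell-list neighbor search that is
exactly equivalent to the $O(N^2)$ double loop (a tested identity, not
an approximation).

**Torsion potential.** Per-amino-acid $(\phi, \psi)$ counts on a 30°
grid over $[-180°, 180°)^2$ against a uniform reference; terminal or
backbone-incomplete residues are skipped. The 30° default is coarse by
crystallographic standards but appropriate for the modest training
corpora this package targets; it is configurable.

## Stage 2: quasi-clustering

The five top-ranked decoys become reference models and every decoy's
predicted quality — the **quasi score** — is its mean GDT_TS to the
references, putting the output on the interpretable 0–100 scale. Design
choices the method statement leaves open, fixed here: a reference model
is averaged over the *other* references only (self-similarity would
otherwise gift every reference +100/5); with $n \le 5$ decoys the score
degenerates gracefully to a leave-one-out mean; non-comparable pairs
drop out of the mean with a warning rather than polluting it as zeros.
$k = 5$ is exposed as a parameter for ablation but is the method's
constant.

## Structure similarity

GDT_TS is intractable to maximize exactly, so, as the community's
scoring tools do, the implementation searches with LGA-style iterative
seeding: every seed window is Kabsch-superposed, inliers under the
threshold are refitted to a fixed point (≤ 10 rounds), and the best
inlier count per threshold is kept. For chains of ≤ 32 matched residues
the seeds are *all* contiguous windows of length ≥ 3; longer chains use
lengths {3..7, n/4, n/2, n}. The full-length superposition is always
among the seeds, so the reported score never falls below the
single-fit lower bound. Tests hold the search to within 1 GDT unit of
an exhaustive-seed oracle on random ≤ 30-residue chains; the same
seeding drives TM-score with the standard
$d_0 = 1.24(L-15)^{1/3} - 1.8$ Å normalization ($L < 16$ falls back to
$d_0 = 0.5$ Å with a warning). Alignment is by residue index — CASP QA
decoys share the target sequence — and residues missing from a model
count against the reference-length denominator, matching how partial
models are scored in practice. The search core is C++
(Rcpp/RcppArmadillo), as every structure-comparison tool in this space
compiles its inner loop.

## Evaluation metrics

The CASP QA suite: Diff (mean |predicted − true|), MCC and rank-based
(Mann–Whitney, ties ½) AUC at the 50 GDT_TS threshold, Loss (true
quality gap between the best available and the predicted-best model,
predicted-argmax ties broken lexicographically by id — deliberately
*not* by best true value, which would silently flatter the method),
per-target mean correlation (mPCC, zero-variance targets excluded with a
warning) and pooled correlation (PCC), and top-k overlap. Scale-aware
reporting: Diff and Loss are meaningful for the GDT_TS-scale quasi
score; AUC and the correlations apply to either score.

## Synthetic data: what it emulates, what it does not

Generators make the package testable offline. `make_native()` builds
ideal-geometry backbones (N, CA, C, O, pseudo-CB) from canonical
$(\phi, \psi)$ values — helix, extended strand, or a self-avoiding coil
walk. `make_decoys()` perturbs a native with i.i.d. Gaussian coordinate
noise along a ladder of $\sigma$ values plus a random rigid motion; the
`select20` regime ($\sigma \in \{0, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4.5,
7\}$ Å, 2 decoys each) spans GDT_TS roughly 10–100 like CASP's
"select 20" sets, and `best150` (σ ≤ 1.25 Å, 150 decoys) mimics the
high-quality "best 150" regime. `make_planted_feature_suite()` draws
feature tables with a known weight vector so ranker recovery is exactly
checkable.

What this does *not* emulate: real decoys are physically plausible
alternative folds with correlated, segment-wise errors, not isotropic
noise clouds; real feature noise is structured, not Gaussian. Passing
the synthetic suites therefore demonstrates that the machinery is
correct and that the pipeline recovers known signal — it does not
certify CASP-level accuracy, which depends on training corpus and
feature quality. The packaged CASP12 T0912 table (15 published decoy
scores) supplies one real-data anchor: ranking its published
rank-score column against GDT_TS reproduces the 4/5 top-5 consistency
and zero loss of the published assessment.

## Numerical and degenerate-input conventions

Kabsch excludes reflections (smallest singular direction flipped when
$\det < 0$) and warns on near-collinear point sets. Similarity requires
≥ 3 shared CA residues; pairs below that are flagged missing (`NA`),
never scored 0. Feature tables refuse non-finite values; duplicate
external `model_id` rows are an error naming the id. Unreadable decoy
files are logged and skipped (the CLI exits 2 when any were skipped,
1 when none survive) rather than aborting a whole submission. All
generators and the training path are deterministic given seeds; the
svm fit is deterministic given the pair set.

## Packaged default model

`cmd_score()` works out of the box via a small model shipped in
`inst/extdata` and rebuilt by `scripts/build_default_model.R`:
potentials trained on 16 synthetic natives (coil/helix/sheet, 40–60
residues) and a two-feature (pair + torsion energy) ranking model
trained on 8 synthetic select20-like decoy sets labeled by GDT_TS to
their natives. The shipped pair potential uses 1 Å bins — a
better-estimated table for so compact a corpus and a smaller file; the
training default remains 0.5 Å. This model is explicitly synthetic-data
trained: for production use on real decoys, retrain with `cmd_train()`
on real targets with natives and predictions, and add external QA
scores as plug-in features.

## Problem sizes used in the shipped tests

Test and acceptance runs use 20–60-residue chains, 20-decoy select20
sets, 10–20 synthetic targets and planted suites of 20 targets × 50
models — sizes chosen so the full suite exercises every code path,
including the end-to-end pipeline, at desk scale. The statistical
conclusions (recovery cosines ≥ 0.99, held-out τ ≥ 0.95, quasi-score
per-target r ≥ 0.8) are stable across seeds at these sizes.

## Known limitations

Single-chain models only (the reader keeps the chain with the most CA
atoms); no mmCIF, ligands, or NMR ensembles. No orientation-dependent
(GOAP-style) or side-chain-packing energy terms natively — such scores
enter as external columns. The GDT search is a heuristic: it can in
principle undershoot an adversarial optimum, though never below the
full-fit bound. One global ranking model is trained across targets;
per-category models are not provided. The secondary-structure assigner
is dihedral-based and deliberately simple; it is not a DSSP replacement
for crystallographic work.
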