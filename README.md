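# decoyrank

Learning-to-rank quality assessment of protein decoy models.

Structure prediction pipelines emit many candidate 3-D models ("decoys")
for a target sequence; the practical bottleneck is deciding, without the
native structure, which candidates are good. `decoyrank` implements a
two-stage global model quality assessment method for this task, aimed at
structural bioinformaticians who need to rank CASP-style decoy sets or
their own sampling output.

## Method

**Stage 1 — pairwise learning-to-rank.** Each decoy *i* of a target is
described by a feature vector *x<sub>i</sub>*: knowledge-based energies (a
distance-dependent all-atom pair potential with a DFIRE-style reference
state, *E(i,j,r) = −ln[(N<sub>obs</sub> + p)/(N<sub>exp</sub> + p)]* with
*N<sub>exp</sub> ∝ (r/r<sub>cut</sub>)<sup>α</sup>*, and a backbone (φ,ψ)
torsion potential), secondary-structure and solvent-accessibility
agreement features against sequence-based predictions, and optional
external per-model score tables. Ranking is cast as classification:
every within-target pair becomes a difference instance
*(x<sub>i</sub> − x<sub>j</sub>, sign(q<sub>i</sub> − q<sub>j</sub>))*
where *q* is GDT_TS to the native, and a linear large-margin classifier
(L2-regularized hinge loss) learns a weight vector *w*. The **rank
score** of a new decoy is *w · x* (arbitrary scale, higher = better).

**Stage 2 — quasi-clustering.** The five top-ranked decoys become
reference models, and every decoy's predicted quality — the **quasi
score** — is its mean GDT_TS (or TM-score) to the references, i.e. a
consensus score anchored on single-model selection rather than on the
full decoy population. The quasi score lives on the GDT_TS scale
(0–100).

Supporting machinery: a PDB reader/writer, Kabsch superposition with an
LGA-style iterative seeded search for GDT_TS
(*GDT_TS = (P<sub>1</sub>+P<sub>2</sub>+P<sub>4</sub>+P<sub>8</sub>)/4*)
and TM-score (*d<sub>0</sub> = 1.24(L−15)<sup>1/3</sup> − 1.8*), the
CASP QA metric suite (Diff, MCC and AUC at 50 GDT_TS, Loss, per-target
mean and pooled Pearson correlations, top-k overlap), and synthetic
generators (ideal-geometry backbones, noise-ladder decoy sets emulating
the CASP "best 150" / "select 20" regimes, planted-weight feature
suites) that make every stage testable offline.

## Worked example

Simulate a 30-residue target with 20 decoys spanning the quality range,
score it with the packaged default model, and evaluate against the known
truth:

```sh
Rscript inst/cli/decoyrank.R simulate -o demo/t1 --length 30 --seed 5
Rscript inst/cli/decoyrank.R score -i demo/t1/decoys.list -o demo/scores.txt
head -4 demo/scores.txt
```

```
demo/t1/decoy_L01_01.pdb -5.54 97.29
demo/t1/decoy_L01_02.pdb -5.58 97.29
demo/t1/decoy_L02_01.pdb -6.58 96.67
demo/t1/decoy_L02_02.pdb -5.74 97.08
```

Each line is: model path, rank score (stage 1, arbitrary scale), quasi
score (stage 2, GDT_TS scale). The low-noise decoys `L01`/`L02` are
predicted near-native (quasi ≈ 97), matching their true GDT_TS of
100/96.7. Evaluating the quasi scores against the generator's truth
table:

```sh
Rscript inst/cli/decoyrank.R evaluate -p demo/pred.tsv -t demo/t1/truth.tsv -o demo/report
cat demo/report.json
```

```
{"diff":1.57933333333333,"mcc":1,"auc":1,"loss":0,"mpcc":0.999605698296883,"pcc":0.999605698296883,"threshold":50}
```

i.e. the predicted qualities track the true GDT_TS to within 1.6 GDT_TS
units on average, the best decoy is identified exactly (loss 0), and
good/poor models separate perfectly at the 50 GDT_TS threshold.

The same pipeline is available programmatically
(`load_decoy_set()` → `build_feature_table()` → `rank_models()` →
`select_references()` → `quasi_scores()`); `cmd_train()` fits a new
ranking model from any collection of decoy sets with natives. See
`vignettes/decoyrank-methods.Rmd` for the model details and design
choices.

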