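---
title: "Classifying cell-penetrating peptides from molecular descriptors"
author: "convboost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cell-penetrating peptides from molecular descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cell-penetrating peptides (CPPs) are short peptides — 5 to 30 residues,
typically cationic, Arg/Lys-rich and often amphipathic — that cross the
lipid bilayer and are of direct interest as drug-delivery vehicles.
Discriminating CPPs from non-penetrating peptides is a binary
classification problem whose inputs are molecular descriptors computed
from the peptide's sequence and structure. This package implements the
full pipeline: descriptor computation, assembly of named descriptor sets
("feature compositions"), a soft-voting ensemble of a one-dimensional
convolutional network and a gradient-boosted tree model, and stratified
ten-fold cross-validation with the standard binary metrics.

```{r, eval = FALSE}
library(convboost)

peps <- generate_peptides(generator_config(seed = 1))   # or read_fasta()
features <- extract_features(peps, "FC-STR", "+NOHo")
cv <- ten_fold_cv(features, convboost_spec("FC-STR"), seed = 42)
glance(cv)
```

## Descriptors

**Structure-based block.** A whole-peptide molecular graph is assembled
from per-residue heavy-atom templates: residues are joined by amide
bonds with condensation (one water per bond), the N-terminus is a free
amine, the C-terminus a free carboxylic acid, and protonation states are
neutral. From this graph the package computes molecular weight (average
atomic masses, Da), the fraction of sp³ carbons (Fsp³), Lipinski-style
hydrogen-bond acceptor (all N/O) and donor (N/O bearing ≥ 1 H) counts,
aromatic ring count (SSSR of the aromatic subgraph), rotatable bonds
(non-ring single bonds between non-terminal heavy atoms, amide C–N
excluded), and the nitrogen and oxygen atom counts. Topological polar
surface area is the Ertl fragment-contribution sum over N/O
environments (Å²) and cLogP the Wildman–Crippen atomic-contribution
logP; both are evaluated as frozen per-residue contribution tables in
the three backbone contexts a residue can occupy (N-terminal, internal,
C-terminal), a decomposition that is exact because both schemes are
strictly local atomic typings. Charged-group counts follow a fixed
pH-7-like convention: NG = arginines (guanidine groups), NNCAA =
aspartates + glutamates, NPA = lysines + the free N-terminal α-amine,
and NetC = (Arg + Lys) − (Asp + Glu) with histidine neutral and the
termini excluded by default (they approximately cancel at neutral pH;
each terminus can be switched on separately). Several toolkit
conventions exist for HBA/HBD/rotatable bonds and protonation; the
definitions above are fixed and documented, and the golden values in the
test suite are pinned to them.

**Sequence-based block.** The arginine and lysine fractions (`F[ARG]`,
`F[LYS]`); Chou's type-1 pseudo amino-acid composition with λ = 2
sequence-order tiers (so 20 + λ = 22 components) and weight w = 0.05,
using the three classical property scales (Eisenberg consensus
hydrophobicity, Hopp–Woods hydrophilicity, side-chain mass), each
standardised to zero mean and unit population SD over the 20 residues;
and the dipeptide composition over a fixed 40-pair catalogue. λ is
forced by the 22-component contract; w = 0.05 is the standard default of
the formulation. Ten catalogue entries are the uptake-motif pairs used
by the Kendall-selected composition (GL, GF, LG, GA, VC, RK, RQ, KR,
KK, RR); the remaining thirty are documented defaults drawn from
Arg/Lys/Gly/Leu/Ala/Phe/Val/Cys/Gln/Trp pairings and are fully
overridable through `feature_config()`, since no canonical list of the
forty exists.

**Hydrophobicity.** The Eisenberg consensus scale is embedded as a data
constant. Two hydrophobic moments are provided: the sequence
(helical-wheel) moment, the magnitude of
\(\sum_n H_n (\cos n\delta, \sin n\delta)\) at δ = 100°/residue, and the
structural moment \(|\sum_n H_n S_n|\), where \(S_n\) is the unit vector
from the α-carbon to the side-chain centroid of residue *n* (glycines
contribute zero and are reported). The descriptor exported as `Ho` is
the **per-residue sequence moment** (magnitude / length): it needs no
coordinates, and dividing by length makes it comparable across 5–30-mers.
The structural form is available for PDB input via
`structural_hydrophobic_moment()` but is not used by the default
compositions.

## Feature compositions and redundancy filtering

Four named compositions are shipped: FC-SEQ (64 sequence descriptors),
FC-STR (12 structure descriptors), FC-SEQ-STR (their union, 76) and
FC-Kendall (43: AAC, PseAAC, the ten motif dipeptides, and the structure
block minus tPSA, NRB and HBD). The `+NOHo` variants add the nitrogen
count, oxygen count and `Ho` to every structure-containing composition
and drop the descriptors a Kendall redundancy analysis flags against
them — HBD and MW in the structure-containing sets, `F[ARG]` in the
sequence-containing ones — giving sizes 63, 13, 77 and 44. These default
lists are hard-coded outcomes; `kendall_filter()` exists to re-derive or
re-examine them on the user's own data. Its defaults — remove one member
of every pair with |τ| ≥ 0.8, dropping the member with the larger mean
|τ| against all other features, ties broken alphabetically — are
explicit choices made here for reproducibility; the analysis that
produced the shipped lists did not publish its threshold or tie policy.

## The ensemble

**Convolutional member.** The descriptor vector is presented as a
1-channel signal in feature-composition order (the order is part of the
model and stored with it). The network has four groups of two
1-D convolution layers (kernel 3, same padding, tanh) with 32, 64, 128
and 256 filters, a size-2 max pool immediately before the last group and
a size-3 max pool after it, dropout 0.5, then dense layers of 256, 128,
64, 32 and 16 units (tanh) and a 2-way softmax trained with
cross-entropy (with a softmax pair this is the same objective as binary
cross-entropy on the positive-class probability). L1 regularisers are
placed per layer: activity 10⁻³ on conv groups 2–4 and the 256/128/64/32
dense layers; bias 10⁻² on conv groups 3–4 and 10⁻³ on the 256/128/64
dense layers; group 1 and the 16-unit and output layers carry none.
Training uses Adam at its defaults (learning rate 10⁻³), minibatches of
32, and a fixed epoch budget per composition — 25 (FC-SEQ), 20 (FC-STR),
25 (FC-SEQ-STR), 20 (FC-Kendall). Two pooling stages mean the input must
have at least 6 descriptors; `build_cnn()` reports the minimum when
violated. The implementation is im2col + BLAS matrix products with small
compiled kernels for the gather/scatter, elementwise backprop and Adam
steps; a finite-difference check in the test suite pins the gradients.
All randomness (initialisation, shuffling, dropout) derives from one
seed, so training is bit-reproducible.

**Boosted member.** XGBoost (binary logistic, single thread for
reproducibility). Hyperparameters can be tuned by Bayesian optimisation
over the documented space (trees 50–1000, depth 2–12, learning rate
0.01–0.3 log-scaled, row/column subsampling 0.5–1, `gamma`/L1/L2 0–10,
class weight 0.5–2, tree method exact/hist): a maximin Latin hypercube
seeds the search, a Gaussian-process surrogate (RBF kernel on the unit
cube, lengthscale by marginal likelihood over a small grid, 10⁻⁴ nugget)
is fit to cross-validated accuracies, and expected improvement over 512
seeded candidates proposes each next configuration, 32 evaluations in
total by default. When tuning is off, a fixed documented default
configuration is used (300 trees, depth 6, η = 0.1, 0.9 row/column
subsampling); tuning is performed once per feature composition, not
re-run inside every cross-validation fold.

**Soft vote.** The ensemble probability is the mean of the two members'
CPP probabilities; the label is CPP when it exceeds 0.5. A tie at
exactly 0.5 is deterministically called nonCPP.

## Evaluation

`ten_fold_cv()` uses stratified folds (the balanced design assumes
stratification; folds derive from the master seed). Within each fold the
scaler (z-score, fit on the training part only — leakage-safe), the
network and the boosted model are refit. Metrics are accuracy, Matthews
correlation (reported as 0 with a warning when a confusion margin is
zero), sensitivity, specificity, F1 = 2TP/(2TP + FP + FN), and AUC by
the rank (Mann–Whitney) estimator with ties counted half. Aggregates are
reported both as fold-metric means (the default summary) and as metrics
of the pooled confusion counts; the two differ slightly for ratio
metrics, and both views are kept so either convention can be read off.
`independent_test()` refits once on the full training table and
evaluates once on a disjoint test table (ids must not overlap).

## The synthetic generator

Real CPP collections are curated from external databases and are not
redistributable here, so the generator emulates the distributional
assumptions the classifier relies on: CPPs are drawn with elevated
Arg/Lys frequency on the polar face and hydrophobic residues placed at
positions whose 100°/residue helical phase points into the apolar face
(making `Ho` informative by construction); non-CPPs are drawn from
background proteome frequencies; lengths are uniform on 5–30. Defaults
generate the reference scale of 300 + 300 training and 75 + 75 test
records. The `separation` knob gives `strong` (fully structured),
`weak` (each position structured with probability ½) and `none`
(identical distributions; any classifier should hit chance level).
`class_separation_check()` summarises a labelled set by the mean
standardised class difference of the combined Arg+Lys fraction and the
per-residue moment: the strong setting calibrates well above 1, `none`
near 0. `add_helix_coordinates()` supplies ideal α-helix geometry (rise
1.5 Å, 100°/residue, radius 2.3 Å, centroids radially outward) for the
structural-moment path; consecutive α-carbons land ~3.8 Å apart. The
generator makes no claim of biological sequence realism: passing tests
show the pipeline recovers class structure of this synthetic form, not
that the shipped defaults reach any particular accuracy on curated CPP
databases.

## Numerical and design notes

- Descriptors are computed from the sequence-built graph even when
  coordinates are supplied; geometry only enters the structural moment.
- Duplicate peptides are exact sequence matches; duplicates with
  conflicting labels are an error, not a silent drop. Length bounds are
  inclusive. Preprocessing is idempotent.
- Nonstandard PDB residues are mapped only through an explicit
  user-extendable table (`default_residue_map()` covers MSE, SEC, PYL,
  HYP); unmapped codes fail loudly. First model/first chain by default.
- The MCC zero-margin convention, the 0.5 tie-break, the Kendall keep
  policy and the fold-mean default are all deterministic choices
  documented above so that identical configurations reproduce identical
  outputs byte for byte.
- Test-suite and acceptance problem sizes: cross-validation runs at the
  reference scale (600 records, 13-descriptor FC-STR +NOHo, 20 epochs,
  10 folds); unit tests exercise the same code paths on smaller tables.
  The Bayesian tuner is exercised at a reduced budget in unit tests;
  its default budget (32 evaluations, 3 inner folds) is the
  documented setting for real use.

## Limitations

- tPSA/cLogP contribution tables cover linear peptides of the 20
  canonical residues with free termini; modified or cyclic peptides are
  out of scope (map modified residues to parents explicitly when
  parsing PDBs).
- The 30 non-motif dipeptides of the default DPC catalogue and the
  PseAAC weight/scales are documented defaults, not recovered
  constants; override them via `feature_config()` if your upstream
  feature definitions differ.
- With ~600 training records the convolutional member is small but still
  data-hungry; on weakly separated data the boosted member tends to
  carry the vote.
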