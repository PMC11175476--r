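# convboost

Classification of **cell-penetrating peptides** (CPPs) — short peptides
(5–30 residues, typically cationic, Arg/Lys-rich and amphipathic) that
cross the lipid bilayer — from sequence- and structure-based molecular
descriptors, for peptide chemists and machine-learning practitioners who
need a reproducible descriptor → ensemble → cross-validation pipeline in
R.

## What it computes

**Descriptors.** From a residue-template molecular graph of the whole
peptide: MW, tPSA (Ertl fragment sums), cLogP (Wildman–Crippen atomic
contributions), Fsp³, Lipinski-style HBA/HBD, aromatic rings (NAR),
rotatable bonds (NRB), N and O atom counts, and charged-group counts
(NetC, NPA, NG, NNCAA). From sequence: Arg/Lys fractions, Chou's type-1
pseudo amino-acid composition (22 components, λ = 2, w = 0.05), a
40-dipeptide composition, and the Eisenberg-scale hydrophobic moment

```
Ho = | Σₙ Hₙ Sₙ |
```

with `Hₙ` the consensus hydrophobicity of residue *n* and `Sₙ` the unit
side-chain direction — the idealised helical-wheel form at 100°/residue
from sequence (exported per residue, `Ho/L`), or the structural form
from Cα → side-chain-centroid vectors when a PDB is supplied.

**Feature compositions.** Named descriptor sets FC-SEQ (64), FC-STR
(12), FC-SEQ-STR (76) and FC-Kendall (43), plus their `+NOHo` variants
(63/13/77/44) that add the N and O counts and `Ho` and drop the
descriptors a Kendall (τ-b) redundancy analysis flags against them (HBD,
MW, F[ARG]). `kendall_filter()` re-derives such removals on any feature
table.

**Classifier.** A soft-voting ensemble: a 1-D convolutional network
(4 × 2 conv layers with 32/64/128/256 filters, kernel 3, tanh, max pools
of size 2 and 3 around the last group, dropout 0.5, dense
256/128/64/32/16, softmax, per-layer L1 activity/bias regularisers,
Adam) and an XGBoost model, optionally Bayes-tuned by a
Gaussian-process expected-improvement search; the ensemble probability
is the mean of the two members' CPP probabilities. Evaluation is
stratified ten-fold cross-validation and independent testing with ACC,
MCC, SN, SP, F1 and rank-based AUC.

A synthetic generator (`generate_peptides()`) emulates labelled
CPP-like vs background peptide sets at the reference scale (300 + 300
train, 75 + 75 test) so the whole pipeline is testable without external
databases.

## Worked example

```r
library(convboost)

peps  <- generate_peptides(generator_config(n_cpp = 60, n_noncpp = 60, seed = 7))
ft    <- extract_features(peps, "FC-STR", "+NOHo")     # id, label + 13 descriptors
model <- fit_convboost(ft, convboost_spec("FC-STR", epochs = 10L), seed = 42)

tat <- tibble::tibble(id = "TAT47-57", sequence = "YGRKKRRQRRR")
predict(model, tat)
#> # A tibble: 1 × 5
#>   id       p_cnn p_xgb p_ensemble label
#>   <chr>    <dbl> <dbl>      <dbl> <chr>
#> 1 TAT47-57 0.740 0.938      0.839 CPP
```

`p_cnn` and `p_xgb` are the members' CPP probabilities; `p_ensemble` is
their average (here 0.839, so the HIV-Tat basic domain is called CPP —
it is Arg/Lys-rich and cationic, exactly the signal the descriptors
carry). For real data, start from `read_fasta()` / `read_pdb()` +
`preprocess_peptides()` (length filter 5–30, deduplication) instead of
the generator, and evaluate with:

```r
cv <- ten_fold_cv(ft, convboost_spec("FC-STR"), seed = 42)
glance(cv)       # fold-mean ACC, MCC, SN, SP, F1, AUC
tidy(cv)         # per-fold confusion counts and metrics
autoplot(cv)
```

A command-line wrapper over the same stages ships in
`inst/cli/convboost` (`synth`, `extract`, `train`, `cv`, `test`,
`predict`).

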