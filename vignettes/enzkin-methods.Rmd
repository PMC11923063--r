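---
title: "Methods: leakage-free enzyme kinetics prediction with enzkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leakage-free enzyme kinetics prediction with enzkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(enzkin)
```

## The problem

Machine-learning predictors of enzyme kinetic parameters — the turnover
number kcat (s⁻¹), the Michaelis constant Km (mM) and the catalytic
efficiency kcat/Km — are trained on public measurement collections in which
the same enzyme, or a close homolog of it, typically appears many times.
Under a randomly partitioned cross-validation such homologs straddle the
train/test boundary, and a model can score well by recognizing the family
rather than learning anything about catalysis. `enzkin` packages the whole
countermeasure pipeline: curation of raw kinetic tables, identity-threshold
clustering and cluster-respecting fold assignment with a leakage audit,
pluggable featurization, shallow regressors with a two-stage attention-
corrected kcat/Km model, mutant-ranking benchmarks, and a PSSM-filtered
in-silico directed-evolution workflow. A synthetic benchmark generator
reproduces the homology structure that makes random splits leak, so every
claim is testable at desk scale.

## Curation model

Raw tables carry one measurement per row (enzyme accession, sequence,
substrate SMILES, parameter, value, unit). The cleaning rules are:

* rows whose accession field holds several UniProt ids, or which lack a
  SMILES or a sequence, are dropped and counted in a skip report;
* units outside an explicit allow-list are treated as ambiguous and the
  rows removed; surviving values are converted to canonical units — kcat to
  s⁻¹, Km to mM (the BRENDA convention) — *before* duplicate resolution;
* duplicate (sequence, SMILES) measurements collapse to the **maximum**
  kcat and the **minimum** Km, i.e. the most favorable measurement is
  treated as closest to the enzyme's capability;
* labels are log10-transformed; for pairs with several raw measurements
  the population standard deviation of the log10 values is kept as a
  per-entry label-noise annotation (single-measurement pairs carry none);
* the kcat/Km dataset is the key intersection of the curated kcat and Km
  datasets, with label log10 kcat − log10 Km and both parent labels kept.

The pair key is the exact amino-acid string plus the SMILES string, so
point mutants of one accession are distinct entries. Whether `X` residues
should be filtered is left to the caller; the identity machinery accepts
them (they match only themselves).

## Homology-aware splitting

Sequence identity is computed from a global Needleman–Wunsch alignment
(match +1, mismatch 0, linear gap −1, via `Biostrings::pairwiseAlignment`)
as identical columns divided by the shorter sequence length — the CD-HIT
convention. Clustering is greedy and incremental at a threshold of 0.4:
sequences are processed longest-first (ties broken lexicographically by
id), each joining the first existing cluster whose representative it
matches at or above the threshold, otherwise founding a new cluster. No
k-mer prescreen is used; at desk scale the O(n²) alignments are cheap, and
any prescreen would be required not to change results.

Folds are assigned whole clusters at a time, balancing **record** counts
(not cluster counts — with near-equal fold sizes as the observable
consequence): clusters sorted largest-first go to the currently smallest
fold, equal-sized clusters in a seeded shuffled order, fold ties toward
the lowest index. The random baseline deals a seeded shuffle round-robin.
`auditLeakage` certifies a split by computing the exact maximum cross-fold
identity; for a clustered split this is strictly below the clustering
threshold by construction, and the audit verifies it rather than assuming
it.

## Featurization

A reaction is the concatenation (protein embedding, molecule embedding,
MACCS keys), in that order; with the default 1024-dimensional protein and
768-dimensional molecule providers the vector has 1024 + 768 + 167 = 1959
entries. Embedding providers are deterministic maps from a string to a
fixed-length vector; protein/molecule language models plug in through
`matrixProvider` (precomputed embedding matrices, mean-pooled per sequence
by the exporting tool), and two synthetic providers support desk-scale
work:

* `iid_hash` — a seeded pseudo-random unit-scale vector per distinct
  string; distinct inputs are nearly orthogonal at moderate dimension;
* `kmer_composition` — a fixed seeded vector per k-mer, the embedding
  being the mean over the string's k-mers, so embedding distance grows
  with substitution count. This is what gives the synthetic benchmark its
  family signal.

MACCS keys are computed with OpenBabel (through `ChemmineOB`), whose bits
match the de-facto 167-key convention of the standard cheminformatics
toolkits; the two count-based keys OpenBabel leaves unset — key 125 (more
than one aromatic ring) and key 166 (more than one fragment) — are
computed in-package from ring perception and SMILES components, and the
whole vector is pinned against an independent toolkit's bits on a fixture
set in the tests. No feature scaling is applied by default.

Multi-substrate reactions are represented by the elementwise mean of the
per-substrate molecule features (embedding and MACCS parts alike), and
predicted by averaging per-substrate predictions; ensembles of fold-models
average arithmetically at inference.

## Regressors

The prediction module is deliberately shallow: one ReLU hidden layer
(default width 256, the only width used anywhere in the model family) and
a linear output, trained with an RMSE loss by Adam. Because RMSE-loss
gradients keep a roughly constant magnitude near the optimum, a constant
Adam step leaves a noise floor proportional to the step size; the learning
rate therefore decays linearly to zero over the run (default 0.01 over 300
epochs, full batch). The output layer starts at zero with the bias at
mean(y), so optimization starts from the best constant predictor — a
constant target is fit exactly, and early epochs cannot be worse than the
mean. All randomness (initialization, minibatch shuffles, fold seeds)
derives from one run seed, making training bit-reproducible. An
extra-trees backend (`ranger`, extratrees split rule) satisfies the same
predict contract for tree-ensemble baselines.

The kcat/Km model is two-stage. Stage 1 pre-trains kcat and Km submodels
on the parent labels of the ratio dataset, per training fold; their
parameters are then frozen (the trainer asserts bit-identity after stage
2). Stage 2 learns a correction: the 1959-feature input passes a dense
layer to 256 dimensions, then a feature-wise attention gate

&nbsp;&nbsp;&nbsp;&nbsp;A = Softmax(W·h), h_A = A ⊙ h,

with W square (256×256), and a linear output. The final prediction is

&nbsp;&nbsp;&nbsp;&nbsp;a·(kcat_pred − km_pred) + b·correction,

where the blend weights (a, b) are learnable scalars initialized at 1 and
trained jointly with the correction network (the combination weighting was
an open design point; joint training on the training fold is the simplest
choice consistent with the freeze contract). The correction output layer
starts at zero, so training starts exactly at the raw log-difference
baseline; a seeded internal validation split (15 % of the training fold)
selects the epoch to keep, the initial state included, which prevents the
correction from generalizing worse than the baseline by more than
validation noise. Grid search is exhaustive by mean out-of-fold RMSE with
ties resolved toward the earlier grid point.

## Mutant-ranking benchmarks

A reaction is one UniProt-accession/SMILES pair; its panel is the
wild-type plus all variant sequences measured against it. Panels with at
least N variants (N = 20 and 30 are the standard operating points) are
evaluated by the within-panel Spearman correlation between predicted and
experimental log10 values (unweighted mean over panels — panel-size
weighting was an open point; unweighted keeps every reaction equally
informative), and by pairwise ordering accuracy M_true/M_total over the
N(N−1)/2 variant pairs. Tie policy (the sources are silent): pairs tied
experimentally are excluded from M_total, and a tied prediction on an
informative pair counts as incorrect — a predictor cannot harvest accuracy
by declaring ties. Mutation effects are the panel-mean-centered labels;
pooled correlations concatenate the centered vectors across panels.

## Mining and directed evolution

Candidate homologs first pass a length filter (|Δlength| strictly greater
than 20 residues removed — the boundary value itself is kept), then are
ranked by predicted catalytic efficiency, log10 kcat − log10 Km, and
truncated to the top 150. The combination rule for the two predictions was
an open point; the log-ratio is the natural efficiency proxy, and
single-parameter ranking is available by calling with one model's score.
Pocket sites are residues whose minimum heavy-atom distance to any ligand
heavy atom is within 12 Å (hydrogens ignored; the any-heavy-atom reading
of the distance criterion is adopted over Cα-only), minus explicit
exclusions such as metal-coordinating histidines. Saturation mutagenesis
produces exactly 19 mutants per site. Screening keeps the top
⌈M/2⌉ mutants by predicted kcat/Km, then those with ΔPSSM =
PSSM(site, mutant) − PSSM(site, wild-type) strictly greater than 7.
PSSMs are consumed from the standard PSI-BLAST ASCII layout (header-keyed,
so permuted column orders parse correctly); generating them is out of
scope. A second engineering round runs the same machinery with a
multi-mutant template passed as the wild-type.

## The synthetic benchmark

`simulateFamilies` grows each family from a random ancestor by iid
substitutions (uniform over the 19 alternatives, no indels — identity
stays analytic) at a per-position rate; a member therefore sits at
≈ (1 − rate) identity to its ancestor and ≈ (1 − rate)² to a sibling.
`simulateKinetics` draws log10 labels as

&nbsp;&nbsp;&nbsp;&nbsp;label = μ + family + substrate + variant + ε,

with each effect drawn once per family/substrate/enzyme at standard
deviations (σ_fam, σ_sub, σ_var, σ_ε). Substrates come from a fixed pool
of 16 valid small-molecule SMILES so fingerprinting never fails. Variant
effects are deliberately **not** encoded in the synthetic embeddings: they
are irreducible noise to any model, so the performance difference between
split modes is attributable to family memorization alone.

The leakage experiment's defaults are the study conditions: 40 families ×
10 members, 120-residue sequences at 5 % within-family substitution rate,
8 substrates (2 per enzyme, 800 records), σ = (1.0, 0.5, 0.2, 0.2),
k-mer-composition providers (protein dim 128, k = 3; molecule dim 64,
k = 2 — modest widths that keep a full run in minutes on one core), and
the default regressor configuration under ten-fold cross-validation. Under
these conditions the substrate component is learnable in both split modes,
the family component only under the random split, so the out-of-fold PCC
gap isolates the leakage inflation. What passing this shows about real
data: that the pipeline's clustered splits remove the homology shortcut a
random split leaves open. What it does not show: that any particular
accuracy level transfers to real kinetic tables, whose label noise, unit
heterogeneity and chemistry are richer than the generator's additive
model.

## Numerical choices and degenerate inputs

* Correlations refuse zero-variance input (flagged as undefined rather
  than returned as 0); per-fold metrics on folds with fewer than two
  records are flagged NA.
* The Spearman statistic uses the explicit rank-difference formula when
  ranks are unique and Pearson-on-average-ranks under ties, to which the
  formula reduces in the tie-free case.
* Softmax subtracts the row maximum before exponentiating.
* Deduplication is idempotent and order-independent; entries are sorted
  by key on output.
* Greedy clustering and fold assignment are deterministic given input and
  seed; assignment tie-breaks are documented above.
* The smaller problem sizes used in the test suite (e.g. 20 × 8 families
  for the two-stage benchmark, 5 folds) are the package's own choice of
  desk-scale defaults for quick verification; the leakage benchmark runs
  at its full default size.

## Known limitations

* The synthetic generator has no indels, no correlated substitution
  process, and additive label structure; it is a test harness, not a
  biological simulator.
* Real language-model embeddings are consumed, never computed; the
  synthetic providers share their dimensionality but not their chemistry.
* The greedy clustering reproduces the CD-HIT convention, not CD-HIT's
  exact output (word filtering is not emulated), and identity is defined
  by one fixed scoring scheme.
* The PSSM reader expects the 20-column ASCII layout; profiles with
  nonstandard alphabets are rejected.
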