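---
title: "codonlife: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{codonlife: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonlife)
```

# Scope

`codonlife` links coding-sequence composition to protein homeostasis
parameters (lifetime, protein and mRNA abundance, ribosome density). It
covers feature extraction, correlation screens with wobble-class
summaries, a cross-validated prediction harness, synonymous gene design at
target GC3 levels, pulse-chase decay fitting, and a synthetic-data
generator that plants recoverable statistical structure. It deliberately
does *not* predict secondary structure (H/E/C strings are inputs or
simulated), compute mRNA folding energies, retrieve GO/PFAM annotations
(generic binary term matrices substitute), or model the cell biology of
label-based lifetime measurements.

# Sequence features

**Composition tier (81 features).** Percentages of the 20 amino acids over
the protein and of the 61 sense codons over the CDS. The terminal stop
codon is excluded from all counts; the initiator Met codon is included,
consistent with defining the "N-terminal residue" as the residue at
position 2 (initiator-Met cleavage is not modelled — its outcome depends
on downstream enzymology that composition features cannot see). All 61
codon columns are always emitted, with zeros for absent codons, so feature
matrices from different cohorts align by name.

**Synonymous subgroups.** A subgroup is a set of sense codons sharing
amino acid *and* first two nucleotides. The six-fold amino acids (Leu,
Arg, Ser) split into a pair plus a quadruplet, giving 21 subgroups. Met
(ATG) and Trp (TGG) are single-codon families whose third base is fixed;
they carry a wobble class but belong to no subgroup, since a within-group
G/C-vs-A/U comparison is undefined for them. Every one of the 21 subgroups
contains both wobble classes — this is asserted structurally.

**GC3 scopes.** `gc3_fraction()` reports the percentage of codons ending
in G or C, either over all codons (descriptive reporting) or over
wobble-tunable codons only (excluding ATG/TGG; the scope the designer
targets). The tunable scope is what makes a 0% design reachable at all —
ATG and TGG both end in G, so the all-codons scope has a floor set by the
protein's Met/Trp content.

**Physicochemical scalars.** GRAVY is the mean Kyte–Doolittle hydropathy.
The aliphatic index follows Ikai's mole-percent formula with relative
side-chain volumes 2.9 (Val) and 3.9 (Ile/Leu). The isoelectric point is
found by bisection (100 iterations on pH 0–14, far below float precision)
on the Henderson–Hasselbalch net charge under the EMBOSS pKa set
(N-terminus 8.6, C-terminus 3.6, K 10.8, R 12.5, H 6.5, D 3.9, E 4.1,
C 8.5, Y 10.1). Molecular weight uses standard average residue masses plus
one water. The pKa and mass tables are frozen package constants so results
do not drift with an external tool's version; different published pKa sets
shift absolute pI values by a few tenths of a pH unit but preserve the
orderings the models consume.

**Sequence tier.** Adds the structure-stratified composition (the 81
features recomputed within H, E and C regions; 243 columns, zero-filled
with a flag when a class is empty), the physicochemical scalars, protein
length, and a 20-column one-hot of the position-2 residue. **All tier**
appends binary annotation columns filtered to terms present in at least 10
proteins — rarer terms cannot support stable importance estimates. Any
feature trivially derived from the response is dropped (length when
predicting length) and recorded in the matrix's `dropped` attribute.

# Association statistics

Per-feature Pearson correlations are computed within each response dataset
over the proteins shared with the feature matrix, then aggregated with an
*unweighted* mean and s.e.m. across datasets: the datasets play the role
of independent studies, and weighting by sample size would let one large
study dominate the inter-study error bar. A pooled mode (concatenating
proteins across datasets) would answer a different question and is not the
default. Responses are used on the scale provided; an optional natural-log
transform flag exists because lifetime-like quantities are often
right-skewed, but no transform is imposed.

The wobble summary averages, per subgroup, the per-dataset mean r over
G/C-ending members and over A/U-ending members, and compares the two
classes with a two-sample Student's t-test across datasets (equal
variances by default, matching the use of s.e.m.-style error bars across
a handful of datasets; Welch is available). With a single dataset the
difference is still reported but the test is undefined. The degron motif
screen reports point-biserial correlations with Benjamini–Hochberg
adjusted p-values alongside raw ones; the N-end-rule check takes the
stability table as input data, since published scales differ.

# Prediction harness

**Split.** 20% of proteins are held out for testing; the remaining 80% is
divided into 10 balanced folds, re-initialised 10 times (each fold is an
8% validation slice of the whole dataset, i.e. the 72/8/20 layout).
Test ids never enter preprocessing statistics, tuning or importance
estimation; this is asserted by id bookkeeping in the tests.

**Preprocessing.** Features are centred and scaled with statistics fitted
on the training partition only. Optional filters remove near-zero-variance
columns, exact linear combinations, and one member of each pair with
|r| > 0.95 (all thresholds configurable). On planted data filtering
changes the feature count but moves test RMSE by well under 10%, so both
modes are supported and filtering defaults to on.

**Learners.** Three families, tuned by minimising mean CV RMSE over
folds × repeats, then refit on the full training set:

- *ensemble_trees*: random forest (`ranger`), 300 trees, mtry grid
  {√p, p/3}, min node size 5; the only learner able to capture
  non-linearity, which the tests verify on a step-function response.
- *elastic_linear*: elastic net (`glmnet`) over mixing grid α ∈ {0, 0.5, 1}
  and a 60-point penalty path down to 10⁻⁵ of λ_max.
- *greedy_forward_backward*: stepwise least squares written in-package —
  forward steps add the feature most correlated with the current residual,
  a backward step removes the weakest active feature whenever that costs
  less than half the last forward gain, and the model size along the path
  is chosen by CV. This is a sparse selector: it recovers sparse planted
  signals essentially exactly but is not expected to match the dense
  learners when the true signal spreads over all 59 tunable codons.

The hyperparameter grids are fixed, documented defaults; CV ties break
toward the simpler configuration (more penalised / fewer features). An
optional one-standard-error rule serves as the "tolerance model" variant.

**Metrics.** Test RMSE, Pearson r and r² = r² (asserted to machine
precision). `percent_of_max(r2_model, r2_interstudy)` expresses prediction
quality relative to inter-study reproducibility; it is reported as an
integer (rounded half away from zero, so 100·0.21/0.48 = 43.75 → 44) with
the raw value retained.

**Importances.** Random-forest importances are the mean decrease in node
impurity. For the linear learners the raw importance is |mean
coefficient| / sd(coefficient) — a t-statistic — over 30 leave-fold-out
refits of the chosen configuration on the training set (the resampling
scheme for these refits is a design choice; any scheme that perturbs the
training set comparably would do). Raw values are scaled so the maximum is
exactly 100, making learners comparable, and summed over amino-acid
classes (small hydrophobic A/I/L/V; negatively charged/polar D/E/N/Q;
positively charged K/R; potentially phosphorylated S/T; unusually
shaped/bonded P/W/C), separately for amino-acid and codon features.

# Codon design

`design_variant()` recodes a protein so that `round(target/100 ×
n_tunable)` (half away from zero; the residual quantum 100/n_tunable is
reported) of its tunable codons end in G or C. Positions are drawn
uniformly at random under the recorded seed — nothing in the construct
data constrains the spatial arrangement at intermediate targets, so the
unbiased choice is random, with an `even` spacing alternative. Within a
wobble class the codon is the alphabetically first for determinism, or the
highest-weight codon under a user-supplied usage table; the designer may
cross six-fold subgroup boundaries freely since only the wobble class is
targeted. The default stop codon TAA is excluded from all GC3 accounting.
`audit_variant()` re-derives everything by an independent per-codon scan
and treats a translation mismatch as a hard failure. mRNA folding energy
is not computed; designed FASTA output can be fed to an external folding
engine.

# Decay kinetics

Pulse-chase intensities are fitted as
`I(t) = b + f0·exp(−(k_deg + k_div)·t)`: a single-exponential labelled
pool over a constant background, with degradation and division-dilution
rates adding in the exponent. The model form is the package's choice — a
single compartment is the simplest model consistent with pulse-chase
curves of one construct. `k_div` defaults to a supplied constant (measured
from a proliferation control, as the dilution reference line suggests);
joint fitting is optional and needs ≥ 5 time points. Fitting is bounded
Levenberg–Marquardt (`minpack.lm`) with a small cascade of starting values
(the background/rate starts interact badly when the true background is
near zero); non-convergence returns a flagged result, not an error. Two
half-lives are reported: the division-corrected `ln 2 / k_deg` and the
composite `ln 2 / (k_deg + k_div)`, since published t½ values are
sometimes one and sometimes the other. A degradation rate with
`k_deg · t_max < 10⁻⁶` is indistinguishable from zero over the observation
window and is reported as an infinite half-life with a flag. An optional
log-linear fit (OLS on log(I − b)) provides a closed-form cross-check on
background-free data.

# The synthetic generator

The generator's defaults are the study conditions used throughout the
package's validation: cohorts of **2000 proteins** of **100–500 residues**
(typical proteome scale at desk-size), per-protein amino-acid frequencies
drawn from a Dirichlet with concentration 1.5 per residue class (giving
single-amino-acid percentages spanning roughly 1–20%, the spread real
proteomes show), and per-protein within-family codon usage drawn from a
Dirichlet with concentration 5 around uniform usage — one interpretable
knob controlling between-protein wobble heterogeneity (0.1 gives extreme,
nearly deterministic per-protein usage; 100 gives almost none). A
user-supplied usage table can replace the uniform within-family baseline.

Responses are planted as `y = X w + ε` with `w` defaulting to +δ/2 on
every G/C-ending and −δ/2 on every A/U-ending tunable codon percentage
(δ = 1), Gaussian noise calibrated so the population r² between the
noiseless signal and the response equals `target_r2` (default 0.5).
Gaussian noise on the response scale is an assumption, not a fact about
lifetime measurements. Replicate datasets mix the standardised original
with fresh noise, `ρ·z + √(1−ρ²)·η`, so their correlation is `replicate_r`
in expectation — default 0.69, the typical agreement between independent
lifetime studies of the same tissue; the weights follow in closed form
from the target correlation, which makes the construction testable.

What the generator does **not** emulate: real codon-usage tables, gene
length distributions, phylogenetic or functional correlation between
proteins, GO term co-occurrence, spatially structured secondary structure
(strings are i.i.d. per residue), heteroskedastic or non-Gaussian
measurement error, and any coupling between composition and annotation.
Passing recovery tests therefore demonstrate that the algorithms recover
the structures they claim to recover — not that those structures have any
particular strength in real tissues.

# Validation scale and numerical choices

Unit tests run on cohorts of 20–400 proteins; recovery properties use the
full 2000-protein study conditions (wobble contrast recovered in 21/21
subgroups over 8 datasets; planted explainable r² ∈ {0.2, 0.5, 0.8}
recovered within ±0.1 by the elastic net under the default 10×10 CV;
replicate correlation within 0.69 ± 0.05), the r²-convergence check uses
n = 5000, and decay recovery uses > 50 simulated curves at 5% noise with a
median relative t½ error under 15%. These sizes are the package's own
validation design: large enough for the sampling error of each statistic
to sit well inside the asserted tolerance, small enough to run routinely.

Numerical conventions: all randomness flows through explicit seeds
(generators restore the caller's RNG state); correlations of constant
vectors return flagged `NA` rather than errors; percentages live on the
0–100 scale end to end; TSV round-trips are lossless at 10 significant
digits; JSON reports carry unrounded values.

# Known limitations

- The greedy forward–backward learner's backward scan is O(k²) least
  squares per path and is intended for the feature-set sizes here
  (≤ a few hundred), not for thousands of annotation columns.
- The pI model ignores charged-residue interactions and modified termini.
- The decay model assumes a single homogeneous labelled pool; mixtures of
  fast- and slow-turnover subpopulations will bias `k_deg` toward the
  slower component at late chase times.
- Annotation features are generic binary terms; no attempt is made to
  reproduce a specific GO/PFAM release, whose contents are
  database-version dependent.
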