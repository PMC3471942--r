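---
title: "Predicting mutation-induced stability change with anti-symmetric features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting mutation-induced stability change with anti-symmetric features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddgforest)
```

## The problem and the model

A point mutation changes a protein's folding free energy by
$\Delta\Delta G$ (kcal/mol; in this package positive values are
stabilizing). Because free energy is a state function, the hypothetical
reverse event — mutant back to wild type — has exactly
$\Delta\Delta G_{\mathrm{rev}} = -\Delta\Delta G_{\mathrm{fwd}}$. Predictors
trained only on forward (mostly destabilizing) records often violate this
identity badly, which is a symptom of over-fitting to the composition of the
training set rather than learning the physics. `ddgforest` therefore makes
the identity structural:

1. every forward record is paired with its constructed reverse record
   (substitution letters exchanged, label negated), which also balances the
   stabilizing/destabilizing classes exactly;
2. the feature set is built so the parts of it that depend on the mutation
   are either *exactly anti-symmetric* under the wild-type/mutant swap or
   swap among themselves in a known pattern.

The regressor is a Random Forest (2,000 trees per model by default,
otherwise stock parameters — the algorithm is famously insensitive to
tuning), and predictions are classified stabilizing/destabilizing at the
zero-$\Delta\Delta G$ threshold.

## The 41 features

* **Evolutionary information (10).** From the wild-type protein's
  position-specific scoring matrix: log-odds and weighted observed
  percentage of the wild-type and the mutant residue at the site
  (`Wtlo`, `Wtwt`, `Mulo`, `Muwt`), and window averages of per-position
  total conservation for windows of 5, 9 and 15 residues
  (`wtlo5` ... `wtwt15`). Multi-point records average the per-site values.
  Windows are centred on the site and truncated at the termini; the
  per-position aggregate is the sum of the 20 matrix entries. Raw matrix
  units are kept: tree ensembles are invariant under per-feature monotone
  rescaling, so any hidden normalisation would not change splits. Reverse
  records reuse the wild-type profile with swapped residue lookups, making
  the swap identity exact by construction; a separately computed
  mutant-sequence profile can be attached instead where one is available.
* **Secondary structure and exposure of the mutated sites (5).** Fractions
  of the sites in helix/sheet/coil and exposed/buried, using the wild-type
  conformation for both sequences (mutations are assumed not to change the
  conformation). Exposure is binary at 25% relative solvent accessibility
  (RSA = ASA divided by the residue's maximum reference area; the shipped
  scale is the Tien et al. 2013 theoretical maxima, replaceable). A value
  exactly at a threshold goes to the higher-exposure class.
* **Relative differences (6).** Whole-sequence mutant-minus-wild-type
  differences of: positively charged (R,K,H), charged (R,K,H,D,E), small
  (T,D — implemented verbatim as published for this feature family, with a
  config override), tiny (A,G,P,S) composition, mean per-residue maximum
  ASA, and mean per-residue isoelectric point. All six negate exactly under
  sequence swap.
* **Sequential fragment potentials (13).** Tetra-peptide statistics learned
  by contrasting two reference corpora (thermophile-like vs mesophile-like):
  one unconditioned occurrence table, six occurrence tables conditioned on
  the fragment's state (helix/sheet/coil, buried/intermediate/exposed with
  the intermediate band [0.25, 0.50)), and six state propensity tables
  $\ln P(f\mid s) - \ln P(f)$ differenced between corpora. The occurrence
  form is a smoothed log-ratio with additive pseudocount $\kappa = 1$ over
  the $20^4$ key space. A fragment's state is the majority state of its four
  residues, ties broken by the third residue. The feature is the
  score difference mutant minus wild type, so only the at most $4 \times$
  (number of substitutions) windows overlapping a site contribute; the
  implementation rescores exactly those windows, and a property test pins
  the equality with whole-sequence rescoring to 1e-12.
* **Delaunay fragment potentials (7, structure mode).** The C-alpha trace
  is tetrahedralized (Bowyer–Watson incremental insertion with a
  determinant insphere predicate for borderline cells; cells with any edge
  above 10 Å — hull slivers without packing meaning — are dropped, a
  configurable cutoff). Each tetrahedron is classed by sequence
  continuity: `D43` (contains a run of ≥ 3 consecutive residues), `D2`
  (an adjacent pair only), `D1` (none). Fragment keys are unordered
  residue compositions (8,855 keys), since spatial neighbours carry no
  canonical order. Tables mirror the sequential design: one unconditioned
  occurrence table, per-class occurrence tables, per-class propensities.
  The published wording for the occurrence-style spatial features says
  "entropy difference" without defining it; we use the same smoothed
  log-ratio as the sequential tables for coherence and keep the functional
  form isolated behind the table object so an alternative drops in.

Sequence mode uses the first 34 features and reads secondary structure and
RSA from an external predictor's output (a documented 3-column TSV);
structure mode adds the 7 Delaunay features, with DSSP-derived annotation
(8-state codes collapsed H,G,I→H; E,B→E; rest→C — whether isolated bridges
belong with strand or coil differs between pipelines, so the mapping is
config data).

## Evaluation protocol

Folds are assigned to whole identity clusters, not proteins: single-linkage
at > 30% pairwise global identity (Needleman–Wunsch, BLOSUM62, gap open 10 /
extend 0.5; identity = matches over alignment length), largest cluster
first into the lightest fold. Reverse records share their forward partner's
protein, hence its fold — no homologous pair ever straddles train/test.
Out-of-fold predictions are pooled over the five folds and scored per
direction: accuracy and midrank AUC at the zero threshold (records with
experimental $\Delta\Delta G$ exactly 0 sit on the class boundary and are
excluded from the classification metrics; predictions of exactly 0 classify
destabilizing), plus Pearson R. Feature importance is the impurity
(residual-sum-of-squares) decrease summed over trees, averaged across
folds. The per-feature stabilizing-vs-destabilizing contrast table uses the
two-sample Kolmogorov–Smirnov test with the asymptotic p-value.

## What the synthetic generator emulates — and what it does not

All tests and the acceptance script run on synthetic fixtures with known
ground truth:

* sequences drawn from UniProt-like residue frequencies;
* C-alpha traces as ideal helices (rise 1.5 Å, radius 2.3 Å, 100°/residue,
  0.01 Å general-position jitter) or self-avoiding 3.8 Å walks;
* profiles with the native residue up-weighted by `exp(concentration)`
  (default 3), multinomial percentage rows;
* reference corpora whose charged-residue composition is tilted up/down by
  ±0.4 log-units, standing in for the thermophile/mesophile contrast;
* mutation records whose $\Delta\Delta G$ is a planted linear signal over
  difference-type features plus Gaussian noise. Because every weighted
  feature is exactly anti-symmetric, the planted truth obeys the
  reverse-mutation identity by construction. The default
  signal-to-noise ratio is 2:1 (noise SD set to half the signal SD).

This establishes that the machinery — augmentation, fold hygiene,
anti-symmetry, recovery of a signal that lives in the features — works. It
does not show that real mutations are predictable at any particular
accuracy: real $\Delta\Delta G$ values are not linear in these features,
real profiles and structures are far richer than the fixtures, and
experimental labels carry measurement error and sign-convention
heterogeneity. Published-data performance must be measured on the real
datasets through the documented bundle path.

## Numerical and design choices

* Pseudocount $\kappa = 1$ and the 20-letter alphabet are defaults; a
  reduced alphabet (grouping file) is the supported way to fight sparsity
  with small corpora. Fragments unseen in both corpora score a table-wide
  closed-form constant.
* Whether the published pipeline summed fragment scores over the whole
  sequence or only mutation-local windows is immaterial by the locality
  property — the difference is identical — which is why the difference, not
  the raw score, is the feature.
* Tessellation determinism: cells are sorted lexicographically; the result
  is invariant under rigid-body motion (property-tested) and matches an
  empty-circumsphere enumeration oracle on small clouds.
* $\Delta\Delta G$ sign convention (positive = stabilizing) is asserted at
  exactly one place, dataset load, where a `negate_ddg` flag adapts sources
  with the opposite convention.
* All randomness flows from explicit integer seeds; the caller's RNG state
  is restored. Two runs of `ddg_cv()` with one seed produce byte-identical
  reports.
* Problem sizes in the test suite are desk-scale by design: the acceptance
  checks use 30 proteins of length 90, 500 single- + 200 double-point
  records (1,400 after augmentation) and 500-tree forests, which keeps the
  full run in a few minutes while leaving the recovered correlation far
  from the pass threshold. The null-distribution check for the KS
  machinery uses unequal group sizes (400/600) because the statistic's
  discrete support is then fine enough for the asymptotic p-value to be
  near-uniform under the null.

## A worked run

```{r example, eval = FALSE}
proteins <- sim_proteins(12, 80, seed = 1) |> sim_layers(seed = 2)
corpusA <- sim_corpus(10, 80, tilt = 0.4, seed = 3)
corpusB <- sim_corpus(10, 80, tilt = -0.4, seed = 4)
potentials <- build_potentials(corpusA, corpusB)

sim <- sim_mutations(proteins, 200, potentials, snr = 2, seed = 5)
cv <- ddg_cv(sim$mutations, proteins, potentials,
             mode = "sequence", n_trees = 500, seed = 6)
glance(cv)
autoplot(cv, type = "importance")
```

## Known limitations

* The Bowyer–Watson implementation targets protein-sized point sets
  (hundreds of residues); it is quadratic and not meant for large clouds.
* Sequence-identity clustering aligns every protein pair; for hundreds of
  proteins a sketching pre-filter would be needed.
* The reverse-record profile is the reused wild-type matrix by default;
  supplying true mutant profiles changes the evolutionary features and is
  supported but not simulated.
* Zero-$\Delta\Delta G$ records are kept for regression but excluded from
  classification metrics; with many such records the reported ACC/AUC
  cover a subset of the data.
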