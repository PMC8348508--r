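---
title: "Topological proximity descriptors and GA-MLR QSAR modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological proximity descriptors and GA-MLR QSAR modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoqsar)
```

## The modelling problem

Factor Xa is the serine protease that bridges the intrinsic and extrinsic
branches of the coagulation cascade, and it is the target of several
marketed anti-thrombotic drugs. A quantitative structure-activity
relationship (QSAR) model links the inhibition constant of a candidate
molecule, expressed as pKi = -log10(Ki[nM] x 1e-9), to numerical
descriptors of its 2D structure. `topoqsar` implements the complete
workflow: molecular-graph annotation, atom-class proximity descriptors, a
genetic-algorithm (GA) descriptor search scored by cross-validated ordinary
least squares (OLS), and a validation battery covering internal,
external, randomization and applicability-domain checks. It also ships the
frozen published six-descriptor model for factor Xa inhibition
(`published_model()`), so new molecules can be scored without refitting.

The package operates entirely on the hydrogen-suppressed 2D molecular
graph. Every descriptor it computes is topological (bond-count distances)
or electrostatic via 2D-assigned partial charges, so no conformer
generation or geometry optimization is performed, and stereochemistry is
ignored by construction.

## Molecular graphs and atom classes

`parse_molecule()` converts SMILES through OpenBabel (via ChemmineOB) into
an annotated graph: element, aromaticity, hybridization, ring membership,
formal charge, partial charge, the bond list, and the all-pairs matrix of
topological distances (shortest heavy-atom bond counts; `Inf` between
disconnected fragments, so fragment-crossing proximities never count).

Perception choices worth stating explicitly:

* **Aromaticity** comes from the toolkit's SYBYL atom typing; ring atoms
  joined by MOL2 "ar" bonds are also aromatic (this admits pyrrole-type
  nitrogens), while acyclic atoms on "ar" bonds (the SYBYL notation for
  carboxylates and amidinium groups) are not.
* **Hybridization** maps SYBYL types to sp/sp2/sp3; aromatic atoms are
  always sp2, and planar/amide nitrogens (N.am, N.pl3) are treated as sp2,
  matching the perception conventions of mainstream cheminformatics
  toolkits.
* **Ring membership** is graph-theoretic: an atom is in a ring exactly when
  it lies on a cycle (an edge that is not a bridge).
* **Partial charges** default to Gasteiger-Marsili; the scheme is a
  parameter of `parse_molecules()`. "Positively charged" always means
  charge strictly greater than zero. Because different toolkits implement
  different charge schemes, numeric parity of charge-sum descriptors with
  other software is not claimed.
* **Amide nitrogen** is a nitrogen single-bonded to a carbon that bears a
  double-bonded oxygen.

Curation (`curate()`) drops records with missing or qualified Ki values,
strips salt fragments (keeping the fragment with the most heavy atoms),
excludes molecules containing elements outside H, B, C, N, O, F, Si, P, S,
Se and the halogens, and de-duplicates by canonical SMILES keeping the
first occurrence. Charged species are not neutralized: the deposited
protonation state is modelled as given. Curation parses without charge
assignment because metal species lie outside the Gasteiger parameter set
and no curation rule needs charges.

## Proximity descriptors

All descriptors derive from one engine (`descriptor_spec()`,
`proximity_value()`). For a source class A, a target class B and a bond
distance k, with d(b) the distance from target atom b to its nearest
source atom (excluding b itself):

* `exactly_k_excl` counts target atoms with d(b) = k. This encodes the
  exclusion rule of the "f"-prefixed descriptors: a target atom that also
  has a source atom *closer* than k bonds is not counted, because its
  minimum distance is then below k.
* `within_le_k` counts target atoms with 1 <= d(b) <= k ("at least one
  source atom within k bonds").
* `pairs_le_k` counts ordered (source, target) pairs at distance 1..k; it
  is provided for sensitivity analysis because the counting convention of
  "_kB" descriptors in other descriptor packages is not standardized.
  Counting qualifying target atoms (not pairs) is the default because it
  matches the exclusion rule's phrasing literally.

Two identities tie the modes together and are enforced by tests: summing
`exactly_k_excl` over k = 1..K equals `within_le_k` at K, and
`within_le_k` is non-decreasing in k. The partition identity is tested up
to K = 12 to keep runtimes short; the descriptors themselves have no
distance cap.

`named_descriptor_set()` returns the six descriptors of the published
model — `ringCplus_sumpc` (sum of partial charges over positively charged
ring carbons), `aroN_sp2C_4B` (aromatic N within 4 bonds of sp2 carbon),
`fClamdN5B` (amide N exactly 5 bonds from the nearest chlorine),
`fsp2Osp3O6B`, `fsp2Nsp3O9B` and `fsp2Csp2O8B` — plus ten comparator
descriptors (plain class counts and off-distance variants) that are useful
for the kind of substitution analyses that motivate the model descriptors.
Whether `aroN_sp2C_4B` should exclude the sp2 carbons of the nitrogen's
own ring is not specified anywhere; all sp2 carbons count here.

## Objective feature selection and splitting

`ofs_filter()` removes zero-variance columns, near-constant columns (by
default a column is near-constant when at least 95% of rows share one
value; the 0.05 tolerance is this package's choice, as no numeric rule is
standard), and then one member of every pair with |Pearson R| > 0.90.
Pairs are pruned in decreasing |R| order for determinism; within a pair
the column less correlated with the response is dropped when the response
is supplied, otherwise the later column. Survivors are therefore pairwise
below the cut, which the tests assert.

`split_dataset()` performs the uniformly random, seed-reproducible 80/20
split used by the study design (897 train / 224 external at n = 1121). An
activity-stratified split is deliberately not the default: the reference
protocol splits at random.

## GA-MLR subjective feature selection

`ga_mlr_search()` evolves fixed-size descriptor subsets. Chromosomes are
index sets of size m; crossover samples the union of two parents back down
to m (cardinality repair), mutation swaps members for non-members with
per-gene probability 0.05, tournament selection (size 2) picks parents,
and 2 elites survive unchanged, which makes the best fitness monotone.
Defaults (population 100, 300 generations, crossover 0.8) are this
package's choices; the reference GA's internals are proprietary to
QSARINS, so reproduction of the published model is statistical rather than
bitwise. Fitness is Q2_LOO computed through the PRESS identity (below);
singular designs score `-Inf` and are logged rather than raised. Ties in
fitness are broken by lexicographic descriptor-name order. Results are
deterministic given the seed, and all evaluated subsets are cached, which
makes the per-size scan (`model_size_scan()`) cheap.

Model size is chosen at the *breaking point* of the Q2_LOO-versus-size
curve: the smallest m whose successor improves Q2_LOO by less than delta
(`breaking_point()`, delta = 0.02 by default). The reference protocol
locates this point visually on a plot; delta makes the same judgement
reproducible and is reported in the output.

## Validation statistics

All formulas operate on the training set (tr) or external set (ext):

* R2 = 1 - SSres/SStot; R2_adj = 1 - (1-R2)(n-1)/(n-p-1);
  F = (SSreg/p)/(SSres/(n-p-1)).
* **Lin's concordance correlation** uses population (1/n) moments:
  CCC = 2 cov(y, yhat) / (var y + var yhat + (mean y - mean yhat)^2). The
  sample-variance variant differs in the fourth decimal; the population
  form is used consistently.
* **Q2_LOO**: leave-one-out residuals via the PRESS identity
  e_i/(1 - h_i), which tests verify against an explicit n-refit loop to
  1e-10. Rows with leverage numerically 1 are refit explicitly.
* **Q2_LMO**: each round leaves out 30% of rows (default, 1000 rounds);
  squared errors are aggregated over all rounds against deviations from
  the full training mean. This convention reduces exactly to Q2_LOO when
  rounds are the n singletons, which the tests exercise exhaustively at
  n = 12.
* **External block**: Q2_F1 references the training mean, Q2_F2 the
  external mean, Q2_F3 compares mean squared error against training
  variance per observation. The through-origin diagnostics follow the
  canonical forms: k = sum(y yhat)/sum(yhat^2) and
  k' = sum(y yhat)/sum(y^2); Ro2 = 1 - sum((y - k yhat)^2)/sum((y - mean
  y)^2) and R'o2 analogously with roles swapped; r2m = r2 (1 - sqrt(r2 -
  Ro2)). R2_ex is the squared Pearson correlation of observed and
  predicted external activities.
* **Y-scrambling** permutes the response (identity permutation excluded),
  refits, and records R2, Q2_LOO and the Todeschini K correlation of the
  scrambled [X, y] block per round (1000 rounds by default; the reported
  R2_Yscr is the mean, with the maximum retained in the table since
  conventions differ).
* **Applicability domain**: leverages h_i = x_i' (X'X)^{-1} x_i from the
  training design with intercept, threshold h* = 3(p+1)/n, standardized
  residuals e/s with a default cutoff of 2.5 (the boundary value drawn but
  not numbered in the reference Williams plots; configurable).

## The synthetic-data generators

Two generators make every stage testable without external data.

`gen_motif_molecule()` assembles molecules by template: each requested
motif (amide N at exactly k bonds from Cl; ether O at exactly k bonds from
a carbonyl O; pyridine rings for aromatic N and positively charged ring
carbons) becomes a substituent on an alkane backbone, with attachment
points separated by 14 methylenes so cross-motif distances exceed the
12-bond descriptor range — requested distances are therefore exact by
construction, and fidelity is asserted on every generated molecule in the
tests. The seed controls substituent order and a branched alkyl tail.
These molecules emulate controlled motif placement only; they do not
emulate the scaffold diversity, size distribution or property ranges of a
medicinal-chemistry dataset, so green tests certify the descriptor and
selection machinery, not chemical generalization.

`gen_planted_table()` draws descriptor-like columns (small non-negative
Poisson integers for count-like descriptors, and bounded continuous values
in [0, 1.5] for charge-sum-like ones, every fifth column) and plants a
sparse linear response. The default coefficients and intercept are those
of the published six-descriptor model, with noise sigma = 0.3 on the pKi
scale — about the residual error of a good large-dataset QSAR model — so
recovery experiments run under realistic signal-to-noise. Planted sizes
used by the test battery (n = 300 with 194 decoys for recovery, n = 400
with a pool of 50 for the breaking point) are the package's chosen
experiment sizes.

`gen_qsar_dataset()` closes the loop: motif molecules are drawn with
random motif content, their named descriptors computed, and activities
generated from the published model plus noise, then back-transformed to Ki
so the set round-trips through curation.

## Pipeline and reproducibility

`run_pipeline()` chains curation, descriptor calculation, objective
feature selection, splitting, the GA scan, the breaking point, the final
fit and full validation, writing CSV/JSON artifacts and a run log with the
config hash. Every random stage takes an explicit seed; re-running an
identical config reproduces byte-identical numeric outputs, and running
the stages individually with the same seeds matches the pipeline, both of
which are asserted by tests. The canonical-SMILES dialect is OpenBabel's,
recorded in the descriptor-matrix provenance.

## Known limitations

* Descriptor values are not guaranteed to match other descriptor software
  numerically: the counting convention of "_kB" descriptors and the
  partial-charge scheme behind charge sums are both toolkit-dependent
  choices, declared here rather than reverse-engineered.
* The published model is frozen from its printed coefficients; its
  training data (a curated ChEMBL set of 1121 molecules) is not bundled,
  so full-data statistics are not recomputable from this package alone.
* 3D phenomena (conformation, stereochemistry, tautomerism) are out of
  scope by design.

## Worked micro-example

```{r example, eval = FALSE}
mol <- parse_molecule("ClCCCCNC(C)=O")   # amide N five bonds from Cl
specs <- named_descriptor_set()
proximity_value(mol, specs$fClamdN5B)    # 1

# score molecules with the frozen published model
smi <- tempfile(fileext = ".smi")
writeLines(c("ClCCCCNC(C)=O m1", "c1ccncc1 m2"), smi)
run_predict(smi, model = "published")
```

The README walks through a complete synthetic study with the numbers it
prints.
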