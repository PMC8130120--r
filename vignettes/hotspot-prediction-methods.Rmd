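---
title: "Methods: structure-based prediction of protein-DNA hot spot residues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based prediction of protein-DNA hot spot residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnahotspot)
```

## The problem

Hot spots are the minority of interface residues that contribute most of the
binding free energy of a protein-DNA complex; experimentally they are found
by alanine-scanning mutagenesis. `dnahotspot` implements a structure-based
pipeline that, given the coordinates of a protein-DNA complex, encodes every
interface residue as a 24-dimensional structural feature vector, selects a
compact feature subset in two steps, and classifies residues with an
RBF-kernel support vector machine. Every stage is exercised end-to-end on
synthetic fixtures, so no external structures, binaries or databases are
needed to validate the implementation.

## The feature encoding

For a target interface residue $i$, with per-residue solvent accessibility
measured in four components (side-chain/total $\times$ absolute
$\mathrm{ASA}$ in A$^2$ / relative $\mathrm{RSA}$ in percent), the encoding
comprises:

* **Bound accessibilities** $B*$: the four components in the complex.
* **Changes on binding** $C* = \mathrm{mono} - \mathrm{comp}$, where the
  "mono" (unbound) state is the protein chains of the same structure with
  coordinates frozen — no re-minimization, matching the convention of
  computing accessibility change "upon complexation" from a single
  structure.
* **Relative changes** $R* = C*/\mathrm{mono}$, defined as 0 when the
  monomer value is 0 (a residue buried even in the monomer carries no
  relative-change signal, and the convention keeps values finite).
* **Eig**: eigenvector centrality of the residue in the interface network
  (nodes = interface residues, edge when C$\alpha$-C$\alpha$ $\le$ 7 A).
* **Psi**: the backbone torsion N-CA-C-N(next), IUPAC sign convention.
* **HbCN**: half-sphere contact number — C$\alpha$ contacts within 13 A
  split by the hemisphere of the C$\alpha\to$C$\beta$ vector; the feature is
  the total count (up and down counts are also computed).
* **DN**: hydrogen bonds donated by the residue in the bound complex, by
  geometric criteria (donor-acceptor $\le$ 3.9 A; with explicit hydrogens
  additionally H-acceptor $\le$ 2.5 A and D-H-A angle $\ge$ 90 deg).
* **Interfacial neighborhood properties**, the ratio-form features that
  compare the target with the mean over its interfacial neighbors $j$
  (interface residues with C$\alpha$-C$\alpha$ distance $\le$ 6.5 A,
  excluding the target itself):

$$\mathrm{INP1}(i) = \frac{\mathrm{ASA}_{mono}(i)}{\tfrac1n\sum_j
\mathrm{ASA}_{mono}(j)} - \frac{\mathrm{ASA}_{comp}(i)}{\tfrac1n\sum_j
\mathrm{ASA}_{comp}(j)}, \qquad
\mathrm{INP2}(i) = \frac{\mathrm{CASA}(i)}{\tfrac1n\sum_j \mathrm{CASA}(j)}$$

INP1 is computed for the four accessibility components, INP2 for the four
change components, giving 8 INP features. Conventions where the defining
ratios degenerate: no neighbors ($n = 0$) gives 0; a zero neighbor mean
with a nonzero numerator gives 0 with a mask flag. Both choices bound the
feature and are recorded in the feature table's mask. Whether the neighbor
mean should include the target is ambiguous in the source protocol; the
plain reading of "neighbor" excludes it, and that is what is implemented.

## Surface areas

Accessible surface areas use the Shrake-Rupley method: each heavy atom is
surrounded by a sphere of radius $r_{vdw} + r_{probe}$ (probe 1.4 A,
NACCESS-style heavy-atom radii C 1.87, N 1.65, O 1.40, S 1.85, P 1.90)
carrying a deterministic Fibonacci lattice of 960 points; the exposed-point
fraction times the sphere area is the atom's ASA. The deterministic lattice
makes results exactly reproducible; accuracy is verified against the
analytic isolated-sphere and two-equal-spheres closed forms (1% at 10,000
points) and by a lattice-refinement convergence test. Hydrogens have radius
0: they contribute no area and do not occlude, but are used for
hydrogen-bond gating when present.

Relative accessibility normalizes by a reference maximum per residue type.
Rather than shipping a transcription of one of the published tripeptide
tables, the reference is computed once per parameter set from an extended
Ala-X-Ala host tripeptide built by the package's own ideal-geometry peptide
builder and scored with the same lattice, radii and probe. This
self-consistent construction (in the spirit of the classical
tripeptide-based normalizations) guarantees that a fully exposed extended
residue scores 100%, which is also what the test suite asserts. Any choice
of reference table shifts RSA-derived features by a constant per residue
type; downstream min-max scaling absorbs such constants. Limitation: the
builder uses a reduced side-chain representation (C$\beta$ only), so for
full-atom structures the normalization of large side chains is
underestimated; relative values remain internally consistent.

Glycine's side-chain ASA is 0 by the no-C$\beta$ convention (its side-chain
RSA is 0/0, reported as 0).

## Interface definition

The source protocol computes features "for each interface residue" without
defining the interface. The implemented default: a protein residue is
interfacial iff its total absolute ASA strictly decreases from the unbound
(protein-only, coordinates frozen) to the bound state — i.e. CASA > 0, with
the threshold exposed as a parameter. This burial-based definition is the
convention that matches the CASA machinery the features are built on. A
distance-based alternative (any heavy atom within 5 A of a DNA heavy atom)
is available via `criterion = "distance"`.

## Classifier and selection

The C-SVC dual is solved by sequential minimal optimization with
maximal-violating-pair working-set selection, implemented in compiled code
inside the package because no SVM library is part of the dependency stack.
The solver is validated against a quadratic-programming oracle and a
closed-form two-point maximum-margin solution.

*Two-step selection.* Step 1 is SVM-based recursive feature elimination:
a linear-kernel SVM (weights are only defined for linear kernels) is fitted
on min-max scaled features and the smallest-|weight| feature is eliminated,
one per iteration; each subset size is scored by stratified tenfold
cross-validated AUC of the working RBF classifier at its default parameters
(C = 4.5, gamma = 0.05 — a full grid search at every elimination step would
multiply the cost ~60-fold without changing the ranking criterion); the
selected size maximizes CV AUC with ties to the smaller subset. Step 2
removes redundancy: among the step-1 features, pairs with Pearson r > 0.65
(signed — "highly positive correlation"; an |r| flag exists) are pruned
iteratively, dropping the worse-RFE-ranked member of the currently most
correlated pair until no pair exceeds the threshold.

*Grid search.* The final model is an RBF-kernel SVM tuned over
C $\in$ [0.1, 10] and gamma $\in$ [0.005, 0.5] (default grids include the
reference optimum C = 4.5, gamma = 0.05) by stratified tenfold CV, ties
toward smaller C then smaller gamma, refit on all rows at the winner.

*CV scoring.* The CV score is the mean of per-fold AUCs. Pooling held-out
decision values across folds into a single ROC was tried first and found to
be biased and over-dispersed under permuted labels, because fold-specific
decision offsets mix on pooling; the per-fold mean removes the artifact.
Note the honest null spread that remains: for 150 rows and this kernel the
permuted-label CV AUC has a standard deviation near 0.10 per draw (verified
to match a scikit-learn reference run), so chance-level behaviour is a
distributional statement, not a per-run guarantee.

*Probabilities.* A Platt sigmoid fitted to the winner's out-of-fold decision
values (robust Newton procedure) maps decisions to hot spot probabilities;
classification uses a 0.5 probability threshold. AUC is unchanged by this
monotone map. Median imputation (for masked values such as chain-terminal
Psi) and the min-max scaler are fitted on the training table only and
persisted with the model.

## Evaluation

Confusion-matrix scalars (SEN, SPE, PRE, F1, ACC, MCC) follow the standard
definitions with explicit degenerate-denominator conventions (undefined
metrics are `NA`; MCC is 0 when a marginal is empty). AUC is the
Mann-Whitney concordance probability with half credit for ties, computed
from midranks and cross-checked against the trapezoidal area of the
threshold-sweep ROC. Reported tables round half-up to 3 decimals; raw
values are retained. The worked-example acceptance targets reconstruct the
unique integer confusion matrices implied by printed sensitivity/
specificity and class compositions (26/38 test, 62/88 training) and verify
the derived MCC/ACC/F1/PRE to the printed precision.

## The synthetic world

Two generators stand in for external data:

* `make_toy_complex()` emits PDB text for an ideal-geometry extended
  peptide (N/CA/C/O/CB atoms, phi = -135, psi = +135) placed at a
  controlled gap from an idealized B-DNA duplex backbone (rise 3.4 A,
  twist 36 deg, sugar-phosphate shell plus a glycosidic-nitrogen anchor).
  It emulates the geometry that drives burial, contacts and hydrogen
  bonds; it does not emulate side-chain rotamers, base pairing chemistry,
  or sequence-dependent DNA deformation. A gap of 3.5 A produces a real
  interface; 30 A produces none.
* `make_feature_table()` emulates the labelled residue-by-feature training
  table at the published composition (62 hot spots / 88 non-hot spots, 24
  features by default): informative features are class-shifted Gaussians
  with a standardized mean difference of 1.0 by default (a moderate,
  realistic per-feature separation consistent with the overall
  discriminability the published protocol reports), noise features are
  class-independent, and planted correlated pairs reproduce the
  redundancy structure that step-2 pruning targets (e.g. 11 features
  containing 4 pairs with r > 0.9 prune to 7).

A green test on this world establishes that the algorithms implement their
definitions and recover planted structure; it does not establish predictive
performance on real complexes, which depends on curated alanine-scanning
labels outside this package's scope.

## Numerical and design choices

* Altloc: highest occupancy wins, ties by altloc code; model 1 only for
  multi-model files; waters dropped; author residue numbering throughout.
* Dihedral sign: IUPAC, verified against an external reference
  implementation on a frozen case (+90 deg) and by mirror antisymmetry.
* Eigenvector centrality is computed per connected component (dense
  symmetric eigendecomposition; graphs here have at most a few dozen
  nodes) and max-normalized within each component; isolated nodes score 0.
  This differs from conventions that scale only the global principal
  eigenvector, and is the reason the computation is not delegated to a
  graph library.
* Glycine's hemisphere axis uses an ideal tetrahedral pseudo-C$\beta$
  constructed from N, CA, C — the same construction the fixture builder
  uses for real C$\beta$ placement, so the two stay consistent.
* SMO stops when the maximal KKT violation gap drops below 1e-3 (1e-6 in
  oracle comparisons); the bias is the midpoint of the violating-pair
  bounds.
* Seeds: every stochastic step (fold assignment, generators) takes an
  explicit seed and restores the caller's RNG state.

## Limitations

* Surface areas are lattice approximations (~1-2% from analytic values at
  default settings), not Lee-Richards exact areas; exact replication of
  NACCESS output is a non-goal.
* The HbCN feature is a structural half-sphere contact count, standing in
  for a sequence-based neural predictor of the same quantity used by the
  original protocol; absolute values are not comparable, ranks largely are.
* No mmCIF input, no biological-assembly expansion, and modified
  nucleotides are handled only by name table.
* Benchmark performance numbers on the published 64-complex dataset are
  out of scope (they require external alanine-scanning labels); the
  acceptance suite instead reproduces the published worked-example metric
  rows exactly and validates every formula against independent oracles.
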