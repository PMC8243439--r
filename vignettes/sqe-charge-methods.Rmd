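---
title: "Split-charge equilibration charges and their parameterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-charge equilibration charges and their parameterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sqecharge)
library(dplyr)
```

## The models

Partial atomic charges are per-atom real numbers approximating how a
molecule's electron density distributes over its atoms. They are not
observables; empirical charge models assign them by minimizing a quadratic
charge energy whose coefficients — per-atom-type electronegativities
$\chi$, hardnesses $\eta$, and for bond-space models per-bond-type bond
hardnesses $\kappa$ — are fitted against quantum-mechanical reference
charges (typically natural population analysis, NPA).

**Electronegativity equalization (EEM, QEq, EQeq).** Charges minimize

$$E(q) = \sum_i \chi_i q_i + \tfrac12 q^\top H q,
\qquad \text{s.t. } \textstyle\sum_i q_i = Q,$$

where $Q$ is the total molecular charge and $H$ is the hardness matrix.
This package uses the conventional interaction kernel:
$H_{ii} = \eta_{t(i)}$ (the hardness of atom $i$'s type) and
$H_{ij} = 1/r_{ij}$ with $r_{ij}$ the interatomic distance in ångström.
Any Coulomb prefactor is absorbed into the fitted parameters, which is
harmless precisely because every parameter is fitted against the same
kernel; the unit prefactor is not separately identifiable. The constrained
minimization is solved exactly through the augmented (Lagrange) linear
system. QEq is implemented over the same quadratic form with its own
independently fitted parameters (no Slater-overlap or iterative
hydrogen-specific terms). EQeq expands each atomic energy about the
formal-charge reference state $q_{0,i}$ rather than the neutral atom,
which shifts the linear coefficient: the right-hand side becomes
$-\chi + \eta * q_0$. These three are deliberately plain, clearly
documented baselines; published parameter sets fitted against a different
kernel will not transfer bit-exactly (see *Limitations*).

**Split-charge equilibration (SQE).** SQE moves the variables from atoms
to bonds: each bond $b = (i, j)$ carries a split-charge $p_b$, and an
atom's charge is the signed sum over its incident bonds,
$q = T^\top q_{sp}$, where $T$ is the bond–atom incidence matrix (one row
per bond: $+1$ at the lower-indexed endpoint, $-1$ at the other). The
split-charges solve

$$\left(T H T^\top + \mathrm{diag}(\kappa)\right) q_{sp} = T\chi .$$

Because every column sum of $T^\top$ is zero, SQE charges always sum to
zero — the formalism has no way to impose a total charge, which is
its known weakness for charged functional groups.

**SQE+q0** seeds the system with the molecule's integer formal charges
$q_0$:

$$\left(T H T^\top + \mathrm{diag}(\kappa)\right) q_{sp}
  = T\left(\chi - Hq_0 + \eta * q_0\right),
\qquad q = T^\top q_{sp} + q_0,$$

so the charge sum equals the formal-charge sum ($*$ is the element-wise
product).

**SQE+qp** replaces the integer seeds by *fitted* per-atom-type initial
charges $q_p$. Since a sum of per-type values need not equal the molecular
charge $Q$, the seed vector is first shifted uniformly:

$$q_p^{norm} = q_p - \tfrac{1}{N}\left(\mathbf{1}^\top q_p - Q\right),$$

with $N$ the atom count, and then enters the SQE+q0 system as $q_0$. This
gives the model freedom to place fractional seed charge on chemically
distinct types — valuable for homogeneous datasets such as peptides, where
plain SQE and SQE+q0 have little leverage.

A sign convention worth recording: with the systems as printed above, the
equivalent energy being minimized in bond space is
$E(q_{sp}) = -\chi^\top q + \tfrac12 q^\top H q + \tfrac12\sum_b \kappa_b
p_b^2 - (\eta * q_0)^\top (q - q_0)$ — electronegative atoms *attract*
charge. The test suite verifies each solver against direct numerical
minimization of this energy.

## Atom and bond types

Parameters are shared within atom types. Three classifiers are provided:

* `plain` — the element symbol (`"O"`);
* `hbo` — element plus the highest order among the atom's bonds
  (`"C/2"` for a carbonyl carbon, `"O/1"` for a hydroxyl oxygen);
* `ba` — element plus the lexicographically sorted elements of all bonded
  atoms (`"C/CCCH"`, `"O/CH"`), a finer scheme suited to homogeneous
  datasets where each type still retains many atoms.

Bond types combine the two endpoint atom types (stored in sorted order, so
they are direction-independent) with the integer bond order. Aromatic
(order 4) molfile bonds are rejected rather than kekulized on the fly:
guessing orders would silently change HBO types. Isolated atoms are
labelled `El/1` under HBO and by the bare element under BA — the fitting
datasets contain none, but a defined fallback beats an exception.

## Quality metrics and the objective

For each molecule, $R^2$ (squared Pearson correlation) and RMSD between
empirical and reference charges are computed and averaged over molecules
with equal weight. The per-type RMSD pools all atoms of one atomic type
across the dataset — pooling, rather than per-molecule averaging, is the
only definition that keeps the statistic meaningful for rare types — and
$\mathrm{RMSD}_{at}$ is the largest of them, i.e. the worst-described atom
class. The fitting objective is

$$\text{objective} = \underbrace{\overline{\mathrm{RMSD}}_{\text{molecules}}}_{\text{equal molecule weight}}
 + \underbrace{\overline{\mathrm{RMSD}}_{\text{types}}}_{\text{mean over types}},$$

which pressures both overall accuracy and the worst types. Molecules whose
charge vectors are constant (undefined correlation) are excluded from the
$R^2$ average only, with a warning; they still count toward RMSD.

## Parameterization engines

Both engines are guided minimization: random multistart inside box bounds
followed by local refinement.

* **GDMIN** scores every initial sample on the full training set, then
  runs bounded local minimization from the best few.
* **optGM** scores a much larger initial sample on a small molecule subset
  that still contains at least `nmin` atoms of every atomic type
  (greedily selected, deterministic), rescores only the top `n_refine`
  candidates on the full training set, and locally refines the best
  `n_local`. The subset stage makes each initial evaluation cheap, so the
  parameter space — much larger for SQE-family methods, which add one
  parameter per bond type — can be covered far more densely for the same
  cost. With the subset equal to the full set and equal budgets, optGM's
  candidate ranking reduces exactly to GDMIN's.

Design choices that were genuinely open:

* **Local optimizer.** The objective is smooth almost everywhere (linear
  solves composed with RMSDs), so the local stage uses bounded L-BFGS-B
  with finite-difference gradients rather than a simplex search: box
  constraints are native and convergence is much faster at these
  dimensions (10–40 parameters). Near a perfect fit the square root in
  RMSD has unbounded curvature, which stalls quasi-Newton steps at the
  default differencing step; a second, reduced-step *polish* pass from the
  best candidate (`polish = TRUE`, step `1e-5`) recovers the remaining
  order of magnitude. Parameter vectors whose linear systems fail or go
  non-finite score a large finite penalty during refinement and are
  discarded from ranking.
* **Sampling bounds** default to $\chi \in [0,5]$, $\eta \in [0.1,5]$,
  $\kappa \in [0.1,5]$, $q_p \in [-1,1]$ — wide enough to bracket
  physically sensible electronegativity/hardness scales under the 1/r
  kernel, recorded in every fit's metadata, and overridable.
* **Budgets** (`n_samples` 500 for GDMIN vs 10 000 for optGM, `n_refine`
  50, `n_local` 5, `nmin` 50) are configuration, not science; every fit
  records its budget, seed and bounds for reproducibility.
* **Stratified 80/20 split.** Molecules are shuffled under the given seed
  and assigned to the test set only while every atom type keeps at least
  one training occurrence, so every type is trainable. Molecules are
  weighted equally (not by atom count) in all averages, consistent with
  the metric definitions.
* **Determinism.** Every randomized entry point takes an explicit seed;
  ranking ties break by sample index, so results are independent of
  evaluation order.

## Synthetic fixtures: what they do and do not show

`generate_molecules()` builds connected, valence-plausible random graphs
(spanning trees with occasional ring closures), embeds them in 3D at
covalent bond lengths (pairwise distances kept above 0.5 Å), and
optionally protonates a nitrogen or deprotonates an oxygen to emulate the
charge states of peptide-like molecules. The defaults emulate the small
heteroorganic regime (4–10 atoms, H/C/N/O); `preset = "peptide"` switches
to an H/C/N/O/S alphabet at 20–40 atoms, mimicking di- and tripeptides.
`generate_reference_charges()` produces charges from a *known* parameter
set, optionally with Gaussian noise, so parameter recovery can be measured
against ground truth: at $\sigma = 0$ both engines should reach a
near-zero objective, and the test suite requires $< 10^{-3}$.

These fixtures validate the machinery — solvers, typing, metrics,
optimization — not chemistry. Real QM charges are not generated by any
member of the model family, carry systematic (not i.i.d. Gaussian)
deviations, and real datasets have far more heterogeneous type
distributions. Passing recovery tests therefore demonstrates correctness
and optimizer adequacy, not the accuracy any method will achieve on real
molecules.

## Numerical choices

* Linear systems are solved by dense direct factorization; bond-space
  dimensions stay in the hundreds for all intended inputs, so robustness
  beats sparsity. User-facing solves guard with a reciprocal-condition
  estimate ($< 10^{-12}$ raises a typed numerical-failure error naming the
  molecule); the fitting loop instead treats failures as infinite
  objective values.
* Coincident atoms (zero interatomic distance) raise a typed
  degenerate-geometry error before any solve.
* All-pairs interaction, no cutoff or periodicity: the intended inputs
  are isolated small molecules.
* An SQE-family solve on a molecule with no bonds returns the seed vector
  (zeros for plain SQE), consistent with each method's conservation law.

## Worked example

```{r example}
mols <- generate_molecules(fixture_spec(n_molecules = 30, seed = 1))
registry <- build_registry(mols, "hbo")
truth <- example_params(registry, "sqe", seed = 2)
ref <- generate_reference_charges(mols, truth, noise_sigma = 0.02, seed = 3)

split <- split_train_test(mols, 0.8, seed = 4)
fit <- optgm(split$train, ref, "sqe", "hbo", seed = 5,
             config = fit_config(n_samples = 60, n_refine = 10,
                                 n_local = 2, nmin = 20,
                                 local_maxit = 25, polish = FALSE))
glance(fit)

test_charges <- compute_charges(split$test, fit$params)
report <- dataset_metrics(split$test, test_charges, ref, "hbo")
glance(report)
```

```{r plot, fig.width = 6, fig.height = 4}
plot_correlation(
  correlation_graph_data(split$test, test_charges, ref, "hbo"))
```

The problem sizes above (tens of molecules, desk-scale optimizer budgets)
are chosen so the vignette and test suite run in minutes; the same code
scales to thousands of molecules by raising `n_samples`, `nmin` and
`local_maxit`.

## Limitations

* The exact interaction kernel used by other published implementations is
  not always documented; parameter sets fitted elsewhere transfer only if
  the kernel convention matches (the per-type parameters here assume
  diagonal $\eta$, off-diagonal $1/r$, ångström units). Quality metrics
  computed with mismatched conventions will be systematically off.
* The EQeq baseline implements the charged-atom-reference expansion over
  the shared kernel; published EQeq variants with orbital-overlap
  corrections will differ.
* V2000 molfiles only, explicit integer bond orders, no bond perception
  from geometry, no V3000, no periodic systems, no fragment charge
  constraints.
* The 80/20 split is a single stratified split; no cross-validation.
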