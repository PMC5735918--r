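---
title: "Normal-mode sampling: method, conventions and design choices"
author: "nmsgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normal-mode sampling: method, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmsgen)
```

## The problem

Machine-learned interatomic potentials need training data that covers not
just equilibrium molecular geometries but the off-equilibrium region a
simulation actually visits. Normal-mode sampling (NMS) is a cheap,
embarrassingly parallel way to build such data: starting from an
energy-minimized geometry and its harmonic normal modes, it draws random
thermally-scaled displacements along the modes and evaluates a single-point
energy at each displaced geometry, producing a "window" of the potential
energy surface around each minimum.

`nmsgen` implements the full pipeline around that idea: vibrational
analysis of a Cartesian Hessian, the thermal displacement draw, per-size
sampling schedules, energy-window curation, an HDF5 dataset format with
separate low- and high-energy blocks, and the coverage statistics used to
check that the sampled data actually widens conformational coverage. The
quantum-chemistry stages that normally surround NMS (geometry optimization
and DFT single points) are deliberately out of scope; they are replaced by
a calculator contract with analytic toy backends, so every stage runs and
is testable at desk scale.

## The sampling model

For a molecule of $N_a$ atoms with $N_f$ vibrational degrees of freedom
($3N_a-5$ if linear, $3N_a-6$ otherwise), the vibrational analysis yields
normal modes $\hat q_1,\dots,\hat q_{N_f}$ and force constants
$K_1,\dots,K_{N_f}$. One conformer is drawn as follows:

1. Draw weights $c_1,\dots,c_{N_f} \ge 0$ with $\sum_i c_i \le 1$. Each
   $c_i$ is the fraction of the classical thermal energy
   $\tfrac32 N_a k_b T$ assigned to mode $i$.
2. Set the displacement magnitude along mode $i$ by equating the harmonic
   energy stored in that mode to the assigned thermal share:
   $$\tfrac12 K_i R_i^2 = c_i\,\tfrac32 N_a k_b T
   \quad\Longrightarrow\quad
   R_i = \sqrt{\frac{3\,c_i\,N_a\,k_b\,T}{K_i}}.$$
3. Draw an independent fair sign $s_i \in \{+1,-1\}$ per mode, so both
   sides of each well are sampled equally.
4. Displace the equilibrium geometry by the superposition
   $\sum_i s_i R_i \hat q_i$ and evaluate a single-point energy there.

Per molecule, $N = S \times N_f$ conformers are drawn, where $S$ (points
per degree of freedom) and the temperature come from a schedule keyed by
heavy-atom count. The shipped `default_schedule()` gives small molecules
many points at high temperature (S = 500 at 2000 K for one heavy atom)
and large molecules few points at moderate temperature (S = 5 at 450 K
for eight), which keeps the total dataset size and the per-molecule
coverage balanced.

Because $\sum_i c_i \le 1$ and the modes are energy-orthogonal on a
quadratic surface, the total energy rise of a draw is exactly
$\tfrac32 N_a k_b T \sum_i c_i \le \tfrac32 N_a k_b T$. This identity is
the backbone of the test suite: on the harmonic toy backend it must hold
to floating-point accuracy, and the bound can never be exceeded.

## Mode normalization: the one consequential convention

Quantum-chemistry packages differ in how they normalize normal modes
(Cartesian-normalized, mass-weighted-normalized, or reduced-mass-scaled),
and the force constant reported alongside a mode depends on that choice.
`nmsgen` fixes the convention explicitly:

* each mode $\hat q_i$ has **unit norm in plain Cartesian space**, and
* its force constant is **defined** as the quadratic form
  $K_i = \hat q_i^{\mathsf T} H \hat q_i$ (Ha/Å²).

With this pairing, a displacement $x\hat q_i$ of a quadratic surface has
energy exactly $\tfrac12 K_i x^2$, so the displacement formula above is
dimensionally consistent ($K_i$ in Ha/Å², $R_i$ in Å) and the thermal
identity holds by construction, whatever produced the Hessian. A pipeline
that ingests externally computed modes and force constants
(`read_modes_files()`) must supply constants consistent with this
convention; constants defined against mass-weighted or reduced-mass
normalized modes differ by per-mode mass factors and would bias every
$R_i$.

## Vibrational analysis details

`normal_mode_analysis()` mass-weights the Hessian, projects out rigid-body
motion with an orthonormal basis built from the three translations and the
two or three infinitesimal rotations (rank-detected by QR, so linear
molecules lose exactly one rotation), diagonalizes the projected matrix
and keeps the $N_f$ largest eigenvalues. Numerical choices:

* **Linearity** is decided geometrically: smallest principal moment of
  inertia below $10^{-8}$ (relative) times the largest. The flag can be
  forced; a mismatch between the flag and the detected rigid-body rank is
  an error rather than a silent reinterpretation.
* **Degenerate eigenvalues** are returned in the deterministic order of
  the symmetric eigensolver, and every mode's sign is fixed by making its
  first component of magnitude above $10^{-8}$ positive, so repeated runs
  and platforms agree.
* **Imaginary modes** ($K_i \le 0$, as produced by saddle points) are an
  error by default because the displacement magnitude is undefined for
  them. `allow_imaginary = TRUE` drops them with a warning and samples
  the remaining modes — the pragmatic choice when a dataset keeps
  saddle-point geometries whose true minimum was never found.
* The largest surviving rigid-body eigenvalue is reported as
  `projection_residual`; on the shipped analytic Hessians it is at the
  $10^{-16}$ level and the tests require it below $10^{-6}$ of the largest
  vibrational eigenvalue.

## The weight draw: an under-determined corner

The only hard constraints on the weights are $c_i \ge 0$ and
$\sum c_i \in [0,1]$; the joint law is otherwise a design choice. The
default (`"simplex"`) normalizes $N_f$ i.i.d. uniforms to unit sum and
scales by one further independent uniform, so the total assigned fraction
is itself uniform on $[0,1]$ for every $N_f$ and the per-mode weights are
exchangeable. The alternative (`"rejection"`) redraws $N_f$ i.i.d.
uniforms until their sum is at most 1; it has heavier per-mode tails but
becomes astronomically wasteful beyond a handful of modes, which is why
it is not the default. Both schemes are seed-reproducible and selectable
per call (`weight_scheme`).

Temperature is similarly under-determined: the schedule stores a *maximum*
temperature. `temperature_mode = "fixed_at_max"` (default) draws every
conformer at $T_{\max}$; `"uniform_up_to_max"` draws a fresh
$T \sim U(0, T_{\max}]$ per conformer. The fixed mode is the default
because the thermal-energy bound and the identity tests are sharpest
there; both modes are reproducible under the same seed.

The equilibrium geometry is stored alongside the sampled conformers but
is **not** counted inside $N = S \times N_f$.

## Failure handling and curation

Single-point evaluations can fail (the SCF analogue); a failure is a typed
result, not an exception. Failed conformers stay in the `conformer_set`
with status `"energy_failed"` and `NA` energy, are excluded from every
exported array, and are counted in the pipeline's exclusion report. The
report reproduces retention arithmetic exactly:
`exclusion_report(485, 57947)` gives 57,462 retained and a 0.84 % failure
rate (percentages rounded half-even to two decimals).

Energy-window curation splits each molecule's conformers at a fixed energy
above the set's minimum (default 275 kcal/mol, converted internally to
Hartree). Conventions, each encoded and tested:

* the boundary is **inclusive**: a conformer exactly at the threshold
  stays low (only strictly greater energies are removed);
* the reference minimum **includes the equilibrium energy** by default
  (the equilibrium structure is a conformer of the set); a switch
  excludes it, and re-curation of an on-disk record — which no longer
  knows the equilibrium — always uses the conformer minimum;
* the window is relative, so it is invariant under any constant energy
  shift, and the split is a true partition (low + high = ok conformers,
  always).

## The dataset format

Records are written one HDF5 group per molecule, `gdb<NN>/mol<i>` with
`NN` the zero-padded heavy-atom count, holding datasets `coordinates`,
`energies`, `species`, `coordinatesHE`, `energiesHE` and `smiles`. A
C-order reader sees coordinates as `(conformers, atoms, 3)`. Coordinates
are stored as 32-bit floats — the practical precision of Cartesian
geometries — while energies stay 64-bit: a 275 kcal/mol (0.44 Ha) window
sits on total energies of order $10^2$ Ha, and float32's ~7 significant
digits would corrupt the split. Both dtypes are overridable. Empty HE
blocks are written with explicit zero extent rather than omitted, so
shape invariants hold for every record. Reads are lexicographic in group
path (deterministic), validate the shape invariants, and offer a lenient
mode that skips malformed groups with a warning for foreign files.

## Coverage statistics

The validation statistics tally, over every conformer: pair distances
normalized by a reference single-bond length $r_0$ (per element pair,
user-supplied — recomputing $r_0$ ab initio is out of scope), internal
angles at a central atom (default restricted to "bonded" triples within
$1.6\,r_0$ of the center, with an all-triples mode), total energy per
electron (grouped by heavy-atom count, each group normalized to unit
area), and atomization energy against a per-element reference table.
Histograms report raw counts plus $\log_{10}$ of domain-normalized
counts; empty bins are omitted from the log series (`NA`), never clamped
to a floor value. Pair tallies can be Bernoulli-subsampled at a seeded
rate, mirroring how a $10^7$-conformer dataset is thinned (1 % in the
reference analysis); the subsampled total is Binomial and tested within
4σ. The qualitative claim that matters — off-equilibrium sampling
strictly widens the occupied support relative to an equilibrium-only
dataset — is asserted on toy data via `histogram_support()`.

## What the synthetic generator emulates — and what it does not

`build_synthetic_dataset()` runs the whole pipeline on randomized toy
molecules: four templates (water-like bent triatomic, CO-like heavy
diatomic, linear symmetric triatomic, methane-like tetrahedral) with
bond lengths jittered ±3 % and spring constants ±20 %, analytic Hessians
rebuilt at the jittered geometry, the published sampling schedule, and
either the harmonic or the Morse backend. Hessians are sums of
internal-coordinate rank-1 terms $k\,g g^{\mathsf T}$ (bond-stretch and
angle-bend gradients at equilibrium), which makes them exactly
translation- and rotation-invariant and, for the equal-mass diatomic,
gives the closed-form stretch constant $K = 2k$ used as the analysis
oracle.

What this emulates: the sampling statistics, the failure/exclusion
bookkeeping, the curation arithmetic, and the file format — every
quantity the tests assert. What it does not: chemical realism. Toy
surfaces have no anharmonic mode coupling (harmonic backend) or only
pairwise anharmonicity (Morse backend), molecule sizes stop at five
atoms, and reference energies are synthetic. Passing tests therefore
demonstrate the correctness of the machinery, not the physical fidelity
of any particular dataset built with it; with the harmonic backend and
the default 275 kcal/mol window the high-energy partition is *provably*
empty (the thermal bound for the largest toy is ~30 kcal/mol), so
anharmonic tails only appear under the Morse backend or a narrowed
window.

## Numerical tolerances used in the tests

* Thermal-energy identity: deviation below $10^{-9}$ **relative to the
  thermal scale** $\tfrac32 N_a k_b T$ of the draw. Dividing by the
  per-draw prediction itself would only probe the floating-point
  cancellation floor of $E - E_{\mathrm{ref}}$ as $\sum c_i \to 0$
  (reference energies are $\mathcal O(10^2)$ Ha while rises can be
  $10^{-12}$ Ha); measured deviations sit near $2\times10^{-12}$.
* Closed-form force constants: $10^{-8}$; rigid-body residuals:
  $10^{-6}$ of the largest vibrational eigenvalue.
* Monte-Carlo checks run at fixed seeds with 3σ bands (4σ for the
  subsampling binomial): $10^5$ draws for the weight-sum mean, sign
  fairness and the energy bound, $10^4$ for the energy identity. These
  sizes make the whole suite run in well under a minute while leaving
  the bands an order of magnitude wider than the standard errors.
* Exact-boundary curation cases anchor the set minimum at 0 Ha so the
  relative energy at the threshold is bit-exact.

## Known limitations

* Force constants ingested from external normal-mode files must already
  follow the Cartesian-unit-norm convention; no conversion from
  reduced-mass conventions is attempted.
* The HDF5 reader's lenient mode is best-effort: it tolerates missing HE
  blocks and SMILES and skips malformed groups, but does not attempt to
  guess alternative group hierarchies or dtypes.
* Angle "bondedness" is a fixed distance cutoff ($1.6\,r_0$), not a bond
  perception; there is no SMILES parsing anywhere — SMILES strings are
  opaque metadata.
* Isotopes are not handled beyond the single standard-atomic-weight
  table, and sampling a molecule with fewer usable modes than $N_f$
  (dropped imaginary modes) simply samples the remaining ones.
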