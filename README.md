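# nmsgen

Normal-mode-sampling conformer generation and curation for building
machine-learning potential training datasets in R.

## The problem

Machine-learned interatomic potentials are only as good as their training
data, and equilibrium-only datasets leave the off-equilibrium region — the
part a molecular simulation actually visits — unsampled. **Normal mode
sampling (NMS)** fills that gap cheaply: starting from an energy-minimized
geometry with normal modes $\hat q_i$ and force constants $K_i$
($i = 1,\dots,N_f$, with $N_f = 3N_a-5$ for linear molecules and $3N_a-6$
otherwise), it draws random thermally scaled displacements

$$R_i = \pm\sqrt{\frac{3\,c_i\,N_a\,k_b\,T}{K_i}},$$

where the weights $c_i \ge 0$ satisfy $\sum_i c_i \le 1$ (so each $c_i$ is
the fraction of the classical thermal energy $\tfrac32 N_a k_b T$ assigned
to mode $i$), the sign is a fair Bernoulli draw, and the new conformer is
the equilibrium geometry displaced by the superposition
$\sum_i s_i R_i \hat q_i$. Per molecule, $N = S \times N_f$ conformers are
drawn, with $S$ and $T$ taken from a schedule keyed by heavy-atom count.

`nmsgen` implements the full pipeline for dataset builders:

* **vibrational analysis** of a Cartesian Hessian (mass-weighting,
  rigid-body projection, Cartesian-unit-norm modes with
  $K_i = \hat q_i^{\mathsf T} H \hat q_i$, so $\tfrac12 K_i x^2$ is exact
  by construction);
* **the sampler** above, with the published 1–8-heavy-atom schedule as
  default, seeded per-molecule streams, and pluggable single-point
  backends (analytic harmonic and Morse toys, plus an external-command
  contract) whose failures are typed and excluded like non-converged SCF
  points;
* **energy-window curation** (default 275 kcal/mol above each molecule's
  minimum, inclusive boundary) and the dataset bookkeeping/exclusion
  arithmetic;
* **an HDF5 record format** — one group per molecule holding
  `coordinates`/`energies`, the high-energy `coordinatesHE`/`energiesHE`
  split, `species` and `smiles` — readable from any C-order HDF5 stack as
  `(conformers, atoms, 3)` float32 coordinates with float64 energies;
* **coverage statistics**: $r/r_0$ pair-distance histograms (with seeded
  Bernoulli subsampling), angle distributions, energy-per-electron and
  atomization-energy distributions, all as log10-normalized histograms.

A synthetic-data module ships toy molecules with analytic
internal-coordinate Hessians, so everything runs and is testable without
any quantum-chemistry package.

## Worked example

Sample a window around a toy "water" molecule on its exact harmonic
surface, then curate it with a deliberately narrow 5 kcal/mol window:

```r
library(nmsgen)

toy <- toy_molecule_library()$water
nm  <- normal_mode_analysis(toy$molecule, toy$hessian)
nm
#> <normal modes of water: 3 modes, K in [0.2955, 0.5211] Ha/A^2>

calc <- harmonic_calculator(toy$molecule, toy$reference_energy, toy$hessian)
cs <- sample_window(toy$molecule, nm, default_schedule(), calc, seed = 1)
summary(cs)
#> conformer set water: 1500 drawn, 1500 ok
#> energy above equilibrium (kcal/mol):
#>      Min.   1st Qu.    Median      Mean   3rd Qu.      Max. 
#>  0.002088  4.804262  8.972319  9.072893 13.474145 17.862436 

rec <- as_ani_record(energy_window_split(cs, curation_config(threshold_kcal = 5)))
rec
#> <record water: 3 atoms, 388 conformers + 1112 high-energy>
```

The 1,500 conformers are $S \times N_f = 500 \times 3$ (the schedule row
for one heavy atom: $S = 500$, $T_{\max} = 2000$ K). Every energy rise is
at most $\tfrac32 N_a k_b T_{\max} \approx 17.9$ kcal/mol because
$\sum c_i \le 1$ — the observed maximum sits right at that bound. With the
default 275 kcal/mol window the high-energy block would be empty; at
5 kcal/mol, 1,112 conformers move to the HE arrays.

The end-to-end generator runs sampling, curation and HDF5 export over
randomized toy molecules and prints the bookkeeping table:

```r
out <- build_synthetic_dataset(n_molecules = 8, seed = 1, backend = "morse",
                               path = "dataset.h5")
out$summary
#>  heavy_atoms molecules t_max   S    low high  total
#>            1         5  2000 500 19,500    0 19,500
#>            2         2  1500 450    900    0    900
#>            3         1  1000 425  1,700    0  1,700
#>        Total         8    NA  NA 22,100    0 22,100
```

A thin CLI wraps the same functions:

```sh
nmsgen demo --seed 1 --out demo_dir
nmsgen summarize --in demo_dir/dataset.h5
nmsgen stats --in demo_dir/dataset.h5 --stat dist --pair H,O --r0 0.96
```

(after installation the script lives at
`system.file("exec", "nmsgen", package = "nmsgen")`).

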