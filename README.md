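# saxsmod

Small-angle X-ray scattering (SAXS) curve analysis and low-resolution
hybrid modeling for homodimeric multi-domain proteins, in R.

The package is aimed at structural biologists characterizing a two-domain
homodimer in solution — the motivating system is the intracellular region
of a CNNM-family magnesium transporter, where a disk-shaped
nucleotide-sensing (CBS) module pair and a cyclic-nucleotide-homology
domain pair sit on a shared two-fold axis, joined by disordered linkers
and C-tails. From a 1D profile `I(q)` (q = 4π sin θ / λ) it extracts the
standard structural parameters and builds bead-level 3D models:

* **Primary analysis** — Guinier fit (`ln I` vs `q²` over q·Rg ∈ [0.3, 1.3])
  giving Rg and I(0); indirect Fourier transform to the pair-distance
  distribution P(r) with automatic smoothness regularization and Dmax
  selection; Porod invariant Q = ∫q²I dq, Porod volume 2π²I(0)/Q,
  power-law exponent, and molecular mass (0.58 kDa per nm³) with the
  oligomeric-state ratio; dimensionless Kratky transform
  (qRg)²·I/I(0) — an ideal globular particle peaks at (√3, 1.104).
* **Forward scattering** — the Debye sum
  I(q) = ΣᵢΣⱼ fᵢfⱼ sin(q·rᵢⱼ)/(q·rᵢⱼ) from bead or atomic models
  (histogram-accelerated, exact path for reference) and reduced-χ² fitting
  with optimal scaling.
* **Ab initio shape reconstruction** — simulated annealing of a
  chain-compatible dummy-residue model against the curve; ensemble
  alignment, outlier filtering and occupancy-grid averaging under the
  normalized spatial discrepancy (NSD).
* **C2-symmetric assembly search** — places two homodimers on a shared
  2-fold axis, scans the rotation φ about the axis and the axial
  separation t, excludes clashes, gates candidates by reduced χ² and
  breaks near-ties by morphological complementarity (buried interface
  area minus a near-clash penalty); three scenarios (both dimers rigid,
  or either partner's subunit free).
* **Linker completion** — disordered linkers/tails grown as steered
  self-avoiding dummy-residue chains, C2-mirrored across protomers, the
  completed model selected by χ² against the curve.
* **Synthetic data** — ground-truth toy structures (spheres, dumbbells,
  two-domain C2 dimers with a twisted/flat conformational switch) and
  SEC-SAXS-like noisy curves (σ = 0.02·I + 0.001·I(0)) for end-to-end
  parameter-recovery testing.

## Worked example

Simulate a noisy curve from a known C2 dimer, recover its parameters, and
re-find the true rigid-body placement:

```r
library(saxsmod)

spec  <- toy_spec("two_domain_c2_dimer", twist = 0)
model <- generate_structure(spec)
ds    <- simulate_curve(model, noise = noise_spec(seed = 1))

g <- guinier_fit(ds$noisy)
g
#> <guinier_result> Rg = 41.00 +/- 0.47 A, I0 = 9.668e+05
#>   window q = 0.0081..0.0317 (q*Rg 0.33..1.30), R^2 = 0.9858, n = 30

cv <- ds$noisy; cv$window <- c(0.004, 0.16)   # low-q window for inversion
fd <- find_dmax(cv, guinier = g)
fd$Dmax
#> [1] 103.9992
fd$pr
#> <pair_distribution> Dmax = 104.0 A, Rg = 40.39 A, I0 = 9.607e+05
#>   alpha = 1, back-transform chi2 = 0.812

p <- porod_analysis(ds$noisy, g)
p
#> <porod_result> V = 59.2 nm^3, exponent = 0.89, MW = 34.3 kDa (0.58/nm^3)
```

The generator's true values are Rg = 40.6 A, a maximum pair distance of
120.7 A, and a bead-fill volume of 63 nm^3. The recovered Rg (both
estimates within 1%) and Porod volume (within 6%) match; the reported
Dmax sits below the geometric maximum because the extreme pair distances
of a blocky dimer carry almost no P(r) mass at this noise level. The low
exponent readout illustrates a documented limitation: for a particle this
elongated the fixed q-Rg fitting window samples the intermediate
(rod-like) regime rather than the asymptotic interface regime, so the
exponent is interpretable for compact particles only (see the methods
vignette).

A rigid-body search against that curve, using the two dimers as separate
bodies placed at rotation 40 degrees and 34 A separation:

```r
comp  <- toy_dimer_components(toy_spec("two_domain_c2_dimer", n_beads = 150, seed = 3))
truth <- place_components(comp$upper, comp$lower, phi = 40, t = 34)
qg    <- seq(0.01, 0.35, length.out = 80)
sim   <- simulate_curve(truth, qg, noise_spec(0.01, 1e-4, seed = 5))
cands <- enumerate_assemblies(comp$upper, comp$lower, sim$noisy, t_range = c(26, 46))
head(cands, 3)
#>   phi  t      chi2    scale clash_count
#> 1  40 34 0.9170112 1.000264           0
#> 2  30 35 1.2414131 1.001420           0
#> 3  35 35 1.4778404 1.001594           0
```

The best candidate is the exact truth placement with χ² ≈ 0.92.

A command-line front end over the same functions is installed at
`inst/cli/saxsmod.R` (subcommands `simulate`, `guinier`, `pr`, `porod`,
`kratky`, `report`, `beads`, `assemble`, `linkers`).

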