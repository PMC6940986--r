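---
title: "Methods: SAXS curve analysis and C2-symmetric hybrid modeling"
author: "saxsmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SAXS curve analysis and C2-symmetric hybrid modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsmod)
```

# Scope and model

`saxsmod` analyses one-dimensional small-angle X-ray scattering profiles
$I(q)$, $q = 4\pi\sin(\theta)/\lambda$, of dilute monodisperse protein
solutions, and reconstructs low-resolution models of two-domain homodimers
such as the intracellular region of a CNNM-family magnesium transporter: a
disk-shaped nucleotide-sensing (Bateman/CBS) module pair and a
cyclic-nucleotide-homology domain pair stacked on a shared two-fold axis,
joined by disordered linkers and tails. The pipeline covers

1. primary curve analysis — Guinier $R_g$ and $I(0)$, the pair-distance
   distribution $P(r)$ with $D_{max}$, Porod invariant/volume/exponent,
   molecular mass and oligomeric state, dimensionless Kratky transform;
2. forward scattering from coordinate models through the Debye sum and
   reduced-$\chi^2$ fitting to data;
3. ab initio dummy-residue (one bead per residue) shape reconstruction by
   simulated annealing, with ensemble alignment/averaging under the
   normalized spatial discrepancy (NSD);
4. a C2-symmetric rigid-body search over the relative rotation and axial
   separation of the two dimers, in three scenarios (both dimers rigid, or
   either partner free), gated by $\chi^2$ and tie-broken by morphological
   complementarity;
5. completion of the assembly with self-avoiding dummy-residue linkers and
   tails selected against the curve;
6. a synthetic-data generator that produces ground-truth toy structures and
   SEC-SAXS-like noisy curves so each stage is testable without downloads.

All lengths are in Angstrom, $q$ in 1/Angstrom, volumes are reported in
nm^3 (1 nm^3 = 1000 A^3), masses in Da or kDa; intensities are in arbitrary
units throughout, since deposited-curve unit conventions vary.

# Forward model

The Debye formula gives the orientation-averaged intensity of a particle of
$N$ point scatterers with weights $f_i$:
$$I(q) = \sum_{i}\sum_{j} f_i f_j \,\frac{\sin(q r_{ij})}{q r_{ij}}.$$
Bead weights are uniform ($f=1$): the modeling here is shape-level, so
relative profiles are all that matters, and per-residue electron counts,
hydration-layer contrast and excluded-volume terms (as in full atomic
predictors) are deliberately omitted. This is the package's main
simplification; absolute intensities and contrast-sensitive features are
out of scope. The default evaluation path aggregates pairs into a distance
histogram (0.1 A bins, evaluated at the per-bin weighted mean distance),
which agrees with the exact double sum to better than one part in $10^6$;
the exact path remains available and is the reference in the tests.

Model-to-data comparison uses the weighted optimal scale
$c = \sum I_m I_d/\sigma^2 \big/ \sum I_m^2/\sigma^2$ and the reduced
$\chi^2 = \frac{1}{N-1}\sum \left((c I_m - I_d)/\sigma\right)^2$. No
constant background is fitted at this stage. The acceptance thresholds used
later (2 for the single construct, 2.5 for phosphatase complexes) are
interpreted on this reduced scale.

# Guinier analysis

$\ln I$ is regressed on $q^2$ with weights $(I/\sigma)^2$ over the largest
contiguous window with $q R_g \in [0.3, 1.3]$, iterating the window from an
initial guess (first ten points) to self-consistency. One refinement was
found necessary: for compact globular shapes the exact curve bends below
the Guinier line well inside $qR_g < 1.3$, and fitting straight through
that curvature inflates $R_g$ by 1–2% (for a homogeneous sphere the
closed-form curve fitted to $qR_g = 1.3$ returns $R_g$ 2% high). After
convergence the high-q end of the window is therefore trimmed while a
$q^4$ term in the fit is statistically significant (|t| > 3) *and* shifts
$R_g$ by more than 0.5%. On noisy experimental-like data the curvature is
rarely significant, the full window is kept, and the reported $sR_g$
limits reach 1.30 as in published tables; on noiseless synthetic shapes
the trim recovers sphere $R_g$ to better than 1%.

# Pair-distance distribution

With the convention $P(r) = \gamma(r) r^2$,
$$I(q) = 4\pi \int_0^{D_{max}} P(r)\,\frac{\sin qr}{qr}\,dr,$$
discretized on 101 r-points. The inversion minimizes the
$1/\sigma$-weighted residual plus $\alpha$ times the sum of squared second
differences, subject to $P \ge 0$ and $P(0)=P(D_{max})=0$ (solved by
non-negative least squares on the augmented system). $\alpha$ is chosen at
the corner of the ($\chi^2$, roughness) L-curve over a log grid
$10^{-4}\ldots10^2$ — the farthest point from the chord in log-log
coordinates. Moments give $R_g^2 = \int r^2 P\,dr / (2\int P\,dr)$ and
$I(0) = 4\pi\int P\,dr$; these agree with the Guinier estimates within 3%
on noiseless compact shapes.

## Choice of Dmax

$D_{max}$ is scanned over $[2R_g, 4R_g]$ in 2 A steps with the
regularization weight fixed across the scan. Each candidate records the
back-transform $\chi^2$, the negativity of the corresponding unconstrained
solution, a roughness measure, and a *truncation indicator*: the fraction
of $P$ mass in the last 5% of the r-range. A too-small $D_{max}$ crams the
genuine tail into a kink at the endpoint (large indicator); a sufficient
$D_{max}$ lets $P$ die off naturally. The selected value is the smallest
$D_{max}$ whose $\chi^2$ has reached the scan plateau (within 5% or +0.1)
and whose truncation indicator is below 5% — the automated version of the
operator's trial-and-error search for the smoothest strictly positive
distribution. A composite score
($\chi^2 + 10\cdot\text{negativity} + \text{roughness}$) is reported per
candidate for inspection; it is not used for selection because the
unconstrained-solution negativity rises steadily with $D_{max}$ (ridge
ringing in the spurious tail) and an arg-min over it lands 10–20 A short
on elongated shapes.

A caveat the synthetic benchmarks make explicit: the extreme pair
distances of a blocky dimer carry almost no $P(r)$ mass, so at realistic
noise the recoverable $D_{max}$ sits 5–10 A below the geometric maximum
distance no matter the estimator. Tests therefore hold sphere and dumbbell
recovery to ±1–2 grid steps but the noisy-dimer median to 10 A.

# Porod analysis

The invariant $Q = \int_0^\infty q^2 I\,dq$ is assembled from the Guinier
extrapolation below the first measured point, the trapezoid over the data,
and an analytic $q^{-4}$ tail beyond the last point. A flat background
estimated from a high-q $I = Kq^{-4} + B$ fit is subtracted first; for
discrete bead models this removes the constant self-term $\sum f_i^2$
(which would otherwise inflate $Q$ and shrink the volume by ~20%), and for
ideal continuous curves $B \approx 0$. The Porod volume is
$V = 2\pi^2 I(0)/Q$ and the molecular mass uses the empirical rule
0.58 kDa per nm^3; the coarser "half the Porod volume in A^3, read as Da"
heuristic is reported alongside but never mixed in. The mass ratio against
the protomer sequence mass (average residue masses plus one water) yields
the oligomeric state, with a caution flag when the ratio is more than 0.35
from an integer.

The Porod exponent — 4 for sharp interfaces, lower for flexible chains —
is the log-log slope over $qR_g \in [2.5, 6.5]$, fitted on the means of
ten log-q bins. Binning mean intensities (not mean logs) keeps the
near-zero oscillation minima of compact particles from dragging the slope;
the window and bin count were validated against closed forms only
(homogeneous sphere 4, pure power laws $p$, ideal Gaussian coil 2), and
with a window ending at $qR_g = 6$ the exact sphere measures 3.64, which
is why the deeper 6.5 end is used.

# Dimensionless Kratky

$y = (qR_g)^2 I/I(0)$ against $x = qR_g$; an ideal globular particle
obeying the Guinier law peaks at $(\sqrt3, 3/e \approx 1.104)$, flexible
chains plateau near 2. The peak is located by parabolic interpolation
around the discrete maximum. Note that a homogeneous sphere evaluated with
its exact $R_g$ and $I(0)$ peaks at (1.61, 1.03), a few percent below the
ideal-curve constants — tests compare against the closed form, not the
idealized 1.104.

# Ab initio reconstruction

A chain-compatible dummy-residue model (3.8 A virtual bonds) is annealed
against the curve inside a search sphere of radius $D_{max}/2$ (hard wall
at 1.1 times that). Moves are single-bead Gaussian displacements (1 A);
the energy is $\chi^2$ plus 10 times the summed squared bond-length
deviation plus 10 per non-adjacent pair closer than 3 A. Cooling is
geometric (factor 0.9 per stage, 100 moves per bead per stage, at most 60
stages, early stop after 15 stages without improvement). The initial
temperature is 10 times the mean |dE| of fifty probe moves: anchoring it
to the per-move energy scale is what lets the schedule freeze within the
stage budget — tying it to the total starting energy (thousands of
$\chi^2$ units) leaves the final temperature far above the move scale and
the walk never orders. Runs are bit-reproducible for a fixed seed.

Independent runs are compared by NSD after superposition (principal-axis
sign enumeration refined by iterated nearest-neighbour/Kabsch steps,
optional inversion for chirality). Ensembles drop members whose mean NSD
exceeds the ensemble mean by two standard deviations, align survivors to
the most typical model, and report an occupancy-grid consensus (2 A
voxels, thresholded to the median single-model voxel count). No symmetry
is imposed inside the reconstruction; symmetric particles are
reconstructed whole.

# Symmetric rigid-body search

Both dimers must pass the two-fold test: the least-squares rotation
mapping one chain onto the other over common residues must be within 5
degrees of 180. Each body is then moved to a canonical pose (axis along
+z through the centroid, deterministic sign), making the two axes
collinear by construction — lateral offsets between the axes are not
searched, since a C2-symmetric assembly of two C2 dimers requires a single
shared axis. The search grid is the rotation $\phi \in [0°, 180°)$ of the
lower body (5° steps; $\phi$ and $\phi+180°$ are equivalent under C2) and
the axial separation $t$ from 5 A below to 25 A above axial contact (1 A
steps). Candidates with any inter-body pair closer than 3 A are
clash-flagged and excluded; survivors are ranked by reduced $\chi^2$ of
the combined Debye curve. In scenarios 2 and 3 one dimer is predefined and
a single free subunit of the other partner is scanned in orientation
(three angles, 30° default steps) and radial offset (2 A steps), its mate
generated by the predefined partner's C2 operation so candidates stay
exactly symmetric.

Searches against pseudo-symmetric partners often admit two rotation minima
(a rotamer pair); both are reported when they pass the gate and are at
least two grid steps apart. Ties within 0.2 in $\chi^2$ are ordered by
*morphological complementarity*, operationalized as the buried interface
area (Shrake–Rupley SASA, 960 sphere points per particle, 1.4 A probe,
3.5 A bead radii; buried = (SASA(A)+SASA(B)−SASA(A∪B))/2) minus 50 A^2 per
inter-body pair in the 3.0–3.5 A near-clash band. The criterion is named
in the literature but not defined; this operationalization is the
package's own.

# Linker and tail completion

Disordered segments — for the target construct a 33-residue interdomain
linker (residues 512–544) and a 45-residue C-tail (731–775) — are grown as
self-avoiding walks at 3.8 A per step, rejecting contacts below 3 A with
themselves or the rigid context. End-anchored chains draw growth
directions from a cone steered at the anchor, its half-angle narrowing
from 90° when slack (remaining contour over twice the gap) to 15° when
taut, and the final bead is solved on the circle satisfying both its bond
and the bond to the anchor, so accepted chains close exactly. Growth uses
per-step retries (30) on top of whole-chain rejection; pure whole-chain
rejection leaves 45-mers with vanishing acceptance. Protomer 2's chains
are the C2 images of protomer 1's, preserving the assembly's symmetry to
machine precision, and the best of an ensemble of completed models (by
$\chi^2$) is reported — single-conformer style, matching one deposited
model per condition rather than a flexibility ensemble.

# Synthetic data

Shapes are lattice fills (one bead per (4 A)^3 by default); the flagship
two-domain dimer stacks an upper pair of ellipsoidal blocks
(36 × 12 × 11 A semi-axes at 23 A from the axis) on a lower pair
(30 × 10 × 10 A at 18 A) separated by 62 A along the shared two-fold axis,
block 2 of each pair being the exact C2 image of block 1. These defaults
give $R_g \approx 40.6$ A — the scale of the real dimer — and
$D_{max} \approx 121$ A, shorter than the deposited constructs because the
disordered tails that extend the real particle are not part of the rigid
toy. The `twist` parameter swings each upper block about the vertical axis
through its own centre, emulating the twisted-vs-flat disk transition; at
the default noise the 0° and 30° conformers separate by $\chi^2 \approx 3$.
Noise is Gaussian with $\sigma(q) = 0.02\,I(q) + 0.001\,I(0)$ — a
multiplicative term with a floor standing in for counting statistics,
reproducing the signal-to-noise decay of column-mode data well enough for
$\chi^2$-based testing. No interparticle or concentration effects are
simulated (the ideal-dilution assumption of inline chromatography), no
detector geometry, and no buffer-mismatch artifacts; conclusions from
passing tests therefore concern estimator correctness and recoverability,
not instrument systematics.

`make_benchmark_suite()` writes the fixed six-fixture set (sphere,
dumbbell, flat and twisted dimers, dimer with linkers, and a
two-rotation-minima case built on a pseudo-four-fold partner) with truth
tables; regeneration under one seed is byte-identical.

# Problem sizes and numerical choices

Test and example runs use desk-scale sizes chosen as representative rather
than exhaustive: curves of 50–512 points, bead models of a few hundred to
~2000 particles, 150-bead reconstructions, 36 × 21–31 assembly grids, and
20-replicate recovery studies. Degenerate inputs are handled explicitly:
all-zero curves invert to the zero distribution, collinear point sets fall
back to centroid alignment with a warning, non-dimeric inputs are rejected
by the axis test, an infeasible linker (anchor gap beyond the 3.8 A
contour) errors at specification time, and an annealing run ending above
the $\chi^2$ ceiling (5) is returned but flagged unconverged.

# Known limitations

* Uniform bead weights: no hydration shell or per-residue contrast, so
  absolute-scale and contrast-variation analyses are out of scope.
* The Guinier window trim targets compact shapes; strongly elongated
  particles still carry the usual low bias of Guinier $R_g$.
* $D_{max}$ is bounded by information content at realistic noise (see
  above); the reported value is the supported, not the geometric, maximum.
* Scenarios 2/3 scan coarse orientation grids; they rank hypotheses rather
  than refine poses.
* The complementarity score is a geometric proxy; no energetics.
* The Porod-exponent window is tied to $qR_g$ and calibrated on globular
  shapes; for strongly elongated particles ($R_g$ far above the
  cross-section radius) it samples the intermediate rod-like regime and
  reads well below 4 even for rigid bodies. Interpret it for compact
  particles, or refit over an explicit high-q window via the
  configuration.
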