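---
title: "Conformational energy landscapes from cryo-EM class ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational energy landscapes from cryo-EM class ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volscape)
```

volscape quantifies conformational heterogeneity in single-particle
cryo-EM of two-body complexes such as the 26S proteasome, where a mobile
regulatory particle (RP) rotates as a near-rigid body about the long axis
of a fixed core particle (CP). This vignette explains the models and
algorithms, the parameters that matter, what the synthetic phantom does
and does not emulate, and the numerical choices behind the defaults.

## The model

Extensive 3D classification of a heterogeneous particle set yields a large
number of class volumes, each an average over the particles assigned to
it. volscape treats those classes as samples of a conformational ensemble
in thermal equilibrium and proceeds in four steps.

**1. Fixed-subcomplex alignment.** Every class volume is rigidly aligned
to a reference using the normalised cross-correlation (NCC) computed only
inside a CP mask, so that all residual variability is attributed to the
mobile subcomplex. The search is an exhaustive grid over z-y-z Euler
angles (default ±6° in 2° steps) and integer voxel shifts, followed by
quadratic interpolation on the score grid and a Nelder-Mead polish of all
six rigid parameters. Trilinear interpolation is used for resampling;
it is accurate at phantom scale and swappable in principle.

**2. Eigenvolume PCA.** With the N masked, aligned, mean-centred volumes
as rows of a data matrix \(X\) (N × V voxels, N ≪ V), the decomposition
is computed from the N × N Gram matrix \(G = XX^\top\): if
\(G u_k = \lambda_k u_k\), the k-th eigenvolume is
\(v_k = X^\top u_k / \sqrt{\lambda_k}\) and class i has coefficient
\(c_{ik} = \sqrt{\lambda_k}\, u_{ik}\) — its "linear factor" along mode
k. The eigenvolumes are orthonormal over the analysis mask, eigenvalues
are reported in variance units, and with K = N − 1 the classes are
reconstructed exactly. The PCA is *unweighted*: particle counts play no
role in finding the modes and enter only the landscape. A count-weighted
variant is available behind the `weighted` flag. Volumes are
mean-centred but not variance-normalised, because rescaling volumes would
distort the occupancy geometry that the landscape step depends on. Each
eigenvolume's sign is fixed so that its largest-magnitude masked voxel is
positive; coefficients are therefore reproducible across runs and
platforms.

**3. Boltzmann inversion.** Each class carries a particle count
\(n_i\). Binning the classes on a 2D grid over a chosen coefficient pair
and applying Boltzmann's law gives the free energy of bin b,
\[
E_b = -k_BT \,\ln\!\left(\frac{n_b}{n_{\max}}\right),
\]
reported in units of \(k_BT\) (dimensionless), with the maximum-occupancy
bin as the zero point. An optional flag converts to kJ/mol at a stated
temperature. Empty bins are undefined (NaN) or, under a flag, capped at
the maximum defined energy + 1.

**4. Minima and barriers.** Minima are local minima of the defined bins
over 8-neighbourhoods. The barrier between the two lowest minima is the
*minimax path* value: bins are flooded in order of increasing energy and
the level at which the minima first become connected is the lowest
possible maximal energy along any connecting path; the barrier height is
that level minus the higher minimum. Disconnected minima yield an
infinite barrier, which is flagged rather than silently capped.

## The two-state classifier

The package also reproduces, at phantom scale, the negative-stain
counting experiment that measures how inhibitors shift the rotated /
non-rotated equilibrium: each particle image is aligned independently
against projection libraries of a rotated and a non-rotated reference and
assigned to the better-fitting one by full-image, zero-mean, unit-norm
NCC; after each of three iterations, new volumes are reconstructed from
the assigned particles by backprojection, low-pass filtered to the same
resolution, and normalised. Matching uses a quasi-uniform
Fibonacci-lattice viewing grid (default 15°) crossed with an in-plane
grid (default 10°), a continuous Nelder-Mead orientation polish per
particle and reference, and a ±3 px integer shift search via windowed FFT
cross-correlation. Exact score ties go to the non-rotated state.
Reconstruction is real-space backprojection with a 2D ramp (|f|)
pre-filter that compensates the 1/|f| sampling density of central
sections, normalised by a coverage map with a floor at 10% of its mean;
it is not a Fourier-gridded reconstruction, which limits fidelity at high
frequency and is the main fidelity limitation of this module.

**Known bias at skewed fractions.** With few particles in the minority
class, the minority reference is reconstructed from less data, and the
resulting quality asymmetry makes borderline particles drift toward the
majority over iterations. At the study conditions (n = 400, snr = 2,
25° separation) the recovered fraction for a 13% minority is typically
biased low by 1-2 percentage points per iteration at coarse comparison resolutions, and by well under 1 point per iteration at the default, while
balanced mixtures are recovered within ~1 point. This is a property of
competitive classification at small counts, not of the implementation;
the experiment it emulates used roughly 25-fold more particles per
condition. The per-iteration counts are reported so the drift is visible.

## The synthetic phantom

All claims are tested against a two-rigid-body phantom: Gaussian
pseudo-atoms on a 48³ grid at 4 Å/voxel (192 Å box, matching the scale of
a proteasome-sized complex). The CP is a barrel-like body in the lower
half; the RP occupies the upper half and rotates rigidly about +z.
Rotations are right-handed degrees about the axis through the box centre.

Two geometry choices are deliberate and matter:

* **The CP is azimuthally asymmetric** (an off-axis ridge). A CP built
  only of on-axis Gaussians would be exactly rotationally symmetric about
  the long axis; the rotated-state volume would then be a *global*
  rotation of the non-rotated one — the two states would be
  indistinguishable from projections, and CP-only alignment could not fix
  the azimuth, leaving the rotation coordinate undefined. Real core
  particles are only pseudo-symmetric, and the asymmetry stands in for
  that.
* **The RP mass is peripheral and asymmetric** (three lobes at distinct
  azimuths, radius 30-45 Å, plus a small axial cap). The rotation signal
  of a body scales with the lateral arc its mass sweeps (≈ 17 Å at 25°
  for the outer lobe), and an azimuthally symmetric RP would make the
  rotation invisible. The lobe geometry is chosen so the two states are
  clearly distinguishable in most projections at the working resolution,
  emulating the visually obvious RP rotation in negative-stain class
  averages.

Class ensembles draw per-class counts from a multinomial with
\(p_i \propto e^{-E(\theta_i)}\) over an even angle grid; energy
functions are flat, harmonic (\(E = \tfrac{\kappa}{2}(\theta-\theta_0)^2\),
κ in \(k_BT/\)deg²), or a double well built from C¹ piecewise-cosine
segments through (edge, well, barrier, well, edge) anchors — the anchors
are attained exactly and nothing overshoots, so generated ensembles have
exactly the stated well energies and barrier height. Particle images are
noise-free projections at uniformly random orientations plus white
Gaussian noise with variance = signal variance / snr; there is no CTF,
because the emulated protocol corrects the CTF per particle upstream of
classification, and no stain or ice artefacts.

What passing these tests shows: the estimators recover known rigid-body
rotations, occupancy-derived energies, and mixture fractions from data
whose forward model is exactly the one assumed. What they do not show:
robustness to CTF residuals, non-rigid deformation, alignment errors
inherited from upstream refinement, or model bias in real 3D
classification.

## Defaults and why

| Parameter | Default | Rationale |
|---|---|---|
| box, voxel | 48, 4 Å | proteasome-scale box at desk-scale cost |
| alignment grid | ±6°, 2° steps, ±8 Å shifts | coarse grid capturing class jitter; polish supplies sub-step accuracy |
| rotation search | ±30°, 0.5° steps | covers the 25° physiological range with sub-degree readout |
| PCA K | 2 | the landscape is 2D; further modes are reported, not binned |
| landscape bins | 32 × 32 (+5% margin) | resolves ~100 classes without emptying most bins |
| smoothing sigma | 1 bin | visual smoothing of occupancy *before* the log; set 0 for quantitative barrier readout, since smearing point deposits into the saddle biases barriers low |
| classifier grids | 15° directions, 10° in-plane, ±3 px | coarse candidates only; the continuous per-particle polish does the precision work |
| classifier lowpass | 2.25 voxels (9 Å) | common comparison resolution. Calibrated on ensembles with known truth: at coarser resolutions the iteration loses minority-class particles each round (quality asymmetry of the references), while near the Nyquist limit the recovered fraction tracks the ground truth stably |
| ensemble presets | 346 classes, 10⁵ particles | the class density of the emulated experiment; dense enough that occupied landscape bins integrate the occupancy smoothly and form a connected path across the barrier (sparser ensembles leave gaps or merge well classes and bias barriers up) |

Numerical notes: the low-pass filter is a radial cosine edge two Fourier
shells wide ending *at* the cutoff, so out-of-band power is removed
completely and the mean (DC) is always preserved; on band-limited input
the filter is exactly idempotent, on full-band input repeated application
perturbs only the two edge shells (≤1% here). Landscape energies with
smoothing off equal −ln(count ratios) to machine precision. The
minimax-path flood uses union-find over bins sorted by energy;
ties are broken by bin index for determinism. All randomness flows from
explicit integer seeds; reruns are byte-identical.

## Atomic-model metrics

Independently of the landscape machinery, the package implements the two
atomic-model analyses used when interpreting such structures. Segment-wise
B-factor classification scans non-overlapping windows of five consecutive
modelled residues per chain (the trailing shorter window is classified on
its own mean): mean B < 110 Å² keeps full side chains, 110-150 Å²
(inclusive on both ends, a documented and overridable reading of the
thresholds) truncates to poly-alanine (N, CA, C, O, CB; glycine keeps no
CB), and mean B > 150 Å² removes the segment. Window phasing starts at
each chain's first modelled residue. Ring-symmetry analysis connects six
labelled Cα atoms into a hexagon, projects them onto their least-squares
plane (or a plane perpendicular to a user axis), and reports the inner
angle at each vertex, using the ring's signed area to orient reflex
vertices; deviations from 120° quantify the breaking of six-fold symmetry
in an AAA+ ATPase ring.

## Problem sizes

The test-suite and the bundled analysis scripts run the classifier at
n = 400 particles and box 48, ensembles at 6-346 classes, and alignment
sweeps at up to 41 angles; these sizes were chosen so the full synthetic
study reproduces the printed comparisons of the emulated experiments at
workstation scale.

## Limitations

* Simple (ramp-filtered) backprojection, not Fourier-gridded
  reconstruction; fine at box 48, not suitable for high-resolution work.
* The landscape is 2D over one coefficient pair; coefficients beyond the
  chosen pair are reported but not binned.
* Rotation axis is user-supplied (default +z); long-axis auto-detection
  is out of scope.
* Barrier heights are free energies of occupancy; no kinetic rates are
  inferred.
* The classifier's skewed-fraction bias discussed above.

A note on mixture composition: by default the two-state particle
generator draws each particle's state independently, so the realised
fraction of a finite set fluctuates binomially around the request
(sd ≈ 2.5 points at n = 400). Recovery studies that compare against a
stated ground-truth fraction use `exact_fraction = TRUE`, which fixes the
composition exactly and randomises only the order, so the comparison
isolates classifier error.
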