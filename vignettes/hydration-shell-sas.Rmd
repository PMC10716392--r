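---
title: "Explicit-solvent SAS and the hydration shell: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explicit-solvent SAS and the hydration shell: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrosas)
```

## The problem

Biomolecules in solution carry a hydration shell whose density differs from
bulk water, typically by a few percent.  Small-angle X-ray scattering (SAXS)
probes electron-density contrast and sees this denser shell as part of the
particle, so the apparent radius of gyration exceeds the bare-solute value,
`Rg(SAXS) > Rg(prot)`.  Small-angle neutron scattering (SANS) in D2O sees the
solute at *negative* contrast against the strongly scattering heavy water,
while the denser shell adds scattering length near the surface, which *pulls
Rg down*: `Rg(SANS/D2O) < Rg(prot)`.  In H2O the shell is nearly contrast
matched and the effect is small.  Two observables summarize this footprint:

* `dRg = Rg(SAS) - Rg(prot)` per modality, and
* `dRg(SAS) = Rg(SAXS) - Rg(SANS)`, which cancels the (experimentally
  unknown) bare-solute Rg and compares directly between simulation and
  experiment.

hydrosas implements the full explicit-solvent computational chain that turns
ensembles of solute-in-solvent configurations into these observables, and a
synthetic-system generator that replaces molecular-dynamics trajectories so
the chain can be validated end to end on a desk.

## The scattering model

For one configuration the scattering amplitude at wave vector **q** is the
explicit-atom sum `A(q) = sum_j f_j(q) exp(i q . r_j)` over all solute atoms
plus every solvent and ion atom inside a closed *envelope* built around the
solute (default distance: 0.9 nm from the Van-der-Waals surface).  Buffer
subtraction uses a matched pure-solvent ensemble restricted to the same
envelope.  With independent system (A) and buffer (B) ensembles the
buffer-subtracted intensity is estimated per block as

    I(q) = |<A> - <B>|^2 + Var(A) - Var(B),

where `< >` and `Var` are within-block frame statistics and the squared mean
difference is debiased by the variances of the means.  The `Var(A) - Var(B)`
term carries the physical difference in solvent fluctuation scattering; its
buffer part cancels exactly, so a buffer measured against another buffer
realization is statistically zero at every q — the same cancellation an
experimental buffer subtraction performs.  The orientational average uses
200 quasi-uniform (spherical-Fibonacci) q-vectors per |q| by default, and
the solvent electron density is corrected multiplicatively to the
experimental bulk value of 334 e/nm^3, measured on the buffer ensemble
inside the envelope, in both the system and buffer amplitudes (for SANS the
analogous correction in scattering-length units is applied by default).  No
fitting parameters touch the hydration layer or the excluded volume: the
computed Rg values are fully imposed by the input configurations.

Neutron contrast variation follows the standard H/D bookkeeping: in D2O,
water and polar (O/N/S-bound) hydrogens carry b(D) = +6.671 fm, backbone
amide hydrogens are deuterated with probability 0.90, and non-exchangeable
(carbon-bound) hydrogens keep b(H) = -3.741 fm.  The default "fractional"
mode assigns the ensemble-average length b = 0.9 b(D) + 0.1 b(H) = 5.630 fm
to amide hydrogens, which is exact for coherent scattering at the ensemble
level and free of sampling variance; a Bernoulli "sampled" mode exists for
fidelity checks.  Incoherent scattering is not modeled.

### Statistical errors and variance reduction

Errors are estimated by partitioning both ensembles into 10 contiguous
blocks; system and buffer blocks are paired by index so each intensity
evaluation uses an independent buffer block, and per-q errors are
sd/sqrt(10) over the block intensities.  Rg errors use block jackknifing:
the pooled curve is refit with each block left out and the leave-one-out
radii are turned into pseudo-values, whose scatter gives the SE.  Refitting
pooled curves (rather than fitting single noisy blocks) linearizes the
nonlinear Guinier functional at the pooled noise level, which keeps the Rg
errors calibrated against truly independent replicates.  `dRg(SAS)` errors
difference the pseudo-values pairwise, absorbing the correlation from
shared frames.

The synthetic solvent is an ideal gas of pseudo-waters, so its particle
number in the envelope fluctuates with full Poisson variance — roughly
16 times more than real water, whose structure factor at q -> 0 is ~0.06.
To keep the estimator's noise at a realistic level, the block mean
difference is corrected with a *zero-mean control variate*.  Away from the
solute — beyond `bulk_margin` (default 0.6 x the envelope distance) of any
solute atom — the system and buffer hold bulk solvent at the same
corrected density, so the measured mismatch of their in-envelope
bulk-region solvent weights is pure sampling noise with expectation
exactly zero.  Its projection onto that region's form amplitude E_R(q)
(computed once per run by seeded Monte-Carlo integration) is subtracted
from `<A> - <B>`, and the debiasing terms use the corresponding residual
variances.  Because the variate has known zero mean, every expectation is
unchanged for any solvent model, and — unlike a variate centered on the
sample mean — the correction removes the shot-noise mode from the block
estimates and the pooled curve *coherently*, so the block scatter remains
an honest standard error for the reported values (the property the
error-calibration test checks).  Disable with
`variance_reduction = FALSE`; the default `bulk_margin` must exceed the
hydration-shell extent, as it does for the default system.

## Envelope geometry

The envelope is star-shaped with respect to the solute center: on an
icosphere (recursively subdivided icosahedron; level L has 20 * 4^L faces,
level 6 the reference resolution of 81920), each vertex direction stores the
largest support of the balls of radius (vdW + distance) around all solute
atoms of all construction frames.  The surface along an arbitrary direction
is the spherical-barycentric *linear interpolation of vertex radii*; this
representation is monotone in the radii, so envelopes built at increasing
distances are strictly nested — the property that makes shell volumes
between adjacent envelopes well defined for density profiles.  (A
piecewise-planar triangle mesh does not have this property: where adjacent
vertex radii differ strongly, e.g. over the bumps of a lattice solute,
planar facets of nested surfaces interpenetrate and bin volumes become
inconsistent with membership.)  Volumes integrate r(d)^3/3 over the sphere
exactly for the interpolated field — exact for a single-atom (spherical)
envelope at any subdivision.  Vertex radii are lifted wherever the
interpolation would dip below the required ball support at an edge
midpoint, so enclosure is guaranteed conservatively: concavities are only
ever over-covered, never cut.

Solvent density profiles bin solvent content between nested envelopes at
0.05-nm (default) spacing from the Van-der-Waals surface and divide by the
envelope-derived shell volumes.  Because the star-shaped surface smooths
over surface concavities, a sharp density step imposed at a fixed
min-distance from the surface is smeared by roughly one bin at the
boundary; recovery tests therefore integrate the excess *mass* over the
shell region plus one boundary bin.  Mass balance — binned density times
bin volume summing to the total in-envelope content — holds exactly by
construction.

## Rg extraction

* **Guinier**: weighted linear fit of ln I versus q^2; the fit range is
  iterated to the fixed point of `qmax * Rg <= 1.3` (the community-standard
  validity rule; the pipeline default).  For analytic-sphere validation the
  package uses the conservative `qmax * Rg <= 0.8`, because for a sharp
  sphere the fourth-order term biases the fitted Rg by ~1.7% at 1.3 but
  only ~0.5% at 0.8 — a property of the Guinier approximation, not of the
  fit.  Negative intensities can occur at low contrast (SANS/D2O); the fit
  refuses curves whose small-q head is entirely non-positive and points to
  P(r) analysis instead.
* **P(r)**: regularized indirect Fourier transform on a 201-point grid over
  [0, Dmax] with a second-difference roughness penalty, endpoint constraints
  P(0) = P(Dmax) = 0, and automatic regularization at the L-curve corner
  (maximum Menger curvature); `Rg^2 = int r^2 P dr / (2 int P dr)` by
  trapezoidal quadrature.  This is a generic Tikhonov scheme, not a
  re-implementation of any specific legacy program's criterion.
* **Direct space**: contrast-weighted RMS distance from the weighted
  centroid; electron weighting is the default for the bare-solute reference
  entering `dRg` (uniform and neutron-length weightings are selectable).

On noise-free compact-body curves the Guinier and P(r) routes agree within
1%, mirroring the consistency check used with real data.

## The synthetic system

The generator emulates, at desk scale, the features of a solvated-protein
trajectory that the observables depend on:

* **Solute**: pseudo-atoms on a cubic lattice cut to a sphere (default
  radius 1 nm, spacing 0.25 nm), a hollow cylinder (the shape that can make
  hydration *lower* Rg by filling a central cavity), or an arbitrary point
  set.  Defaults: 8 electrons and -2.5 fm per atom, chosen once so the
  modality contrasts have protein-like signs — electron density above bulk
  water (positive SAXS contrast) and neutron scattering-length density
  below D2O (negative SANS/D2O contrast) but slightly above H2O.
* **Solvent**: single-site 10-electron pseudo-waters with molecular
  scattering lengths b(H2O) = -1.679 fm / b(D2O) = +19.145 fm, placed by
  thinned Poisson (rejection) sampling at the bulk number density
  334/10 = 33.4 nm^-3, zero inside a small exclusion radius around solute
  atoms, and elevated by `shell_excess` (default 0.06, the literature-scale
  hydration excess) within `shell_thickness` (default 0.3 nm, one to two
  water layers) of the Van-der-Waals surface.
* **Exclusion radius** defaults to the solute vdW radius (0.1 nm), kept
  small deliberately: the displaced-solvent contrast then sits at the
  solute atom positions, so at zero shell excess every modality's
  SAS-derived Rg equals the direct-space Rg and all dRg vanish — the clean
  null against which the shell effect is measured.
* **Ensembles** are independent solvent redraws around a rigid (optionally
  Gaussian-jittered) solute with per-frame seeds derived from one master
  seed; identical spec + seed is bit-identical.  A frozen-bulk reference
  region (waters of one buffer draw inside a solute-sized ball, relabeled
  as reference sites) stands in for restrained bulk water when density
  profiles are compared against bulk structure; no restraint dynamics is
  modeled.

What the generator does **not** emulate: the layered (first/second/third
peak) oscillatory shell structure of real hydration water, water-water
correlations (the solvent is an ideal gas), multi-site water geometry,
ions' specific coordination, and conformational dynamics.  Passing tests
therefore demonstrate the correctness of the *computational chain* —
geometry, amplitudes, subtraction, calibration, error model, observable
arithmetic — not the realism of any force field.

### Study conditions used by the validation suite

The slow tests and the acceptance script run at fixed problem sizes chosen
by a power analysis against the generator's noise-free expectation values
(computed semi-analytically by high-statistics Monte-Carlo integration of
the mean amplitudes: dRg(SAXS) = +0.030 nm, dRg(SANS/H2O) = +0.018 nm,
dRg(SANS/D2O) = -0.084 nm for the default sphere):

* sign-structure experiment: 4000 system + 4000 buffer frames, q in
  [0.05, 1.0] nm^-1 (the Guinier region; 20 points), 200 directions,
  10 blocks — SANS/D2O has the smallest per-frame contrast-to-shot-noise
  ratio and dictates the ensemble size;
* error calibration: ten independently regenerated 160 + 160-frame
  ensembles, comparing the 10-block SE of dRg(SAS) against the replicate
  scatter;
* null tests: 300 + 300 buffer frames (buffer vs buffer) and a
  400 + 400-frame zero-excess system;
* shell-excess recovery: 50 frames, 0.1-nm bins.

## Numerical choices and degenerate inputs

* Lengths are nm and momentum transfers nm^-1 internally; Angstrom is
  accepted and converted at the I/O boundary (PDB files are written in
  Angstrom, as the format requires).
* Uniform q-grids take a fast phase-recursion path in the amplitude kernel
  (one sincos per atom-direction pair instead of one per q); non-uniform
  grids use the direct kernel.  Both agree to ~1e-13 relative.
* The solvent density-correction factor is measured on up to 200 buffer
  frames; because the factor multiplies the solvent in both the system and
  the buffer amplitudes, its residual statistical error enters only through
  the small solvent *difference* term (~0.1% of the contrast).
* Empty frames (a vacuum "buffer") and single-frame ensembles are legal;
  block statistics then degenerate to sigma = 0.
* A solute whose lattice spacing exceeds its radius raises an empty-solute
  error; boxes that cannot hold solute + shell + envelope margin are
  rejected at spec construction; envelopes reaching beyond a frame's box
  raise an error at use time.
* Ions count as solvent for envelope membership but are not density
  corrected.

## Known limitations

* The star-shaped envelope over-covers deep concave pockets; for solutes
  with genuine interior cavities (hollow cylinder) the cavity solvent is
  inside the envelope — which is physically wanted — but the density
  *profile* near strongly concave surface regions is smeared.
* `guinier_fit`'s own `Rg_SE` propagates per-q errors as if independent;
  the jackknife SE (used by the pipeline) is the more faithful error and is
  what the calibration test checks.
* Ideal-gas solvent makes absolute intensities correct in expectation but
  (without the control variate) noisier than real-water ensembles of the
  same size.
* `dRg(SAS)` invariance to the bare-solute conformation holds by
  construction for the rigid default solute; with jitter enabled it holds
  only on average over frames.

## A minimal run

```{r example, eval = FALSE}
cfg <- run_config(
  spec = list(),            # the default 1-nm sphere with a 6% shell
  n_frames = 500, n_buffer_frames = 500,
  seed = 7, output_dir = "hydrosas_out")
res <- run_pipeline(cfg)
res$report
```

The report prints Rg per modality with 1-SE errors, the dRg values against
the direct-space solute Rg, and the bare-structure-independent dRg(SAS)
differences; all artifacts (curves, profile, envelope mesh, manifest with
every default and decision) land in `output_dir`.
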