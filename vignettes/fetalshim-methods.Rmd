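---
title: "Image-based B0 shimming for fetal EPI: models and methods"
author: "fetalshim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based B0 shimming for fetal EPI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalshim)
```

# The problem

Echo-planar imaging of the fetal brain runs at deliberately low
phase-encode bandwidth (acoustic-noise and safety constraints force slow
gradient switching), which makes the images doubly sensitive to
off-resonance: local B0 inhomogeneity displaces and distorts the fetal
brain, and the chemically shifted maternal subcutaneous fat — displaced by
tens of pixels along the phase-encode direction — can land on top of it.
Two interlocking remedies are modeled here:

1. **Static image-based (IB) shimming.** A dual-echo field map is acquired
   once, and first/second-order spherical-harmonic shim coefficients are
   fitted to flatten the field over the fetal brain. In the *localized*
   (L-IB) variant only the brain ellipsoid matters; in the
   *fat-constrained* (FC-IB) variant the fit additionally keeps the
   residual frequency at every maternal-fat voxel inside the band where
   the fat-saturation pulse is effective.
2. **An optimized SPIR pulse.** The spectral presaturation pulse is shifted
   toward water (550 Hz offset instead of the default 635 Hz) to cover the
   fat line better, exploiting the narrow water linewidth of the fetal
   brain. Bloch simulation of this pulse defines the constraint band
   (d1, d2) used by FC-IB.

The package implements the full computational chain — field mapping, phase
unwrapping, Dixon fat segmentation, basis fitting, constrained quadratic
optimization, pulse simulation — plus a parametric synthetic abdomen
phantom so the whole pipeline runs and is tested without scanner data.

# Field mapping

A rapid dual-echo spoiled gradient-echo acquisition with TE1/TE2 =
4.6/6.9 ms gives the per-voxel frequency as the phase of
`echo2 * Conj(echo1)` divided by `2*pi*dTE`. The 2.3 ms spacing is the
in-phase period of the water–fat shift (`inPhaseTE2(4.6, 434) = 6.9`): fat
accrues a full cycle between echoes, so fat voxels read their *B0*
deviation rather than the chemical shift, and the map is valid across
tissue types. The mapping window is ±1/(2 dTE) = ±217 Hz; anything beyond
wraps.

Voxels are marked reliable when their geometric-mean echo magnitude
exceeds 5% of the 99th-percentile magnitude — a robust-maximum criterion
that excludes background air without clipping low-signal fetal tissue.

## Goldstein unwrapping

Wrapped maps are unwrapped slice by slice with a Goldstein branch-cut
method: 2×2 loop integrals of wrapped phase differences detect residues;
residues of opposite sign are paired greedily (or tied to the grid border
when that is closer) and connected by straight branch cuts; flood-fill
integration then proceeds without crossing a cut or an invalid voxel. On a
residue-free slice the result equals the true phase up to one 2π constant
per connected component — the property the test suite checks against an
independent Itoh (1-D cumulative) oracle.

Two conventions the method itself does not fix are resolved as follows:

* **Inter-slice consistency.** Unwrapping is purely 2-D, so each slice
  carries an arbitrary 2π multiple. Slices are aligned by removing the
  2π multiple of the median difference between adjacent slices over
  commonly valid voxels.
* **Global anchor.** The shim basis has no 0th-order term, so a global
  full-cycle offset (434.8 Hz for this echo spacing) would bias the fit.
  The remaining global 2π multiple is chosen so the median unwrapped phase
  over valid tissue lies within half a cycle — correct whenever the bulk
  of the field sits inside the mapping window, which holds for abdominal
  fields shimmed about the water center frequency.

# Dixon fat–water separation

Fat regions are segmented from a three-point Dixon acquisition
(TE 4.6/5.6/6.6 ms) under a two-species, single-peak model
`s(te) = (W + F e^{i 2π σ te}) e^{i φ} e^{i 2π f0 te}` with σ = −430 Hz at
3 T. For fixed f0 the demodulated samples live in the fixed complex span
of {1, fat phasor}, so the least-squares misfit reduces to a two-harmonic
trigonometric polynomial in `α = 2π f0 dTE` whose coefficients are echo
cross-products. The global maximizer is found on a dense grid and polished
by vectorized Newton steps — closed-form accuracy with no per-voxel
iteration. f0 is identified within ±1/(2 dTE) = ±500 Hz.

One genuine degeneracy needs a tie-break: a single-species voxel fits
*exactly* both as water at f0 and as fat at f0 + σ. Near-ties (within 2%
of the trig-polynomial magnitude) are resolved toward the smaller |f0| —
the interpretation whose field lies inside the mapping window. Voxels
whose true field exceeds ~215 Hz can still be mislabeled; such fields only
occur immediately next to gas pockets, outside any region the fat mask is
used for. Multi-peak fat spectra are deliberately out of scope: the fat
image is only thresholded (fat fraction > 0.5 above the noise floor), not
quantified.

# The shim model

The eight first/second-order real solid harmonics X, Y, Z,
Z2 = 2z²−x²−y², ZX, ZY, X2−Y2, XY are evaluated at voxel centers in mm
from the isocenter. Each term is normalized by its maximum magnitude on
the 200 mm reference sphere, so a unit coefficient produces 1 Hz at 20 cm
on the term's principal axis ("Hz at 20 cm" units). Coil amp calibration
is an external table by design — the package works purely in field units.
The 0th-order term is excluded from the solve; the residual brain mean is
reported separately as the transmitter-frequency (f0) correction, which is
how scanners apply it.

The design matrix A (brain) or C (fat) stacks the basis evaluated at
masked voxels in deterministic x-fastest order. `projectShim()` simulates
a shim setting by subtracting the basis combination from the measured map,
with the sign convention A·s ≈ field, residual = field − A·s (hardware
applies the negated coefficients).

# The shim solvers

Both solvers minimize

    || A s − b ||² + λ || D s ||²   subject to  lb ≤ s ≤ ub

where D scales each coefficient by the RMS of its design column over the
brain ROI. This normalization makes λ dimensionless: λ = 0.03 (the
default, matching the published setting) then means the same thing
regardless of coefficient units or ROI size. The regularization matters
because a small fetal head yields a nearly collinear design — without it
the solution wanders along ill-conditioned directions. FC-IB adds the
per-fat-voxel band

    d1 ≤ b_fat − C s ≤ d2,     d1 = −350 Hz, d2 = +100 Hz by default,

a convex quadratic program solved with a dual active-set method
(`quadprog`); when no constraint is active the solution equals the
closed-form ridge normal equations, which the tests verify to 1e-8.

Numerical and policy choices:

* **Band endpoints are inclusive** — equality is feasibility in the QP.
* **Infeasible bands** (gas pockets can make strict feasibility
  impossible) default to minimal symmetric widening: the smallest ε with
  [d1−ε, d2+ε] feasible is located by bisection over feasibility solves
  and reported in the solver report. A `strict` policy errors instead,
  listing the most-violated voxels.
* **Rank-deficient designs** are solved (the Tikhonov term guarantees
  uniqueness) with a warning; at λ = 0 a 1e-10 relative ridge is added.
* The solver path is deterministic — no random initialization.
* `qpOracle()` is a test-only exhaustive grid minimizer for ≤3
  coefficients, with optional zoom refinement; it exists so the QP path
  can be cross-checked against something that shares none of its code.

A note on exactness: with λ = 0.03 the recovered coefficients on a
noise-free phantom differ from truth by ~0.05 units along ill-conditioned
directions while the brain residual stays below 0.01 Hz — the documented
regularization bias. Exact-recovery tests therefore run the estimator at
λ = 0, where recovery is exact to floating-point precision.

# SPIR simulation and the origin of (d1, d2)

The vendor's pulse shape is proprietary; the documented stand-in is a
Hamming-windowed sinc with the published parameters (duration 7.5 ms,
time-bandwidth product 6.20, flip 110°), amplitude-calibrated so the
on-resonance rotation equals the nominal flip, and shifted to the fat side
of water by a linear phase ramp (offsets are quoted as positive
magnitudes; internally the band center sits at −offset). Note the
published parameters are mutually inconsistent — 752 Hz × 7.5 ms = 5.64,
not 6.20 — so TBP + duration are treated as primary.

The saturation profile is a hard-pulse Bloch simulation: one Rodrigues
rotation per envelope sample about the effective field (B1x, B1y, Δf),
relaxation neglected during the 7.5 ms pulse (fat T1 ≈ 380 ms ≫
duration). The effective band is the contiguous range where saturation
1 − mz reaches 95% of its peak, edges interpolated linearly, re-expressed
as fat-frequency deviation by subtracting the −430 Hz chemical shift.

```{r band}
spirFatConstraints(duration = 7.5, tbp = 6.2, flip = 110, offset = 550)
```

With the Hamming-sinc stand-in this band is ≈ [−295, +55] Hz, i.e.
350 Hz wide and centered like the published d1 = −350 / d2 = +100 Hz band
but ~100 Hz narrower: the published values imply a pulse with a flatter,
wider 95% plateau (an equiripple/SLR-type design would give one). The
shape is pluggable, every band-derived number records the shape used, and
the defaults for the solver remain the published (−350, 100).

For the signal-versus-offset sweeps, fat and water are modeled as Gaussian
frequency histograms (fat: −430 ± 80 Hz, emulating the broad subcutaneous
line; water: 0 ± 25 Hz, the narrow fetal-brain line), with
mono-exponential T1 recovery (380/2000 ms) over the pulse-to-excitation
delay. That delay defaults to the fat-nulling value
T1_fat·log(1 − cos 110°) ≈ 112 ms. The simulated curves reproduce the
published behavior: fat signal falls monotonically as the offset moves
from 743 to 543 Hz, while water is untouched down to ~550 Hz and only
attenuates below ~500 Hz.

# The synthetic abdomen phantom

`generatePhantom()` builds, on the acquired-resolution grid (70×70×10
voxels at 5×5×10 mm³, i.e. a 350×350×100 mm³ field of view), an elliptical
torso (160×120 mm semi-axes) with a 20 mm subcutaneous fat ring (fat
fraction 0.95), a fetal-brain ellipsoid, a ground-truth field composed of
a shim-basis background plus analytic external sphere-dipole fields
`strength·(3cos²θ−1)/r³` for gas pockets (Lorentz term ignored; no signal
inside a pocket), optional Gaussian field noise, and forward-simulated
echo images (field-map pair and Dixon triplet) with complex Gaussian
receiver noise at a chosen SNR. A fixed seed makes every output
bit-reproducible, and the caller's RNG state is untouched.

The generator also records the *floor*: the brain-ROI SD of the best
unconstrained shim-basis fit of the true field — the homogeneity any
solver can at best reach. Tests require the localized solver to come
within 5% of it.

What the phantom does *not* emulate — and hence what green tests do not
show about real data: anatomy beyond ellipses, motion between and during
acquisitions, B1 inhomogeneity, multi-peak fat, partial-volume mixing at
tissue borders, and receiver-coil shading. It exercises the numerics of
the chain, not its physiological robustness.

## Scenario library

Three presets, with background coefficients (20, −15, 12, 30, −22, 18,
25, −20) "Hz at 20 cm" (field excursions of a few tens of Hz over the
torso, typical of an abdomen at 3 T):

* **pure-SH** — noise-free, no gas: the field is exactly representable,
  coefficients are exactly recoverable, fat constraints stay inactive, and
  L-IB and FC-IB coincide.
* **fat-conflict** — a 14 mm gas pocket 13 mm below a fetal brain that
  sits near the posterior fat ring (echo SNR 200). The localized fit
  chases the dipole gradient with large coefficients whose second-order
  extrapolation at the ring radius (4× the brain radius, hence ~16×
  amplification) throws ~12% of the fat ring outside the saturation band;
  the constrained fit pulls it back to 0% while giving up ~0.1% brain
  homogeneity — the same ordering and near-parity as the published
  in-vivo comparison (10.9 vs 11.7 Hz brain SD, 15% vs 8% fat
  out-of-band).
* **gas** — a 12 mm pocket 5 mm lateral of the brain: its dipole field is
  outside the first/second-order span, so the localized residual SD stays
  well above the pure-SH case no matter the coefficients (the solver still
  reaches the recorded best-fit floor).

Pocket strengths were chosen so the strongest voxel-to-voxel field steps
stay below the ±217 Hz aliasing window: stronger pockets are physically
plausible but make any 2.3 ms-spacing field map non-unwrappable, which is
a limitation of the acquisition being modeled, not of the solver.

# Problem sizes and runtimes

All shipped experiments run on the 70×70×10 acquired-resolution grid
(~15,000 fat-constraint voxels, ~270-voxel brain ROI); a full pipeline
(field map → unwrap → Dixon → both solvers → metrics) takes ~1–2 s, the
Bloch band simulation (512 envelope samples × 1501 offsets) well under
10 s, and the complete test suite well under a minute. Fat voxels can be
subsampled (`fatStride`) for larger grids; the default keeps every voxel.

# Known limitations

* Static single-setting shimming only: no per-slice or dynamic shim
  switching, no RF (B1) shimming, no >2nd-order terms.
* The unwrap anchor assumes the median tissue field lies within half a
  cycle; grossly off-center fields would need an explicit reference.
* The constraint band treats d1/d2 as limits on the residual
  water-frequency deviation at fat voxels (the fat resonance itself is
  offset by −430 Hz); the transmitter f0 correction is reported but not
  fed back into the band.
* Hardware bounds default to wide placeholders (±1000 units) and must be
  supplied for any real system; no coil calibration, eddy-current or
  cross-term modeling.
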