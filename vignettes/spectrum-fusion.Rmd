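---
title: "Fourier-domain fusion of orthogonal anisotropic MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fourier-domain fusion of orthogonal anisotropic MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fousr)
```

## The problem

Ultra-low-field (ULF) MRI — portable scanners operating below 0.1 T —
trades signal-to-noise for accessibility. Because SNR scales with field
strength, clinically usable ULF FLAIR images are acquired with thick
slices: a typical protocol measures 1.7 mm × 1.7 mm in plane but 5 mm
through plane. A thick-slice scan is not merely blurry along its slice
axis; in k-space terms it simply never measures the outer spatial
frequencies along that axis. Radiologists reading such scans for
white-matter lesions (as in multiple sclerosis) therefore see sharp
detail in two directions and partial-volume smear in the third.

When *two* such scans of the same head are acquired in orthogonal planes,
their k-space coverages are complementary: each scan supplies the high
frequencies the other is missing, except for a corner region neither
measured. `fousr` implements the spectrum-splice reconstruction that
exploits this: an inversion of the keyhole idea from dynamic imaging,
borrowing the *high*-frequency periphery from a second scan rather than
re-using a low-frequency core.

## The reconstruction

Let $b$ (base) and $d$ (donor) be the two co-registered, preprocessed
magnitude volumes, $B = \mathcal{F}b$ and $D = \mathcal{F}d$ their
centered 3-D discrete Fourier transforms, and let $a$ be the donor's
slice axis. With an axis of extent $N$ and centre $c = \lfloor N/2
\rfloor$ (0-based), the centered band of width $w$ is the index set

$$\mathcal{B}_w = \{\,c - \lfloor w/2 \rfloor, \dots, c - \lfloor w/2
\rfloor + w - 1\,\}.$$

The fused spectrum takes donor coefficients on the band and base
coefficients elsewhere,

$$S(k) = \begin{cases} D(k) & k_a \in \mathcal{B}_w \\ B(k) &
\text{otherwise,} \end{cases}$$

and the image is $|\mathcal{F}^{-1} S|$. The donor genuinely measured
only its central $w^\ast$ planes along $a$, so the splice inserts exactly
the region of k-space where the donor is trustworthy and the base is not;
everywhere else the base — which fully sampled $a$ in plane — is kept.
The union of the two coverages is recovered; the unmeasured corner (high
frequency along *both* slice axes) remains absent, which is why the fused
image is sharper than either input yet not identical to a native
isotropic acquisition.

### Choosing the band width

The default width is derived from the acquisition geometry. A slice
thickness $t$ with in-plane resolution $p$ under-samples the slice axis
by a factor $t/p$, so of $N$ spectral lines only

$$w^\ast = \mathrm{round}(N / (t/p))$$

were reliably measured. For the 5 mm / 1.7 mm protocol on a 160-line grid
this gives a factor of 2.94 and $w^\ast = 54$; `compute_band_count()`
reports both. The width can be overridden — protocols are sometimes tuned
empirically a little above the geometric value, because the outermost
measured lines are noise-dominated, and 64 lines is a known working
choice for the 160-line ULF protocol — and `band_sweep()` automates that
tuning by scoring a range of widths with the sharpness measure. On
noiseless simulations the sweep's maximizer sits at (or within a plane or
two of) $w^\ast$, which the test suite checks.

Base/donor orientation follows the same logic in both directions: the
replacement axis is always the *donor's* slice axis. Swapping the roles
of the two scans changes which scan contributes the band and which the
periphery, i.e. which scan's contrast dominates the result.

## Preprocessing

`run_fuse()` applies a fixed order — resample, pad, normalize — before
fusion:

1. **Resample** each scan to an isotropic grid (default 1.7 mm) with
   nearest-neighbour interpolation. Nearest-neighbour is deliberate: it
   introduces no new intensity values, so tissue statistics (means over
   masks) are unbiased. The output extent per axis is
   `round(extent_mm / target_mm)`, rounding half away from zero — a
   deterministic, documented convention.
2. **Zero-pad** both scans to their common maximal shape, centring with a
   `floor((target − current)/2)` offset.
3. **Normalize** each scan to the 98th percentile of its *nonzero*
   voxels (linear-interpolation percentile). The nonzero support matters:
   zero-padded and skull-stripped backgrounds would otherwise drag the
   percentile toward zero. Values above the percentile are not clipped;
   the normalization is a rescaling that equalizes the two scans'
   intensity ranges before their spectra are mixed, robust to a few
   extreme outliers.

Registration is an explicit precondition, not a pipeline step: the two
inputs must already be voxelwise co-registered (clinically this is done
against a high-field reference with a nonlinear registration tool). The
package validates grid compatibility only. Residual misregistration
shows up in the fused image as ringing — phase inconsistency between the
two spectra — and is the method's characteristic failure mode.

## Quality metrics

The evaluation suite mirrors standard ULF lesion-imaging practice. With
masks for lesions, normal-appearing white matter (NAWM) and a
signal-free background-noise region:

* **SNR** — mean lesion intensity / sd of the noise region.
* **CNR** — |mean lesion − mean NAWM| / sd of the noise region.
* **Lesion conspicuity** — (mean lesion − mean NAWM) / (mean lesion +
  mean NAWM); bounded in [−1, 1], independent of the noise region.
* **Image sharpness** — the standard deviation of the response of the
  6-neighbour discrete 3-D Laplacian (the canonical second-difference
  stencil; borders are edge-replicated). Blur attenuates second
  differences, so sharper images score higher. The literature speaks of
  the "variance of the Laplacian" but operationally reports its standard
  deviation; this package does the same, using the sample (n − 1)
  denominator throughout.
* **Lesion sharpness** — lesion masks are split into connected clusters
  (26-connectivity, deterministic labelling by first voxel in array
  order), each cluster is dilated by one voxel with the full 3×3×3
  structuring element so the ROI straddles the lesion boundary, and the
  Laplacian sharpness over that ROI is natural-log transformed (the
  log's variance-stabilising role for downstream mixed-model analysis).
  A boundary-free lesion in a constant background has sharpness 0 and is
  reported as `NA` rather than an error.

All four scalar metrics are invariant to global positive intensity
scaling, which the suite verifies; this is what makes them comparable
across differently normalized reconstructions.

## The synthetic study

`make_phantom()` + `simulate_acquisition()` define the conditions under
which every quantitative claim in this package is tested.

The phantom is piecewise-constant: an ellipsoidal "head" of tissue
intensity 1 (semi-axes 0.40/0.46/0.42 of the field of view) in an
air background of 0, bar inserts at three spatial scales (1-, 2- and
3-voxel stripes, intensity 0.5) in the lower half as a resolution
target, and spherical FLAIR-hyperintense lesions (intensity 1.6, radii
4–8 mm — the size range of typical white-matter lesions) placed randomly
in the upper half. Lesions are rejected-and-resampled until they are
fully inside the tissue, clear of the inserts, and separated from each
other by at least two voxels, so the connected-component count always
equals the requested lesion count. The default grid is 96³ at 1.7 mm;
the ROI set (lesion, NAWM = tissue minus lesions and inserts,
background noise far outside the head) is exact by construction.

The acquisition model is ideal k-space truncation: the slice profile is
a sinc (hard spectral support), matching the framing of resolution as
spectral coverage and making the recovery property exact rather than
approximate. Noise, when requested, is complex Gaussian added to both
channels after truncation, with the magnitude taken last — the standard
Rician magnitude-MRI model, Rayleigh-distributed in signal-free
background with sd $\sigma\sqrt{2 - \pi/2}$, which the suite checks
against the closed form. One deliberate wrinkle: a *noiseless*
simulation returns the signed real image rather than its magnitude, so
that truncation is exactly a spectral mask (rectifying the small
negative ringing lobes would smear energy back outside the band and
break the exact-recovery oracle tests). Noisy simulations always return
magnitudes.

For the noisy study the noise level is set from the closed form
$\sigma = L / (\mathrm{SNR}_\mathrm{target} \sqrt{2 - \pi/2})$ with
lesion level $L = 1.6$ and a target single-scan SNR of 40, the magnitude
typical of ULF FLAIR lesion measurements. Under these conditions the
package reproduces, as seeded properties, the orderings that matter
clinically: fused sharpness exceeds the blurred average's, the average's
SNR exceeds a single scan's (noise averaging), and the fused RMSE
against ground truth beats both single scans and their average.

What the simulation does *not* emulate: realistic anatomy and tissue
texture, B0 inhomogeneity, coil sensitivity, slab-select slice profiles,
motion, and — most importantly — registration error between the two
scans, which is assumed perfect. Passing tests therefore demonstrate the
algorithm's correctness and its information-recovery property under the
stated model, not robustness to the registration and artifact burden of
clinical data.

## Numerical choices and edge cases

* **Spectrum centring** — zero frequency at 0-based index
  $\lfloor N/2 \rfloor$ on every axis; the band convention above is tied
  to the same centre, so even- and odd-extent axes are both handled
  deterministically.
* **Output realness** — fusing two independently measured magnitude
  images leaves a small imaginary residue after inversion (unmatched
  phases, Nyquist-plane asymmetry); the complex magnitude is taken,
  matching magnitude-image conventions. Splice idempotence is exact at
  the spectrum level; at the image level re-fusing reproduces the first
  fusion up to a few percent RMS on coarse sharp-edged phantoms, the
  magnitude step being the only nonlinearity.
* **Ties in `band_sweep()`** — the smallest width wins, preferring the
  least donor-contrast contamination.
* **Degenerate inputs** — all-zero volumes cannot be normalized;
  empty masks and zero-variance noise regions are errors with distinct
  messages; a band width of the full axis extent legally degenerates the
  fusion to the donor.
* **Determinism** — every stochastic step (phantom placement, noise)
  takes an explicit seed and restores the caller's RNG state; re-running
  a pipeline configuration with the same seed writes byte-identical
  report tables.

Problem sizes in the shipped tests (96³ for the noiseless recovery
study, 64³ across ten seeds for the noisy orderings, ≤ 48³ elsewhere)
were chosen as the smallest grids on which the phantom's three structure
scales and 4–8 mm lesions remain resolvable against 5 mm slices.

## Limitations

The comparator labelled `sharpened_average` is a simplified surrogate —
per-input iterative Laplacian sharpening (`v ← v − w·∇²v`, default 2
iterations, weight 0.3) followed by averaging — standing in for
template-based super-resolution pipelines; results for it characterize
that surrogate only. The fusion operates on preprocessed magnitude
images, not raw scanner k-space; on-scanner implementation via k-space
trajectory changes is out of scope, as are registration,
skull-stripping, group statistics and reader studies.
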