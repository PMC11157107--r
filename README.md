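# fousr

Fourier-domain super-resolution fusion of orthogonal anisotropic MRI.

## The problem

Ultra-low-field (ULF, < 0.1 T) MRI scanners are portable and cheap but
signal-starved, so clinical ULF FLAIR protocols acquire thick slices:
1.7 mm × 1.7 mm in plane, 5 mm through plane. In k-space terms a
thick-slice scan never measures the outer spatial frequencies along its
slice axis. When the same head is scanned in two orthogonal planes, the
two k-space coverages are complementary — each scan holds the high
frequencies the other is missing.

`fousr` reconstructs a single sharper isotropic volume by splicing the
two centered spectra. With base spectrum *B*, donor spectrum *D*, donor
slice axis *a*, axis extent *N*, centre *c* = ⌊N/2⌋ and band width *w*,

    S(k) = D(k)   if k_a ∈ [c − ⌊w/2⌋, c − ⌊w/2⌋ + w)
           B(k)   otherwise,

and the fused image is |F⁻¹S|. The default *w* comes from the geometry:
a *t* mm slice at *p* mm in-plane resolution reliably measured only
`round(N / (t/p))` central planes — for the 5 / 1.7 mm, 160-line
protocol a 2.94-fold factor and 54 lines (an empirically tuned 64 is a
known preset for that protocol and can be passed as an override). The
package also ships the matching image-quality suite (SNR, CNR, lesion
conspicuity, variance-of-Laplacian sharpness, per-lesion log sharpness),
a digital phantom generator with simulated thick-slice acquisitions
under Rician noise, comparator reconstructions, and a command-line
pipeline. It is aimed at researchers working on low-field MRI
reconstruction and at anyone who needs a fully testable reference
implementation of k-space splice fusion.

## Worked example

Simulate a ground-truth phantom, image it twice with orthogonal 5 mm
slice stacks at a single-scan SNR of about 40, fuse, and score every
reconstruction:

```r
library(fousr)

ph    <- make_phantom(phantom_spec(shape = c(64, 64, 64), seed = 1))
sigma <- noise_sigma_for_snr(40, signal_level = 1.6)
scans <- simulate_orthogonal_pair(
  ph$truth,
  acquisition_sim(acquisition_geometry(1.7, 5, slice_axis = 2), sigma, seed = 11),
  acquisition_sim(acquisition_geometry(1.7, 5, slice_axis = 3), sigma, seed = 12))

run <- run_fuse(list(base = scans$a, donor = scans$b,
                     lesion_mask = ph$rois$lesion_mask,
                     nawm_mask  = ph$rois$nawm_mask,
                     noise_mask = ph$rois$noise_mask))
#> preprocessed to 64x64x64 voxels at 1.7 mm isotropic
#> fusion plan: 22 centered planes along axis 3 (band_width = auto)
#> scored 5 methods on 8 lesions

run$report
#> # A tibble: 5 × 7
#>   method              snr   cnr conspicuity image_sharpness n_lesions mean_log_lesion_sharpness
#>   <chr>             <dbl> <dbl>       <dbl>           <dbl>     <int>                     <dbl>
#> 1 base              38.4  13.8        0.218           0.399         8                    -0.641
#> 2 donor             38.3  14.0        0.223           0.374         8                    -0.654
#> 3 average           54.3  19.6        0.220           0.306         8                    -0.901
#> 4 sharpened_average  7.27  2.88       0.247           2.73          8                     1.27
#> 5 FouSR             40.6  14.9        0.225           0.420         8                    -0.492
```

Reading the table: averaging the two scans buys SNR (54.3 vs ~38) at the
price of the lowest sharpness of any method (0.306) — averaging two
images blurred along different axes blurs both. The spectrum splice
(`FouSR`) keeps SNR at the single-scan level while scoring the highest
honest sharpness (0.420) and the highest per-lesion boundary sharpness
(−0.49 in log units). The `sharpened_average` row illustrates why raw
Laplacian sharpening is not a free lunch: its sharpness score explodes
because sharpening amplifies noise, which the collapsed SNR (7.3)
exposes. Conspicuity, which ignores the noise region, is nearly method-
independent, as it should be for intensity-preserving reconstructions.

The band width resolved to 22 because the 64-line axis supports
`round(64 / (5/1.7)) = 22` measured planes; on the clinical 160-line
grid the same rule gives the familiar numbers:

```r
compute_band_count(5, 1.7, 160)
#> $factor
#> [1] 2.94
#> $n_lines
#> [1] 54
```

`band_sweep()` scores a range of widths and `autoplot()` displays the
sweep; `intensity_profile()` extracts per-method line profiles across
structure edges; `write_volume()` saves any result as NIfTI. A thin CLI
(`inst/cli/fousr.R`) exposes `fuse`, `simulate`, `metrics`, `sweep` and
`profile` subcommands over the same functions.

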