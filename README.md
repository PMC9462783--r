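# stripesim

Simulation and reconstruction of stripe-pattern structured illumination
microscopy (SIM) in pure R.

A SIM microscope projects a sinusoidal stripe pattern onto the sample —
here modelled as a binary stripe pattern displayed on a digital micromirror
device (DMD), whose fundamental harmonic after the optics is the effective
sinusoid. Multiplying the sample by the pattern mixes high sample
frequencies down into the passband of the objective; recording nine raw
frames (3 stripe orientations × 3 phase steps), algebraically separating
the mixed frequency bands, shifting each band back to its true position and
fusing them with a generalized Wiener filter yields an image whose lateral
resolution exceeds the diffraction limit by up to a factor of
1 + |k<sub>θ</sub>|/k<sub>c</sub> (1.8× at the default stripe frequency of
0.8 k<sub>c</sub>).

The package covers the full chain:

| Stage | Functions |
|---|---|
| DMD patterns | `generate_stripe_pattern()`, `pattern_sequence()`, `pixel_shift_for_phase()`, `period_to_nm()` |
| Optics | `optical_system()`, `cutoff_frequency()`, `analytic_otf()`, `otf_to_psf()`, `load_measured_otf()` |
| Forward simulation | `make_ground_truth()`, `illumination_model()`, `simulate_stack()`, `sim_noise()` |
| Pre-processing | `preprocess_stack()`, `histogram_match()`, `median_filter()` |
| Parameter estimation | `estimate_all()`, `find_modulation_peak()`, `refine_frequency_subpixel()`, `phase_at_frequency()` |
| Reconstruction | `reconstruct()`, `separation_matrix()`, `separate_components()`, `fourier_shift()`, `wiener_combine()` |
| Backends | `list_backends()`, `use_backend()`, `backend_map()`, `launch_geometry()` |
| I/O and pipeline | `read_stack()`, `write_stack()`, `read_config()`, `run_pipeline()`, `inst/cli/stripesim.R` |
| Metrics | `measure_fwhm()`, `spectral_support_radius()` |

## The model in brief

Each raw frame is `D_n = (I_n · S) ⊗ PSF` with illumination
`I_n(r) = I0 (1 + m cos(2π k_θ·r + φ_n))`. In the Fourier domain,

```
D̃_n(k) = I0 [ S̃(k) + (m/2) e^{iφ_n} S̃(k − k_θ) + (m/2) e^{−iφ_n} S̃(k + k_θ) ] · OTF(k)
```

Three frames per orientation give a 3×3 linear system per pixel; its
inverse (the separation matrix) recovers the three bands. The plus/minus
bands are translated by ∓k<sub>θ</sub> via a Fourier phase ramp on a 2×
zero-embedded grid, then all nine bands (three per orientation) are fused:

```
S_SIM(k) = Σ_n OTF_n*(k) R_n(k)  /  ( Σ_n |OTF_n(k)|² + w )
```

The incoherent OTF is the classic autocorrelation-of-pupil form with
cutoff k<sub>c</sub> = 2·NA/λ (0.2423 cycles/px at NA 1.4, λ 520 nm,
45 nm pixels).

Illumination parameters are estimated *from the raw data*: a coarse peak
is found on the frame-to-widefield cross-correlation spectrum, the stripe
frequency is refined to sub-pixel precision by an OTF-cross-weighted band
correlation evaluated with a zoomed DTFT, and the per-frame phases are
read off the raw spectra at the refined frequency (phase of peak). See
`vignettes/sim-reconstruction-methods.Rmd` for derivations and the
reasoning behind each estimator.

## Worked example

Simulate a noisy 256×256 bead sample, estimate the illumination parameters
blindly, and reconstruct. Output below is the actual console output.

```r
library(stripesim)

sys <- optical_system(na = 1.4, wavelength_nm = 520, pixel_nm = 45,
                      shape = c(256, 256))
print(sys)
#> Optical system: NA 1.4, lambda 520 nm, pixel 45 nm, grid 256 x 256
#>   cutoff: 0.005385 cycles/nm (185.7 nm period), 0.2423 cycles/px

truth <- make_ground_truth("beads", c(256, 256), seed = 7, n = 150,
                           blur_sigma = 2)
stack <- simulate_stack(truth, sys,
                        noise = sim_noise(photons = 2000, sigma_read = 2),
                        seed = 7)
print(stack)
#> SIM raw stack: 9 frames of 256 x 256 (orientation-major)
#>   nominal orientations: 0.0, 60.0, 120.0 deg, m = 0.8

otf <- analytic_otf(sys)
est <- estimate_all(stack, otf)   # blind: uses only the 9 raw frames
summary(est)
#> SIM illumination parameter estimate
#>   orientation 1: theta =   -0.00 deg, |k| = 0.19391 cycles/px (49.64, -0.00 cells), phases = 0.89, 118.70, -122.66 deg
#>   orientation 2: theta =   60.00 deg, |k| = 0.19385 cycles/px (24.81, 42.98 cells), phases = 0.85, 119.18, -119.31 deg
#>   orientation 3: theta =  -60.00 deg, |k| = 0.19387 cycles/px (24.81, -42.98 cells), phases = 1.56, -119.39, 119.86 deg
#>   m (assumed) = 0.8; m_est = 0.72, 0.72, 0.73; peak significance = 21, 24, 25
#>   cutoff k_c = 0.2423 cycles/px; |k|/k_c = 0.800, 0.800, 0.800

recon <- reconstruct(stack, est, otf)
print(recon)
#> SIM reconstruction: 512 x 512 image (input 256 x 256)
#>   effective cutoff 0.4362 cycles/px (widefield 0.2423): support extended 1.80x
#>   Wiener w = 0.1, apodization = none, imaginary residual 8.03e-04
```

The estimated stripe frequency (nominal 0.8 k<sub>c</sub> = 0.19387
cycles/px) is recovered to within a few 10⁻⁵ cycles/px and the 0/±120°
phase steps to about a degree, even with Poisson + read noise.

Resolution gain on an isolated sub-diffraction bead, reconstructed with the
true parameters (noiseless):

```r
sharp  <- make_ground_truth("beads", c(256, 256), seed = 11, n = 25, margin = 24)
stack2 <- simulate_stack(sharp, sys, seed = 11)
recon2 <- reconstruct(stack2, stack2$meta$model, otf)
ctr <- sharp$centers[1, ]
measure_fwhm(recon2$widefield, ctr, pixel_nm = 45)$fwhm       # widefield, nm
#> [1] 192.1422
measure_fwhm(recon2$image, 2 * ctr - 1, pixel_nm = 22.5)$fwhm  # SIM, nm
#> [1] 102.7209
```

192 nm matches the Airy-core prediction 0.514 λ/NA ≈ 191 nm; the SIM
reconstruction narrows the bead to 103 nm (ratio 0.53).

## Pipeline and command line

The same chain runs from a YAML configuration:

```yaml
# config.yaml — every key optional; these are the defaults
optics:        {na: 1.4, wavelength_nm: 520, pixel_nm: 45}
illumination:  {orientations_deg: [0, 60, 120], phases_deg: [0, 120, 240],
                period_px: 6, ktheta_frac: 0.8, m: 0.8}
estimation:    {r_inner_frac: 0.3, r_outer_frac: 1.1, min_significance: 5, refine: true}
reconstruction: {w: 0.1, pad_factor: 2, apodization: none}
preprocess:    {enabled: true, reference_index: 1, median_window: 3}
backend: serial
seed: 1
```

```r
cfg <- read_config("config.yaml")
run_pipeline(cfg, "stack.tif", "out/")
# out/: recon.tif, widefield.tif, params.json, manifest.json
```

or from the shell via the installed CLI script:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "stripesim.R", package = "stripesim"))')
Rscript "$CLI" simulate --kind beads --shape 256 --seed 7 --out stack.tif
Rscript "$CLI" run --stack stack.tif --out out/
```

Raw stacks are multi-page TIFF (or a directory of single-page TIFFs),
orientation-major: frames 1–3 are the three phases of orientation 1, etc.
`write_stack()` stores float32 with a JSON sidecar recording an exactly
invertible power-of-two scale/offset, so round trips are lossless.

Elementwise stages run through a swappable backend (`serial`, `threads`);
both produce bit-identical reconstructions.

## Tests

```sh
R CMD INSTALL .
Rscript -e 'testthat::test_dir("tests/testthat", package = "stripesim", load_package = "installed")'
```

The suite includes property tests against brute-force oracles (median
filter, band separation, Fourier shift) and `tests/testthat/test-acceptance.R`
with one block per end-to-end acceptance check (pattern arithmetic, frame count,
blind estimation accuracy over seeds, resolution gain, oracle
equivalences, backend equality, phase-error monotonicity).

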