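---
title: "Methods: stripe-pattern SIM simulation and reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stripe-pattern SIM simulation and reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the mathematical model, the estimation and
reconstruction algorithms, the numerical conventions, and the known
limitations of **stripesim**. It is a methods reference, not a tutorial;
see the README for a worked end-to-end example.

## 1. Image-formation model

A structured-illumination acquisition illuminates the fluorophore density
$S(\mathbf r)$ with a sinusoidal stripe field

$$I(\mathbf r) \;=\; I_0\,\bigl(1 + m \cos(2\pi\,\mathbf k_\theta\!\cdot\!\mathbf r + \varphi)\bigr),$$

where $\mathbf k_\theta$ is the 2-D stripe frequency at orientation
$\theta$, $\varphi$ the pattern phase and $m \in [0,1]$ the modulation
depth. The camera records

$$D(\mathbf r) \;=\; \bigl[(I \cdot S) \otimes \mathrm{PSF}\bigr](\mathbf r),$$

so in frequency space each raw frame is a three-band mixture attenuated by
the OTF:

$$\tilde D(\mathbf k) \;=\; I_0\Bigl[\tilde S(\mathbf k)
 + \tfrac m2 e^{ i\varphi}\,\tilde S(\mathbf k-\mathbf k_\theta)
 + \tfrac m2 e^{-i\varphi}\,\tilde S(\mathbf k+\mathbf k_\theta)\Bigr]\,
 \mathrm{OTF}(\mathbf k).$$

The shifted copies alias sample frequencies up to
$k_c + |\mathbf k_\theta|$ into the passband — the moiré effect that SIM
inverts. A full acquisition is $3$ orientations $\times$ $3$ phases $= 9$
frames, orientation-major.

### Optics

The incoherent OTF of a circular pupil is used in closed form,
$O(\rho) = \tfrac 2\pi\bigl(\arccos\rho - \rho\sqrt{1-\rho^2}\bigr)$ with
$\rho = |\mathbf k|/k_c$ and cutoff $k_c = 2\,\mathrm{NA}/\lambda$
(`cutoff_frequency`, `analytic_otf`). A measured OTF image can be
substituted (`load_measured_otf`). Defaults follow a high-NA oil objective
imaging green emission: NA $1.4$, $\lambda = 520$ nm, $45$ nm sample-plane
pixels, giving $k_c \approx 0.2423$ cycles/px; the default illumination
frequency is $|\mathbf k_\theta| = 0.8\,k_c$ at orientations
$0^\circ/60^\circ/120^\circ$ and phases $0^\circ/120^\circ/240^\circ$,
$m = 0.8$. These problem sizes and defaults are the package's own choices
for desk-scale work on a single CPU; nothing in the code depends on them.

### DMD patterns

On a digital micromirror device the stripes are binary (mirror on/off), so
phase steps must be integer mirror shifts: a step of $\varphi$ at period
$P$ px is $P\varphi/2\pi$ px (`pixel_shift_for_phase`). The canonical
three-step acquisition with $120^\circ$ steps and a 50 % duty cycle
therefore needs $P = 6$ px (3 on, 3 off): the step is exactly 2 px. At the
sample plane a period of e.g. 33 px $\times$ 45 nm/px is 1485 nm/cycle
(`sample_period_nm`).

### Forward simulator

`simulate_stack` evaluates the illumination in *real space* at a
continuous frequency, multiplies by the ground truth and convolves
circularly via the OTF. Off-grid $\mathbf k_\theta$ is therefore
represented exactly — necessary for exercising sub-pixel frequency
estimation. Noise (optional) is Poisson shot noise at a configurable peak
photon budget plus Gaussian read noise (`sim_noise`), reproducible by
seed. Ground-truth generators (`make_ground_truth`) provide point-source
beads, a Siemens-star spoke target, random-walk filaments, or custom
matrices, each optionally Gaussian-blurred (`blur_sigma`) to produce a
band-limited sample.

**Generator realism and limitations.** Frames are noiseless-exact to the
model above but idealized relative to a real microscope: circular
(wrap-around) boundaries, no background fluorescence, no out-of-focus
light (the model is strictly 2-D), no spherical aberration or OTF
anisotropy, perfectly sinusoidal illumination (a real DMD square wave also
carries higher harmonics that the objective largely filters out at these
periods), and shot noise applied per pixel without camera gain structure.

## 2. Pre-processing

`preprocess_stack` histogram-matches every frame to a reference frame
(monotone quantile mapping on unique values, so pixel rank order is
preserved) and applies a $3\times3$ median filter (exact median-of-9
sorting network, mirror-reflected edges). Matching removes frame-to-frame
intensity drift so it is not mistaken for modulation; the median filter
rejects impulse noise before anything reaches the frequency domain.

## 3. Illumination-parameter estimation

Reconstruction quality is limited by how well $\mathbf k_\theta$ and the
phases are known; both are measured from the data (`estimate_all`).

**Widefield removal.** For equispaced phases the $0$th band is identical
in the three frames of one orientation, so subtracting the orientation
mean removes it exactly, leaving only the $\pm1$ bands.

**Coarse peak.** The integer-cell peak is the argmax, inside a band-pass
annulus (default $0.3\,k_c \le |\mathbf k| \le 1.1\,k_c$), of the
cross-correlation spectrum between each mean-subtracted frame and the
orientation widefield, $|\mathrm{FFT}(d_n \cdot \bar w)|$. This statistic
peaks at $\pm\mathbf k_\theta$ regardless of the sample's spectral shape;
the plain band magnitude does not — the band carries
$\tilde S(\mathbf k - \mathbf k_\theta)$, which is largest toward DC, and
under the OTF weighting its argmax can sit several cells from
$\mathbf k_\theta$ for low-pass samples. Of the conjugate pair the
positive-$k_x$ member is reported; a peak-to-median significance gate
turns "no stripes present" into an error rather than a garbage estimate.

**Sub-pixel frequency.** The separated $+1$ band is a copy of the $0$th
band translated by $\mathbf k_\theta$, so their cross-correlation peaks at
the true frequency. The correlation is evaluated as the zoomed DTFT of the
pixelwise product $b_+ \bar b_0$ and maximized over a three-stage grid
($\pm1.5$ cells at $0.1$, then $0.02$, then $0.002$-cell granularity).
Two details matter for accuracy (`refine_frequency_subpixel`):

1. *OTF cross-weighting.* Band 0 is multiplied by
   $\mathrm{OTF}(\mathbf k + \hat{\mathbf k})$ and band $+1$ by
   $\mathrm{OTF}(\mathbf k - \hat{\mathbf k})$. Both correlation terms then
   carry the identical weight
   $\mathrm{OTF}(\mathbf u)\,\mathrm{OTF}(\mathbf u + \mathbf k_\theta)$
   at source frequency $\mathbf u$, making the correlation magnitude an
   autocorrelation — maximal exactly at zero lag (Cauchy–Schwarz). Without
   this the asymmetric weighting biases the peak by a few hundredths of a
   cell, which propagates into a common phase offset of several degrees
   ($\Delta\varphi \approx 2\pi\,\delta\mathbf k \cdot \bar{\mathbf r}$).
   The whole step is iterated once so the weights use the refined
   frequency.
2. *Raw separation.* The bands entering the correlation are separated from
   unfiltered spectra; a Wiener pre-filter would attach a weight to one
   band that the other does not share and re-introduce a small bias.

**Phases.** With the refined frequency, each frame's phase is the complex
argument of the single-frequency DTFT of the mean-subtracted frame — the
"phase of peak" estimator evaluated off-grid. The modulation depth is
estimated per orientation from the peak amplitude against the widefield DC
and the OTF value at $\mathbf k_\theta$ (`m_est`), with the band
separation itself using a user-supplied $m$ (default $0.8$).

**Accuracy and limitations.** On noiseless band-limited samples the
estimator is essentially exact (angle error $\le 10^{-3}$ degrees,
$|\mathbf k|$ error $\le 10^{-3}$ cells, phase error $\le 0.2^\circ$ at
$512^2$). For *broadband* samples (unblurred point sources) the absolute
phases degrade: sample content at $2\mathbf k_\theta$ leaks between the
$\pm1$ bands, and a non-iterative phase-of-peak estimator cannot separate
it. Parameter-recovery studies therefore use low-pass (blurred) samples;
resolution studies use point sources with known parameters.

## 4. Reconstruction

Per orientation (`reconstruct`):

1. **Band separation.** The three phase-stepped spectra are a linear
   mixture with matrix rows
   $[1,\ \tfrac m2 e^{i\varphi_n},\ \tfrac m2 e^{-i\varphi_n}]$;
   `separation_matrix` inverts it (exactly for pairwise-distinct phases)
   and `separate_components` applies the inverse pixelwise.
2. **Fourier shift.** Bands are embedded in a `pad_factor`-times larger
   frequency grid (same bin spacing, doubled range, so the extended
   support is not clipped), then the $\pm1$ bands are translated by
   $\mp\mathbf k_\theta$ via a complex exponential ramp in real space
   (`fourier_shift`) — exact for non-integer shifts. After the shift the
   $+1$ band is $\tilde S(\mathbf k)\,\mathrm{OTF}(\mathbf k + \mathbf
   k_\theta)$: sample information beyond $k_c$ now sits at its true
   position under a shifted passband (`shifted_otf`).
3. **Generalized Wiener fusion.** The nine bands are combined as
   $$\tilde S_{\mathrm{SIM}}(\mathbf k) = \frac{\sum_n
   \mathrm{OTF}_n^*(\mathbf k)\, R_n(\mathbf k)}{\sum_n
   |\mathrm{OTF}_n(\mathbf k)|^2 + w},$$
   with Wiener constant $w$ (default $0.1$ against a DC-normalized OTF).
   An optional triangle apodization tapers the spectrum to zero at the
   extended cutoff $k_c + \max_\theta |\mathbf k_\theta|$ to suppress
   ringing. The inverse transform's real part, scaled by
   `pad_factor`$^2$, is the reconstruction — on pixels half the input
   size for the default `pad_factor = 2`.

With the defaults the effective cutoff is $1.8\,k_c$; on synthetic beads
this halves the measured FWHM-limited spot size (widefield $\approx192$ nm
matching the Airy expectation $0.51\lambda/\mathrm{NA}$, SIM
$\approx103$ nm) and extends the $1\%$-level spectral support by more than
$0.7\,|\mathbf k_\theta|$ beyond $k_c$ (`measure_fwhm`,
`spectral_support_radius`).

Phase errors produce the classic SIM artefacts: residual un-demixed band
content beats against the true image. Reconstruction error against ground
truth grows monotonically with imposed phase perturbations
($0^\circ/10^\circ/30^\circ$), which the acceptance suite checks.

## 5. Execution backends

The fusion inner loop is a handful of element-wise array operations routed
through a registry (`elementwise`, `list_elementwise_ops`). Two backends
ship: `serial` (vectorized base R, the reference semantics) and `threads`
(row tiles dispatched over forked workers; tile heights follow the
CUDA-style `launch_geometry` with 32-row blocks). Backends must agree with
the serial reference to float tolerance — the test suite enforces
equality — so switching backends is purely an execution choice. Additional
executors (e.g. a GPU array library) can be attached at run time with
`register_backend`.

A note on `launch_geometry`: blocks per axis are computed as
`ceiling(size/dim)`. The literal integer idiom `ceil((size + dim - 1) /
dim)` over-allocates one block when `dim` divides `size` if evaluated in
floating point; the intent — full coverage with minimal overhang — is what
is implemented and documented.

## 6. Numerical conventions

* User-facing spectra are **centered**: DC at `floor(n/2)+1` per axis
  (`dc_index`), converted with `fftshift2`/`ifftshift2`.
* Coordinates: `x = col - 1`, `y = row - 1`, origin top-left; frequencies
  in cycles/px; "cells" are frequencies times the grid size.
* Frame and orientation indices are 1-based; stacks are orientation-major
  (frame $3(o-1)+j$).
* Of a conjugate peak pair the positive-$k_x$ member is canonical. An
  estimate may therefore be the negated twin of the simulator's
  $\mathbf k_\theta$ with negated phases — self-consistent for
  reconstruction; comparisons against ground truth must sign-align first.
* TIFF round trips: float stacks are scaled by the smallest power of two
  reaching $[0,1]$ (exact in binary floating point) and the scale (plus an
  offset for signed images) is stored in a JSON sidecar, so
  `write_stack`/`read_stack` and `write_image`/`read_image` are lossless
  at float32 precision.

## 7. Limitations

* Strictly 2-D: no optical sectioning, no 3-D SIM order separation.
* Non-iterative parameter estimation (no joint refinement of $m$, phases
  and frequency against the reconstruction); absolute phase accuracy on
  broadband samples is limited as described in §3.
* Circular convolution throughout; real data with hard edges should be
  windowed before processing.
* The `threads` backend requires fork-capable platforms for actual
  parallelism (it falls back to one worker elsewhere) and speeds up only
  the element-wise stage, not the FFTs.
* The analytic OTF assumes an aberration-free circular pupil; use a
  measured OTF for real optics.
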