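---
title: "A foveated log-polar model of binocular disparity processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A foveated log-polar model of binocular disparity processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fovdisp)
```

## The problem

Human spatial resolution falls roughly logarithmically with eccentricity,
and visual input is organized in polar coordinates: the projection from
retina to primary visual cortex is well described by a log-polar
transform. `fovdisp` implements an image-computable model of how this
space-variant architecture shapes stereoscopic depth perception. The model
takes stereo image pairs, resamples them through a discrete log-polar
retino-cortical mapping, processes the cortical images with a population
of phase-shift binocular-energy units pooled into MT-like
vector-disparity units, and decodes a disparity field. Driven by the same
adaptive-staircase psychophysics used with human observers, it acts as a
simulated participant whose disparity sensitivity function (DSF) can be
measured in any annular region of the visual field.

## The retino-cortical front end

The central blind-spot model maps a Cartesian point at polar coordinates
$(\rho, \vartheta)$ to cortical coordinates

$$\xi = \log_a (\rho / \rho_0), \qquad \eta = q\,\vartheta,$$

with $a = (\rho_{max}/\rho_0)^{1/R}$ and $q = S/2\pi$. Points with
$\rho < \rho_0$ are discarded (the log singularity). Discretizing to
integer $(u, v)$ gives an $R \times S$ rings-by-sectors cortical grid. The
sector count defaults to the isotropy rule $S = \mathrm{round}(2\pi/(a-1))$,
which equates local circular and radial sampling intervals and keeps
log-polar pixels near unit aspect ratio. Three derived quantities
summarize a mapping: the compression ratio $CR = N_c N_r / (R S)$ (the
strength of cortical magnification), the maximum receptive-field size
$W_{max} = \rho_0 a^R (1 - a^{-1})$, and the fraction of rings
over-representing the fovea $\chi$.

Forward resampling uses overlapping circular Gaussian receptive fields.
The RF size is a free choice of the mapping, so the package
sets each ring's Gaussian $\sigma$ to half the local log-polar pixel
width, floored at 0.5 Cartesian pixels in the oversampled fovea and
truncated at $3\sigma$; this gives roughly two-fold RF overlap and
anti-aliases the undersampled periphery. The backward transform (used for
visualization and for bringing decoded fields back to retinal
coordinates) interpolates bilinearly in $(\xi, \eta)$ with circular wrap
in $\eta$.

```{r}
m <- lp_mapping(192, 192, R = 61, rho0 = 2)
m
```

At the reference full-scale geometry ($R = 318$, $\rho_0 = 9$ px,
$CR = 6.4$, a 21-degree field), the cortical disparity limit of
$\pm 1.52$ cortical pixels corresponds to a retinal disparity range of
about $\pm 0.43$ arcmin at the foveal edge, growing linearly with
eccentricity to about $\pm 24$ arcmin at 21 degrees:

```{r}
geom <- solve_field_geometry(R = 318, rho0 = 9, CR = 6.4)
disparity_range_arcmin(geom, D = 1.52, field_deg = 21)
```

(The peripheral endpoint is sometimes quoted as $\pm 25$ arcmin; the
geometry above computes 24.2. The package reports the computed value.)

## The cortical population model

V1 binocular simple cells are complex Gabor filters applied directly to
the cortical images — uniform cortical
processing that becomes space-variant retinal processing. Defaults follow
the reference parameterization: peak frequency $f_s = 0.13$
cycles/cortical pixel, envelope $\sigma = 5.12$ cortical pixels (about
0.70 octaves at the one-spectral-standard-deviation cutoff), $N = 12$
tuning directions, $K = 5$ interocular phase-difference channels spanning
a cortical disparity range $D = \pm 1.52$ pixels via
$\Delta\psi = -2\pi f_s d$. Binocular energy is the squared modulus of
the quadrature pair; a power-0.5 static nonlinearity and divisive
normalization across orientations confer contrast invariance. MT units
pool V1 responses over space (Gaussian, $\sigma_{pool} = 3.66$ cortical
pixels) and orientation (cosine weights $w_\phi(\theta) =
\cos(\phi - \theta)$), followed by an exponential nonlinearity with gain
$\lambda = 0.65$; two tuning directions $\phi \in \{0, \pi/2\}$ suffice to
encode the full disparity vector. Uniform zero-mean noise with half-width
a fraction of the local average activity (34% at V1, 18% at MT) is drawn
fresh every trial.

Three implementation choices deserve note, because the printed equations
leave them open:

* **Direction population.** The cosine MT weights with
  $\phi \in [0, 2\pi]$ require the orientation population to sample
  *directions* over the full circle; restricted to $[0, \pi)$ the
  cosine-weighted sum cancels the disparity-sign information and the
  decoder collapses. The package samples $N$ directions over $[0, 2\pi)$,
  implemented with $N/2$ convolutions plus conjugate symmetry.
* **Decoder calibration.** The linear population read-out
  $d_\xi = \sum_i d_i E^{MT}(p, 0, d_i)$ has uncalibrated gain: the
  center of mass of the broad raised-cosine channel tuning underestimates
  a true shift by a fixed factor. By default the package divides by the
  population sum and by a decoder gain measured once per observer from
  known uniform shifts pushed through the noiseless stack. The raw
  printed form is available with `normalize = FALSE`.
* **Noise and grid size.** Noise fractions are interpreted as stated for
  the reference $318 \times 494$ cortical grid. With i.i.d. noise per
  unit, the noise power surviving in the decoded map scales as
  $1/\sqrt{n}$; observers on smaller grids therefore scale the fractions
  by $\sqrt{n/n_{ref}}$ so that the simulated observer's effective
  internal noise is invariant to the simulation size. Disable with
  `noise_ref_units = NULL`.

With these choices, uniform cortical shifts within $\pm D$ are recovered
within one channel spacing at the large majority of nodes — the core
parameter-recovery property of the decoding stack, exercised directly in
the test suite.

## Stimuli

Stimuli are 1/f pink-noise stereograms carrying oblique (45 or 135
degree) sinusoidal disparity corrugations inside annular windows with
1-degree raised-cosine edges, spanning the foveal (0–3 deg), mid (3–9
deg), far (9–21 deg) or full (0–21 deg) visual field. Disparity is
applied as symmetric half-shifts ($\pm d/2$) to the two eyes by cubic
resampling, keeping the cyclopean geometry centered. The degree-to-pixel
scale defaults to the mapping's own $\rho_{max}/21$; at full scale this
equals the ~23.8 px/deg of the laboratory display the stimuli emulate.
The generator is seeded and bit-reproducible; no fixation target is
rendered for the model observer, since it carries no disparity
information.

## The simulated psychophysical observer

Each trial draws a fresh stereogram at the staircase's current
peak-to-trough disparity with a random tilt; the model decodes a cortical
disparity field, only units within the stimulated annulus contribute
(the cue-combination stage), and a 2AFC read-out compares the decoded
horizontal disparity against the two candidate corrugation templates.
The read-out works node-wise on the cortical grid in cortical-pixel
units: every neural unit carries comparable noise, so equal per-node
weighting is the reliability-weighted choice, cortical magnification
automatically emphasizes the fovea, and full-field sensitivity becomes
the near-optimal envelope of the regional sensitivities. (A retinal-map
Fourier peak read-out, `tilt_decision()`, is also provided; on reduced
grids it is dominated by Jacobian-amplified peripheral noise.)

Thresholds come from three-down one-up staircases (converging at
$(1/2)^{1/3} \approx 79.4\%$ correct) with symmetric multiplicative steps
(×1.5 before two reversals, ×1.26 after; start 20 arcmin — clearly
visible), pooled across staircases and fitted with a cumulative normal in
log disparity by weighted least squares (weights = reciprocal binomial
SD); the threshold is the 75% point. Sensitivities (1/threshold) across
the six corrugation frequencies (0.04–1.41 cycles/degree) are fitted with
the three-parameter log-parabola DSF; regional thresholds combine across
the visual field by the inverse-variance (MLE) rule
$T_{opt}^{-2} = \sum_v T_v^{-2}$.

## Problem sizes and what they preserve

The package's tests and examples run the observer on 192-pixel images
(4.6 px/deg) with a 61 × 96 cortical grid and a protocol of 3 staircases
× 40 trials per condition — a deliberate reduction from the full-scale
geometry (1002-pixel images, 318 × 494 grid, 24 × 75 staircase trials),
which needs hours per experiment. The reduction preserves the mapping's
compression ratio (≈ 6.4), the cortical-domain filter parameters, and the
ratio of foveal to peripheral disparity range, so the ordering phenomena
— disparity tuning shifting from fine to coarse scales with eccentricity,
peak sensitivity decreasing peripherally, full-field sensitivity
enveloping the regional curves, and the direction-of-effect of the
compression-ratio, RF-size and noise sweeps — are preserved. Absolute
quantities are not: arcmin-per-pixel is ~5 times coarser, so thresholds
and peak frequencies sit lower than at full scale, and the foveal
fall-off at the lowest corrugation frequency (driven at full scale by the
tiny foveal disparity range) does not reproduce at desk scale. Passing
tests therefore certify orderings and recovery properties, not the
absolute human-scale DSF values.

## Numerical notes and degenerate inputs

* Cortical convolutions wrap circularly along $\eta$ (the cortex is an
  annulus) and mirror along $\xi$; the `noLP` variant mirrors both axes.
* Divisive normalization uses a floor $\varepsilon$ so zero-texture
  regions stay exactly zero rather than 0/0.
* Degenerate psychophysical data (all correct, all wrong, one level) are
  flagged `converged = FALSE` with the threshold pinned at the data
  bound; zero-amplitude stimuli produce seeded random guesses and ~50%
  accuracy.
* The DSF fit is a quadratic regression in log frequency (exact for
  noiseless log-parabola data); when the fitted curvature is not
  negative, a bounded grid search over the peak frequency takes over.
* Staircase levels are clamped to [1e-4, 120] arcmin; the upper clamp
  matches the 2-degree sanity bound of the stimulus renderer.

## Model variants

`model_config(variant = ...)` selects: `LP` (default), `LP2S` (a second,
2× coarser cortical scale whose decoded field is averaged in), `noLP`
(the log-polar front end replaced by uniform downsampling with a
comparable unit count), and `noLP2S`. The `noLP` variants decode the same
disparity everywhere (no eccentricity fall-off) and lose the
fovea-to-periphery ordering of DSF peak frequencies — removing the
log-polar stage removes the model's account of the human pattern.

## Limitations

The model omits vertical/horizontal disparity anisotropies,
crossed/uncrossed asymmetries across the upper and lower field,
vergence-aware epipolar geometry, second-order channels, and
coarse-to-fine warping refinement. The synthetic cohort utilities
(`agreement_metrics`) compare the model against user-supplied human
sensitivity tables; no human raw data ship with the package.
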