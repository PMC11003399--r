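---
title: "Computer-generated acousto-optic holography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computer-generated acousto-optic holography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aoholo)
```

## The patterning problem

An acousto-optic deflector (AOD) diffracts a laser beam from a traveling
acoustic wave and thereby modulates the optical phase — and, through the
acoustic amplitude, also the optical amplitude — along one spatial axis. When
the acoustic waveform is time-locked to a low-repetition pulsed laser
(synchronous mode), every pulse sees a static phase grating, and the device
behaves as a 1D spatial light modulator with an essentially unlimited phase
stroke. Two AODs in a crossed configuration then produce wavefronts of the
separable form

$$\varphi(x, y) = \varphi_x(x) + \varphi_y(y),$$

the *pseudo-2D* (ps2D) function space. The package answers the associated
inverse problem: given a wanted intensity pattern in the focal (target)
plane, find axis holograms — phase profiles, optionally with amplitude
masks — whose reconstruction renders the pattern, and convert them to the
acoustic frequency envelopes that drive the device.

Everything is computed within scalar paraxial Fourier optics: the
holographic (pupil) and target planes are connected by a unitary,
DC-centered discrete Fourier transform, so total power is conserved and the
field center sits at index $N/2$ (0-based) in both planes. Out-of-focus
propagation, vectorial diffraction and device physics (acoustic attenuation,
transducer response, chromatic dispersion) are out of scope.

## Retrieval engines

All engines are Gerchberg–Saxton iterations: alternate between the planes,
imposing in the target plane the wanted amplitude and in the holographic
plane the illumination constraint, keeping the evolving phase.

* **Static target** (`gs_static`): the full target amplitude is re-imposed
  on the whole plane every cycle; the holographic amplitude is clamped to
  the input beam. The output is a phase-only (FM) hologram; the final
  holographic amplitude is retained for later apodization. Point patterns
  reconstruct with inhomogeneous peaks and ghost side lobes, because the
  algorithm must simultaneously render the target and suppress the higher
  diffraction orders it clamps to zero.
* **Dynamic target** (`gs_dynamic`): the amplitude constraint acts only on
  the *target domain*; on the complementary *freedom domain* the current
  amplitude is carried over, so side lobes self-organize without being
  fought. A guard band (default 2 samples) separates the two domains. Peak
  homogeneity improves dramatically; on dense targets the method relegates
  speckle into the freedom domain at the cost of on-target power.
* **Apodization** (`apodize`): the stored holographic amplitude, blended
  with a flat mask as $(1-g) + g\,\hat A_H$, is applied post hoc as a
  transmission mask. At $g = 1$ the hologram becomes the exact complex
  conjugate pair of the converged field and the reconstruction is side-lobe
  free; power efficiency decreases monotonically with $g$.
* **Complex retrieval** (`gs_complex`): the holographic amplitude itself is
  optimized, each cycle replaced by a gain-weighted blend of the beam
  amplitude and the current holographic amplitude rescaled to unit maximum.
  The gain ramps linearly from zero (avoiding early stagnation) to its
  maximum $g_{AM} \le 0.99$, reported on the decadic scale
  $g' = 0.5\,\log_{10}(1/(1-g))$. The FM/AM output renders dense objects —
  lines, triangles, parabolas, sinusoids — essentially speckle-free, the
  amplitude-rejected power going to the zero diffraction order.
* **Extended retrieval** (`gs_extended`): plain 1D retrieval implicitly
  models the pupil as a slit; real systems have circular pupils, which mix
  the axes. Each cycle the 1D holographic field is expanded to a separable
  2D field, the circular aperture imposed, and the 1D field recovered from
  the midline of the 2D transform before the target constraint. This costs
  one 2D FFT per cycle but markedly improves circular-aperture
  reconstructions of dense ps2D targets.

## Parameters, units, defaults

| parameter | default | why |
|---|---|---|
| wavelength | 940 nm | infrared two-photon excitation window |
| grid size $N$ | 1024 samples/axis | resolves all built-in targets; 1D retrievals stay millisecond-fast |
| AOD aperture | 15 mm across the grid | typical large-aperture TeO$_2$ device; with $v_{ac}$ = 650 m/s gives $T_{AOD}$ = 23.1 µs, i.e. a 43.3 kHz rate cap compatible with a 40 kHz laser |
| focal length | 8 mm | yields a 0.50 µm/sample target pitch (513 µm field), so the 3/5/7-point targets (4 µm and 3.5 µm spacings) and the 8–21 µm lines are well sampled |
| iterations | 200 (static/dynamic), 10 (complex) | static engines are past stagnation long before 200 cycles (the error is flat from ~20 cycles on); see below for the complex budget |
| gain ramp | linear over the first half of the cycles | "gradual increase" with a single knob; exposed in `ift_config` |
| initial phase | i.i.d. uniform on $[0, 2\pi)$, seeded | maximally diffuse start; correlated alternatives converge to the same attractor |
| beam | uniform for retrieval and rendering; Gaussian (1/e² diameter = aperture) for power budgets | amplitude convention $e^{-4r^2/d^2}$ |

The complex engine's default budget of 10 cycles (5-cycle ramp) is a
deliberate calibration. Amplitude feedback converges very fast — on-target
speckle is below 0.01 within a few cycles — but the *mask* keeps diffusing
toward a nearly flat profile if iteration continues, inflating the
first-order power efficiency (to ~56% for the 8 µm line at 200 cycles)
and erasing the rich modulation depth that complex holograms of dense
targets exhibit. At the 10-cycle budget the 8 µm-line hologram retains that
structure and transmits 42% of a Gaussian beam into the first order, in
line with the power budget such systems report (~40%). Users needing a
flatter mask can simply raise `iterations`.

One number the package does *not* reproduce: the on-target speckle of the
*phase-only* (zero-gain) line reconstruction saturates at an intensity CV of
about 0.21–0.25 once the iteration has stagnated, for every 1D
configuration we explored (pitch 0.125–0.5 µm, slit width 0.5–1.0 of the
grid, 3–1000 cycles, diffuse and correlated initializations). Reports of
zero-feedback speckle well above 0.3 therefore likely reflect evaluation
details we cannot reconstruct; the *trend* — monotone decrease of speckle
with feedback gain, vanishing at full gain — is robust and tested.

## Target error and speckle metrics

`target_error` is the relative RMS amplitude deviation on the target domain
after rescaling the reconstruction to unit maximum there,
$e = \sqrt{\sum_{TD}(\hat A - T)^2 / \sum_{TD} T^2}$, with $e = 1$ for a
vanishing reconstruction. The unit-peak convention matches how such
reconstructions are normalized for display and makes the metric directly
sensitive to peak inhomogeneity; a least-squares rescaling was considered
and rejected because it partially absorbs exactly the inhomogeneity the
metric is meant to expose (it reports ~13% where the peak-normalized error
reports ~19% on the five-point benchmark whose literature value is 17%).

`speckle_noise` is the coefficient of variation of the intensity-to-target
ratio over the target domain — for flat targets simply the intensity CV,
which is 1 for fully developed (exponential-intensity) speckle.
`power_efficiency` divides first-order (post-mask) power by the beam power
entering through the aperture; amplitude modulation is the only loss channel
modeled, the rejected power going to the zero-order sink.
`moving_phase_variance` computes a sliding-window variance of the
reconstructed phase relative to the window's circular mean, so $2\pi$ wraps
do not register as variance; resolving the constant-phase plateaus at the
target peaks requires oversampling the reconstruction
(`reconstruct_1d(..., oversample = 4)`), since at critical sampling each
diffraction-limited spot is a single sample.

## Device mapping

The synchronous-mode transfer relation
$d\varphi/ds = (2\pi/v_{ac})\,\Delta f(s)$ maps unwrapped phase slopes to
acoustic frequency offsets. `phase_to_frequency` uses central differences
(one-sided at the edges) on the physical coordinate (the grid spans the
aperture); `frequency_to_phase` inverts with the *matching* midpoint
(leapfrog) accumulation rather than a trapezoidal rule — the two stencils
are exact inverses, so a conversion roundtrip reproduces any phase profile
to machine precision, which a trapezoidal integral of central differences
does not. 1D phase profiles contain no vortices and always unwrap.
`aod_validate` checks the rate cap $r_{Laser} \le 1/T_{AOD}$ (inclusive)
and the excursion of the envelope against half the allocated bandwidth.

## The ps2D modal basis

The separable polynomial wavefronts on the unit disk are spanned, order by
order, by $\{1;\; x, y;\; x^2+y^2,\ x^2-y^2;\ \dots;\ x^n+y^n,\ x^n-y^n\}$:
$2n+1$ modes against $n(n+3)/2$ Zernike modes. Gram–Schmidt under the
uniform disk inner product (Cartesian grid; rim pixels weighted by their
inside-area fraction, estimated by 16×16 subsampling) yields an orthonormal
basis whose order-1 and order-2 members coincide with Zernike tilt, defocus
and vertical astigmatism. From order 3 the symmetric/antisymmetric pairs
form pseudo-coma (odd orders) and pseudo-spherical /
pseudo-astigmatism (even orders), mixing in foil terms of the same order;
the fourth-order antisymmetric mode again coincides with its Zernike
counterpart (secondary astigmatism), since
$x^4 - y^4 = r^4\cos 2\theta$ orthogonalizes exactly onto it. The monomial
family above is a design choice: any basis of the separable space gives the
same spans per order, and this family reproduces all structural claims
(mode counts, low-order identities, disjointness of Zernike content across
unequal orders).

`zernike_decompose` projects onto Zernike polynomials (OSA indexing, sign
convention: positive $m$ cosine) that are Löwdin-orthonormalized *on the
grid*, so the discrete Parseval identity
$\sum c^2 + \text{residual}^2 = 1$ holds exactly for unit-norm inputs; the
correction to the analytic polynomials is at the $10^{-5}$ level on a 256²
grid and does not disturb mode identification at the $10^{-3}$ threshold
used throughout.

## Seven-segment serial holography

Text outside the ps2D symmetry class is projected serially from
ps2D-compatible pieces. Segments are numbered 1 = top, 2 = upper-right,
3 = upper-left, 4 = bottom, 5 = lower-right, 6 = lower-left, 7 = middle,
and grouped into five meta segments {1}, {2,3}, {4}, {5,6}, {7}. The
numbering is chosen so each group is separable *by construction*: the
horizontal groups are single y-bands, and the two verticals within a group
share the same y-band, making any union of their columns a rank-1 pattern.
Meta segments are merged whenever their union still passes the rank-1 test
(relative residual of the best rank-1 approximation below $10^{-6}$) — the
operational form of "recognizing y-translation symmetry". "PSL" merges its
top and middle bars (both active exactly over P and S) into four holograms;
"PSG" needs all five, and five is the structural maximum for any supported
text. Hybrid retrieval assigns the complex engine to the axis with the
wider profile support (the dense axis) and phase-only retrieval to the thin
axis, which is where residual FM ghost orders appear and where apodization
can be applied.

`is_ps2d_separable` itself scores the relative Frobenius residual of the
best rank-1 approximation (SVD restricted to nonzero rows/columns; leading
factors are nonnegative by Perron–Frobenius and returned as the axis
profiles). The default tolerance for user patterns is $10^{-3}$; the
all-zero pattern is trivially separable.

## What the fixtures emulate — and what they do not

The built-in targets (equidistant 3/5/7-point grids, an inhomogeneous
7-point variant, 8/16/21 µm boxcar lines, triangle/parabola/sinusoid
profiles, seven-segment characters) are sampled analytically on the
configured grid, deterministically. They represent idealized *intensity
specifications*: hard-edged, noise-free, at the native grid resolution.
Real acquisitions add camera noise, background, registration error and
aberrations; dense targets with super-resolution features (hard edges)
are rendered only to the optical band limit. Passing tests therefore
validate the retrieval algebra and the trends — not photometric agreement
with any particular microscope.

## Numerical conventions and degenerate inputs

Unitary, DC-centered FFTs throughout (`fft_shift` pairs around index
$N/2$, even $N$ required); apertures are hard-edged with sample-center
inclusion tests, a zero-diameter aperture yields the zero field, and a
square aperture the size of the grid is the identity; all-zero targets are
rejected (`degenerate-target`); masks overlapping between target and
freedom domains are rejected; an explicitly empty freedom domain makes the
dynamic engine reproduce the static one bit-for-bit; identical seeds and
configurations reproduce holograms bit-identically; each engine records the
target error of its own output under its own forward model, so
re-reconstruction reproduces the recorded error exactly.

## Problem sizes used by the test-suite

Unit tests run on 64–256-sample grids with the same 0.5 µm target pitch as
the default optics (same physics, smaller fields of view), 5–10 seeds for
trend assertions. The benchmark suite uses the full N = 1024 grid with 30
seeds for the five-point apodization sweep and the 8 µm-line complex
holography, a 512² disk grid for the basis orthonormality check, 256² for
Zernike decompositions, and a 256-sample grid with 30 seeds for the
extended-vs-plain circular-aperture comparison.

## Known limitations

* Focal-plane (2f) reconstruction only; no defocus or 3D stacks.
* The zero-order beam is a power sink, not a propagated field; zero-order
  leakage and inter-order interference are not modeled.
* The extended engine optimizes each axis against a midline extraction;
  a fully coupled two-axis optimization is not attempted (a fixed partner
  profile can be supplied instead).
* Seven-segment text must fit the field of view in one block; long strings
  require a larger grid or a wider pitch.
* Efficiency figures assume an ideal modulator: FM is lossless, AM is the
  only loss, and diffraction efficiency of the device itself is normalized
  away.
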