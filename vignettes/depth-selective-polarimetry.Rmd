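---
title: "Depth-selective backscatter polarimetry: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-selective backscatter polarimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(polarpath)
```

## The problem

Backscattered polarized light carries a memory of how deeply it travelled.
A single reflection-like large-angle scattering event *orthogonalizes* the
polarization state (+45° linear leaves as −45°; right-circular leaves as
left-circular) and turns the photon around near the surface, whereas
polarization-preserving photons must follow an arc of many forward
scatterings, which takes them deeper. Detecting the orthogonalized
component, and then keeping only the image regions where it dominates,
therefore biases an otherwise depth-unresolved backscatter measurement
toward the superficial layers of a turbid medium — the layers where early
enamel demineralization, or early epithelial pathology, lives.

`polarpath` implements this programme end to end:

1. a **Mie single-scattering engine** that tabulates the angular Mueller
   matrix of a sphere and locates the backward angular interval over which
   orthogonalization occurs;
2. a **polarization-tracking Monte Carlo** that forms the backscattered
   co/cross linear and circular analyzer images of a microsphere
   suspension, with per-pixel scattering-event bookkeeping;
3. **spatial field-selection analysis**: per-pixel mean scattering-count
   (N) maps, radial profiles, azimuthal lobe quantification, and
   oriented-region Npp metrics;
4. a **two-group differentiation pipeline** (region intensity sums,
   pooled-deviation t-scores, polarimetric maps) together with a synthetic
   generator of normal-versus-demineralized polarimetric tooth images that
   makes the pipeline testable without specimens.

## Single scattering

For a homogeneous sphere the scattered Stokes vector is
`S_out = M(θ) S_in` with the block-diagonal Mueller matrix

```
| M11  M12   0    0  |
| M12  M11   0    0  |
|  0    0   M33  M34 |
|  0    0  -M34  M33 |
```

whose elements follow from the Mie amplitude functions `S1(θ)`, `S2(θ)`:
`M11 = (|S2|² + |S1|²)/2`, `M12 = (|S2|² − |S1|²)/2`, `M33 = Re(S2 S1*)`,
`M34 = Im(S2 S1*)`. For incident +45° linear light (`[1,0,1,0]`) the
matched scattered component is `U_out = M33(θ)`; for incident
right-circular light (`[1,0,0,1]`) it is `V_out = M33(θ)`. The two
profiles are **identical** — the package exploits this equivalence by
treating co-linear and cross-circular detection as interchangeable
orthogonalization channels. A negative `M33` marks orthogonalization;
`orthogonalization_interval()` reports the largest contiguous negative
interval containing exact backscatter (180°).

Numerical choices:

* **Series truncation** at the Wiscombe order `x + 4x^{1/3} + 2`
  (logarithmic derivative by downward recurrence, Riccati–Bessel functions
  upward), convergent for both the phantom configuration (x ≈ 6.8) and
  the dental one (x ≈ 52). The suite cross-checks the engine against an
  independent fractional-order-Bessel evaluation and the closed-form
  dipole (Rayleigh) matrix.
* **Angular grid** 0.25° by default (configurable in (0, 1]); interval
  onsets are reported at grid resolution.
* **Dead band**: values with `|v| < 1e-12 · max(M11)` are treated as zero
  in interval detection so grid-level sign noise cannot split an interval.
* **Degenerate contrast** (`sphere_index == host_index`) is allowed: the
  table is flagged, a warning raised, and density conversion refuses the
  zero cross-section rather than dividing by it.
* **Sign convention**: V > 0 denotes right-circular in the receiver-frame
  optics convention, used consistently across the simulator and analyzers.

The tooth analysis treats enamel prisms, to first order, as spheres
(λ = 543.5 nm, host 1.573, scatterer 1.619, d = 5.75 µm). Only the sign
structure of the backward hemisphere is asserted for this configuration —
the detailed shape of the dental polar profile depends on uncertain tissue
parameters and on the sphere approximation, so the package tests it as a
sign property (mean `M33` over 90°–180° is negative), not as an exact
interval.

## Polarized Monte Carlo transport

Photon packets carry a position, an orthonormal triad `(e1, e2, v)`, and a
Stokes vector referenced to `e1`/`e2`. One event consists of:

1. free path `s = −ln(ξ)/μt` (index-matched boundaries: a packet crossing
   a face is moved onto it and leaves the medium);
2. joint sampling of `(θ, φ)` by rejection from the
   polarization-dependent phase function
   `P(θ, φ) ∝ M11·I + M12·(Q cos 2φ + U sin 2φ)`, with θ proposals drawn
   from the tabulated `M11 sin θ` marginal and the envelope
   `M11 (1 + √(Q²+U²))` (cap 10⁴ iterations per event);
3. Mueller rotation of the frame about `v` by φ, deflection of `v` by θ in
   the new `(e1, v)` plane, multiplication by `M(θ)`, and renormalization
   of `I` back to the packet weight (the sampling step already accounts
   for the polarization-dependent scattered intensity).

Detection happens on the illuminated face, within an acceptance cone about
exact backscatter. The packet frame is rotated about the exit direction
into a fixed lab detection basis (`d1` = lab x projected off the exit
direction, `d2 = v × d1`); because the propagation reverses, the
orthogonalized state appears **co**-polarized there — the single-event
check (one 180° event of a −45° packet lands entirely in the co-linear
channel) pins this convention down in the unit tests. Analyzer channels
are `½(I ∓ s·U_det)` for co/cross linear and `½(I ± s·V)` for co/cross
circular, where `s` is fixed by the incident state; each detected packet
splits across the analyzer pair, so `co + cross` equals the detected
intensity per pixel exactly.

Per pixel the simulator accumulates the four channel images, the detected
photon count, and pathlength and scattering-event totals — both unweighted
and weighted by each channel's analyzer intensity, which is what lets
per-channel N maps be formed afterwards.

Design choices, and why:

* **Boundaries are index-matched** (no Fresnel step): the physical
  experiment deliberately removed specular interface reflections, and
  matched detection keeps the phantom comparison clean.
* **Absorption defaults to zero** (water at 635 nm over cm scales);
  packets die on exit or at a generous 10⁵-event cap, with capped packets
  counted in the metadata.
* **Acceptance cone 15°** by default. An exact-backscatter detector
  collects no photons in a Monte Carlo, so a finite cone is unavoidable.
  At desk-scale packet counts the region-aggregated Npp metrics *do*
  co-vary with the cone, chiefly because the detected-photon statistics
  (and hence the validity mask of the N map) scale with it — a 10° cone
  halves the detected count of the 15° default and a 30° cone quadruples
  it. Comparisons must therefore hold the cone fixed; all quantitative
  results in this package are defined at the documented 15° default.
* **Unit-weight packets** (with μa = 0, weight-scoring and binary
  detection coincide).
* **RNG**: every packet consumes its own xoshiro256++ stream seeded
  through a splitmix64 chain from `(master seed, packet index)`, so runs
  are bit-reproducible and independent of execution order.
* **θ proposals** are uniform within one 0.25° grid segment; any analysis
  binned on grid-aligned edges sees the exact tabulated distribution.
* **Coordinate convention**: image x is the lab horizontal; the −45°
  incident polarization vector lies along the image diagonal. All region
  orientations are specified **relative to the incident polarization
  axis**, and the simulation stores that reference angle in its metadata
  so the analysis cannot lose it.

## Spatial analysis

`scatter_count_map()` divides per-pixel scattering-event totals by
detected photon counts; pixels with fewer than `min_photons = 5` photons
are masked everywhere (a per-pixel ratio estimator is unstable at tiny
counts). `region_npp()` averages N over the valid pixels whose centres
fall in a region (no partial-area weighting — exactly testable against
enumeration) and reports the percent reduction against the full-image Npp
of the same map; the full-image baseline includes all valid pixels,
including the bright illumination core. Radial profiles use one-pixel
annuli by default; lobe profiles use 72 azimuthal bins (5°), and peaks are
local maxima of the circularly 3-bin-smoothed profile above its mean, ties
broken by amplitude.

**Rectangle geometry for the reduction metrics.** The width is 1.5 mm —
half the 3 mm illumination diameter, the width used in the tooth analysis
to capture the perpendicular axis while avoiding crosstalk from the
45°-axes lobes. The length is not dictated by any physical scale in the
measurement, and "span the whole image" is not orientation-neutral: in a
square field a diagonal rectangle is √2 longer than an axis-aligned one
and reaches the image corners, so rotating "the same" rectangle would
silently change its size. The package therefore compares **identical**
rectangles at every orientation and defaults their length to 10 mm — twice
the ~5 mm radius at which the co- and cross-linear radial N profiles have
converged, i.e. the field over which polarization memory (and hence any
orientation contrast) exists. The acceptance script and test sweep the
length over 6–12 mm and require the perpendicular-over-45° ordering at
every length, so the headline contrast is demonstrably not an artifact of
this choice.

At desk scale the reduction metrics are computed from 8×10⁶ packets on a
101×101 grid over a 14 mm field — sized so the whole analysis field is
well sampled at that packet count. The instrument-scale run (10⁸ packets,
400×400 pixels) is available through the same interface.

## Synthetic tooth images

The generator emulates the *structure* of the two-class tooth study —
7 samples, two spots per side, co-linear and cross-circular channels,
28 data points per channel — not tooth optics. Each image is

```
baseline · [(1−b)·core(r)·f + b·background(r)·f_bg] · h_spot · h_channel + noise
```

with Gaussian radial `core` (σ = 1.5 mm, the illumination scale) and
`background` (σ = 5 mm), background fraction b = 0.45, log-normal spot
heterogeneity (sdlog 0.3, shared between the two channels of a spot, which
is what makes the polarimetric-map points co-vary) plus a smaller
per-channel factor (sdlog 0.1), and additive Gaussian pixel noise clipped
at zero. Demineralization multiplies the core by a reduction factor
`f ∈ (0, 1]` (default 0.6 in both channels — a 40% intensity drop) and the
background by `f_bg = 1 − (1−f)/2`: the orthogonalized, surface-sensitive
light is concentrated in the illumination core, so the effect is
deliberately interior-weighted, which is exactly the property the
interior-region metrics are designed to exploit. The sdlog 0.3 spread was
chosen so that group differences land in the single-digit t-score regime
typical of small-sample intensity comparisons.

What passing tests do and do not show: the pipeline holds its nominal
false-positive rate under the null generator, ranks interior-region
metrics above full-image metrics under an interior-weighted effect, and
gains from pooling the two channels — all *pipeline* properties. They do
not validate the generator as a model of enamel: real teeth add surface
curvature and placement error, speckle, spatially correlated texture, and
class overlap that no parameter here represents, and specimen-level
t-scores depend on the physical teeth themselves.

## The t-score

`t_score()` implements
`t = (x̄₁ − x̄₂) / (S · √(1/n₁ + 1/n₂))` with `S` the standard deviation of
**all** data points pooled across both groups — the estimator named in the
method this package operationalizes, which differs from the classical
pooled *within-group* deviation (available via `s_method = "classical"`;
under the null the two differ little, and the suite verifies the nominal
size empirically). Zero spread with equal means scores 0 (with a warning);
zero spread with differing means is an error rather than an infinity. A
two-sided p-value from the t distribution with `n₁ + n₂ − 2` degrees of
freedom is attached as a labelled interpretive convenience — the reference
distribution for this pooled-deviation statistic is not classical
Student-t, which is why the suite checks the empirical rejection rate
rather than trusting the label.

`polarimetric_map()` pairs each spot's co-linear and cross-circular sums
into a 2-D point and summarizes class separation by the best
single-threshold accuracy along the first principal axis of the
standardized points.

## Known limitations

* Monodisperse spheres only: no size distributions, coatings, absorption
  inside scatterers, or non-spherical prisms.
* Homogeneous single-layer media; flat-field beams only (the Gaussian
  profile of real sources smears the sharp illumination edge that makes
  the simulated core so easy to select).
* Pattern reproduction at desk scale is statistical: lobe orientations and
  region-aggregated Npp contrasts are quantitative, individual image pixels
  are not.
* No speckle or coherence effects; no angularly resolved detection.
* The anisotropy dependence of the spatial patterns (g ≈ 0.92 here) is
  untested outside the phantom configuration.
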