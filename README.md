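# polarpath

Spatial analysis of backscattered polarimetric images for near-surface
sampling sensitivity in turbid, tissue-like media.

## The problem

Polarization gating probes the superficial layers of scattering media:
a single reflection-like backward-scattering event *orthogonalizes* the
polarization state (+45° linear → −45°; right-circular → left-circular)
and returns the photon from shallow depth, whereas polarization-preserving
photons follow deeply penetrating arcs of many forward scatterings. The
orthogonalized component is detectable as the **co-linear** and
**cross-circular** analyzer channels of a backscatter imaging polarimeter,
and the regions of those images where it dominates — close to the
illumination spot, and along the axis perpendicular to the incident linear
polarization vector — sample the medium most shallowly. Selecting those
regions sharpens sensitivity to surface and near-surface structure, e.g.
for differentiating sound from demineralized (early-decay) tooth enamel.

`polarpath` is for researchers in biomedical optics/polarimetry who want
to simulate, quantify, or reuse this spatial field-selection methodology:

* **Mie single-scattering engine** — angular Mueller matrix
  `S_out = M(θ) S_in` with the sphere block structure
  (`M11, M12, M33, M34` from the amplitude functions `S1, S2`), scattered
  Stokes vectors, polar profiles of the matched polarization component
  (`U_out = M33` for ±45° linear, `V_out = M33` for circular — the two are
  identical), orthogonalization intervals, and sphere number densities for
  a target scattering coefficient `μs = ρ σ_sca`.
* **Polarization-tracking Monte Carlo** (compiled kernel) — co/cross
  linear and circular backscatter images of a microsphere suspension with
  per-pixel photon counts and scattering-event totals; deterministic per
  seed.
* **Spatial analysis** — per-pixel mean scattering-count maps
  `N = events/photons` (a sampling-depth proxy), radial profiles,
  azimuthal lobe quantification of the four-lobed patterns, and
  oriented-region **Npp** metrics
  (`reduction = 100·(1 − Npp_region/Npp_full)`).
* **Two-group differentiation** — region intensity sums, the
  pooled-deviation t-score
  `t = (x̄₁ − x̄₂)/(S √(1/n₁ + 1/n₂))` with `S` the standard deviation of
  all points pooled across both groups, five-metric ROI batteries,
  polarimetric maps, and a synthetic generator of normal-vs-demineralized
  polarimetric tooth image pairs.

Results are tibbles (with `tidy()`, `glance()`, `autoplot()` methods), so
everything composes with the tidyverse.

## Worked example

```r
library(polarpath)

# 1. single scattering: where does orthogonalization happen?
params <- mie_parameters(wavelength_nm = 635, host_index = 1.33,
                         sphere_index = 1.59, diameter_um = 1.04)
tab <- mie_mueller_table(params)
glance(tab)
#>   size_parameter relative_index scattering_efficiency anisotropy_g sigma_sca_cm2
#> 1           6.84           1.20                  2.71        0.919  0.0000000231

orthogonalization_interval(polar_intensity_profile(tab, "linear45"))
#>   theta_onset_deg theta_end_deg empty
#> 1            131.          229. FALSE

number_density_for_mus(tab, mus_per_cm = 25)
#> [1] 1084551758
```

The polystyrene sphere orthogonalizes singly scattered light over the
backward cone from ≈131° through exact backscatter (131°–229° in the polar
display), and ≈1.08×10⁹ spheres/cm³ give the enamel-like turbidity
μs = 25 cm⁻¹.

```r
# 2. a reduced-scale backscatter simulation (~2-3 min)
medium <- medium_spec(params, mus_per_cm = 25)
beam <- beam_spec(diameter_mm = 3, incident_state = "linear_minus45")
sim <- run_simulation(medium, beam, n_packets = 8e6, seed = 1,
                      nx = 101, ny = 101, field_mm = 14)
sim
#> <polarpath_sim> 8e+06 packets (seed 1), 229,261 detected in 15 deg cone
#>   101x101 px over 14 mm; mus = 25 /cm; incident linear_minus45

# 3. spatial field selection on the co-linear scattering-count map
map <- scatter_count_map(sim, "co_linear", min_photons = 5)
compare_rectangle_orientations(map, angles_deg = c(90, 45),
                               length_mm = 10, width_mm = 1.5)
#>   region             angle_deg   npp pixel_count npp_full reduction_vs_full_pct
#> 1 rect 10x1.5 mm @ 9…       90  27.5         767     42.7                  35.7
#> 2 rect 10x1.5 mm @ 4…       45  30.9         754     42.7                  27.6
```

Detected co-linear photons inside the rectangle oriented perpendicular to
the incident polarization vector scattered ~36% less than the full-image
average (Npp 27.5 vs 42.7) — i.e. that region samples markedly shallower —
and the perpendicular orientation beats the 45° orientation (27.6%), which
is the depth-selection effect the method exploits.

```r
# 4. synthetic tooth study: five metrics, normal vs acidified
set <- generate_synthetic_tooth_set(synthetic_tooth_config(seed = 1))
battery <- roi_metric_battery(set)
battery
#>   metric                       t p_value mean_normal mean_acidified     s    n1    n2
#> 1 co_linear_full           0.923 0.365         1434.         1207.  652.     14    14
#> 2 co_linear_interior_perp  1.43  0.164          109.           83.2  47.4    14    14
#> 3 cross_circular_full      1.99  0.0576        1247.          888.  479.     14    14
#> 4 cross_circular_interior  2.45  0.0216         142.           91.9  54.1    14    14
#> 5 pooled_interior          2.75  0.00812       125.            87.6  51.5    28    28

glance(polarimetric_map(battery))
#>   n_points accuracy threshold
#> 1       28    0.786    -0.641
```

On this synthetic draw the interior-region metrics separate the classes
better than the full-image sums in both channels, and pooling the two
interior metrics (doubling n) scores highest — the ordering the spatial
field-selection approach predicts.

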