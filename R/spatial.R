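#' Per-pixel mean scattering-count (N) map
#'
#' Divides the per-pixel scattering-event totals of a detection channel by
#' the corresponding per-pixel detected photon counts, giving the mean
#' number of scattering events N of the light detected at each pixel -- a
#' proxy for sampling depth (less scattering, shallower paths). Pixels with
#' fewer than `min_photons` detected photons are masked and excluded from
#' every aggregate (the per-pixel ratio is unstable at tiny counts).
#'
#' @param x A `polarpath_sim` result, or a numeric matrix of per-pixel
#'   event totals.
#' @param channel For the simulation method: which analyzer channel
#'   (`"co_linear"`, `"cross_linear"`, `"co_circular"`, `"cross_circular"`).
#' @param photon_counts For the matrix method: congruent matrix of per-pixel
#'   detected photon counts.
#' @param min_photons Validity threshold on photon counts (default 5).
#' @param pixel_mm,pol_axis_deg For the matrix method: physical pixel pitch
#'   and the image-plane angle of the incident polarization axis (degrees,
#'   CCW from +x; used by oriented regions).
#' @param ... Unused.
#' @return An object of class `scatter_count_map`: list with `n` (matrix,
#'   `NA` on masked pixels), `mask`, `pixel_mm`, `pol_axis_deg`, `channel`.
#' @export
scatter_count_map <- function(x, ...) UseMethod("scatter_count_map")

#' @rdname scatter_count_map
#' @export
scatter_count_map.polarpath_sim <- function(x, channel = "co_linear",
                                            min_photons = 5, ...) {
  totals <- x$images[[paste0("nscat_", channel)]]
  counts <- x$images[[channel]]
  if (is.null(totals) || is.null(counts)) abort("Unknown channel.")
  scatter_count_map(totals, photon_counts = counts, min_photons = min_photons,
                    pixel_mm = x$meta$pixel_mm,
                    pol_axis_deg = x$meta$pol_axis_deg %||% -45,
                    channel = channel)
}

#' @rdname scatter_count_map
#' @export
scatter_count_map.default <- function(x, photon_counts, min_photons = 5,
                                      pixel_mm = 1, pol_axis_deg = -45,
                                      channel = NA_character_, ...) {
  if (!is.matrix(x) || !is.matrix(photon_counts) ||
      !all(dim(x) == dim(photon_counts))) {
    abort("Event totals and photon counts must be matrices of identical shape.")
  }
  mask <- photon_counts >= min_photons
  n <- matrix(NA_real_, nrow(x), ncol(x))
  n[mask] <- x[mask] / photon_counts[mask]
  structure(list(n = n, mask = mask, pixel_mm = pixel_mm,
                 pol_axis_deg = pol_axis_deg, channel = channel,
                 min_photons = min_photons),
            class = "scatter_count_map")
}

#' @export
print.scatter_count_map <- function(x, ...) {
  cat(sprintf(
    "<scatter_count_map> %dx%d px (%.3g mm/px), %d valid pixels, channel %s\n",
    nrow(x$n), ncol(x$n), x$pixel_mm, sum(x$mask), x$channel))
  invisible(x)
}

#' @method tidy scatter_count_map
#' @export
tidy.scatter_count_map <- function(x, ...) {
  ctr <- map_centers(x)
  tibble(x_mm = rep(ctr$x_mm, times = ncol(x$n)),
         y_mm = rep(ctr$y_mm, each = nrow(x$n)),
         n = as.vector(x$n), valid = as.vector(x$mask))
}

#' @method autoplot scatter_count_map
#' @export
autoplot.scatter_count_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm, fill = .data$n)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "N",
                  title = "Mean scattering events per detected photon")
}

# pixel-centre coordinates (mm), origin at the image/beam centre
map_centers <- function(map) {
  nx <- nrow(map$n); ny <- ncol(map$n)
  list(x_mm = (seq_len(nx) - (nx + 1) / 2) * map$pixel_mm,
       y_mm = (seq_len(ny) - (ny + 1) / 2) * map$pixel_mm)
}

# ---------------------------------------------------------------------------
# Regions

#' Region specifications for image aggregation
#'
#' Regions are defined in physical (mm) image coordinates, centred on the
#' beam axis; pixels belong to a region when their centre falls inside it
#' (no partial-area weighting). Rectangle orientation is measured from the
#' incident-polarization axis, so `angle_deg = 90` is the perpendicular
#' axis irrespective of how the beam polarization maps onto the pixel grid.
#'
#' @param diameter_mm Disc diameter (mm).
#' @param length_mm,width_mm Rectangle dimensions (mm); `length_mm = Inf`
#'   spans the full image through the centre.
#' @param angle_deg Rectangle orientation in degrees from the
#'   incident-polarization axis (normalized to \[0, 180)).
#' @param center_mm Region centre `c(x, y)` in mm.
#' @return A `region_spec` object.
#' @name regions
NULL

#' @rdname regions
#' @export
region_full <- function() {
  structure(list(kind = "full_image"), class = "region_spec")
}

#' @rdname regions
#' @export
region_disc <- function(diameter_mm, center_mm = c(0, 0)) {
  if (diameter_mm <= 0) abort("`diameter_mm` must be > 0.")
  structure(list(kind = "disc", diameter_mm = diameter_mm,
                 center_mm = center_mm), class = "region_spec")
}

#' @rdname regions
#' @export
region_rect <- function(length_mm, width_mm, angle_deg = 90,
                        center_mm = c(0, 0)) {
  if (width_mm <= 0 || length_mm <= 0) abort("Rectangle dimensions must be > 0.")
  structure(list(kind = "oriented_rectangle", length_mm = length_mm,
                 width_mm = width_mm, angle_deg = angle_deg %% 180,
                 center_mm = center_mm), class = "region_spec")
}

#' @rdname regions
#' @param a,b Two `region_spec` objects whose intersection is taken.
#' @export
region_intersection <- function(a, b) {
  stopifnot(inherits(a, "region_spec"), inherits(b, "region_spec"))
  structure(list(kind = "intersection", a = a, b = b), class = "region_spec")
}

#' @export
format.region_spec <- function(x, ...) {
  switch(x$kind,
         full_image = "full image",
         disc = sprintf("disc d=%g mm", x$diameter_mm),
         oriented_rectangle = sprintf("rect %gx%g mm @ %g deg",
                                      x$length_mm, x$width_mm, x$angle_deg),
         intersection = paste(format(x$a), "∩", format(x$b)))
}

#' @export
print.region_spec <- function(x, ...) {
  cat("<region_spec>", format(x), "\n"); invisible(x)
}

# logical inclusion mask over pixel centres; pol_axis_deg anchors oriented
# rectangles to the incident polarization axis
region_mask <- function(region, x_mm, y_mm, pol_axis_deg = -45) {
  X <- matrix(rep(x_mm, times = length(y_mm)), length(x_mm))
  Y <- matrix(rep(y_mm, each = length(x_mm)), length(x_mm))
  mask_at <- function(r) {
    switch(r$kind,
      full_image = matrix(TRUE, length(x_mm), length(y_mm)),
      disc = (X - r$center_mm[1])^2 + (Y - r$center_mm[2])^2 <=
               (r$diameter_mm / 2)^2,
      oriented_rectangle = {
        ang <- (pol_axis_deg + r$angle_deg) * pi / 180
        u <- c(cos(ang), sin(ang))
        dx <- X - r$center_mm[1]; dy <- Y - r$center_mm[2]
        along <- dx * u[1] + dy * u[2]
        across <- -dx * u[2] + dy * u[1]
        abs(along) <= r$length_mm / 2 & abs(across) <= r$width_mm / 2
      },
      intersection = mask_at(r$a) & mask_at(r$b),
      abort("unknown region kind"))
  }
  mask_at(region)
}

# ---------------------------------------------------------------------------
# Aggregates

#' Region-aggregated scattering events per photon per pixel (Npp)
#'
#' Averages the per-pixel N values over the valid pixels whose centres fall
#' inside the region ("summing the N-per-photon values at each pixel within
#' the region, then dividing by the number of pixels"), and reports the
#' percent reduction relative to the full-image Npp of the same map. Lower
#' Npp means shallower sampling.
#'
#' @param map A [scatter_count_map()].
#' @param region A `region_spec` (see [regions]).
#' @return A one-row tibble: `region`, `angle_deg` (for oriented rectangles,
#'   else `NA`), `npp`, `pixel_count`, `npp_full`, `reduction_vs_full_pct`.
#' @export
region_npp <- function(map, region) {
  stopifnot(inherits(map, "scatter_count_map"), inherits(region, "region_spec"))
  ctr <- map_centers(map)
  inreg <- region_mask(region, ctr$x_mm, ctr$y_mm, map$pol_axis_deg)
  sel <- inreg & map$mask
  if (!any(sel)) abort("Region contains no valid pixels.")
  npp <- mean(map$n[sel])
  full <- mean(map$n[map$mask])
  ang <- if (identical(region$kind, "oriented_rectangle"))
    region$angle_deg else NA_real_
  lab <- format(region)
  tibble(region = lab, angle_deg = ang,
         npp = npp, pixel_count = sum(sel), npp_full = full,
         reduction_vs_full_pct = 100 * (1 - npp / full))
}

#' Npp of one rectangle swept over orientation angles
#'
#' Rotates an identical rectangle about the beam centre through the given
#' orientation angles (measured from the incident-polarization axis) and
#' computes the region Npp and full-image reduction at each angle.
#'
#' @param map A [scatter_count_map()].
#' @param angles_deg Orientation angles (degrees from the polarization axis).
#' @param length_mm,width_mm Rectangle dimensions (default: full image
#'   length, 1.5 mm width -- half the 3 mm illumination diameter).
#' @return A tibble with one row per angle (columns as [region_npp()]).
#' @export
compare_rectangle_orientations <- function(map, angles_deg = c(90, 45),
                                           length_mm = Inf, width_mm = 1.5) {
  purrr::map_dfr(angles_deg, function(a) {
    region_npp(map, region_rect(length_mm, width_mm, angle_deg = a))
  })
}

#' Radial profile of a map or image
#'
#' Azimuthal average versus radius about the beam centre: each bin's value
#' is the mean over valid pixels whose centre falls in the annulus
#' `[r, r + dr)`; bins containing no valid pixel carry `NA`.
#'
#' @param x A [scatter_count_map()] or a numeric matrix.
#' @param bin_width_mm Radial bin width (default: one pixel pitch).
#' @param center_mm Profile centre `c(x, y)` in mm.
#' @param pixel_mm For the matrix method: pixel pitch in mm.
#' @param ... Unused.
#' @return A tibble: `r_mid_mm`, `value`, `n_pixels`.
#' @export
radial_profile <- function(x, ...) UseMethod("radial_profile")

#' @rdname radial_profile
#' @export
radial_profile.scatter_count_map <- function(x, bin_width_mm = NULL,
                                             center_mm = c(0, 0), ...) {
  radial_profile_impl(x$n, x$pixel_mm, bin_width_mm, center_mm, x$mask)
}

#' @rdname radial_profile
#' @export
radial_profile.matrix <- function(x, pixel_mm = 1, bin_width_mm = NULL,
                                  center_mm = c(0, 0), ...) {
  radial_profile_impl(x, pixel_mm, bin_width_mm, center_mm,
                      !is.na(x))
}

radial_profile_impl <- function(values, pixel_mm, bin_width_mm, center_mm,
                                valid) {
  if (is.null(bin_width_mm)) bin_width_mm <- pixel_mm
  nx <- nrow(values); ny <- ncol(values)
  xs <- (seq_len(nx) - (nx + 1) / 2) * pixel_mm - center_mm[1]
  ys <- (seq_len(ny) - (ny + 1) / 2) * pixel_mm - center_mm[2]
  R <- sqrt(outer(xs^2, ys^2, `+`))
  bin <- floor(R / bin_width_mm)
  keep <- valid & !is.na(values)
  nb <- max(bin) + 1
  out <- tibble(
    r_mid_mm = (seq_len(nb) - 0.5) * bin_width_mm,
    value = NA_real_, n_pixels = 0L)
  agg_sum <- tapply(values[keep], bin[keep], sum)
  agg_n <- tapply(values[keep], bin[keep], length)
  idx <- as.integer(names(agg_sum)) + 1L
  out$value[idx] <- as.numeric(agg_sum) / as.numeric(agg_n)
  out$n_pixels[idx] <- as.integer(agg_n)
  out
}

# ---------------------------------------------------------------------------
# Lobe quantification

#' Azimuthal lobe profile of a backscatter image
#'
#' Bins the mean intensity within a radial annulus by azimuth angle
#' (measured relative to the incident-polarization axis) and detects lobe
#' peaks: local maxima of the circularly smoothed (3-bin moving mean)
#' profile exceeding the circular mean, ties broken by amplitude. Four-lobed
#' backscatter patterns show up as peaks near 0/90/180/270 deg (co-linear,
#' "x"-like) or near 45/135/225/315 deg (cross-linear, "+"-like).
#'
#' @param x A `polarpath_sim` or a numeric intensity matrix.
#' @param channel For the simulation method: the analyzer channel.
#' @param r_inner_mm,r_outer_mm Annulus radii (mm).
#' @param n_bins Number of azimuthal bins (default 72, i.e. 5 deg).
#' @param pixel_mm,pol_axis_deg For the matrix method: pixel pitch and the
#'   image-plane polarization-axis angle.
#' @param ... Unused.
#' @return A tibble of class `lobe_profile`: `phi_mid_deg` (relative to the
#'   polarization axis, \[0, 360)), `mean_intensity`, `n_pixels`; attribute
#'   `"peaks"` holds the detected peak angles.
#' @export
lobe_profile <- function(x, ...) UseMethod("lobe_profile")

#' @rdname lobe_profile
#' @export
lobe_profile.polarpath_sim <- function(x, channel = "cross_linear",
                                       r_inner_mm = 1.5, r_outer_mm = 6,
                                       n_bins = 72, ...) {
  lobe_profile(x$images[[channel]], r_inner_mm = r_inner_mm,
               r_outer_mm = r_outer_mm, n_bins = n_bins,
               pixel_mm = x$meta$pixel_mm,
               pol_axis_deg = x$meta$pol_axis_deg %||% -45)
}

#' @rdname lobe_profile
#' @export
lobe_profile.matrix <- function(x, r_inner_mm, r_outer_mm, n_bins = 72,
                                pixel_mm = 1, pol_axis_deg = -45, ...) {
  nx <- nrow(x); ny <- ncol(x)
  xs <- (seq_len(nx) - (nx + 1) / 2) * pixel_mm
  ys <- (seq_len(ny) - (ny + 1) / 2) * pixel_mm
  X <- matrix(rep(xs, times = ny), nx)
  Y <- matrix(rep(ys, each = nx), nx)
  R <- sqrt(X^2 + Y^2)
  sel <- R >= r_inner_mm & R <= r_outer_mm & !is.na(x)
  if (!any(sel)) abort("Annulus contains no pixels.")
  phi <- (atan2(Y[sel], X[sel]) * 180 / pi - pol_axis_deg) %% 360
  bin <- pmin(floor(phi / (360 / n_bins)), n_bins - 1)
  v <- x[sel]
  mean_i <- rep(NA_real_, n_bins)
  npix <- rep(0L, n_bins)
  agg_s <- tapply(v, bin, sum)
  agg_n <- tapply(v, bin, length)
  idx <- as.integer(names(agg_s)) + 1L
  mean_i[idx] <- as.numeric(agg_s) / as.numeric(agg_n)
  npix[idx] <- as.integer(agg_n)
  out <- tibble(phi_mid_deg = (seq_len(n_bins) - 0.5) * 360 / n_bins,
                mean_intensity = mean_i, n_pixels = npix)
  peaks <- find_lobe_peaks(out)
  structure(out, class = c("lobe_profile", class(tibble())),
            peaks = peaks, pol_axis_deg = pol_axis_deg)
}

# circularly smoothed local maxima above the circular mean
find_lobe_peaks <- function(profile) {
  v <- profile$mean_intensity
  n <- length(v)
  v0 <- ifelse(is.na(v), mean(v, na.rm = TRUE), v)
  sm <- (v0 + v0[c(n, 1:(n - 1))] + v0[c(2:n, 1)]) / 3
  prev <- sm[c(n, 1:(n - 1))]
  nxt <- sm[c(2:n, 1)]
  is_peak <- (sm > prev & sm >= nxt) & sm > mean(sm)
  pk <- tibble(phi_deg = profile$phi_mid_deg[is_peak],
               value = sm[is_peak])
  dplyr::arrange(pk, .data$phi_deg)
}

#' @rdname lobe_profile
#' @param profile A `lobe_profile`.
#' @export
lobe_peaks <- function(profile) attr(profile, "peaks")

#' @method autoplot lobe_profile
#' @export
autoplot.lobe_profile <- function(object, ...) {
  pk <- lobe_peaks(object)
  ggplot2::ggplot(object, ggplot2::aes(.data$phi_mid_deg, .data$mean_intensity)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = pk, ggplot2::aes(xintercept = .data$phi_deg),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "azimuth relative to polarization axis (deg)",
                  y = "mean intensity in annulus",
                  title = "Azimuthal lobe profile")
}
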