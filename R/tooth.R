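#' Sum image intensity over a region
#'
#' Sums pixel values whose centres fall inside the region (pixel-centre
#' inclusion, no partial-area weighting).
#'
#' @param image Numeric matrix.
#' @param region A `region_spec` (see [regions]).
#' @param pixel_mm Pixel pitch in mm.
#' @param pol_axis_deg Image-plane angle of the incident polarization axis
#'   (anchors oriented rectangles).
#' @return Summed intensity (scalar).
#' @export
sum_intensity <- function(image, region = region_full(), pixel_mm = 1,
                          pol_axis_deg = -45) {
  stopifnot(is.matrix(image), inherits(region, "region_spec"))
  nx <- nrow(image); ny <- ncol(image)
  xs <- (seq_len(nx) - (nx + 1) / 2) * pixel_mm
  ys <- (seq_len(ny) - (ny + 1) / 2) * pixel_mm
  sel <- region_mask(region, xs, ys, pol_axis_deg)
  if (!any(sel)) abort("Region contains no pixels.")
  sum(image[sel])
}

#' Two-group t-score with pooled-deviation scaling
#'
#' Computes `t = (mean(x1) - mean(x2)) / (S * sqrt(1/n1 + 1/n2))` where, in
#' the default `"pooled_all"` form, `S` is the standard deviation of all the
#' data points pooled across both groups. The classical two-sample pooled-
#' variance form is available as `s_method = "classical"`. A two-sided
#' p-value from the t distribution with `n1 + n2 - 2` degrees of freedom is
#' reported as an interpretive convenience alongside the score.
#'
#' @param group1,group2 Numeric vectors (each of length >= 2).
#' @param s_method `"pooled_all"` (deviation of the pooled data points) or
#'   `"classical"` (classical pooled within-group variance).
#' @return An object of class `t_score`: list with `mean1`, `mean2`, `s`,
#'   `n1`, `n2`, `t`, `p_value`, `s_method`. `tidy()`/`glance()` return the
#'   same as a one-row tibble.
#' @examples
#' t_score(c(2, 4), c(1, 3))
#' @export
t_score <- function(group1, group2, s_method = c("pooled_all", "classical")) {
  s_method <- match.arg(s_method)
  if (length(group1) < 2 || length(group2) < 2) {
    abort("Each group needs at least 2 data points.")
  }
  n1 <- length(group1); n2 <- length(group2)
  s <- if (s_method == "pooled_all") {
    sd(c(group1, group2))
  } else {
    sqrt(((n1 - 1) * stats::var(group1) + (n2 - 1) * stats::var(group2)) /
           (n1 + n2 - 2))
  }
  if (!is.finite(s) || s <= 0) {
    # zero spread: define t = 0 when the means also agree (no difference at
    # all); a nonzero mean difference with zero spread has no finite score
    if (isTRUE(all.equal(mean(group1), mean(group2)))) {
      warn("All data points are identical; t-score set to 0.")
      s <- 0
      t <- 0
    } else {
      abort("Zero pooled deviation with differing means: the t-score is undefined.")
    }
  } else {
    t <- (mean(group1) - mean(group2)) / (s * sqrt(1 / n1 + 1 / n2))
  }
  structure(list(mean1 = mean(group1), mean2 = mean(group2), s = s,
                 n1 = n1, n2 = n2, t = t,
                 p_value = 2 * pt(-abs(t), df = n1 + n2 - 2),
                 s_method = s_method),
            class = "t_score")
}

#' @export
print.t_score <- function(x, ...) {
  cat(sprintf("<t_score> t = %.4g (means %.4g vs %.4g, S = %.4g, n = %d + %d, p ~ %.3g)\n",
              x$t, x$mean1, x$mean2, x$s, x$n1, x$n2, x$p_value))
  invisible(x)
}

#' @method tidy t_score
#' @export
tidy.t_score <- function(x, ...) {
  tibble(mean1 = x$mean1, mean2 = x$mean2, s = x$s, n1 = x$n1, n2 = x$n2,
         t = x$t, p_value = x$p_value, s_method = x$s_method)
}

#' @method glance t_score
#' @export
glance.t_score <- function(x, ...) tidy(x)

# ---------------------------------------------------------------------------
# Synthetic polarimetric tooth images

#' Configuration for the synthetic tooth-image generator
#'
#' Describes a two-class study emulating polarimetric tooth measurements:
#' per tooth sample, two measurement spots on the normal side and two on the
#' acidified (demineralized) side, each spot imaged in the co-linear and
#' cross-circular channels. Demineralization reduces the mean backscattered
#' intensity in both channels (roughened surface lowers the specular-like
#' orthogonalized return; a more depolarizing sub-surface lowers the
#' polarized fraction), with the effect concentrated in the illumination
#' core where the orthogonalized light lives.
#'
#' @param nx Image side in pixels (square), default 64.
#' @param pixel_mm Pixel pitch (mm), default 0.2 (12.8 mm field).
#' @param baseline Named peak intensities for `co_linear`, `cross_circular`.
#' @param reduction Named demineralization intensity-reduction factors in
#'   (0, 1\] applied to the illumination-core component of the acidified
#'   class (1 = no effect).
#' @param background_effect Fraction of the core reduction that also applies
#'   to the broad diffuse background (0..1, default 0.5): the background
#'   factor is `1 - (1 - reduction) * background_effect`.
#' @param core_sigma_mm,background_sigma_mm Gaussian radial scales of the
#'   bright illumination core and the diffuse background (mm).
#' @param background_frac Fraction of the peak carried by the background.
#' @param heterogeneity_sdlog Log-normal sd of the per-spot multiplicative
#'   heterogeneity (shared between channels of one spot).
#' @param channel_sdlog Additional per-channel log-normal sd.
#' @param noise_sd Additive Gaussian pixel noise (intensity units; negative
#'   pixels clipped to zero).
#' @param n_samples Number of tooth samples (default 7).
#' @param spots_per_side Measurement spots per side (default 2; 7 x 2 x 2 =
#'   28 data points).
#' @param acid_min Acid exposure minutes per sample (recycled).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A `synthetic_tooth_config` list.
#' @export
synthetic_tooth_config <- function(
    nx = 64, pixel_mm = 0.2,
    baseline = c(co_linear = 1, cross_circular = 0.8),
    reduction = c(co_linear = 0.6, cross_circular = 0.6),
    background_effect = 0.5,
    core_sigma_mm = 1.5, background_sigma_mm = 5, background_frac = 0.45,
    heterogeneity_sdlog = 0.3, channel_sdlog = 0.1, noise_sd = 0.02,
    n_samples = 7, spots_per_side = 2,
    acid_min = c(1, 5, 10, 25, 40, 40, 40), seed = 1L) {
  if (any(reduction <= 0) || any(reduction > 1)) {
    abort("`reduction` factors must lie in (0, 1].")
  }
  if (noise_sd < 0 || heterogeneity_sdlog < 0 || channel_sdlog < 0) {
    abort("Noise scales must be >= 0.")
  }
  if (n_samples < 1 || spots_per_side < 1) abort("Design sizes must be >= 1.")
  structure(list(nx = nx, pixel_mm = pixel_mm, baseline = baseline,
                 reduction = reduction, background_effect = background_effect,
                 core_sigma_mm = core_sigma_mm,
                 background_sigma_mm = background_sigma_mm,
                 background_frac = background_frac,
                 heterogeneity_sdlog = heterogeneity_sdlog,
                 channel_sdlog = channel_sdlog, noise_sd = noise_sd,
                 n_samples = n_samples, spots_per_side = spots_per_side,
                 acid_min = rep_len(acid_min, n_samples), seed = seed),
            class = "synthetic_tooth_config")
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic two-class polarimetric tooth image set
#'
#' Draws, for every sample/side/spot, co-linear and cross-circular images as
#' a bright illumination core plus diffuse background (both Gaussian in
#' radius) scaled by the class factor, multiplied by log-normal spot/channel
#' heterogeneity, plus additive Gaussian pixel noise clipped at zero.
#' Deterministic given `config$seed`.
#'
#' @param config A [synthetic_tooth_config()].
#' @return A tibble of class `tooth_image_set` with columns `sample_id`,
#'   `side` (`"normal"`/`"acidified"`), `acid_min`, `spot`, `channel`,
#'   `image` (list of matrices); attribute `"config"`.
#' @export
generate_synthetic_tooth_set <- function(config = synthetic_tooth_config()) {
  stopifnot(inherits(config, "synthetic_tooth_config"))
  nx <- config$nx
  xs <- (seq_len(nx) - (nx + 1) / 2) * config$pixel_mm
  R2 <- outer(xs^2, xs^2, `+`)
  core <- exp(-R2 / (2 * config$core_sigma_mm^2))
  bg <- exp(-R2 / (2 * config$background_sigma_mm^2))
  channels <- c("co_linear", "cross_circular")
  design <- tidyr::expand_grid(
    sample_id = seq_len(config$n_samples),
    side = c("normal", "acidified"),
    spot = seq_len(config$spots_per_side))
  design$acid_min <- config$acid_min[design$sample_id]
  with_local_seed(config$seed, {
    rows <- purrr::pmap_dfr(design, function(sample_id, side, spot, acid_min) {
      h_spot <- rlnorm(1, 0, config$heterogeneity_sdlog)
      purrr::map_dfr(channels, function(ch) {
        f <- if (side == "acidified") config$reduction[[ch]] else 1
        fbg <- 1 - (1 - f) * config$background_effect
        h_ch <- rlnorm(1, 0, config$channel_sdlog)
        mean_img <- config$baseline[[ch]] *
          ((1 - config$background_frac) * core * f +
             config$background_frac * bg * fbg) * h_spot * h_ch
        img <- mean_img + matrix(rnorm(nx * nx, 0, config$noise_sd), nx)
        img[img < 0] <- 0
        tibble(sample_id = sample_id, side = side, acid_min = acid_min,
               spot = spot, channel = ch, image = list(img))
      })
    })
  })
  structure(rows, class = c("tooth_image_set", class(tibble())),
            config = config)
}

# ---------------------------------------------------------------------------
# Metric battery and polarimetric map

#' Region-of-interest metric battery with normal-vs-acidified t-scores
#'
#' Computes, for every measurement spot, the five intensity metrics used to
#' differentiate the two classes, and scores each with a normal-vs-acidified
#' [t_score()]:
#' \describe{
#'   \item{co_linear_full}{co-linear full-image sum}
#'   \item{co_linear_interior_perp}{co-linear sum over the illumination disc
#'     intersected with the perpendicular-axis rectangle (width = half the
#'     disc diameter)}
#'   \item{cross_circular_full}{cross-circular full-image sum}
#'   \item{cross_circular_interior}{cross-circular sum over the illumination
#'     disc}
#'   \item{pooled_interior}{the interior co-linear and cross-circular data
#'     points pooled into one doubled-size sample set}
#' }
#'
#' @param tooth_set A `tooth_image_set` (or any tibble with `sample_id`,
#'   `side`, `spot`, `channel`, `image` columns).
#' @param pixel_mm Pixel pitch; defaults to the set's generator config.
#' @param illumination_diameter_mm Diameter of the interior (illumination)
#'   disc, default 3 mm.
#' @param rect_width_mm Width of the perpendicular-axis rectangle, default
#'   half the illumination diameter.
#' @param pol_axis_deg Incident polarization-axis angle in image coordinates.
#' @param s_method Passed to [t_score()].
#' @return A tibble of class `roi_battery` with one row per metric
#'   (`metric`, `t`, `p_value`, `mean_normal`, `mean_acidified`, `s`, `n1`,
#'   `n2`); attribute `"sums"` holds the per-spot metric sums.
#' @export
roi_metric_battery <- function(tooth_set, pixel_mm = NULL,
                               illumination_diameter_mm = 3,
                               rect_width_mm = illumination_diameter_mm / 2,
                               pol_axis_deg = -45,
                               s_method = "pooled_all") {
  cfg <- attr(tooth_set, "config")
  if (is.null(pixel_mm)) {
    if (is.null(cfg)) abort("Supply `pixel_mm` when the set carries no config.")
    pixel_mm <- cfg$pixel_mm
  }
  need <- c("sample_id", "side", "spot", "channel", "image")
  if (!all(need %in% names(tooth_set))) {
    abort("`tooth_set` must have sample_id, side, spot, channel, image columns.")
  }
  if (!all(c("co_linear", "cross_circular") %in% tooth_set$channel)) {
    abort("Both co_linear and cross_circular channels are required.")
  }
  disc <- region_disc(illumination_diameter_mm)
  perp <- region_intersection(
    disc, region_rect(Inf, rect_width_mm, angle_deg = 90))
  region_for <- function(metric) {
    switch(metric,
           co_linear_full = region_full(),
           co_linear_interior_perp = perp,
           cross_circular_full = region_full(),
           cross_circular_interior = disc)
  }
  channel_for <- c(co_linear_full = "co_linear",
                   co_linear_interior_perp = "co_linear",
                   cross_circular_full = "cross_circular",
                   cross_circular_interior = "cross_circular")
  sums <- purrr::map_dfr(names(channel_for), function(m) {
    rows <- tooth_set[tooth_set$channel == channel_for[[m]], ]
    vals <- purrr::map_dbl(rows$image, sum_intensity,
                           region = region_for(m), pixel_mm = pixel_mm,
                           pol_axis_deg = pol_axis_deg)
    tibble(metric = m, sample_id = rows$sample_id, side = rows$side,
           spot = rows$spot, sum_intensity = vals)
  })
  score <- function(df) {
    ts <- t_score(df$sum_intensity[df$side == "normal"],
                  df$sum_intensity[df$side == "acidified"],
                  s_method = s_method)
    tibble(t = ts$t, p_value = ts$p_value, mean_normal = ts$mean1,
           mean_acidified = ts$mean2, s = ts$s, n1 = ts$n1, n2 = ts$n2)
  }
  per_metric <- sums %>%
    dplyr::group_by(.data$metric) %>%
    dplyr::group_modify(~score(.x)) %>%
    dplyr::ungroup()
  pooled_points <- sums[sums$metric %in%
                          c("co_linear_interior_perp", "cross_circular_interior"), ]
  pooled <- dplyr::bind_cols(tibble(metric = "pooled_interior"),
                             score(pooled_points))
  out <- dplyr::bind_rows(per_metric, pooled)
  out <- out[match(c("co_linear_full", "co_linear_interior_perp",
                     "cross_circular_full", "cross_circular_interior",
                     "pooled_interior"), out$metric), ]
  structure(out, class = c("roi_battery", class(tibble())), sums = sums)
}

#' @rdname roi_metric_battery
#' @param battery A `roi_battery`.
#' @export
battery_sums <- function(battery) attr(battery, "sums")

#' @method autoplot roi_battery
#' @export
autoplot.roi_battery <- function(object, ...) {
  sums <- battery_sums(object)
  ggplot2::ggplot(sums, ggplot2::aes(.data$side, .data$sum_intensity,
                                     fill = .data$side)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.5) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "summed intensity (a.u.)",
                  title = "Normal vs acidified intensity metrics") +
    ggplot2::theme(legend.position = "none")
}

#' Polarimetric map of paired co-linear / cross-circular intensities
#'
#' Pairs the two channel sums of every measured spot as
#' `(x, y) = (co-linear, cross-circular)` with its class label, and reports
#' a linear class-separation summary: points are standardized, projected on
#' their first principal axis, and the best single-threshold classification
#' accuracy along that axis is computed.
#'
#' @param battery A [roi_metric_battery()] result (the interior metrics are
#'   paired by default), or a tibble of per-spot sums with columns `metric`,
#'   `sample_id`, `side`, `spot`, `sum_intensity`.
#' @param metrics Length-2 character: the co-linear and cross-circular
#'   metrics to pair.
#' @return A tibble of class `polarimetric_map` (`sample_id`, `spot`, `side`,
#'   `co_linear`, `cross_circular`) with attribute `"separability"` (list:
#'   `accuracy`, `threshold`, `axis`). `glance()` returns the summary.
#' @export
polarimetric_map <- function(battery,
                             metrics = c("co_linear_interior_perp",
                                         "cross_circular_interior")) {
  sums <- if (inherits(battery, "roi_battery")) battery_sums(battery) else battery
  a <- sums[sums$metric == metrics[1], c("sample_id", "spot", "side", "sum_intensity")]
  b <- sums[sums$metric == metrics[2], c("sample_id", "spot", "side", "sum_intensity")]
  names(a)[4] <- "co_linear"; names(b)[4] <- "cross_circular"
  pts <- dplyr::inner_join(a, b, by = c("sample_id", "spot", "side"))
  if (nrow(pts) < nrow(a) || nrow(pts) < nrow(b)) {
    abort("Unpaired measurement spots: every spot needs both channels.")
  }
  m <- scale(cbind(pts$co_linear, pts$cross_circular))
  pc1 <- svd(m)$v[, 1]
  proj <- as.numeric(m %*% pc1)
  lab <- pts$side == "normal"
  cand <- sort(unique(proj))
  thr <- c(-Inf, (cand[-1] + cand[-length(cand)]) / 2, Inf)
  acc <- vapply(thr, function(th) {
    max(mean((proj > th) == lab), mean((proj <= th) == lab))
  }, numeric(1))
  best <- which.max(acc)
  structure(pts, class = c("polarimetric_map", class(tibble())),
            separability = list(accuracy = acc[best], threshold = thr[best],
                                axis = pc1))
}

#' @method glance polarimetric_map
#' @export
glance.polarimetric_map <- function(x, ...) {
  s <- attr(x, "separability")
  tibble(n_points = nrow(x), accuracy = s$accuracy, threshold = s$threshold)
}

#' @method autoplot polarimetric_map
#' @export
autoplot.polarimetric_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$co_linear, .data$cross_circular,
                                       colour = .data$side)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "co-linear intensity (a.u.)",
                  y = "cross-circular intensity (a.u.)",
                  title = "Polarimetric map of measurement spots")
}
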