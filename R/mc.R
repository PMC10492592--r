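#' Scattering medium specification
#'
#' A cubic (or box-shaped) suspension of monodisperse spheres, described by
#' its scattering/absorption coefficients, the single-sphere Mie parameters
#' and the slab dimensions.
#'
#' @param mie A [mie_parameters()] object for the suspended spheres.
#' @param mus_per_cm Scattering coefficient in 1/cm (> 0).
#' @param mua_per_cm Absorption coefficient in 1/cm (>= 0, default 0; water
#'   at red wavelengths is effectively non-absorbing on cm scales).
#' @param box_cm Slab dimensions `c(Lx, Ly, Lz)` in cm. Default a 2.2 cm cube.
#' @return An object of class `medium_spec`.
#' @examples
#' medium_spec(mie_parameters(635, 1.33, 1.59, 1.04), mus_per_cm = 25)
#' @export
medium_spec <- function(mie, mus_per_cm = 25, mua_per_cm = 0,
                        box_cm = c(2.2, 2.2, 2.2)) {
  stopifnot(inherits(mie, "mie_parameters"))
  if (mus_per_cm <= 0) abort("`mus_per_cm` must be > 0.")
  if (mua_per_cm < 0) abort("`mua_per_cm` must be >= 0.")
  if (length(box_cm) != 3 || any(box_cm <= 0)) abort("`box_cm` must be 3 positive lengths.")
  structure(list(mie = mie, mus_per_cm = mus_per_cm, mua_per_cm = mua_per_cm,
                 box_cm = box_cm), class = "medium_spec")
}

#' Illumination beam specification
#'
#' Flat-field circular beam at normal incidence on the top face, in one of
#' four pure polarization states.
#'
#' @param diameter_mm Beam diameter in mm (> 0), default 3.
#' @param incident_state One of `"linear_minus45"`, `"linear_plus45"`,
#'   `"circular_right"`, `"circular_left"`. The linear states are referenced
#'   to the lab/image x axis, so the -45 degree polarization vector lies
#'   along the image diagonal.
#' @param profile Beam profile; only `"flat_field"` is supported (matching
#'   the simulated illumination the method was developed with).
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(diameter_mm = 3,
                      incident_state = c("linear_minus45", "linear_plus45",
                                         "circular_right", "circular_left"),
                      profile = "flat_field") {
  incident_state <- match.arg(incident_state)
  profile <- match.arg(profile, "flat_field")
  if (diameter_mm <= 0) abort("`diameter_mm` must be > 0.")
  structure(list(diameter_mm = diameter_mm, incident_state = incident_state,
                 profile = profile), class = "beam_spec")
}

incident_state_code <- function(state) {
  switch(state, linear_minus45 = 0L, linear_plus45 = 1L,
         circular_right = 2L, circular_left = 3L,
         abort("unknown incident state"))
}

incident_stokes <- function(state) {
  switch(state,
         linear_minus45 = stokes_linear_minus45(),
         linear_plus45 = stokes_linear45(),
         circular_right = stokes_circular_right(),
         circular_left = stokes_circular_left())
}

# absolute image-plane angle (deg, CCW from +x) of the incident linear
# polarization axis; NA for circular states
incident_pol_axis_deg <- function(state) {
  switch(state, linear_minus45 = -45, linear_plus45 = 45, NA_real_)
}

#' Run the polarized backscatter Monte Carlo
#'
#' Launches `n_packets` polarized photon packets into the medium and
#' accumulates the backscattered co/cross linear and circular analyzer
#' images on a detector grid centred on the beam axis, together with
#' per-pixel detected-photon counts and (channel-weighted) scattering-event
#' and pathlength totals. Index-matched boundaries; packets are detected when
#' they exit the illuminated top face within the acceptance cone.
#'
#' The run is deterministic given `seed`: each packet consumes an independent
#' counter-derived RNG stream, so results do not depend on execution order.
#'
#' @param medium A [medium_spec()].
#' @param beam A [beam_spec()].
#' @param n_packets Number of photon packets to launch (>= 1).
#' @param seed Integer master seed.
#' @param nx,ny Detector grid size in pixels (default 101 x 101).
#' @param field_mm Physical detector extent in mm (square, centred on the
#'   beam axis; default 20).
#' @param acceptance_deg Half-angle of the detection acceptance cone about
#'   exact backscatter, in degrees (default 15).
#' @param max_events Safety cap on scattering events per packet (default 1e5;
#'   capped packets are counted in the metadata).
#' @param n_record If > 0, per-packet exit records (position, direction,
#'   detection-frame Stokes, event count, pathlength) are kept for the first
#'   `n_record` detected packets, in `$exits`.
#' @param angle_resolution_deg Angular resolution of the internal Mueller
#'   table (default 0.25).
#' @param table Optionally a precomputed [mie_mueller_table()] (must match
#'   `medium$mie`).
#'
#' @return An object of class `polarpath_sim`: a list with `images` (named
#'   list of `nx` x `ny` matrices: `co_linear`, `cross_linear`, `co_circular`,
#'   `cross_circular`, `counts`, `nscat_sum`, `path_sum`, and channel-weighted
#'   `nscat_<channel>` totals), `meta` (run metadata, including the incident
#'   polarization-axis angle used by the spatial analysis), and `exits`
#'   (tibble or NULL).
#' @export
run_simulation <- function(medium, beam, n_packets, seed, nx = 101, ny = 101,
                           field_mm = 20, acceptance_deg = 15,
                           max_events = 1e5, n_record = 0,
                           angle_resolution_deg = 0.25, table = NULL) {
  stopifnot(inherits(medium, "medium_spec"), inherits(beam, "beam_spec"))
  if (n_packets < 1) abort("`n_packets` must be >= 1.")
  if (is.null(table)) {
    table <- mie_mueller_table(medium$mie, angle_resolution_deg)
  }
  res <- mc_backscatter_cpp(
    table$theta_deg, table$m11, table$m12, table$m33, table$m34,
    medium$mus_per_cm, medium$mua_per_cm,
    medium$box_cm[1], medium$box_cm[2], medium$box_cm[3],
    beam$diameter_mm / 20,  # radius in cm
    incident_state_code(beam$incident_state),
    as.integer(nx), as.integer(ny), field_mm / 10, acceptance_deg,
    as.numeric(n_packets), as.numeric(seed), as.numeric(max_events),
    as.integer(n_record))
  images <- lapply(res$images, function(v) matrix(v, nrow = nx, ncol = ny))
  exits <- NULL
  if (res$n_recorded > 0) {
    m <- res$exits[seq_len(res$n_recorded), , drop = FALSE]
    exits <- tibble(
      x_mm = m[, 1] * 10, y_mm = m[, 2] * 10,
      vx = m[, 3], vy = m[, 4], vz = m[, 5],
      weight = m[, 6], Q_det = m[, 7], U_det = m[, 8], V = m[, 9],
      n_scatter = m[, 10], pathlength_cm = m[, 11])
  }
  meta <- list(
    n_packets = n_packets, seed = seed,
    n_detected = res$n_detected, n_top_exits = res$n_top_exits,
    n_out_of_grid = res$n_out_of_grid, n_capped = res$n_capped,
    n_rejection_failures = res$n_rejection_failures,
    nx = nx, ny = ny, field_mm = field_mm, pixel_mm = field_mm / nx,
    acceptance_deg = acceptance_deg,
    incident_state = beam$incident_state,
    pol_axis_deg = incident_pol_axis_deg(beam$incident_state),
    beam_mm = beam$diameter_mm, mus_per_cm = medium$mus_per_cm,
    mua_per_cm = medium$mua_per_cm, box_cm = medium$box_cm,
    wavelength_nm = medium$mie$wavelength_nm,
    diameter_um = medium$mie$diameter_um,
    host_index = medium$mie$host_index, sphere_index = medium$mie$sphere_index,
    anisotropy_g = attr(table, "anisotropy_g"),
    max_events = max_events)
  structure(list(images = images, meta = meta, exits = exits),
            class = "polarpath_sim")
}

#' @export
print.polarpath_sim <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<polarpath_sim> %s packets (seed %s), %s detected in %g deg cone\n  %dx%d px over %g mm; mus = %g /cm; incident %s\n",
    format(m$n_packets, big.mark = ","), m$seed,
    format(m$n_detected, big.mark = ","), m$acceptance_deg,
    m$nx, m$ny, m$field_mm, m$mus_per_cm, m$incident_state))
  invisible(x)
}

#' Pixel-centre coordinates of a simulation / image grid
#'
#' @param nx,ny Grid size in pixels.
#' @param field_mm Physical extent (mm), centred on the beam axis.
#' @return List with vectors `x_mm`, `y_mm` of pixel-centre coordinates.
#' @keywords internal
pixel_centers <- function(nx, ny, field_mm) {
  px <- field_mm / nx
  py <- field_mm / ny
  list(x_mm = -field_mm / 2 + (seq_len(nx) - 0.5) * px,
       y_mm = -field_mm / 2 + (seq_len(ny) - 0.5) * py)
}

#' @method tidy polarpath_sim
#' @export
tidy.polarpath_sim <- function(x, channels = c("co_linear", "cross_linear",
                                               "co_circular", "cross_circular"),
                               ...) {
  ctr <- pixel_centers(x$meta$nx, x$meta$ny, x$meta$field_mm)
  purrr::map_dfr(channels, function(ch) {
    img <- x$images[[ch]]
    tibble(channel = ch,
           x_mm = rep(ctr$x_mm, times = x$meta$ny),
           y_mm = rep(ctr$y_mm, each = x$meta$nx),
           intensity = as.vector(img))
  })
}

#' @method glance polarpath_sim
#' @export
glance.polarpath_sim <- function(x, ...) {
  m <- x$meta
  tibble(n_packets = m$n_packets, seed = m$seed, n_detected = m$n_detected,
         n_top_exits = m$n_top_exits, n_out_of_grid = m$n_out_of_grid,
         n_capped = m$n_capped, nx = m$nx, ny = m$ny, field_mm = m$field_mm,
         acceptance_deg = m$acceptance_deg, incident_state = m$incident_state,
         mus_per_cm = m$mus_per_cm, anisotropy_g = m$anisotropy_g)
}

#' @method autoplot polarpath_sim
#' @export
autoplot.polarpath_sim <- function(object, channel = "co_linear",
                                   trans = "sqrt", ...) {
  df <- tidy(object, channels = channel)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = channel,
                  title = sprintf("Backscattered %s image", channel))
}

# ---------------------------------------------------------------------------
# R-level packet operations. These mirror the compiled kernel's conventions
# exactly and exist so each transport step can be exercised and unit-tested
# in isolation; the compiled kernel is the fast path for full runs.

#' Launch a polarized photon packet
#'
#' Start position uniform on the flat-field beam disc at the top surface,
#' direction into the medium (+z), local frame `e1 = x`, `e2 = y`, Stokes set
#' to the pure incident state.
#'
#' @param beam A [beam_spec()].
#' @return A `photon_packet`: list with `pos` (cm), `v`, `e1`, `e2`
#'   (orthonormal triad), `stokes`, `n_scatter`, `pathlength_cm`, `weight`,
#'   `alive`.
#' @export
launch_packet <- function(beam) {
  stopifnot(inherits(beam, "beam_spec"))
  r <- beam$diameter_mm / 20 * sqrt(runif(1))
  a <- runif(1, 0, 2 * pi)
  structure(list(
    pos = c(r * cos(a), r * sin(a), 0),
    v = c(0, 0, 1), e1 = c(1, 0, 0), e2 = c(0, 1, 0),
    stokes = incident_stokes(beam$incident_state),
    n_scatter = 0L, pathlength_cm = 0, weight = 1, alive = TRUE,
    exited = NA_character_), class = "photon_packet")
}

#' Propagate a packet one exponential free path
#'
#' Samples a step `s = -log(xi) / mu_t` and advances the packet; if a slab
#' boundary is crossed the packet is moved exactly onto the boundary, marked
#' dead and labelled with the exit face (no scattering increment).
#'
#' @param packet A `photon_packet`.
#' @param medium A [medium_spec()].
#' @param xi Optional uniform deviate (for deterministic tests).
#' @return The advanced packet; `$exited` is one of `"top"`, `"bottom"`,
#'   `"side"` or `NA` (still inside, due a scattering event).
#' @export
propagate_step <- function(packet, medium, xi = NULL) {
  stopifnot(inherits(packet, "photon_packet"), packet$alive)
  mut <- medium$mus_per_cm + medium$mua_per_cm
  if (is.null(xi)) xi <- runif(1)
  s <- -log(xi) / mut
  L <- medium$box_cm
  v <- packet$v; p <- packet$pos
  t_exit <- Inf; face <- NA_character_
  cand <- list(
    c(if (v[3] < 0) -p[3] / v[3] else Inf, "top"),
    c(if (v[3] > 0) (L[3] - p[3]) / v[3] else Inf, "bottom"),
    c(if (v[1] > 0) (L[1] / 2 - p[1]) / v[1] else Inf, "side"),
    c(if (v[1] < 0) (-L[1] / 2 - p[1]) / v[1] else Inf, "side"),
    c(if (v[2] > 0) (L[2] / 2 - p[2]) / v[2] else Inf, "side"),
    c(if (v[2] < 0) (-L[2] / 2 - p[2]) / v[2] else Inf, "side"))
  for (cc in cand) {
    t <- as.numeric(cc[[1]])
    if (t < t_exit) { t_exit <- t; face <- cc[[2]] }
  }
  if (s >= t_exit) {
    packet$pos <- p + t_exit * v
    packet$pathlength_cm <- packet$pathlength_cm + t_exit
    packet$alive <- FALSE
    packet$exited <- face
  } else {
    packet$pos <- p + s * v
    packet$pathlength_cm <- packet$pathlength_cm + s
    mus <- medium$mus_per_cm
    packet$weight <- packet$weight * mus / mut
  }
  packet
}

# Mueller rotation of the Stokes reference frame about v by phi (radians);
# the new e1 is rotated towards e2.
rotate_packet_frame <- function(packet, phi) {
  c2 <- cos(2 * phi); s2 <- sin(2 * phi)
  s <- packet$stokes
  packet$stokes <- c(s[1], s[2] * c2 + s[3] * s2, -s[2] * s2 + s[3] * c2, s[4])
  e1 <- cos(phi) * packet$e1 + sin(phi) * packet$e2
  e2 <- -sin(phi) * packet$e1 + cos(phi) * packet$e2
  packet$e1 <- e1; packet$e2 <- e2
  packet
}

# Sample (theta, phi) by rejection from the polarization-dependent phase
# function P ~ M11 I + M12 (Q cos 2phi + U sin 2phi); theta proposals from
# the tabulated M11 sin(theta) marginal.
sample_scatter_angles <- function(table, stokes, max_iter = 10000) {
  th <- table$theta_deg * pi / 180
  w <- table$m11 * sin(th)
  dth <- th[2] - th[1]
  seg <- 0.5 * (w[-1] + w[-length(w)]) * dth
  cum <- c(0, cumsum(seg))
  tot <- cum[length(cum)]
  p <- sqrt(stokes[2]^2 + stokes[3]^2) / stokes[1]
  for (i in seq_len(max_iter)) {
    u <- runif(1) * tot
    lo <- findInterval(u, cum, rightmost.closed = TRUE)
    frac <- (u - cum[lo]) / max(seg[lo], .Machine$double.xmin)
    theta <- th[lo] + frac * dth
    phi <- runif(1, 0, 2 * pi)
    el <- interp_mueller(table, theta * 180 / pi)
    ratio <- (1 + (el$m12 / el$m11) *
                (stokes[2] * cos(2 * phi) + stokes[3] * sin(2 * phi)) /
                stokes[1]) / (1 + p)
    if (runif(1) <= ratio) return(list(theta = theta, phi = phi))
  }
  abort("Rejection sampling failed to accept within the iteration cap (malformed envelope?).")
}

#' Scatter a packet at one Mie event
#'
#' Rotates the Stokes frame into the scattering plane (rotation by `phi`),
#' applies the sphere Mueller matrix at `theta`, updates the direction triad
#' and renormalizes the Stokes vector to the packet-weight convention
#' (`I` back to the weight-carried intensity). When `theta`/`phi` are not
#' supplied they are sampled from the polarization-dependent phase function.
#'
#' @param packet A `photon_packet` (alive).
#' @param table A [mie_mueller_table()].
#' @param theta,phi Optional forced scattering/azimuth angles in radians
#'   (deterministic tests).
#' @return The scattered packet (`n_scatter` incremented).
#' @export
scatter_event <- function(packet, table, theta = NULL, phi = NULL) {
  stopifnot(inherits(packet, "photon_packet"), packet$alive)
  if (is.null(theta) || is.null(phi)) {
    ang <- sample_scatter_angles(table, packet$stokes)
    theta <- ang$theta; phi <- ang$phi
  }
  packet <- rotate_packet_frame(packet, phi)
  ct <- cos(theta); st <- sin(theta)
  vn <- st * packet$e1 + ct * packet$v
  e1n <- ct * packet$e1 - st * packet$v
  el <- interp_mueller(table, theta * 180 / pi)
  s <- unname(packet$stokes)
  iout <- el$m11 * s[1] + el$m12 * s[2]
  if (iout <= 0) abort("Scattering into a zero-probability state.")
  w <- s[1]  # preserve packet weight convention
  packet$stokes <- c(
    w,
    (el$m12 * s[1] + el$m11 * s[2]) / iout * w,
    (el$m33 * s[3] + el$m34 * s[4]) / iout * w,
    (-el$m34 * s[3] + el$m33 * s[4]) / iout * w)
  packet$v <- vn; packet$e1 <- e1n
  packet$n_scatter <- packet$n_scatter + 1L
  packet
}

#' Detector grid accumulator (R-level)
#'
#' @param nx,ny Pixels; `field_mm` physical extent; `acceptance_deg` cone
#'   half-angle.
#' @return A `detector_grid` accumulator with zeroed channel images.
#' @export
detector_grid <- function(nx = 101, ny = 101, field_mm = 20,
                          acceptance_deg = 15) {
  z <- matrix(0, nx, ny)
  structure(list(nx = nx, ny = ny, field_mm = field_mm,
                 acceptance_deg = acceptance_deg,
                 co_linear = z, cross_linear = z, co_circular = z,
                 cross_circular = z, counts = z, nscat_sum = z, path_sum = z,
                 n_out_of_grid = 0, n_detected = 0),
            class = "detector_grid")
}

#' Score an exiting packet into the detector grid
#'
#' Transforms the packet Stokes vector into the fixed lab detection frame
#' (handling the propagation-reversal frame flip) and accumulates the four
#' analyzer channels `1/2 (I -+ s U_det)` (co/cross linear) and
#' `1/2 (I +- s V)` (co/cross circular) at the exit pixel, together with the
#' photon count, scattering-event total and pathlength total.
#'
#' @param packet A packet that exited the top face (`$exited == "top"`).
#' @param grid A [detector_grid()].
#' @param incident_state The incident polarization state (fixes the co/cross
#'   analyzer signs).
#' @return The updated grid.
#' @export
detect_packet <- function(packet, grid, incident_state = "linear_minus45") {
  stopifnot(inherits(packet, "photon_packet"), inherits(grid, "detector_grid"))
  if (!identical(packet$exited, "top")) {
    abort("Packet did not exit through the illuminated (top) face.")
  }
  v <- packet$v
  if (-v[3] < cos(grid$acceptance_deg * pi / 180)) return(grid)
  d1 <- c(1 - v[1]^2, -v[1] * v[2], -v[1] * v[3])
  d1 <- d1 / sqrt(sum(d1^2))
  # rotation angle from (e1,e2) to the detection basis about v:
  # d1 = cos(psi) e1 + sin(psi) e2
  cpsi <- sum(packet$e1 * d1); spsi <- sum(packet$e2 * d1)
  c2 <- cpsi^2 - spsi^2; s2 <- 2 * spsi * cpsi
  s <- packet$stokes
  Ud <- -s[2] * s2 + s[3] * c2
  s_lin <- if (incident_state == "linear_plus45") 1 else -1
  s_circ <- if (incident_state == "circular_left") -1 else 1
  w <- s[1]
  i_co_l <- 0.5 * (w - s_lin * Ud)
  i_cx_l <- 0.5 * (w + s_lin * Ud)
  i_co_c <- 0.5 * (w + s_circ * s[4])
  i_cx_c <- 0.5 * (w - s_circ * s[4])
  grid$n_detected <- grid$n_detected + 1
  px <- grid$field_mm / 10 / grid$nx
  ix <- floor((packet$pos[1] + grid$field_mm / 20) / px) + 1
  iy <- floor((packet$pos[2] + grid$field_mm / 20) / px) + 1
  if (ix < 1 || ix > grid$nx || iy < 1 || iy > grid$ny) {
    grid$n_out_of_grid <- grid$n_out_of_grid + 1
    return(grid)
  }
  grid$co_linear[ix, iy] <- grid$co_linear[ix, iy] + i_co_l
  grid$cross_linear[ix, iy] <- grid$cross_linear[ix, iy] + i_cx_l
  grid$co_circular[ix, iy] <- grid$co_circular[ix, iy] + i_co_c
  grid$cross_circular[ix, iy] <- grid$cross_circular[ix, iy] + i_cx_c
  grid$counts[ix, iy] <- grid$counts[ix, iy] + w
  grid$nscat_sum[ix, iy] <- grid$nscat_sum[ix, iy] + w * packet$n_scatter
  grid$path_sum[ix, iy] <- grid$path_sum[ix, iy] + w * packet$pathlength_cm
  grid
}
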