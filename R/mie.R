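#' Mie input parameters for a homogeneous sphere in a non-absorbing host
#'
#' Bundles the optical configuration of a single spherical scatterer: vacuum
#' wavelength, host and sphere refractive indices, and sphere diameter. The
#' derived size parameter is `x = pi * d * n_host / lambda_vac`.
#'
#' @param wavelength_nm Vacuum wavelength in nanometres (> 0).
#' @param host_index Real refractive index of the host medium (>= 1).
#' @param sphere_index Real refractive index of the sphere.
#' @param diameter_um Sphere diameter in micrometres (> 0).
#'
#' @return An object of class `mie_parameters`: a list with the four inputs
#'   plus `size_parameter` and the relative index `m = sphere_index /
#'   host_index`.
#' @examples
#' mie_parameters(635, 1.33, 1.59, 1.04)
#' @export
mie_parameters <- function(wavelength_nm, host_index, sphere_index, diameter_um) {
  stopifnot(is.numeric(wavelength_nm), length(wavelength_nm) == 1,
            is.numeric(host_index), length(host_index) == 1,
            is.numeric(sphere_index), length(sphere_index) == 1,
            is.numeric(diameter_um), length(diameter_um) == 1)
  if (wavelength_nm <= 0) abort("`wavelength_nm` must be > 0.")
  if (diameter_um <= 0) abort("`diameter_um` must be > 0.")
  if (host_index < 1) abort("`host_index` must be >= 1.")
  if (sphere_index <= 0) abort("`sphere_index` must be > 0.")
  x <- pi * diameter_um * host_index / (wavelength_nm / 1000)
  structure(
    list(wavelength_nm = wavelength_nm, host_index = host_index,
         sphere_index = sphere_index, diameter_um = diameter_um,
         size_parameter = x, relative_index = sphere_index / host_index),
    class = "mie_parameters")
}

#' @export
print.mie_parameters <- function(x, ...) {
  cat(sprintf(
    "<mie_parameters> lambda = %g nm, n_host = %g, n_sphere = %g, d = %g um (x = %.4g, m = %.4g)\n",
    x$wavelength_nm, x$host_index, x$sphere_index, x$diameter_um,
    x$size_parameter, x$relative_index))
  invisible(x)
}

# Mie coefficients a_n, b_n for real relative index m and size parameter x.
# Logarithmic derivative by downward recurrence; Riccati-Bessel psi/chi upward.
mie_coefficients <- function(x, m) {
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)  # Wiscombe truncation
  nmx <- max(nmax, ceiling(abs(m * x))) + 16
  mx <- m * x
  D <- numeric(nmx)
  for (n in seq(nmx - 1, 1)) {
    D[n] <- (n + 1) / mx - 1 / (D[n + 1] + (n + 1) / mx)
  }
  a <- complex(length.out = nmax)
  b <- complex(length.out = nmax)
  psim2 <- cos(x); psim1 <- sin(x)
  chim2 <- -sin(x); chim1 <- cos(x)
  for (n in 1:nmax) {
    psi <- (2 * n - 1) / x * psim1 - psim2
    chi <- (2 * n - 1) / x * chim1 - chim2
    xi <- complex(real = psi, imaginary = -chi)
    xim1 <- complex(real = psim1, imaginary = -chim1)
    ta <- D[n] / m + n / x
    tb <- D[n] * m + n / x
    a[n] <- (ta * psi - psim1) / (ta * xi - xim1)
    b[n] <- (tb * psi - psim1) / (tb * xi - xim1)
    psim2 <- psim1; psim1 <- psi
    chim2 <- chim1; chim1 <- chi
  }
  list(a = a, b = b, nmax = nmax)
}

# Amplitude functions S1, S2 at the given cos(theta) values.
mie_amplitudes <- function(coef, cos_theta) {
  nmax <- coef$nmax
  S1 <- complex(length.out = length(cos_theta))
  S2 <- S1
  pi0 <- rep(0, length(cos_theta))
  pi1 <- rep(1, length(cos_theta))
  for (n in 1:nmax) {
    tau <- n * cos_theta * pi1 - (n + 1) * pi0
    f <- (2 * n + 1) / (n * (n + 1))
    S1 <- S1 + f * (coef$a[n] * pi1 + coef$b[n] * tau)
    S2 <- S2 + f * (coef$a[n] * tau + coef$b[n] * pi1)
    pin <- ((2 * n + 1) * cos_theta * pi1 - (n + 1) * pi0) / n
    pi0 <- pi1; pi1 <- pin
  }
  list(S1 = S1, S2 = S2)
}

#' Angular Mueller matrix of a single sphere
#'
#' Tabulates the four independent Mueller elements of a homogeneous sphere,
#' `M11, M12, M33, M34`, on a uniform scattering-angle grid, from the Mie
#' amplitude functions `S1(theta)`, `S2(theta)`:
#' `M11 = (|S2|^2 + |S1|^2) / 2`, `M12 = (|S2|^2 - |S1|^2) / 2`,
#' `M33 = Re(S2 S1*)`, `M34 = Im(S2 S1*)`. The same series also yields the
#' scattering efficiency `Q_sca` and the anisotropy `g` (mean cosine of the
#' scattering angle), carried as attributes.
#'
#' The series is truncated at the Wiscombe order `x + 4 x^(1/3) + 2`. An
#' index-matched sphere (`sphere_index == host_index`) is a valid degenerate
#' input: it scatters nothing, the table is flagged with `attr(., "degenerate")`
#' and a warning is raised.
#'
#' @param params A [mie_parameters()] object.
#' @param angle_resolution_deg Uniform angular grid step in degrees,
#'   in (0, 1]. Default 0.25.
#'
#' @return A tibble of class `mueller_table` with columns `theta_deg`, `m11`,
#'   `m12`, `m33`, `m34`, and attributes `params`, `scattering_efficiency`,
#'   `anisotropy_g`, `sigma_sca_cm2` (scattering cross-section),
#'   `n_terms`, `degenerate`.
#' @examples
#' tab <- mie_mueller_table(mie_parameters(635, 1.33, 1.59, 1.04))
#' glance(tab)
#' @export
mie_mueller_table <- function(params, angle_resolution_deg = 0.25) {
  stopifnot(inherits(params, "mie_parameters"))
  if (!is.numeric(angle_resolution_deg) || angle_resolution_deg <= 0 ||
      angle_resolution_deg > 1) {
    abort("`angle_resolution_deg` must be in (0, 1].")
  }
  theta <- seq(0, 180, by = angle_resolution_deg)
  if (theta[length(theta)] < 180) theta <- c(theta, 180)
  ct <- cos(theta * pi / 180)
  x <- params$size_parameter
  m <- params$relative_index
  degenerate <- isTRUE(all.equal(m, 1, tolerance = 1e-12))

  coef <- mie_coefficients(x, m)
  amp <- mie_amplitudes(coef, ct)
  n <- seq_len(coef$nmax)
  qsca <- 2 / x^2 * sum((2 * n + 1) * (Mod(coef$a)^2 + Mod(coef$b)^2))
  if (degenerate || qsca <= .Machine$double.eps) {
    warn("Index-matched (or vanishing-contrast) sphere: no scattering; table is degenerate.")
    degenerate <- TRUE
    g <- 1
  } else {
    nn <- n[-length(n)]
    gq <- sum(nn * (nn + 2) / (nn + 1) *
                Re(coef$a[nn] * Conj(coef$a[nn + 1]) +
                   coef$b[nn] * Conj(coef$b[nn + 1]))) +
      sum((2 * n + 1) / (n * (n + 1)) * Re(coef$a * Conj(coef$b)))
    g <- 4 / x^2 * gq / qsca
  }
  out <- tibble(
    theta_deg = theta,
    m11 = 0.5 * (Mod(amp$S2)^2 + Mod(amp$S1)^2),
    m12 = 0.5 * (Mod(amp$S2)^2 - Mod(amp$S1)^2),
    m33 = Re(amp$S2 * Conj(amp$S1)),
    m34 = Im(amp$S2 * Conj(amp$S1)))
  # scattering cross-section in cm^2 (geometric area * efficiency)
  radius_cm <- params$diameter_um * 1e-4 / 2
  structure(
    out,
    class = c("mueller_table", class(out)),
    params = params,
    scattering_efficiency = qsca,
    anisotropy_g = g,
    sigma_sca_cm2 = qsca * pi * radius_cm^2,
    n_terms = coef$nmax,
    degenerate = degenerate)
}

#' @method glance mueller_table
#' @export
glance.mueller_table <- function(x, ...) {
  p <- attr(x, "params")
  tibble(
    size_parameter = p$size_parameter,
    relative_index = p$relative_index,
    scattering_efficiency = attr(x, "scattering_efficiency"),
    anisotropy_g = attr(x, "anisotropy_g"),
    sigma_sca_cm2 = attr(x, "sigma_sca_cm2"),
    n_terms = attr(x, "n_terms"),
    degenerate = attr(x, "degenerate"))
}

#' Stokes vector constructors and physicality
#'
#' A Stokes vector is a length-4 numeric `(I, Q, U, V)`; `I >= 0` and
#' `I^2 >= Q^2 + U^2 + V^2` (equality for fully polarized states).
#'
#' @param I,Q,U,V Stokes components.
#' @return `stokes()` returns a named numeric vector of length 4.
#' @examples
#' stokes_linear45()
#' stokes_circular_right()
#' @export
stokes <- function(I, Q = 0, U = 0, V = 0) {
  s <- c(I = I, Q = Q, U = U, V = V)
  if (!is_physical_stokes(s)) {
    abort("Non-physical Stokes vector: need I >= 0 and I^2 >= Q^2 + U^2 + V^2.")
  }
  s
}

#' @rdname stokes
#' @param s A numeric vector of length 4.
#' @param tol Relative tolerance on the degree-of-polarization bound.
#' @export
is_physical_stokes <- function(s, tol = 1e-9) {
  length(s) == 4 && is.numeric(s) && s[1] >= 0 &&
    s[1]^2 * (1 + tol) + tol >= s[2]^2 + s[3]^2 + s[4]^2
}

#' @rdname stokes
#' @export
stokes_linear45 <- function() stokes(1, 0, 1, 0)

#' @rdname stokes
#' @export
stokes_linear_minus45 <- function() stokes(1, 0, -1, 0)

#' @rdname stokes
#' @export
stokes_circular_right <- function() stokes(1, 0, 0, 1)

#' @rdname stokes
#' @export
stokes_circular_left <- function() stokes(1, 0, 0, -1)

# Interpolate the four Mueller elements at arbitrary angles.
interp_mueller <- function(table, theta_deg) {
  list(
    m11 = approx(table$theta_deg, table$m11, theta_deg, rule = 2)$y,
    m12 = approx(table$theta_deg, table$m12, theta_deg, rule = 2)$y,
    m33 = approx(table$theta_deg, table$m33, theta_deg, rule = 2)$y,
    m34 = approx(table$theta_deg, table$m34, theta_deg, rule = 2)$y)
}

#' Scatter a Stokes vector through the single-sphere Mueller matrix
#'
#' Applies the block-structured sphere Mueller matrix at scattering angle
#' `theta_deg` (elements interpolated from the table) to an incident Stokes
#' vector: `I' = M11 I + M12 Q`, `Q' = M12 I + M11 Q`,
#' `U' = M33 U + M34 V`, `V' = -M34 U + M33 V`.
#'
#' @param table A [mie_mueller_table()] result.
#' @param s_in Incident Stokes vector, numeric length 4 (physical).
#' @param theta_deg Scattering angle(s) in degrees, each in \[0, 180\].
#'
#' @return A tibble with columns `theta_deg`, `I`, `Q`, `U`, `V` (one row per
#'   angle).
#' @export
scatter_stokes <- function(table, s_in, theta_deg) {
  stopifnot(inherits(table, "mueller_table"))
  if (!is_physical_stokes(s_in)) abort("`s_in` is not a physical Stokes vector.")
  if (any(theta_deg < 0 | theta_deg > 180)) {
    abort("`theta_deg` must lie in [0, 180].")
  }
  el <- interp_mueller(table, theta_deg)
  tibble(
    theta_deg = theta_deg,
    I = el$m11 * s_in[1] + el$m12 * s_in[2],
    Q = el$m12 * s_in[1] + el$m11 * s_in[2],
    U = el$m33 * s_in[3] + el$m34 * s_in[4],
    V = -el$m34 * s_in[3] + el$m33 * s_in[4])
}

#' Polar profile of the matched polarization component
#'
#' For incident +45 degree linear light `[1,0,1,0]` returns the scattered
#' 45-degree linear component `U(theta)`; for incident right-circular light
#' `[1,0,0,1]` returns the scattered circular component `V(theta)`. Negative
#' values mark orthogonalization (+45 leaves as -45; right-circular leaves as
#' left-circular). For a sphere the two profiles are identical, which is what
#' lets co-linear and cross-circular channels be used interchangeably as
#' orthogonalization detectors.
#'
#' @param table A [mie_mueller_table()] result.
#' @param incident `"linear45"` or `"circular_right"`.
#' @return A tibble of class `polar_profile` with columns `theta_deg`,
#'   `intensity` (signed) and attribute `incident`.
#' @export
polar_intensity_profile <- function(table, incident = c("linear45", "circular_right")) {
  incident <- match.arg(incident)
  s_in <- switch(incident,
                 linear45 = stokes_linear45(),
                 circular_right = stokes_circular_right())
  out <- scatter_stokes(table, s_in, table$theta_deg)
  component <- if (incident == "linear45") out$U else out$V
  structure(
    tibble(theta_deg = table$theta_deg, intensity = component),
    class = c("polar_profile", class(tibble())),
    incident = incident,
    m11_max = max(table$m11))
}

#' Backward orthogonalization interval of a polar profile
#'
#' Finds the largest contiguous angular interval containing 180 degrees over
#' which the profile is negative (polarization orthogonalized). Values within
#' a dead-band `|value| < 1e-12 * max(M11)` are treated as zero and do not
#' break a run (guards against grid-level sign noise). Reported in the
#' polar-display convention where the scattering-angle interval
#' `[onset, 180]` mirrors to `[180, 360 - onset]`.
#'
#' @param profile A [polar_intensity_profile()] result (uniform grid on
#'   \[0, 180\]).
#' @return A one-row tibble: `theta_onset_deg`, `theta_end_deg`
#'   (`= 360 - theta_onset_deg`), `empty` (TRUE when no negative region
#'   contains 180 degrees, in which case the angles are `NA`).
#' @export
orthogonalization_interval <- function(profile) {
  stopifnot(is.data.frame(profile), all(c("theta_deg", "intensity") %in% names(profile)))
  v <- profile$intensity
  scale <- attr(profile, "m11_max") %||% max(abs(v))
  tol <- 1e-12 * scale
  state <- ifelse(v < -tol, -1L, ifelse(v > tol, 1L, 0L))
  n <- length(state)
  if (state[n] > 0L) {
    return(tibble(theta_onset_deg = NA_real_, theta_end_deg = NA_real_, empty = TRUE))
  }
  i <- n
  saw_negative <- FALSE
  while (i >= 1 && state[i] <= 0L) {
    if (state[i] < 0L) saw_negative <- TRUE
    i <- i - 1
  }
  if (!saw_negative) {
    return(tibble(theta_onset_deg = NA_real_, theta_end_deg = NA_real_, empty = TRUE))
  }
  # trim leading dead-band zeros so onset is the first strictly negative angle
  j <- i + 1
  while (j <= n && state[j] == 0L) j <- j + 1
  onset <- profile$theta_deg[j]
  tibble(theta_onset_deg = onset, theta_end_deg = 360 - onset, empty = FALSE)
}

#' Sphere number density for a target scattering coefficient
#'
#' Converts a target scattering coefficient into a sphere number density via
#' `rho = mus / sigma_sca`, with the scattering cross-section taken from the
#' Mie scattering efficiency and the geometric cross-section.
#'
#' @param table A [mie_mueller_table()] result (carries `sigma_sca_cm2`), or a
#'   [mie_parameters()] object (the table is computed).
#' @param mus_per_cm Target scattering coefficient in 1/cm (> 0).
#' @return Number density in spheres per cm^3.
#' @examples
#' number_density_for_mus(mie_parameters(635, 1.33, 1.59, 1.04), 25)
#' @export
number_density_for_mus <- function(table, mus_per_cm) {
  if (inherits(table, "mie_parameters")) {
    table <- mie_mueller_table(table, angle_resolution_deg = 1)
  }
  stopifnot(inherits(table, "mueller_table"))
  if (!is.numeric(mus_per_cm) || any(mus_per_cm <= 0)) {
    abort("`mus_per_cm` must be > 0.")
  }
  sigma <- attr(table, "sigma_sca_cm2")
  if (isTRUE(attr(table, "degenerate")) || sigma <= 0) {
    abort("Index-matched sphere has zero scattering cross-section; no finite density exists.")
  }
  mus_per_cm / sigma
}

`%||%` <- function(a, b) if (is.null(a)) b else a
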