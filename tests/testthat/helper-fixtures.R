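# Shared fixtures and independent oracles, built in code at test time.

polystyrene_params <- function() mie_parameters(635, 1.33, 1.59, 1.04)
dental_params <- function() mie_parameters(543.5, 1.573, 1.619, 5.75)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

poly_table <- function() cached("poly", mie_mueller_table(polystyrene_params()))
dental_table <- function() cached("dental", mie_mueller_table(dental_params()))

# Independent Mie oracle: Riccati-Bessel functions from R's fractional-order
# Bessel functions, derivatives from the standard downward identity,
# Bohren & Huffman a_n/b_n. Shares no code with the package engine.
oracle_mie <- function(x, m, nmax) {
  n <- seq_len(nmax)
  sj <- function(z, nn) sqrt(pi / (2 * z)) * besselJ(z, nn + 0.5)
  sy <- function(z, nn) sqrt(pi / (2 * z)) * besselY(z, nn + 0.5)
  psi <- x * sj(x, n)
  chi <- -x * sy(x, n)
  xi <- complex(real = psi, imaginary = -chi)
  psimx <- (m * x) * sj(m * x, n)
  psi_prev <- c(sin(x), psi[-nmax])
  chi_prev <- c(cos(x), chi[-nmax])
  xi_prev <- complex(real = psi_prev, imaginary = -chi_prev)
  psimx_prev <- c(sin(m * x), psimx[-nmax])
  dpsi <- psi_prev - n / x * psi
  dxi <- xi_prev - n / x * xi
  dpsimx <- psimx_prev - n / (m * x) * psimx
  a <- (m * psimx * dpsi - psi * dpsimx) / (m * psimx * dxi - xi * dpsimx)
  b <- (psimx * dpsi - m * psi * dpsimx) / (psimx * dxi - m * xi * dpsimx)
  list(a = a, b = b,
       qsca = 2 / x^2 * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2)),
       qext = 2 / x^2 * sum((2 * n + 1) * Re(a + b)))
}

# closed-form dipole (Rayleigh) ratio M33/M11 = 2 cos(t) / (1 + cos(t)^2)
rayleigh_m33_over_m11 <- function(theta_deg) {
  ct <- cos(theta_deg * pi / 180)
  2 * ct / (1 + ct^2)
}

# random physical Stokes vector (fully or partially polarized)
random_stokes <- function() {
  p <- runif(1)
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2)) * p
  c(1, u)
}

# direct, independent evaluation of the pooled-deviation t-score formula
oracle_t <- function(x1, x2) {
  (mean(x1) - mean(x2)) /
    sqrt(stats::var(c(x1, x2)) * (1 / length(x1) + 1 / length(x2)))
}

# Single-scattering radiative-transfer prediction for the detected
# scattering-angle density in a thin slab: first interaction at depth z
# (density mus * exp(-mus z)), exponential survival along the slanted exit
# path back to the illuminated face. Closed form per angle.
single_scatter_weights <- function(tab, mus, L) {
  c_abs <- abs(cos(tab$theta_deg * pi / 180))
  a <- 1 + 1 / c_abs
  tab$m11 * sin(tab$theta_deg * pi / 180) * (1 - exp(-mus * L * a)) / a
}

# trapezoid mass of a tabulated weight between grid-aligned bin edges
bin_masses <- function(tab, w, edges) {
  vapply(seq_len(length(edges) - 1), function(i) {
    sel <- which(tab$theta_deg >= edges[i] & tab$theta_deg <= edges[i + 1])
    sum(w[sel]) - 0.5 * (w[sel[1]] + w[sel[length(sel)]])
  }, 0)
}
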