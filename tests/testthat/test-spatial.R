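test_that("scattering-count map is the masked element-wise quotient", {
  totals <- matrix(c(0, 2, 4, 6, 8,
                     1, 3, 5, 7, 9,
                     10, 0, 20, 30, 40,
                     5, 5, 5, 5, 5,
                     0, 0, 0, 0, 0), 5, 5, byrow = TRUE)
  counts <- matrix(5, 5, 5)
  counts[2, 3] <- 0
  counts[4, 4] <- 3
  m <- scatter_count_map(totals, photon_counts = counts, min_photons = 5,
                         pixel_mm = 1, pol_axis_deg = 0)
  expect_true(is.na(m$n[2, 3]))     # zero photons: masked
  expect_true(is.na(m$n[4, 4]))     # below min_photons: masked
  sel <- !is.na(m$n)
  expect_equal(m$n[sel], totals[sel] / 5)
  # all-zero totals with positive counts give N == 0
  m0 <- scatter_count_map(matrix(0, 3, 3), photon_counts = matrix(9, 3, 3))
  expect_true(all(m0$n == 0))
  expect_error(scatter_count_map(matrix(0, 3, 3), photon_counts = matrix(1, 2, 2)),
               "shape")
})

test_that("radial profile equals a brute-force per-pixel binning", {
  # uniform map: profile constant in every populated bin
  mu <- scatter_count_map(matrix(3, 21, 21) * 7, photon_counts = matrix(7, 21, 21),
                          pixel_mm = 0.5)
  pu <- radial_profile(mu)
  expect_true(all(abs(pu$value[pu$n_pixels > 0] - 3) < 1e-12))
  # single nonzero pixel at the centre: only the first bin is nonzero
  img <- matrix(0, 21, 21); img[11, 11] <- 5
  ps <- radial_profile(img, pixel_mm = 1, bin_width_mm = 1)
  expect_equal(ps$value[1], 5)
  expect_true(all(ps$value[-1][ps$n_pixels[-1] > 0] == 0))
  # random fixture vs explicit loop
  set.seed(4)
  vals <- matrix(runif(64 * 64), 64, 64)
  bw <- 0.7; pmm <- 0.31; ctr <- c(0.4, -0.6)
  prof <- radial_profile(vals, pixel_mm = pmm, bin_width_mm = bw,
                         center_mm = ctr)
  sums <- numeric(200); ns <- integer(200)
  for (i in 1:64) for (j in 1:64) {
    x <- (i - 32.5) * pmm - ctr[1]
    y <- (j - 32.5) * pmm - ctr[2]
    b <- floor(sqrt(x^2 + y^2) / bw) + 1
    sums[b] <- sums[b] + vals[i, j]
    ns[b] <- ns[b] + 1L
  }
  nb <- nrow(prof)
  expect_equal(prof$n_pixels, ns[seq_len(nb)])
  got <- prof$value[prof$n_pixels > 0]
  want <- (sums / pmax(ns, 1))[seq_len(nb)][prof$n_pixels > 0]
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("region Npp matches hand enumeration and the full-image baseline", {
  totals <- matrix(as.numeric(1:25), 5, 5)
  m <- scatter_count_map(totals, photon_counts = matrix(1, 5, 5),
                         min_photons = 1, pixel_mm = 1, pol_axis_deg = 0)
  # full image: mean of all valid pixels
  rfull <- region_npp(m, region_full())
  expect_equal(rfull$npp, mean(1:25))
  expect_equal(rfull$reduction_vs_full_pct, 0)
  expect_equal(rfull$pixel_count, 25L)
  # 3x1 vertical rectangle through the centre: pixels (3,2),(3,3),(3,4)
  rr <- region_npp(m, region_rect(3, 1, angle_deg = 90))
  expect_equal(rr$pixel_count, 3L)
  expect_equal(rr$npp, mean(c(totals[3, 2], totals[3, 3], totals[3, 4])))
  expect_equal(rr$reduction_vs_full_pct, 100 * (1 - rr$npp / mean(1:25)))
  # disc of diameter 2: centre pixel plus 4 orthogonal neighbours
  rd <- region_npp(m, region_disc(2))
  expect_equal(rd$pixel_count, 5L)
  expect_equal(rd$npp,
               mean(c(totals[3, 3], totals[2, 3], totals[4, 3],
                      totals[3, 2], totals[3, 4])))
  # empty region errors
  expect_error(region_npp(m, region_disc(0.5, center_mm = c(40, 40))), "valid")
})

test_that("Npp is a pure ratio statistic and nests monotonically", {
  set.seed(21)
  totals <- matrix(rpois(31 * 31, 40), 31, 31)
  counts <- matrix(rpois(31 * 31, 12) + 5, 31, 31)
  m1 <- scatter_count_map(totals, photon_counts = counts, pixel_mm = 0.4)
  m2 <- scatter_count_map(totals * 3, photon_counts = counts * 3, pixel_mm = 0.4)
  r1 <- region_npp(m1, region_disc(4)); r2 <- region_npp(m2, region_disc(4))
  expect_equal(r1$npp, r2$npp, tolerance = 1e-12)
  expect_equal(r1$reduction_vs_full_pct, r2$reduction_vs_full_pct,
               tolerance = 1e-12)
  # radially non-decreasing N: disc Npp non-decreasing in diameter
  xs <- (seq_len(31) - 16) * 0.4
  rad <- sqrt(outer(xs^2, xs^2, `+`))
  mr <- scatter_count_map(rad * 10, photon_counts = matrix(10, 31, 31),
                          pixel_mm = 0.4)
  npps <- vapply(c(2, 4, 6, 8, 10),
                 function(d) region_npp(mr, region_disc(d))$npp, 0)
  expect_true(all(diff(npps) >= 0))
})

test_that("rectangle orientation sweep finds a low-N ridge", {
  # uniform map: every orientation gives the same Npp, zero reduction
  mu <- scatter_count_map(matrix(2, 41, 41), photon_counts = matrix(1, 41, 41),
                          min_photons = 1, pixel_mm = 0.5, pol_axis_deg = 0)
  sweep_u <- compare_rectangle_orientations(mu, c(0, 45, 90, 135),
                                            length_mm = 12, width_mm = 2)
  expect_true(all(abs(sweep_u$reduction_vs_full_pct) < 1e-12))
  # low-N ridge along the image vertical (90 deg from a 0-deg pol axis)
  xs <- (seq_len(41) - 21) * 0.5
  ridge <- 10 - 8 * exp(-outer(xs^2, 0 * xs^2, `+`) / 2)
  mrid <- scatter_count_map(ridge, photon_counts = matrix(1, 41, 41),
                            min_photons = 1, pixel_mm = 0.5, pol_axis_deg = 0)
  sw <- compare_rectangle_orientations(mrid, c(0, 45, 90, 135),
                                       length_mm = 18, width_mm = 1.5)
  expect_equal(sw$angle_deg[which.min(sw$npp)], 90)
})

test_that("lobe profile recovers a constructed four-lobed harmonic", {
  n <- 101
  xs <- seq_len(n) - 51
  X <- matrix(rep(xs, n), n); Y <- t(X)
  phi <- atan2(Y, X)
  img <- 1 + cos(4 * phi)
  lp <- lobe_profile(img, r_inner_mm = 10, r_outer_mm = 45, n_bins = 72,
                     pixel_mm = 1, pol_axis_deg = 0)
  pk <- lobe_peaks(lp)
  expect_equal(nrow(pk), 4)
  circ_dist <- function(a, b) pmin(abs(a - b), 360 - abs(a - b))
  for (want in c(0, 90, 180, 270)) {
    expect_lte(min(circ_dist(pk$phi_deg, want)), 5)
  }
  # angles are reported relative to the polarization axis
  lp45 <- lobe_profile(img, r_inner_mm = 10, r_outer_mm = 45, n_bins = 72,
                       pixel_mm = 1, pol_axis_deg = -45)
  pk45 <- lobe_peaks(lp45)
  for (want in c(45, 135, 225, 315)) {
    expect_lte(min(circ_dist(pk45$phi_deg, want)), 5)
  }
  expect_error(lobe_profile(img, 500, 600, pixel_mm = 1), "Annulus")
})
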