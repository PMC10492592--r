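test_that("launched packets start in the pure incident state on the beam disc", {
  expect_equal(launch_packet(beam_spec(3, "circular_right"))$stokes,
               stokes_circular_right(), ignore_attr = TRUE)
  expect_equal(launch_packet(beam_spec(3, "linear_minus45"))$stokes,
               stokes_linear_minus45(), ignore_attr = TRUE)
  set.seed(5)
  beam <- beam_spec(3)
  r <- replicate(4e4, {
    p <- launch_packet(beam)$pos
    sqrt(p[1]^2 + p[2]^2)
  })
  expect_true(all(r <= 0.15 + 1e-12))  # radius 1.5 mm = 0.15 cm
  # uniform over the disc: equal-area annular bins, chi-square GOF
  edges <- 0.15 * sqrt(seq(0, 1, length.out = 11))
  counts <- hist(r, breaks = edges, plot = FALSE)$counts
  chi <- sum((counts - length(r) / 10)^2 / (length(r) / 10))
  expect_gt(pchisq(chi, df = 9, lower.tail = FALSE), 0.01)
})

test_that("free paths are exponential with mean 1/mu_s and respect boundaries", {
  med <- medium_spec(polystyrene_params(), 25)
  # xi -> 1 limit: zero step
  pk <- launch_packet(beam_spec())
  expect_equal(propagate_step(pk, med, xi = 1)$pathlength_cm, 0)
  # mean sampled step within 3 standard errors of 1/25 cm
  set.seed(8)
  n <- 3e4
  steps <- replicate(n, propagate_step(launch_packet(beam_spec()), med)$pathlength_cm)
  steps <- steps[steps < 2.2]  # drop the few boundary-truncated paths
  expect_lt(abs(mean(steps) - 0.04), 3 * 0.04 / sqrt(length(steps)))
  # a packet at the boundary moving outward exits without scattering
  pk <- launch_packet(beam_spec())
  pk$v <- c(0, 0, -1)  # at z = 0 heading out
  out <- propagate_step(pk, med, xi = 0.5)
  expect_false(out$alive)
  expect_identical(out$exited, "top")
  expect_equal(out$n_scatter, 0L)
})

test_that("frame rotation round-trips and backscatter flips helicity", {
  tab <- poly_table()
  pk <- launch_packet(beam_spec(3, "linear_minus45"))
  pk$stokes <- c(1, 0.3, -0.5, 0.2)
  rt <- polarpath:::rotate_packet_frame(
    polarpath:::rotate_packet_frame(pk, 1.1), -1.1)
  expect_equal(rt$stokes, pk$stokes, tolerance = 1e-12)
  expect_equal(rt$e1, pk$e1, tolerance = 1e-12)
  # single 180-degree event reverses circular helicity
  pc <- launch_packet(beam_spec(3, "circular_right"))
  out <- scatter_event(pc, tab, theta = pi, phi = 0.7)
  expect_equal(out$stokes[4], -1, tolerance = 1e-9)
  expect_equal(out$v, c(0, 0, -1), tolerance = 1e-12)
  expect_equal(out$n_scatter, 1L)
})

test_that("sampled scattering angles follow the M11 sin(theta) marginal when unpolarized", {
  tab <- poly_table()
  pk <- launch_packet(beam_spec())
  pk$stokes <- c(1, 0, 0, 0)
  set.seed(12)
  n <- 2e4
  th <- vapply(seq_len(n), function(i) {
    polarpath:::sample_scatter_angles(tab, pk$stokes)$theta * 180 / pi
  }, 0)
  edges <- seq(0, 180, by = 7.5)  # aligned with the 0.25-degree grid
  obs <- hist(th, breaks = edges, plot = FALSE)$counts
  w <- tab$m11 * sin(tab$theta_deg * pi / 180)
  expw <- vapply(seq_len(length(edges) - 1), function(i) {
    sel <- which(tab$theta_deg >= edges[i] & tab$theta_deg <= edges[i + 1])
    sum(w[sel]) - 0.5 * (w[sel[1]] + w[sel[length(sel)]])
  }, 0)
  keep <- expw / sum(expw) * n >= 5
  expc <- expw[keep] / sum(expw[keep]) * sum(obs[keep])
  chi <- sum((obs[keep] - expc)^2 / expc)
  expect_gt(pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE), 0.01)
})

test_that("detection sorts orthogonalized backscatter into the co-linear channel", {
  tab <- poly_table()
  for (phi in c(0, 0.4, 1.3, 2.9)) {
    pk <- launch_packet(beam_spec(3, "linear_minus45"))
    pk <- scatter_event(pk, tab, theta = pi, phi = phi)
    pk$exited <- "top"; pk$alive <- FALSE
    g <- detect_packet(pk, detector_grid(11, 11, 20, 60), "linear_minus45")
    expect_equal(sum(g$co_linear), 1, tolerance = 1e-9)
    expect_equal(sum(g$cross_linear), 0, tolerance = 1e-9)
    # analyzer pair completeness and N bookkeeping at the exit pixel
    expect_equal(sum(g$co_linear + g$cross_linear), unname(pk$stokes[1]),
                 tolerance = 1e-12)
    expect_equal(sum(g$nscat_sum), unname(pk$stokes[1] * pk$n_scatter),
                 tolerance = 1e-12)
  }
})

test_that("simulation is deterministic and conserves analyzer-pair energy", {
  med <- medium_spec(polystyrene_params(), 25)
  beam <- beam_spec(3, "linear_minus45")
  s1 <- run_simulation(med, beam, n_packets = 2e4, seed = 9, nx = 31, ny = 31)
  s2 <- run_simulation(med, beam, n_packets = 2e4, seed = 9, nx = 31, ny = 31)
  expect_identical(s1$images, s2$images)
  s3 <- run_simulation(med, beam, n_packets = 2e4, seed = 10, nx = 31, ny = 31)
  expect_false(identical(s1$images, s3$images))
  # per-pixel energy split, both analyzer families
  tot <- s1$images$counts
  for (pair in list(c("co_linear", "cross_linear"),
                    c("co_circular", "cross_circular"))) {
    ss <- s1$images[[pair[1]]] + s1$images[[pair[2]]]
    expect_lt(max(abs(ss - tot) / pmax(tot, 1e-12)), 1e-9)
  }
  expect_true(all(vapply(s1$images, function(m) all(m >= 0), TRUE)))
  expect_lte(s1$meta$n_detected, 2e4)
})

test_that("a near-transparent medium backscatters almost nothing", {
  med <- medium_spec(polystyrene_params(), mus_per_cm = 0.01)
  sim <- run_simulation(med, beam_spec(), n_packets = 1e5, seed = 3,
                        nx = 21, ny = 21)
  expect_lt(sim$meta$n_detected / 1e5, 0.01)
})

test_that("dilute-medium detected singles follow the single-scattering prediction", {
  p <- polystyrene_params()
  med <- medium_spec(p, mus_per_cm = 2.5, box_cm = c(2.2, 2.2, 0.02))
  sim <- run_simulation(med, beam_spec(3, "linear_minus45"), n_packets = 5e6,
                        seed = 5, acceptance_deg = 75, n_record = 2e5,
                        field_mm = 40, nx = 21, ny = 21)
  e <- sim$exits[sim$exits$n_scatter == 1, ]
  expect_gt(nrow(e), 1500)
  theta <- acos(pmax(-1, pmin(1, e$vz))) * 180 / pi
  tab <- poly_table()
  w <- single_scatter_weights(tab, mus = 2.5, L = 0.02)
  edges <- seq(108, 180, by = 4)
  obs <- hist(theta[theta >= 108], breaks = edges, plot = FALSE)$counts
  expw <- bin_masses(tab, w, edges)
  expc <- expw / sum(expw) * sum(obs)
  chi <- sum((obs - expc)^2 / expc)
  expect_gt(pchisq(chi, df = length(obs) - 1, lower.tail = FALSE), 0.01)
})
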