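test_that("sum_intensity is a pixel-centre region sum", {
  expect_equal(sum_intensity(matrix(0, 8, 8), region_full()), 0)
  expect_equal(sum_intensity(matrix(2.5, 8, 8), region_full()), 2.5 * 64)
  # disc sum vs explicit enumeration
  set.seed(2)
  img <- matrix(runif(64), 8, 8)
  pmm <- 0.5
  want <- 0
  for (i in 1:8) for (j in 1:8) {
    x <- (i - 4.5) * pmm; y <- (j - 4.5) * pmm
    if (x^2 + y^2 <= 1.5^2) want <- want + img[i, j]
  }
  expect_equal(sum_intensity(img, region_disc(3), pixel_mm = pmm), want)
  expect_error(sum_intensity(img, region_disc(0.1, center_mm = c(9, 9)),
                             pixel_mm = pmm), "no pixels")
})

test_that("t-score implements the pooled-deviation formula exactly", {
  ts <- t_score(c(2, 4), c(1, 3))
  expect_equal(ts$s, sd(c(2, 4, 1, 3)))
  expect_equal(ts$t, 1 / (sd(c(2, 4, 1, 3)) * sqrt(1 / 2 + 1 / 2)))
  # identical groups score zero; swapping negates
  expect_equal(t_score(c(1, 5), c(1, 5))$t, 0)
  set.seed(33)
  for (i in 1:1000) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    x1 <- rnorm(n1, sd = runif(1, 0.5, 3))
    x2 <- rnorm(n2, mean = runif(1, -2, 2))
    t12 <- t_score(x1, x2)$t
    expect_equal(t12, oracle_t(x1, x2), tolerance = 1e-12)
    expect_equal(t_score(x2, x1)$t, -t12, tolerance = 1e-12)
  }
  # degenerate spread: zero score (with a warning) or a clear error
  expect_warning(t0 <- t_score(c(3, 3), c(3, 3)), "identical")
  expect_equal(t0$t, 0)
  expect_error(t_score(c(3, 3), c(4, 4), s_method = "classical"), "undefined")
  expect_error(t_score(1, c(1, 2)), "at least 2")
  # classical pooled-variance variant matches t.test
  set.seed(7)
  x1 <- rnorm(9); x2 <- rnorm(7, 0.8)
  tt <- stats::t.test(x1, x2, var.equal = TRUE)
  expect_equal(t_score(x1, x2, s_method = "classical")$t,
               unname(tt$statistic), tolerance = 1e-12)
})

test_that("synthetic generator is deterministic with a clean null", {
  cfg <- synthetic_tooth_config(seed = 11)
  s1 <- generate_synthetic_tooth_set(cfg)
  s2 <- generate_synthetic_tooth_set(cfg)
  expect_identical(s1$image, s2$image)
  expect_equal(nrow(s1), 7 * 2 * 2 * 2)  # 28 spots x 2 channels
  expect_true(all(vapply(s1$image, function(m) all(m >= 0), TRUE)))
  # no effect, no randomness: the two classes are identical images
  cfg0 <- synthetic_tooth_config(
    reduction = c(co_linear = 1, cross_circular = 1),
    heterogeneity_sdlog = 0, channel_sdlog = 0, noise_sd = 0, seed = 1)
  s0 <- generate_synthetic_tooth_set(cfg0)
  co_n <- s0$image[s0$side == "normal" & s0$channel == "co_linear"]
  co_a <- s0$image[s0$side == "acidified" & s0$channel == "co_linear"]
  expect_identical(co_n[[1]], co_a[[1]])
  expect_error(synthetic_tooth_config(reduction = c(co_linear = 0,
                                                    cross_circular = 0.5)),
               "reduction")
  expect_error(synthetic_tooth_config(noise_sd = -1), "Noise")
})

test_that("metric battery reproduces the interior-over-full ordering", {
  # uniform identical images on both sides: every metric scores zero
  base <- generate_synthetic_tooth_set(synthetic_tooth_config(seed = 2))
  flat <- base
  flat$image <- lapply(flat$image, function(m) matrix(1, nrow(m), ncol(m)))
  suppressWarnings(b0 <- roi_metric_battery(flat))
  expect_true(all(b0$t == 0))
  expect_equal(b0$metric,
               c("co_linear_full", "co_linear_interior_perp",
                 "cross_circular_full", "cross_circular_interior",
                 "pooled_interior"))
  # interior-concentrated effect: interior metrics beat full-image metrics
  tmat <- t(vapply(1:12, function(sd) {
    b <- roi_metric_battery(generate_synthetic_tooth_set(
      synthetic_tooth_config(seed = 500 + sd)))
    setNames(b$t, b$metric)
  }, setNames(numeric(5), b0$metric)))
  expect_gt(mean(tmat[, "co_linear_interior_perp"]),
            mean(tmat[, "co_linear_full"]))
  expect_gt(mean(tmat[, "cross_circular_interior"]),
            mean(tmat[, "cross_circular_full"]))
  expect_true(all(colMeans(tmat) > 0))
  # pooled metric doubles the sample size (n = 28 per group)
  b <- roi_metric_battery(generate_synthetic_tooth_set(
    synthetic_tooth_config(seed = 3)))
  expect_equal(b$n1[b$metric == "pooled_interior"], 28)
  # pooling duplicated identical points can only strengthen the score
  x1 <- rnorm(14, 1); x2 <- rnorm(14)
  expect_gte(abs(t_score(rep(x1, 2), rep(x2, 2))$t), abs(t_score(x1, x2)$t))
  expect_error(roi_metric_battery(base[base$channel == "co_linear", ]),
               "cross_circular")
})

test_that("mean t-score grows as the demineralization effect deepens", {
  mean_t <- function(f) {
    mean(vapply(1:12, function(sd) {
      set <- generate_synthetic_tooth_set(synthetic_tooth_config(
        reduction = c(co_linear = f, cross_circular = f), seed = 700 + sd))
      co <- set[set$channel == "co_linear", ]
      s <- vapply(co$image, sum, 0)
      t_score(s[co$side == "normal"], s[co$side == "acidified"])$t
    }, 0))
  }
  ts <- vapply(c(0.5, 0.7, 0.9, 1.0), mean_t, 0)
  expect_true(all(diff(ts) < 0))
})

test_that("polarimetric map pairs spots and summarizes separability", {
  set <- generate_synthetic_tooth_set(synthetic_tooth_config(seed = 41))
  pm <- polarimetric_map(roi_metric_battery(set))
  expect_equal(nrow(pm), 28)  # one point per measured spot
  expect_true(all(c("co_linear", "cross_circular") %in% names(pm)))
  # constructed well-separated classes: perfect threshold separability
  sums <- tibble::tibble(
    metric = rep(c("co_linear_interior_perp", "cross_circular_interior"),
                 each = 8),
    sample_id = rep(rep(1:4, each = 2), 2),
    side = rep(rep(c("normal", "acidified"), 4), 2),
    spot = 1L,
    sum_intensity = rep(c(10, 1), 8) + rnorm(16, 0, 0.01))
  pm2 <- polarimetric_map(sums)
  expect_equal(glance(pm2)$accuracy, 1)
  # unpaired spots are an error
  expect_error(polarimetric_map(sums[-1, ]), "Unpaired")
  # null generator: separability hovers near chance
  acc0 <- vapply(1:12, function(sd) {
    s0 <- generate_synthetic_tooth_set(synthetic_tooth_config(
      reduction = c(co_linear = 1, cross_circular = 1), seed = 800 + sd))
    glance(polarimetric_map(roi_metric_battery(s0)))$accuracy
  }, 0)
  expect_lt(mean(acc0), 0.75)
})
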