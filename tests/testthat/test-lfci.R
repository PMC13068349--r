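test_that("knn_neighborhood matches a brute-force oracle", {
  x <- withr::with_seed(5, matrix(rnorm(200 * 4), 200, 4))
  for (ci in c(1, 57, 200)) {
    nb <- knn_neighborhood(x, ci, k = 10)
    d <- sqrt(colSums((t(x) - x[ci, ])^2))
    d[ci] <- Inf
    oracle <- order(d, seq_len(200))[1:10]
    expect_equal(nb$member_indices, oracle)
    expect_equal(nb$points, x[oracle, , drop = FALSE])
  }
  expect_error(knn_neighborhood(x, 1, k = 200), "P-1")
  expect_error(knn_neighborhood(x, 0, k = 10), "center")
})

test_that("delta has the equilateral-triangle closed form", {
  # side-1 equilateral triangle: centroid-vertex distance 1/sqrt(3),
  # every nearest-neighbor distance 1
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(delta(tri), 1 / sqrt(3), tolerance = 1e-12)
})

test_that("delta flags curvature on a full sphere but not on flat patches", {
  sph <- uniform_hypersphere(d_sphere = 2, p = 2000, seed = 6)
  expect_gt(delta(sph$points), 2)       # center of mass far off the surface
  flat <- uniform_hyperplane(d = 2, n_ambient = 3, p = 2000, seed = 6)
  expect_lt(delta(flat$points), 2)
})

test_that("delta subsampled denominator stays close to the exact value", {
  x <- uniform_hypercube(d = 3, p = 1500, seed = 10)$points
  expect_equal(delta(x, max_exact = 300), delta(x, max_exact = 2000),
               tolerance = 0.05)
})

test_that("default_k_grid is ascending, bounded and log-spaced", {
  g <- default_k_grid(10000)
  expect_equal(length(g), 12)
  expect_equal(g[1], 50)
  expect_equal(g[12], 9999)
  expect_true(all(diff(g) > 0))
  expect_equal(default_k_grid(400)[length(default_k_grid(400))], 399)
})

test_that("multiscale_estimates is deterministic and well-formed", {
  x <- uniform_hyperplane(d = 2, n_ambient = 3, p = 1200, seed = 1)$points
  a <- multiscale_estimates(x, k_grid = c(50, 150, 400), m = 8, seed = 3)
  b <- multiscale_estimates(x, k_grid = c(50, 150, 400), m = 8, seed = 3)
  expect_identical(a, b)
  expect_equal(nrow(a), 24)
  expect_setequal(unique(a$k), c(50, 150, 400))
  expect_true(all(is.finite(a$d_local)))
  expect_true(all(a$delta >= 0))
})

test_that("gof_threshold rules behave and ignore curvature-dominated scales", {
  est <- data.frame(
    center_index = rep(1:50, 2),
    k = rep(c(100, 5000), each = 50),
    d_local = 2,
    delta = rep(c(1, 10), each = 50),           # K=5000 entirely curved
    gof = c(seq(0.004, 0.008, length.out = 50), # honest local fits
            seq(0.0001, 0.0005, length.out = 50)), # spuriously good global fits
    reliable = NA)
  g <- gof_threshold(est)
  expect_gt(g, 0.004)    # must come from the delta-credible scale
  expect_equal(g, quantile(est$gof[est$k == 100], 0.99, names = FALSE))
  expect_equal(gof_threshold(est, "lowest_median"), g)
})

test_that("filter_reliable is monotone in gamma and errors when empty", {
  x <- uniform_hyperplane(d = 2, n_ambient = 3, p = 1500, seed = 2)$points
  est <- multiscale_estimates(x, k_grid = c(60, 200), m = 10, seed = 2)
  g <- gof_threshold(est)
  k1 <- filter_reliable(est, g)
  k2 <- filter_reliable(est, g / 2)
  expect_lte(nrow(k2), nrow(k1))
  expect_true(all(k1$gof <= g), all(k1$delta <= 2))
  expect_error(filter_reliable(est, 0), "no reliable")
})

test_that("id_histogram_report finds the mode and percentile band", {
  d <- c(rep(2, 60), rep(3, 25), rep(5, 5))
  rel <- data.frame(center_index = seq_along(d), k = 100, d_local = d,
                    delta = 1, gof = 0.001, reliable = TRUE)
  rep <- id_histogram_report(rel, gamma = 0.01)
  expect_s3_class(rep, "id_report")
  expect_equal(rep$d_star, 2, tolerance = 0.05)
  expect_equal(rep$n_reliable, 90)
  expect_lt(rep$p10, rep$p90)
  expect_warning(
    id_histogram_report(rel[1:5, ], gamma = 0.01), "low-confidence")
})

test_that("histogram mode is robust to a heavy tail of outlying estimates", {
  # a dominant peak near 2 plus a minority of huge noise-floor fits must not
  # widen the bins and wash out the mode
  d <- c(withr::with_seed(3, rnorm(300, 2.1, 0.05)),
         withr::with_seed(4, runif(60, 5, 250)))
  rel <- data.frame(center_index = seq_along(d), k = 50, d_local = d,
                    delta = 1, gof = 0.001, reliable = TRUE)
  rep <- id_histogram_report(rel, gamma = 0.01)
  expect_equal(rep$d_star, 2.1, tolerance = 0.08)
})

test_that("lfci end-to-end: deterministic, correct on a small plane", {
  x <- uniform_hyperplane(d = 2, n_ambient = 3, p = 2000, seed = 4)$points
  r1 <- lfci(x, k_grid = c(50, 120, 300, 700), m = 25, seed = 4)
  r2 <- lfci(x, k_grid = c(50, 120, 300, 700), m = 25, seed = 4)
  expect_equal(r1[setdiff(names(r1), "estimates")],
               r2[setdiff(names(r2), "estimates")])
  expect_equal(r1$d_star, 2, tolerance = 0.15)
  expect_false(r1$global_fallback)
  expect_s3_class(r1, "id_report")
})

test_that("lfci falls back to the global fit when all scales are curved", {
  # analyzing a sphere only at K ~ P gives delta > 2 everywhere
  sph <- uniform_hypersphere(d_sphere = 2, p = 600, seed = 12)
  rep <- lfci(sph$points, k_grid = c(580, 599), m = 15, seed = 12)
  expect_true(rep$global_fallback)
  expect_equal(rep$n_reliable, 0L)
  expect_true(is.finite(rep$d_star))
})
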