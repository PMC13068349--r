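test_that("participation ratio matches closed forms", {
  # cross design in 3-D: sample covariance exactly diag(2a^2, 2b^2, 2c^2)/(n-1)
  pts <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, sqrt(2), 0), c(0, -sqrt(2), 0),
               c(0, 0, sqrt(2)), c(0, 0, -sqrt(2)))
  # eigenvalue proportions (2, 1, 1) -> PR = (2+1+1)^2 / (4+1+1) = 8/3
  expect_equal(participation_ratio(pts), 8 / 3, tolerance = 1e-12)
  # rank-1 data -> PR = 1
  line <- matrix(seq(-1, 1, length.out = 50), ncol = 1) %*% t(c(1, 2, 3))
  expect_equal(participation_ratio(line), 1, tolerance = 1e-10)
  # isotropic spectrum -> PR = N (exactly, using an orthogonal design)
  iso <- rbind(diag(3), -diag(3))
  expect_equal(participation_ratio(iso), 3, tolerance = 1e-12)
})

test_that("pca_id counts components to the variance threshold", {
  pts <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, sqrt(2), 0), c(0, -sqrt(2), 0),
               c(0, 0, sqrt(2)), c(0, 0, -sqrt(2)))
  # spectrum proportions (1/2, 1/4, 1/4)
  expect_equal(pca_id(pts, alpha = 0.5), 1L)
  expect_equal(pca_id(pts, alpha = 0.74), 2L)
  expect_equal(pca_id(pts, alpha = 0.76), 3L)
})

test_that("parallel analysis finds planted linear dimensions", {
  x <- withr::with_seed(31, {
    latent <- matrix(rnorm(800 * 3), 800, 3) %*% diag(c(5, 4, 3))
    rot <- qr.Q(qr(matrix(rnorm(20 * 20), 20, 20)))[, 1:3]
    latent %*% t(rot) + 0.2 * matrix(rnorm(800 * 20), 800, 20)
  })
  expect_equal(parallel_analysis(x, n_shuffles = 30, seed = 1), 3L)
  # pure noise: no component should beat its own shuffle null decisively
  noise <- withr::with_seed(32, matrix(rnorm(500 * 10), 500, 10))
  expect_lte(parallel_analysis(noise, n_shuffles = 30, seed = 1), 2L)
})

test_that("corrdim recovers low dimensions on dense flat data", {
  x <- uniform_hypercube(d = 2, p = 4000, seed = 13)$points
  expect_equal(corrdim(x), 2, tolerance = 0.2)
})

test_that("mle_id matches the hand-computed Levina-Bickel example", {
  # collinear points at 0, 1, 2, 4; K = 3
  pts <- matrix(c(0, 1, 2, 4), ncol = 1)
  inv <- c(
    (log(4 / 1) + log(4 / 2)) / 2,   # point 0: dists 1, 2, 4
    (log(3 / 1) + log(3 / 1)) / 2,   # point 1: dists 1, 1, 3
    (log(2 / 1) + log(2 / 2)) / 2,   # point 2: dists 1, 2, 2
    (log(4 / 2) + log(4 / 3)) / 2    # point 4: dists 2, 3, 4
  )
  expect_equal(mle_id(pts, k = 3), 1 / mean(inv), tolerance = 1e-12)
  # and sane behavior on real flat data
  cube <- uniform_hypercube(d = 3, p = 3000, seed = 14)$points
  expect_equal(mle_id(cube, k = 20), 3, tolerance = 0.25)
})

test_that("twonn estimates the dimension of uniform flat samples", {
  x2 <- uniform_hypercube(d = 2, p = 4000, seed = 15)$points
  expect_equal(twonn(x2), 2, tolerance = 0.25)
  x5 <- uniform_hypercube(d = 5, p = 4000, seed = 16)$points
  expect_equal(twonn(x5), 5, tolerance = 0.6)
  expect_error(twonn(x2[1:50, ]), "at least 100")
})

test_that("twonn matches the Pareto-ratio oracle it is built on", {
  # with ratios mu following an exact Pareto(d) law, the regression slope
  # must recover d; feed synthetic ratios through the same formula
  d_true <- 3
  mu <- withr::with_seed(17, (1 - runif(5000))^(-1 / d_true))
  n <- length(mu); mu <- sort(mu)
  keep <- seq_len(floor(n * 0.9))
  xx <- log(mu[keep]); yy <- -log(1 - keep / n)
  ok <- xx > 0
  slope <- sum(xx[ok] * yy[ok]) / sum(xx[ok]^2)
  expect_equal(slope, d_true, tolerance = 0.1)
})

test_that("twonn_decimated returns a plateau estimate and curve", {
  x <- uniform_hypercube(d = 2, p = 3000, seed = 18)$points
  res <- twonn_decimated(x, fractions = c(1, 0.5, 0.25), n_rep = 2, seed = 1)
  expect_named(res, c("estimate", "curve"))
  expect_equal(nrow(res$curve), 3)
  expect_equal(res$estimate, 2, tolerance = 0.3)
})

test_that("cvpca_project isolates the stimulus-related subspace", {
  sim <- repeated_stimulus_responses(d_signal = 3, n_stim = 200,
                                     n_neurons = 40, noise_sd = 0.5, seed = 19)
  proj <- cvpca_project(sim$rep1, sim$rep2, variance_fraction = 0.95)
  expect_equal(attr(proj, "n_dims"), 3L)
  expect_equal(ncol(proj), 3)
  expect_equal(nrow(proj), 200)
  # pure noise repetitions: cross-repetition variance collapses towards zero
  a <- withr::with_seed(20, matrix(rnorm(100 * 30), 100, 30))
  b <- withr::with_seed(21, matrix(rnorm(100 * 30), 100, 30))
  cross_noise <- attr(cvpca_project(a, b), "cross_variance")
  cross_signal <- attr(proj, "cross_variance")
  expect_lt(max(cross_noise), 0.05 * max(cross_signal))
})
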