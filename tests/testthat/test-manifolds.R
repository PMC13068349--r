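test_that("generators are bit-reproducible and carry metadata", {
  a <- uniform_hyperplane(d = 2, n_ambient = 5, p = 300, seed = 7)
  b <- uniform_hyperplane(d = 2, n_ambient = 5, p = 300, seed = 7)
  expect_identical(a, b)
  expect_s3_class(a, "manifold_sample")
  expect_equal(dim(a$points), c(300, 5))
  expect_equal(a$true_id, 2)
  expect_equal(a$generator_name, "plane")
  c <- uniform_hyperplane(d = 2, n_ambient = 5, p = 300, seed = 8)
  expect_false(identical(a$points, c$points))
})

test_that("uniform_hyperplane embeds isometrically", {
  s <- uniform_hyperplane(d = 3, n_ambient = 10, p = 200, seed = 2)
  # rotations preserve pairwise distances; with a unit-cube patch the
  # largest pairwise distance cannot exceed sqrt(3)
  expect_lte(max(dist(s$points)), sqrt(3) + 1e-10)
  # rank of the centered cloud equals the intrinsic dimension
  sv <- svd(scale(s$points, scale = FALSE))$d
  expect_equal(sum(sv > 1e-8), 3)
})

test_that("swiss_roll points lie exactly on the roll surface", {
  s <- swiss_roll(p = 500, seed = 3)
  t_par <- s$params$t
  expect_equal(sqrt(s$points[, 1]^2 + s$points[, 3]^2), t_par,
               tolerance = 1e-10)
  expect_true(all(t_par >= 1.5 * pi & t_par <= 4.5 * pi))
  expect_true(all(s$points[, 2] >= 0 & s$points[, 2] <= 20))
  expect_equal(s$true_id, 2)
})

test_that("uniform_hypersphere has unit-norm rows and sphere ID", {
  s <- uniform_hypersphere(d_sphere = 4, p = 400, seed = 4)
  expect_equal(dim(s$points), c(400, 5))
  expect_equal(rowSums(s$points^2), rep(1, 400), tolerance = 1e-12)
  expect_equal(s$true_id, 4)
})

test_that("anisotropic_flat keeps support and reduces to uniform at alpha 0", {
  iso <- anisotropic_flat(d = 3, p = 500, alpha_aniso = 0, seed = 5)
  expect_true(all(abs(iso$points) <= 1))
  hard <- anisotropic_flat(d = 3, p = 500, alpha_aniso = 2, seed = 5)
  expect_true(all(abs(hard$points) <= 1))
  # alpha > 0 concentrates mass near the origin
  expect_lt(median(abs(hard$points)), median(abs(iso$points)))
})

test_that("latent_trajectories are standardized and smooth", {
  lat <- latent_trajectories(d = 4, p = 2000, seed = 6)
  expect_equal(dim(lat), c(2000, 4))
  expect_equal(apply(lat, 2, sd), rep(1, 4), tolerance = 1e-10)
  expect_equal(colMeans(lat), rep(0, 4), tolerance = 1e-10)
  # smoothing induces strong lag-1 autocorrelation; unsmoothed does not
  ac <- function(v) cor(v[-1], v[-length(v)])
  raw <- latent_trajectories(d = 1, p = 2000, seed = 6, smooth = FALSE)
  expect_gt(ac(lat[, 1]), 0.6)
  expect_lt(abs(ac(raw[, 1])), 0.1)
})

test_that("linear_embed preserves the latent rank", {
  lat <- latent_trajectories(d = 6, p = 800, seed = 7)
  emb <- linear_embed(lat, n_ambient = 96, seed = 8)
  expect_equal(dim(emb$points), c(800, 96))
  sv <- svd(scale(emb$points, scale = FALSE))$d
  expect_equal(sum(sv > 1e-6 * sv[1]), 6)
  expect_equal(emb$true_id, 6)
})

test_that("linear_embed normalizes the ambient variance", {
  lat <- latent_trajectories(d = 6, p = 1500, seed = 11,
                             rate_model = "gaussian")
  emb <- linear_embed(lat, n_ambient = 20, seed = 12)
  expect_equal(apply(emb$points, 2, sd), rep(1, 20), tolerance = 1e-10)
  # without normalization the ambient scale grows like sqrt(d)
  raw <- linear_embed(lat, n_ambient = 20, seed = 12,
                      normalize_variance = FALSE)
  expect_gt(median(apply(raw$points, 2, sd)), 1.5)
})

test_that("nonlinear_embed rescaling makes alpha scale-free", {
  x <- withr::with_seed(13, matrix(rnorm(400), 200, 2))
  y1 <- nonlinear_embed(x, alpha = 1)
  # an affine change of coordinates must not change the result
  y2 <- nonlinear_embed(3 * x + 7, alpha = 1)
  expect_equal(y1, y2, tolerance = 1e-12)
  expect_true(all(y1 >= 0 & y1 <= 1))
  # rescale = FALSE evaluates the raw formula
  expect_equal(nonlinear_embed(x, alpha = 1, rescale = FALSE),
               (exp(x) - 1) / (exp(1) - 1), tolerance = 1e-12)
})

test_that("nonlinear_embed has the exact endpoint identities", {
  x <- matrix(c(0, 0.5, 1), ncol = 1)
  y <- nonlinear_embed(x, alpha = 1)
  expect_equal(y[1, 1], 0)
  expect_equal(y[3, 1], 1)
  expect_equal(y[2, 1], (exp(0.5) - 1) / (exp(1) - 1))   # 0.37754...
  expect_equal(nonlinear_embed(x, alpha = 0), x)
  # monotone distortion, dimension-preserving on a manifold sample
  s <- uniform_hypercube(d = 2, p = 300, seed = 9)
  s2 <- nonlinear_embed(s, alpha = 1)
  expect_equal(s2$true_id, 2)
  expect_true(all(diff(sort(s2$points[, 1])) >= 0))
})

test_that("repeated_stimulus_responses shares signal across repetitions", {
  sim <- repeated_stimulus_responses(3, n_stim = 150, n_neurons = 25,
                                     noise_sd = 0.05, seed = 10)
  expect_equal(dim(sim$rep1), dim(sim$rep2))
  # repetitions correlate through the shared signal, noise is independent
  expect_gt(cor(as.numeric(sim$rep1), as.numeric(sim$rep2)), 0.9)
  expect_equal(qr(sim$signal)$rank, 3)
})
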