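test_that("tuning_curve matches the closed-form ring response", {
  dirs <- 2 * pi * (0:31) / 32
  # stimulus exactly at a preferred direction: peak 0.8 * gamma there
  u <- tuning_curve(dirs[9], gamma = 1)
  expect_equal(u[9], 0.8)
  expect_equal(which.max(u), 9L)
  # pi/8 offset: 0.8 * exp(-1/2)
  expect_equal(tuning_curve(pi / 8, 1)[1], 0.8 * exp(-0.5), tolerance = 1e-12)
  # linear in gamma
  expect_equal(tuning_curve(1.1, 3), 3 * tuning_curve(1.1, 1), tolerance = 1e-12)
  # symmetric around the stimulus; midway between two preferred directions
  u2 <- tuning_curve(dirs[5] + pi / 32, 1)
  expect_equal(u2[5], u2[6], tolerance = 1e-12)
  # multiple stimuli are summed
  expect_equal(tuning_curve(c(0, pi), c(1, 2)),
               tuning_curve(0, 1) + tuning_curve(pi, 2), tolerance = 1e-12)
  expect_error(tuning_curve(0, -1), ">= 0")
})

test_that("make_trial builds consistent trials for all 20 tasks", {
  cfg <- sim_config()
  for (task in cogtask_battery()) {
    tr <- make_trial(task, seed = 11, config = cfg)
    expect_s3_class(tr, "task_trial")
    expect_equal(ncol(tr$inputs), 65)
    expect_equal(ncol(tr$targets), 33)
    expect_equal(dim(tr$targets), dim(tr$mask))
    expect_equal(nrow(tr$inputs), nrow(tr$targets))
    expect_true(all(tr$targets >= 0 & tr$targets <= 1))
    expect_true(all(tr$mask %in% c(0, 1, 5)))
    expect_true(length(tr$meta$response_steps) > 0)
  }
  expect_error(make_trial("nosuchtask"), "arg")
  # seeded trials are bit-reproducible
  expect_identical(make_trial("dm1", seed = 3), make_trial("dm1", seed = 3))
})

test_that("go and anti trials point at the expected directions", {
  tr_go <- make_trial("fdgo", seed = 21)
  expect_equal(tr_go$meta$target_angle, tr_go$meta$psi[1])
  tr_anti <- make_trial("fdanti", seed = 21)
  expect_equal(tr_anti$meta$target_angle,
               (tr_anti$meta$psi[1] + pi) %% (2 * pi))
  # DM: target is the direction of the stronger stimulus
  tr_dm <- make_trial("dm1", seed = 22)
  expect_true(tr_dm$meta$respond)
  expect_equal(length(tr_dm$meta$gamma), 2)
})

test_that("simulate_rnn has the zero-weight fixed point log(2)", {
  cfg <- sim_config(n_rec = 16)
  p0 <- init_rnn_params(cfg, seed = 1)
  p0$W_in[] <- 0; p0$W_rec[] <- 0; p0$b[] <- 0
  out <- simulate_rnn(p0, matrix(0, 100, cfg$n_in), cfg, noise_on = FALSE)
  expect_equal(unname(out$rates[100, ]), rep(log(2), 16), tolerance = 1e-8)
  # outputs of zero readout weights sit at logistic(0) = 1/2
  expect_equal(unname(out$outputs[1, ]), rep(0.5, cfg$n_out))
})

test_that("simulate_rnn is deterministic and keeps rates non-negative", {
  cfg <- sim_config(n_rec = 32)
  p <- init_rnn_params(cfg, seed = 2)
  tr <- make_trial("rtgo", seed = 4, config = cfg)
  o1 <- simulate_rnn(p, tr, cfg, seed = 9)
  o2 <- simulate_rnn(p, tr, cfg, seed = 9)
  expect_identical(o1, o2)
  o3 <- simulate_rnn(p, tr, cfg, noise_on = FALSE)
  o4 <- simulate_rnn(p, tr, cfg, noise_on = FALSE)
  expect_identical(o3, o4)
  expect_true(all(o1$rates >= 0))   # softplus outputs blended from r0 = 0
  expect_equal(dim(o1$rates), c(nrow(tr$inputs), 32))
  expect_equal(dim(o1$outputs), c(nrow(tr$inputs), 33))
})

test_that("decode_response scores ideal and absent responses correctly", {
  tr <- make_trial("fdgo", seed = 5)
  # feed the targets themselves as outputs: must be correct
  ideal <- decode_response(tr$targets, tr)
  expect_true(ideal$responded)
  expect_true(ideal$correct)
  err <- abs(((ideal$angle - tr$meta$target_angle + pi) %% (2 * pi)) - pi)
  expect_lt(err, 0.12)
  # silent ring: no response
  silent <- tr$targets
  silent[, -1] <- 0.05
  expect_false(decode_response(silent, tr)$responded)
})

test_that("rnn_loss_grad matches finite-difference gradients", {
  cfg <- sim_config(n_rec = 6, n_in = 9, n_out = 5, sigma_rec = 0.03)
  # a miniature trial compatible with the 4-unit ring of this config
  T_len <- 12
  tr <- structure(list(
    inputs = matrix(withr::with_seed(1, rnorm(T_len * 9, 0, 0.3)), T_len, 9),
    targets = matrix(withr::with_seed(2, runif(T_len * 5)), T_len, 5),
    mask = matrix(1, T_len, 5),
    meta = list()), class = "task_trial")
  params <- init_rnn_params(cfg, seed = 3, g = 0.8)
  params$W_out <- matrix(withr::with_seed(4, rnorm(5 * 6, 0, 0.3)), 5, 6)
  lg <- withr::with_seed(7, lfci:::rnn_loss_grad(params, list(tr), cfg))
  eps <- 1e-6
  for (nm in c("W_rec", "W_in", "W_out", "b")) {
    idx <- if (nm == "b") 3 else cbind(2, 3)
    up <- params; up[[nm]][idx] <- up[[nm]][idx] + eps
    dn <- params; dn[[nm]][idx] <- dn[[nm]][idx] - eps
    # identical seed reproduces the same noise draws in all three passes
    lu <- withr::with_seed(7, lfci:::rnn_loss_grad(up, list(tr), cfg))$loss
    ld <- withr::with_seed(7, lfci:::rnn_loss_grad(dn, list(tr), cfg))$loss
    expect_equal(lg$grads[[nm]][idx], (lu - ld) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("untrained networks perform at chance, manifolds have trial shape", {
  cfg <- sim_config(n_rec = 32)
  p <- init_rnn_params(cfg, seed = 5)
  acc <- task_accuracy(p, "rtgo", n_trials = 24, seed = 6, config = cfg)
  expect_lt(acc, 0.6)
  mf <- collect_manifold(p, "rtgo", n_trials = 3, seed = 7, config = cfg)
  expect_equal(nrow(mf), 3 * attr(mf, "trial_length"))
  expect_equal(ncol(mf), 32)
  # the network starts silent: the first row of each trial is near zero
  expect_lt(max(abs(mf[1, ])), 0.2)
})
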