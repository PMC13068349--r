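#' Simulator configuration for cognitive-task rate networks
#'
#' Holds the sizes and physical constants of the rate-RNN simulator: a
#' recurrent layer of `n_rec` softplus units driven by a 65-dimensional input
#' (1 fixation cue + two 32-unit stimulus rings, one per modality) and read out
#' by 33 logistic units (1 fixation output + one 32-unit response ring). Time
#' is discretized with an Euler step `dt`; `alpha = dt / tau` is the resulting
#' leak factor.
#'
#' @param n_rec Recurrent units.
#' @param n_in Input channels; must equal `1 + 2 * ring_size`.
#' @param n_out Output channels; must equal `1 + ring_size`.
#' @param tau Neuronal time constant, ms.
#' @param dt Euler discretization step, ms; `dt <= tau`.
#' @param sigma_rec Recurrent noise scale (applied as `sqrt(2/alpha) *
#'   sigma_rec` per step).
#' @param sigma_in Input noise scale, same convention.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config()
#' cfg$alpha   # 0.2
#' @export
sim_config <- function(n_rec = 256, n_in = 65, n_out = 33,
                       tau = 100, dt = 20,
                       sigma_rec = 0.05, sigma_in = 0.01) {
  ring <- (n_in - 1) / 2
  if (ring != round(ring) || n_out != ring + 1)
    stop("ring sizes inconsistent: need n_in = 1 + 2*ring and n_out = 1 + ring")
  if (dt <= 0 || tau <= 0 || dt > tau) stop("need 0 < dt <= tau")
  structure(list(n_rec = as.integer(n_rec), n_in = as.integer(n_in),
                 n_out = as.integer(n_out), ring_size = as.integer(ring),
                 tau = tau, dt = dt, alpha = dt / tau,
                 sigma_rec = sigma_rec, sigma_in = sigma_in),
            class = "sim_config")
}

# Preferred directions of a stimulus/response ring: psi_i = pi/16 * (i - 1)
# for the default 32-unit ring, covering [0, 2*pi).
ring_directions <- function(ring_size = 32) {
  2 * pi * (seq_len(ring_size) - 1) / ring_size
}

# Minimal angular distance, wrapped to [0, pi].
ang_dist <- function(a, b) {
  d <- abs((a - b) %% (2 * pi))
  pmin(d, 2 * pi - d)
}

#' Ring tuning curve for an angular stimulus
#'
#' Activity of a 32-unit ring of input neurons with preferred directions
#' \eqn{\psi_i = \pi i / 16} responding to a stimulus at direction \eqn{\psi}
#' with intensity \eqn{\gamma}:
#' \deqn{u_i = 0.8\,\gamma\, \exp\!\left(-\tfrac12
#'   \left(\frac{8\,|\psi - \psi_i|}{\pi}\right)^2\right),}
#' with the angular distance wrapped to \eqn{[0, \pi]}. Activities of multiple
#' simultaneous stimuli are summed.
#'
#' @param psi Stimulus direction(s), radians.
#' @param gamma Stimulus intensity (or intensities), `>= 0`, recycled against
#'   `psi`.
#' @param ring_size Number of ring units.
#' @return Non-negative vector of length `ring_size`.
#' @examples
#' u <- tuning_curve(pi / 2, gamma = 1)
#' max(u)       # 0.8 at the preferred direction closest to pi/2
#' @export
tuning_curve <- function(psi, gamma = 1, ring_size = 32) {
  if (any(gamma < 0)) stop("`gamma` must be >= 0")
  k <- max(length(psi), length(gamma))
  psi <- rep_len(psi, k)
  gamma <- rep_len(gamma, k)
  dirs <- ring_directions(ring_size)
  u <- numeric(ring_size)
  for (s in seq_len(k))
    u <- u + gamma[s] * 0.8 * exp(-0.5 * (8 * ang_dist(psi[s], dirs) / pi)^2)
  u
}

#' The 20-task cognitive battery
#'
#' Task names understood by [make_trial()]: the Go family (`fdgo`, `rtgo`,
#' `dlygo` and their `anti` counterparts), the decision-making family (`dm1`,
#' `dm2`, `ctxdm1`, `ctxdm2`, `multidm` and their delayed versions `dlydm1`,
#' `dlydm2`, `ctxdlydm1`, `ctxdlydm2`, `multidlydm`), and the matching family
#' (`dms`, `dnms`, `dmc`, `dnmc`).
#'
#' @return Character vector of the 20 task names.
#' @export
cogtask_battery <- function() {
  c("fdgo", "rtgo", "dlygo", "fdanti", "rtanti", "dlyanti",
    "dm1", "dm2", "ctxdm1", "ctxdm2", "multidm",
    "dlydm1", "dlydm2", "ctxdlydm1", "ctxdlydm2", "multidlydm",
    "dms", "dnms", "dmc", "dnmc")
}

# Epoch durations in ms. Fixed per task family so trials of one task share a
# common length (simple minibatching); the exact values follow the cited
# battery's conventions only qualitatively and are configurable here.
cogtask_epochs <- function(task, dt) {
  ms <- switch(task,
    fdgo = , fdanti = c(fix = 300, stim = 500, resp = 500),
    rtgo = , rtanti = c(fix = 300, resp = 700),
    dlygo = , dlyanti = c(fix = 300, stim = 300, delay = 400, resp = 500),
    dm1 = , dm2 = , ctxdm1 = , ctxdm2 = , multidm =
      c(fix = 300, stim = 700, resp = 500),
    dlydm1 = , dlydm2 = , ctxdlydm1 = , ctxdlydm2 = , multidlydm =
      c(fix = 300, stim1 = 300, delay1 = 300, stim2 = 300, delay2 = 300,
        resp = 500),
    dms = , dnms = , dmc = , dnmc =
      c(fix = 300, sample = 300, delay = 500, resp = 500),
    stop("unknown task: ", task)
  )
  steps <- round(ms / dt)
  ends <- cumsum(steps)
  starts <- c(1, utils::head(ends, -1) + 1)
  out <- Map(seq, starts, ends)
  names(out) <- names(ms)
  out
}

# Draw a second direction uniformly between 90 and 270 degrees away from psi.
draw_apart <- function(psi) {
  (psi + stats::runif(1, pi / 2, 3 * pi / 2)) %% (2 * pi)
}

# Intensity pair for a decision between two stimuli: mean 1, seeded contrast.
draw_gammas <- function() {
  c_half <- stats::runif(1, 0.05, 0.25)
  if (stats::runif(1) < 0.5) c(1 + c_half, 1 - c_half) else c(1 - c_half, 1 + c_half)
}

#' Generate one cognitive-task trial
#'
#' Builds the input time series, target outputs and loss mask for one trial of
#' a task in [cogtask_battery()]. Inputs are a fixation cue channel plus two
#' 32-unit stimulus rings (modality 1 and 2); ring drive follows
#' [tuning_curve()], and Gaussian noise of standard deviation
#' `sqrt(2/alpha) * sigma_in` is added to every input channel and step.
#' Targets are a fixation output (high until the response epoch on trials
#' requiring a response, high throughout otherwise) and a response ring with a
#' tuning-shaped bump toward the correct direction during the response epoch.
#' The loss mask is 0 in a 100 ms grace period at the start of the response
#' epoch, 5 during the rest of the response epoch, and 1 elsewhere.
#'
#' Family conventions: Go-family trials present one stimulus and require a
#' response at its direction (`go`) or at the opposite direction (`anti`);
#' `fd` variants respond at fixation-cue offset, `rt` variants as soon as the
#' stimulus appears, `dly` variants after a memory delay. Decision-making
#' trials present two stimuli of unequal intensity (the second direction drawn
#' uniformly between 90 and 270 degrees away from the first) and require a
#' response toward the stronger; `ctx` variants show independent stimulus
#' pairs in both modalities and are resolved by the task-designated modality,
#' `multi` variants by the summed intensities; `dly` variants present the two
#' stimuli sequentially. Matching trials present a sample and, after a delay,
#' a test stimulus; the network responds toward the test stimulus on a match
#' (`dms`: same direction; `dmc`: same semicircle category) and maintains
#' fixation otherwise, with `dnms`/`dnmc` inverting the rule.
#'
#' @param task Task name, see [cogtask_battery()].
#' @param seed Integer seed, or `NULL` to draw from the current RNG state.
#' @param config A [sim_config()].
#' @return An object of class `task_trial`: list with `inputs` (T x 65),
#'   `targets` (T x 33), `mask` (T x 33) and `meta` (task, stimulus angles and
#'   intensities, `respond`, `target_angle`, epoch step indices,
#'   `response_steps`).
#' @export
make_trial <- function(task, seed = NULL, config = sim_config()) {
  task <- match.arg(task, cogtask_battery())
  if (!is.null(seed)) return(withr::with_seed(seed, make_trial(task, NULL, config)))
  ring <- config$ring_size
  epochs <- cogtask_epochs(task, config$dt)
  T_len <- max(unlist(epochs))
  u <- matrix(0, T_len, config$n_in)
  mod1 <- 1 + seq_len(ring)
  mod2 <- 1 + ring + seq_len(ring)

  psi <- stats::runif(1, 0, 2 * pi)
  gamma <- 1
  respond <- TRUE
  target_angle <- NA_real_
  family <- task

  if (task %in% c("fdgo", "rtgo", "dlygo", "fdanti", "rtanti", "dlyanti")) {
    anti <- grepl("anti", task)
    target_angle <- if (anti) (psi + pi) %% (2 * pi) else psi
    bump <- tuning_curve(psi, gamma, ring)
    if (task %in% c("fdgo", "fdanti")) {
      stim_steps <- c(epochs$stim, epochs$resp)     # stimulus stays on
      fix_on <- c(epochs$fix, epochs$stim)
    } else if (task %in% c("rtgo", "rtanti")) {
      stim_steps <- epochs$resp                      # onset is the go signal
      fix_on <- seq_len(T_len)                       # cue never turns off
    } else {
      stim_steps <- epochs$stim
      fix_on <- c(epochs$fix, epochs$stim, epochs$delay)
    }
    u[stim_steps, mod1] <- matrix(bump, length(stim_steps), ring, byrow = TRUE)
    u[fix_on, 1] <- 1
  } else if (task %in% c("dm1", "dm2", "ctxdm1", "ctxdm2", "multidm",
                         "dlydm1", "dlydm2", "ctxdlydm1", "ctxdlydm2",
                         "multidlydm")) {
    delayed <- grepl("dly", task)
    ctx <- grepl("ctxdm|ctxdly", task)
    multi <- grepl("multi", task)
    psi2 <- draw_apart(psi)
    g_a <- draw_gammas()                             # modality 1 (or only pair)
    g_b <- if (ctx || multi) draw_gammas() else NULL # modality 2 pair
    relevant <- if (multi) g_a + g_b
                else if (grepl("2", task)) { if (is.null(g_b)) g_a else g_b }
                else g_a
    target_angle <- if (relevant[1] >= relevant[2]) psi else psi2
    put <- function(steps, cols, angle, g)
      u[steps, cols] <<- u[steps, cols] +
        matrix(tuning_curve(angle, g, ring), length(steps), ring, byrow = TRUE)
    cols_primary <- if (task %in% c("dm2", "dlydm2")) mod2 else mod1
    if (!delayed) {
      put(epochs$stim, cols_primary, psi, g_a[1])
      put(epochs$stim, cols_primary, psi2, g_a[2])
      if (!is.null(g_b)) {
        put(epochs$stim, mod2, psi, g_b[1])
        put(epochs$stim, mod2, psi2, g_b[2])
      }
    } else {
      put(epochs$stim1, cols_primary, psi, g_a[1])
      put(epochs$stim2, cols_primary, psi2, g_a[2])
      if (!is.null(g_b)) {
        put(epochs$stim1, mod2, psi, g_b[1])
        put(epochs$stim2, mod2, psi2, g_b[2])
      }
    }
    fix_on <- setdiff(seq_len(T_len), epochs$resp)
    u[fix_on, 1] <- 1
    gamma <- g_a
  } else {                                           # matching family
    match_rule_cat <- task %in% c("dmc", "dnmc")
    invert <- task %in% c("dnms", "dnmc")
    is_match <- stats::runif(1) < 0.5
    if (!match_rule_cat) {
      psi_test <- if (is_match) psi else draw_apart(psi)
    } else {
      cat1 <- psi < pi
      same_cat <- if (is_match) cat1 else !cat1
      psi_test <- stats::runif(1, 0, pi) + if (same_cat) 0 else pi
    }
    respond <- xor(is_match, invert)
    target_angle <- if (respond) psi_test else NA_real_
    u[epochs$sample, mod1] <-
      matrix(tuning_curve(psi, 1, ring), length(epochs$sample), ring, byrow = TRUE)
    u[epochs$resp, mod1] <- u[epochs$resp, mod1] +
      matrix(tuning_curve(psi_test, 1, ring), length(epochs$resp), ring, byrow = TRUE)
    u[, 1] <- 1                                      # cue on; rule decides
    psi <- c(psi, psi_test)
    family <- "matching"
  }

  u <- u + matrix(stats::rnorm(length(u), 0,
                               sqrt(2 / config$alpha) * config$sigma_in),
                  nrow(u), ncol(u))

  resp_steps <- epochs$resp
  grace <- resp_steps[seq_len(min(length(resp_steps), round(100 / config$dt)))]
  targets <- matrix(0.05, T_len, config$n_out)
  targets[setdiff(seq_len(T_len), resp_steps), 1] <- 0.8
  if (respond) {
    targets[resp_steps, 1 + seq_len(ring)] <-
      matrix(0.05 + tuning_curve(target_angle, 1, ring),
             length(resp_steps), ring, byrow = TRUE)
  } else {
    targets[resp_steps, 1] <- 0.8
  }
  mask <- matrix(1, T_len, config$n_out)
  mask[resp_steps, ] <- 5
  mask[grace, ] <- 0

  structure(list(inputs = u, targets = targets, mask = mask,
                 meta = list(task = task, family = family, psi = psi,
                             gamma = gamma, respond = respond,
                             target_angle = target_angle, epochs = epochs,
                             response_steps = setdiff(resp_steps, grace))),
            class = "task_trial")
}

#' Random initial RNN parameters
#'
#' Gaussian weights with standard scaling: recurrent gain `g / sqrt(n_rec)`,
#' input scale `1 / sqrt(n_in)`, zero output weights and biases. No sign or
#' structure constraints are imposed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param g Recurrent spectral scale (default 0.5, comfortably stable).
#' @return An object of class `rnn_params`: list with `W_in`, `W_rec`,
#'   `W_out`, `b`.
#' @export
init_rnn_params <- function(config = sim_config(), seed = 1, g = 0.5) {
  withr::with_seed(seed, {
    structure(list(
      W_in = matrix(stats::rnorm(config$n_rec * config$n_in,
                                 0, 1 / sqrt(config$n_in)),
                    config$n_rec, config$n_in),
      W_rec = matrix(stats::rnorm(config$n_rec^2, 0, g / sqrt(config$n_rec)),
                     config$n_rec, config$n_rec),
      W_out = matrix(0, config$n_out, config$n_rec),
      b = numeric(config$n_rec)
    ), class = "rnn_params")
  })
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Simulate the rate network on one trial
#'
#' First-order Euler integration of the rate dynamics
#' \deqn{r_t = (1-\alpha) r_{t-1} + \alpha\, f\!\left(W^{rec} r_{t-1} +
#'   W^{in} u_t + b + \sqrt{2/\alpha}\,\sigma_{rec}\,\xi_t\right)}
#' with softplus \eqn{f}, starting from the silent state \eqn{r_0 = 0};
#' outputs are \eqn{z_t = \mathrm{logistic}(W^{out} r_t)}.
#'
#' @param params An [init_rnn_params()] object (or trained parameters).
#' @param trial A [make_trial()] object, or a plain T x n_in input matrix.
#' @param config A [sim_config()].
#' @param seed Integer seed for the recurrent noise, or `NULL` to use the
#'   current RNG state.
#' @param noise_on If `FALSE`, recurrent noise is disabled (deterministic).
#' @return List with `rates` (T x n_rec) and `outputs` (T x n_out).
#' @examples
#' cfg <- sim_config(n_rec = 8, n_in = 65, n_out = 33)
#' p0 <- init_rnn_params(cfg, seed = 1)
#' p0$W_in[] <- 0; p0$W_rec[] <- 0
#' out <- simulate_rnn(p0, matrix(0, 50, 65), cfg, noise_on = FALSE)
#' out$rates[50, 1]   # ~ log(2), the zero-input fixed point
#' @export
simulate_rnn <- function(params, trial, config = sim_config(), seed = NULL,
                         noise_on = TRUE) {
  u <- if (inherits(trial, "task_trial")) trial$inputs else as.matrix(trial)
  if (ncol(u) != config$n_in) stop("input width must equal n_in")
  if (!is.null(seed))
    return(withr::with_seed(seed, simulate_rnn(params, u, config,
                                               NULL, noise_on)))
  T_len <- nrow(u)
  a <- config$alpha
  noise_sd <- if (noise_on) sqrt(2 / a) * config$sigma_rec else 0
  rates <- matrix(0, T_len, config$n_rec)
  drive_in <- u %*% t(params$W_in)                   # T x n_rec, precomputed
  r <- numeric(config$n_rec)
  for (t in seq_len(T_len)) {
    pre <- drop(params$W_rec %*% r) + drive_in[t, ] + params$b
    if (noise_sd > 0) pre <- pre + stats::rnorm(config$n_rec, 0, noise_sd)
    r <- (1 - a) * r + a * softplus(pre)
    if (any(!is.finite(r)))
      stop("non-finite network state at step ", t)
    rates[t, ] <- r
  }
  outputs <- logistic(rates %*% t(params$W_out))
  list(rates = rates, outputs = outputs)
}

#' Decode the network's response from its output ring
#'
#' Population-vector readout: the response angle is the circular mean of the
#' ring directions weighted by the mean ring-output activity over the response
#' epoch (grace period excluded). The network counts as having responded if
#' the peak mean ring activity exceeds 0.4. A trial is correct if the network
#' responded within 36 degrees of the target direction (response trials), or
#' withheld its response (catch trials).
#'
#' @param outputs T x n_out output matrix from [simulate_rnn()].
#' @param trial The [make_trial()] trial the outputs belong to.
#' @param tolerance Angular tolerance, radians (default 36 degrees).
#' @return List with `responded`, `angle` (`NA` if no response), `correct`.
#' @export
decode_response <- function(outputs, trial, tolerance = pi / 5) {
  stopifnot(inherits(trial, "task_trial"))
  steps <- trial$meta$response_steps
  ring <- ncol(outputs) - 1
  z <- colMeans(outputs[steps, 1 + seq_len(ring), drop = FALSE])
  responded <- max(z) > 0.4
  angle <- if (responded) {
    dirs <- ring_directions(ring)
    atan2(sum(z * sin(dirs)), sum(z * cos(dirs))) %% (2 * pi)
  } else NA_real_
  correct <- if (trial$meta$respond) {
    responded && ang_dist(angle, trial$meta$target_angle) <= tolerance
  } else {
    !responded
  }
  list(responded = responded, angle = angle, correct = correct)
}

#' Task accuracy of a parameter set
#'
#' Fraction of correct trials (per [decode_response()]) over `n_trials` fresh
#' seeded trials simulated with noise on.
#'
#' @param params An `rnn_params` object.
#' @param task Task name.
#' @param n_trials Number of evaluation trials.
#' @param seed Integer seed.
#' @param config A [sim_config()].
#' @return Accuracy in `[0, 1]`.
#' @export
task_accuracy <- function(params, task, n_trials = 64, seed = 1,
                          config = sim_config()) {
  withr::with_seed(seed, {
    mean(vapply(seq_len(n_trials), function(i) {
      tr <- make_trial(task, NULL, config)
      out <- simulate_rnn(params, tr, config, NULL, noise_on = TRUE)
      decode_response(out$outputs, tr)$correct
    }, logical(1)))
  })
}

# Forward + backward pass of one minibatch; returns loss and parameter
# gradients. States are batch x n_rec matrices; backpropagation through time
# uses dL/dr_t = (1-alpha) dL/dr_{t+1} + dA_{t+1} W_rec with
# dA_t = alpha * dL/dr_t * logistic(pre_t) (softplus' = logistic).
rnn_loss_grad <- function(params, trials, config) {
  a <- config$alpha
  B <- length(trials)
  T_len <- nrow(trials[[1]]$inputs)
  n_rec <- config$n_rec
  U <- lapply(seq_len(T_len), function(t)
    t(vapply(trials, function(tr) tr$inputs[t, ], numeric(config$n_in))))
  Y <- lapply(seq_len(T_len), function(t)
    t(vapply(trials, function(tr) tr$targets[t, ], numeric(config$n_out))))
  M <- lapply(seq_len(T_len), function(t)
    t(vapply(trials, function(tr) tr$mask[t, ], numeric(config$n_out))))
  mask_total <- sum(unlist(M))
  noise_sd <- sqrt(2 / a) * config$sigma_rec

  R <- vector("list", T_len)       # states r_t
  S <- vector("list", T_len)       # logistic(pre_t) = f'(pre_t)
  r <- matrix(0, B, n_rec)
  loss <- 0
  dZ <- vector("list", T_len)
  for (t in seq_len(T_len)) {
    pre <- r %*% t(params$W_rec) + U[[t]] %*% t(params$W_in) +
      matrix(params$b, B, n_rec, byrow = TRUE) +
      matrix(stats::rnorm(B * n_rec, 0, noise_sd), B, n_rec)
    r <- (1 - a) * r + a * softplus(pre)
    S[[t]] <- logistic(pre)
    R[[t]] <- r
    z <- logistic(r %*% t(params$W_out))
    err <- z - Y[[t]]
    loss <- loss + sum(M[[t]] * err^2)
    dZ[[t]] <- (2 * M[[t]] * err * z * (1 - z)) / mask_total
  }
  loss <- loss / mask_total

  gW_out <- matrix(0, config$n_out, n_rec)
  gW_rec <- matrix(0, n_rec, n_rec)
  gW_in <- matrix(0, n_rec, config$n_in)
  gb <- numeric(n_rec)
  G <- matrix(0, B, n_rec)        # dL/dr_t carried backwards
  for (t in rev(seq_len(T_len))) {
    gW_out <- gW_out + crossprod(dZ[[t]], R[[t]])
    G <- G + dZ[[t]] %*% params$W_out
    dA <- a * G * S[[t]]          # gradient at the pre-activation
    r_prev <- if (t > 1) R[[t - 1]] else matrix(0, B, n_rec)
    gW_rec <- gW_rec + crossprod(dA, r_prev)
    gW_in <- gW_in + crossprod(dA, U[[t]])
    gb <- gb + colSums(dA)
    G <- (1 - a) * G + dA %*% params$W_rec
  }
  list(loss = loss,
       grads = list(W_in = gW_in, W_rec = gW_rec, W_out = gW_out, b = gb))
}

#' Train a network on one cognitive task
#'
#' Minimal trainer: masked squared-error loss on the outputs, minibatch
#' stochastic gradients through time, Adam updates with global-norm gradient
#' clipping, and early stopping once held-out accuracy reaches
#' `target_accuracy`. If the budget runs out first, the best parameters seen
#' are returned with `converged = FALSE`.
#'
#' @param task Task name, see [cogtask_battery()].
#' @param seed Integer seed (initialization, trial draws, noise).
#' @param budget Maximum number of Adam steps.
#' @param batch Trials per minibatch.
#' @param lr Adam learning rate.
#' @param target_accuracy Early-stopping accuracy on held-out trials.
#' @param eval_every Steps between held-out evaluations.
#' @param n_eval Held-out trials per evaluation.
#' @param config A [sim_config()].
#' @param verbose Print progress lines.
#' @return List with `params`, `accuracy`, `converged`, `steps`, `loss` (the
#'   final minibatch loss) and `task`.
#' @export
train_cogtask <- function(task, seed = 1, budget = 1500, batch = 16,
                          lr = 2e-3, target_accuracy = 0.95,
                          eval_every = 50, n_eval = 64,
                          config = sim_config(), verbose = FALSE) {
  task <- match.arg(task, cogtask_battery())
  params <- init_rnn_params(config, seed = seed)
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(params = params, accuracy = 0)
  converged <- FALSE
  steps_done <- 0L
  loss <- NA_real_
  withr::with_seed(seed + 1L, {
    for (step in seq_len(budget)) {
      trials <- lapply(seq_len(batch), function(i) make_trial(task, NULL, config))
      lg <- rnn_loss_grad(params, trials, config)
      loss <- lg$loss
      gn <- sqrt(sum(vapply(lg$grads, function(g) sum(g^2), numeric(1))))
      scale <- if (gn > 1) 1 / gn else 1
      for (nm in names(params)) {
        g <- lg$grads[[nm]] * scale
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g^2
        mhat <- m[[nm]] / (1 - b1^step)
        vhat <- v[[nm]] / (1 - b2^step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      steps_done <- step
      if (step %% eval_every == 0 || step == budget) {
        acc <- task_accuracy(params, task, n_trials = n_eval,
                             seed = seed + 1000L + step, config = config)
        if (verbose)
          message(sprintf("step %4d  loss %.5f  accuracy %.3f", step, loss, acc))
        if (acc >= best$accuracy) best <- list(params = params, accuracy = acc)
        if (acc >= target_accuracy) {
          converged <- TRUE
          break
        }
      }
    }
  })
  list(params = best$params, accuracy = best$accuracy, converged = converged,
       steps = steps_done, loss = loss, task = task)
}

#' Collect the neural manifold visited across trials
#'
#' Concatenates the recurrent-layer activity of `n_trials` seeded trials
#' (simulated with noise on) into one point cloud: one row per time step,
#' one column per recurrent unit.
#'
#' @param params Trained `rnn_params`.
#' @param task Task name.
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @param config A [sim_config()].
#' @return A (`n_trials` * T) x n_rec matrix of activities, with attribute
#'   `trial_length`.
#' @export
collect_manifold <- function(params, task, n_trials = 200, seed = 1,
                             config = sim_config()) {
  task <- match.arg(task, cogtask_battery())
  rows <- withr::with_seed(seed, {
    lapply(seq_len(n_trials), function(i) {
      tr <- make_trial(task, NULL, config)
      simulate_rnn(params, tr, config, NULL, noise_on = TRUE)$rates
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "trial_length") <- nrow(rows[[1]])
  out
}
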