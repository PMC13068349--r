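#' @name manifold_sample
#' @title Synthetic manifold samples
#'
#' @description All generators in this file return a `manifold_sample`: a list
#' with elements `points` (P x N matrix), `true_id` (generative intrinsic
#' dimension), `generator_name`, and `params` (all arguments including the
#' seed). Regenerating with identical parameters reproduces the points
#' bit-for-bit.
NULL

new_manifold_sample <- function(points, true_id, generator_name, params) {
  structure(list(points = points, true_id = true_id,
                 generator_name = generator_name, params = params),
            class = "manifold_sample")
}

#' @export
print.manifold_sample <- function(x, ...) {
  cat(sprintf("manifold_sample '%s': %d points in %d dims (true ID = %s)\n",
              x$generator_name, nrow(x$points), ncol(x$points), x$true_id))
  invisible(x)
}

# Random N x d matrix with orthonormal columns (embedding isometry).
random_rotation_into <- function(d, n_ambient) {
  qr.Q(qr(matrix(stats::rnorm(n_ambient * d), n_ambient, d)))[, seq_len(d), drop = FALSE]
}

#' Uniform sample on a flat d-dimensional patch
#'
#' `p` points uniform on the unit cube \eqn{[0,1]^d}, rotated isometrically
#' into `n_ambient` dimensions by a seeded random orthonormal frame.
#'
#' @param d Intrinsic dimension.
#' @param n_ambient Ambient dimension (`>= d`).
#' @param p Number of points.
#' @param seed Integer seed.
#' @return A [manifold_sample].
#' @export
uniform_hyperplane <- function(d, n_ambient = d + 1, p = 10000, seed = 1) {
  stopifnot(d >= 1, n_ambient >= d, p >= 2)
  pts <- withr::with_seed(seed, {
    latent <- matrix(stats::runif(p * d), p, d)
    rot <- random_rotation_into(d, n_ambient)
    latent %*% t(rot)
  })
  new_manifold_sample(pts, d, "plane",
                      list(d = d, n_ambient = n_ambient, p = p, seed = seed))
}

#' Uniform sample on a Swiss roll
#'
#' The classical curved 2-D surface \eqn{(t\cos t,\; y,\; t\sin t)} with
#' \eqn{t \in [1.5\pi, 4.5\pi]} and \eqn{y \in [0, 20]}, sampled uniformly with
#' respect to surface area (the roll coordinate `t` is drawn by inverse-CDF
#' sampling of the arc-length density \eqn{\sqrt{1+t^2}}).
#'
#' @param p Number of points.
#' @param seed Integer seed.
#' @param noise_sd Standard deviation of optional isotropic Gaussian ambient
#'   noise (0 = points exactly on the surface).
#' @return A [manifold_sample] with `true_id = 2`; the generating `t` values
#'   are stored in `params$t`.
#' @export
swiss_roll <- function(p = 10000, seed = 1, noise_sd = 0) {
  stopifnot(p >= 100, noise_sd >= 0)
  t_lo <- 1.5 * pi
  t_hi <- 4.5 * pi
  res <- withr::with_seed(seed, {
    grid <- seq(t_lo, t_hi, length.out = 4096)
    cdf <- cumsum(sqrt(1 + grid^2))
    cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
    tt <- stats::approx(cdf, grid, xout = stats::runif(p), ties = "ordered")$y
    y <- stats::runif(p, 0, 20)
    pts <- cbind(tt * cos(tt), y, tt * sin(tt))
    if (noise_sd > 0) pts <- pts + matrix(stats::rnorm(3 * p, sd = noise_sd), p, 3)
    list(pts = pts, tt = tt)
  })
  new_manifold_sample(res$pts, 2, "swissroll",
                      list(p = p, seed = seed, noise_sd = noise_sd, t = res$tt))
}

#' Uniform sample in a d-dimensional hypercube
#'
#' @param d Dimension.
#' @param p Number of points.
#' @param seed Integer seed.
#' @return A [manifold_sample] with `true_id = d`.
#' @export
uniform_hypercube <- function(d, p = 10000, seed = 1) {
  stopifnot(d >= 1, p >= 2)
  pts <- withr::with_seed(seed, matrix(stats::runif(p * d), p, d))
  new_manifold_sample(pts, d, "cube", list(d = d, p = p, seed = seed))
}

#' Uniform sample on a hypersphere surface
#'
#' `p` points uniform on the unit sphere \eqn{S^{d}} embedded in `d + 1`
#' dimensions (normalized isotropic Gaussians).
#'
#' @param d_sphere Manifold dimension of the sphere.
#' @param p Number of points.
#' @param seed Integer seed.
#' @return A [manifold_sample] with `true_id = d_sphere`.
#' @export
uniform_hypersphere <- function(d_sphere, p = 10000, seed = 1) {
  stopifnot(d_sphere >= 1, p >= 2)
  pts <- withr::with_seed(seed, {
    g <- matrix(stats::rnorm(p * (d_sphere + 1)), p, d_sphere + 1)
    g / sqrt(rowSums(g^2))
  })
  new_manifold_sample(pts, d_sphere, "sphere",
                      list(d_sphere = d_sphere, p = p, seed = seed))
}

#' Flat data with tunable anisotropy
#'
#' Starts from iid uniform points in \eqn{[-1,1]^d} and maps each coordinate
#' \eqn{x \mapsto \mathrm{sign}(x)\,|x|^{1+\alpha}}. `alpha_aniso = 0` is the
#' isotropic identity; increasing values concentrate mass near the origin and
#' the axes while the support (and the intrinsic dimension `d`) is unchanged.
#' Used to calibrate the curvature statistic [delta()] on flat but
#' non-isotropic data.
#'
#' @param d Dimension.
#' @param p Number of points.
#' @param alpha_aniso Anisotropy exponent (`>= 0`).
#' @param seed Integer seed.
#' @return A [manifold_sample] with `true_id = d`.
#' @export
anisotropic_flat <- function(d, p = 10000, alpha_aniso = 0, seed = 1) {
  stopifnot(d >= 1, p >= 2, alpha_aniso >= 0)
  pts <- withr::with_seed(seed, {
    x <- matrix(stats::runif(p * d, -1, 1), p, d)
    sign(x) * abs(x)^(1 + alpha_aniso)
  })
  new_manifold_sample(pts, d, "aniso",
                      list(d = d, p = p, alpha_aniso = alpha_aniso, seed = seed))
}

#' Latent neural-trajectory samples
#'
#' Emulates synthetic neural recordings built from `d` independent
#' firing-rate channels: `p` samples per channel are drawn iid from a rate
#' distribution, then temporally smoothed with a Gaussian kernel
#' (`kernel_sd_ms` s.d. on a `bin_ms` binning, circular convolution), and
#' finally standardized per channel so all latent variances are equal.
#'
#' The default rate model is a unit-log-scale log-normal, a synthetic stand-in
#' that preserves the skewed, positive character of empirical cortical rate
#' distributions; `"gaussian"` gives the equal-variance Gaussian condition.
#'
#' @param d Number of latent channels (intrinsic dimension).
#' @param p Number of time samples.
#' @param seed Integer seed.
#' @param rate_model `"lognormal"` or `"gaussian"`.
#' @param smooth If `FALSE`, skip temporal smoothing (samples stay iid).
#' @param bin_ms,kernel_sd_ms Bin width and smoothing kernel s.d. in ms.
#' @return A `p x d` matrix of latent samples.
#' @export
latent_trajectories <- function(d, p = 10000, seed = 1,
                                rate_model = c("lognormal", "gaussian"),
                                smooth = TRUE, bin_ms = 50, kernel_sd_ms = 50) {
  rate_model <- match.arg(rate_model)
  stopifnot(d >= 1, p >= 10)
  withr::with_seed(seed, {
    raw <- switch(rate_model,
                  lognormal = matrix(stats::rlnorm(p * d, 0, 1), p, d),
                  gaussian  = matrix(stats::rnorm(p * d), p, d))
    if (smooth) {
      sd_bins <- kernel_sd_ms / bin_ms
      half <- ceiling(4 * sd_bins)
      kern <- stats::dnorm(seq(-half, half), sd = sd_bins)
      kern <- kern / sum(kern)
      raw <- apply(raw, 2, function(col)
        as.numeric(stats::filter(col, kern, sides = 2, circular = TRUE)))
    }
    scale(raw)[, , drop = FALSE]
  })
}

#' Linear Gaussian mixing embedding
#'
#' Multiplies `d`-dimensional latent samples by a seeded `n_ambient x d`
#' mixing matrix with iid standard normal entries. The output has rank at most
#' `d`; the intrinsic dimension is unchanged.
#'
#' With `normalize_variance = TRUE` (the default) each ambient variable is
#' rescaled to unit variance after mixing. Raw Gaussian mixing of
#' unit-variance latents gives every ambient coordinate a standard deviation
#' of about `sqrt(d)`, so any scale-sensitive downstream transformation —
#' in particular the exponential of [nonlinear_embed()], whose `alpha` is
#' meant to be the sole knob controlling the degree of nonlinearity — would
#' otherwise act more strongly for larger `d`. The rescaling is a diagonal
#' linear map and leaves the intrinsic dimension unchanged.
#'
#' @param latent `p x d` matrix of latent samples (or a [manifold_sample]).
#' @param n_ambient Ambient dimension (default 96, comparable to a
#'   multi-electrode array).
#' @param seed Integer seed for the mixing matrix.
#' @param normalize_variance Rescale each ambient variable to unit variance
#'   (default `TRUE`).
#' @return A [manifold_sample] with `true_id = ncol(latent)`.
#' @export
linear_embed <- function(latent, n_ambient = 96, seed = 1,
                         normalize_variance = TRUE) {
  latent <- as_point_cloud(latent)
  d <- ncol(latent)
  stopifnot(n_ambient >= d)
  pts <- withr::with_seed(seed, {
    mix <- matrix(stats::rnorm(n_ambient * d), n_ambient, d)
    latent %*% t(mix)
  })
  if (normalize_variance) {
    sds <- apply(pts, 2, stats::sd)
    pts <- sweep(pts, 2, pmax(sds, .Machine$double.eps), "/")
  }
  new_manifold_sample(pts, d, "linear_embed",
                      list(d = d, n_ambient = n_ambient, seed = seed,
                           normalize_variance = normalize_variance))
}

#' Coordinate-wise exponential nonlinearity
#'
#' Applies \eqn{y = (e^{\alpha x} - 1)/(e^{\alpha} - 1)} to every coordinate.
#' The map is strictly increasing with fixed points at 0 and 1, reduces to the
#' identity as \eqn{\alpha \to 0}, and preserves the intrinsic dimension while
#' strongly distorting distances for large \eqn{\alpha}.
#'
#' The normalized exponential is a bijection of the unit interval onto
#' itself — the \eqn{e^{\alpha} - 1} denominator exists precisely to pin
#' \eqn{f(1) = 1}. With `rescale = TRUE` (the default) each coordinate is
#' therefore mapped affinely onto \eqn{[0, 1]} before the exponential is
#' applied, so that `alpha` alone controls the degree of nonlinearity
#' regardless of the input's scale or offset; the affine map is
#' order-preserving and leaves the intrinsic dimension unchanged. Data
#' already in \eqn{[0, 1]} spanning the full interval are unaffected by the
#' rescaling. Set `rescale = FALSE` to evaluate the raw formula.
#'
#' @param data A [manifold_sample] or numeric matrix.
#' @param alpha Nonlinearity strength (`alpha = 0` returns the input
#'   unchanged, the continuity limit).
#' @param rescale Map each coordinate onto `[0, 1]` before applying the
#'   exponential (default `TRUE`).
#' @return Same type as the input, with transformed coordinates.
#' @export
nonlinear_embed <- function(data, alpha, rescale = TRUE) {
  stopifnot(alpha >= 0)
  f <- function(x) {
    if (alpha == 0) return(x)
    if (rescale) {
      lo <- apply(x, 2, min)
      span <- pmax(apply(x, 2, max) - lo, .Machine$double.eps)
      x <- sweep(sweep(x, 2, lo), 2, span, "/")
    }
    (exp(alpha * x) - 1) / (exp(alpha) - 1)
  }
  if (inherits(data, "manifold_sample")) {
    data$points <- f(data$points)
    data$generator_name <- paste0(data$generator_name, "+exp")
    data$params$alpha_nonlin <- alpha
    data
  } else {
    f(as_point_cloud(data))
  }
}

#' Two noisy repetitions of a shared low-rank stimulus response
#'
#' Synthetic test bed for cross-validated PCA: two repetitions of
#' `n_stim` stimulus responses over `n_neurons` neurons share an identical
#' rank-`d_signal` signal component and carry independent Gaussian noise.
#'
#' @param d_signal Rank of the shared stimulus signal.
#' @param n_stim Number of stimuli (rows).
#' @param n_neurons Number of neurons (columns).
#' @param noise_sd Noise standard deviation per repetition.
#' @param seed Integer seed.
#' @return List with matrices `rep1` and `rep2` and the noiseless `signal`.
#' @export
repeated_stimulus_responses <- function(d_signal, n_stim, n_neurons,
                                        noise_sd = 0.1, seed = 1) {
  stopifnot(d_signal <= min(n_stim, n_neurons), d_signal >= 0)
  withr::with_seed(seed, {
    if (d_signal > 0) {
      lat <- matrix(stats::rnorm(n_stim * d_signal), n_stim, d_signal)
      w <- matrix(stats::rnorm(n_neurons * d_signal), n_neurons, d_signal)
      signal <- lat %*% t(w)
    } else {
      signal <- matrix(0, n_stim, n_neurons)
    }
    rep1 <- signal + matrix(stats::rnorm(n_stim * n_neurons, sd = noise_sd),
                            n_stim, n_neurons)
    rep2 <- signal + matrix(stats::rnorm(n_stim * n_neurons, sd = noise_sd),
                            n_stim, n_neurons)
    list(rep1 = rep1, rep2 = rep2, signal = signal)
  })
}
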