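#' Covariance eigenvalue spectrum of a point cloud
#'
#' @param points Numeric matrix, one sample per row.
#' @return Non-increasing vector of covariance eigenvalues.
#' @keywords internal
cov_spectrum <- function(points) {
  points <- as_point_cloud(points)
  if (nrow(points) < 2) stop("need at least 2 samples")
  # eigenvalues of the covariance matrix via SVD of the centered data,
  # cheaper than forming the N x N covariance when N >> P
  x <- sweep(points, 2, colMeans(points))
  sv <- svd(x, nu = 0, nv = 0)$d
  ev <- sv^2 / (nrow(points) - 1)
  c(ev, rep(0, max(0, ncol(points) - length(ev))))
}

#' Linear dimension by PCA variance thresholding
#'
#' Smallest number of leading principal components whose cumulative variance
#' fraction reaches `alpha`.
#'
#' @param points Numeric matrix.
#' @param alpha Variance fraction in (0, 1); typical values 0.8-0.99.
#' @return Integer dimension (0 for all-zero data).
#' @export
pca_id <- function(points, alpha = 0.95) {
  stopifnot(alpha > 0, alpha < 1)
  ev <- cov_spectrum(points)
  tot <- sum(ev)
  if (tot <= 0) return(0L)
  as.integer(which(cumsum(ev) / tot >= alpha)[1])
}

#' Participation ratio
#'
#' The effective number of linear dimensions,
#' \eqn{\mathrm{PR} = 1 / \sum_k (\lambda_k / \mathcal{V})^2} with
#' \eqn{\lambda_k} the covariance eigenvalues and \eqn{\mathcal{V}} the total
#' variance. Equals N for an isotropic spectrum and 1 for rank-1 data;
#' invariant under orthogonal rotation and global scaling.
#'
#' @param points Numeric matrix.
#' @return The participation ratio in \eqn{[1, N]}.
#' @export
participation_ratio <- function(points) {
  ev <- cov_spectrum(points)
  tot <- sum(ev)
  if (tot <= 0) stop("zero total variance")
  1 / sum((ev / tot)^2)
}

#' Parallel analysis
#'
#' Number of principal components significant against a shuffled null:
#' surrogates are built by independently permuting every coordinate column,
#' their covariance eigenvalues pooled into a null distribution, and the
#' returned dimension is the largest K whose eigenvalue
#' \eqn{\lambda_K} exceeds the \eqn{(1-\alpha)} percentile of that pool.
#'
#' @param points Numeric matrix.
#' @param n_shuffles Number of shuffled surrogates (>= 10).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed for the shuffles.
#' @return Integer count of significant components (possibly 0).
#' @export
parallel_analysis <- function(points, n_shuffles = 100, alpha = 0.05, seed = 1) {
  points <- as_point_cloud(points)
  if (n_shuffles < 10) stop("need at least 10 shuffles")
  ev <- cov_spectrum(points)
  null_ev <- withr::with_seed(seed, {
    unlist(lapply(seq_len(n_shuffles), function(i) {
      shuf <- apply(points, 2, sample)
      cov_spectrum(shuf)
    }))
  })
  crit <- stats::quantile(null_ev, 1 - alpha, names = FALSE)
  idx <- which(ev >= crit & ev > 0)
  if (length(idx) == 0) return(0L)
  as.integer(max(idx))
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Log-log slope of the empirical correlation integral in the small-radius
#' window (radii between the 1st and 10th percentile of pairwise distances).
#' Known to underestimate high dimensions under realistic sample sizes.
#'
#' @param points Numeric matrix (>= 100 points).
#' @param n_radii Radii in the fit window.
#' @param max_pairs Pair cap, see [empirical_correlation_integral()].
#' @return Estimated dimension (slope).
#' @export
corrdim <- function(points, n_radii = 16, max_pairs = 2e8) {
  points <- as_point_cloud(points)
  if (nrow(points) < 100) stop("corrdim needs at least 100 points")
  d <- cpp_pair_sample(points, 500000L)
  win <- stats::quantile(d, c(0.01, 0.10), names = FALSE)
  if (win[1] <= 0) win[1] <- min(d[d > 0])
  radii <- exp(seq(log(win[1]), log(win[2]), length.out = n_radii))
  emp <- empirical_correlation_integral(points, radii, max_pairs = max_pairs)
  keep <- emp$rho > 0
  if (sum(keep) < 3) stop("too few pairs in the small-radius window")
  stats::coef(stats::lm(log(emp$rho[keep]) ~ log(emp$radius[keep])))[[2]]
}

#' Maximum-likelihood k-NN intrinsic dimension
#'
#' Levina-Bickel estimator: per point,
#' \eqn{\hat D_i = (K-1) / \sum_{k=1}^{K-1} \log(r_{i,K}/r_{i,k})}; the global
#' estimate is the inverse of the mean of inverses across points (the
#' standard bias-corrected aggregation). Duplicate points (zero neighbor
#' distances) are collapsed with a warning.
#'
#' @param points Numeric matrix.
#' @param k Neighborhood size (>= 3).
#' @return Estimated dimension.
#' @export
mle_id <- function(points, k = 20) {
  points <- as_point_cloud(points)
  if (k < 3) stop("k must be >= 3")
  if (k >= nrow(points)) stop("k must be < number of points")
  r <- cpp_knn_dists(points, as.integer(k))
  zero <- r[, 1] <= 0
  if (any(zero)) {
    warning(sum(zero), " point(s) with duplicate coordinates excluded")
    r <- r[!zero, , drop = FALSE]
  }
  xi <- rowSums(log(r[, k] / r[, -k, drop = FALSE]))  # sum over k = 1..K-1
  inv <- xi / (k - 1)
  1 / mean(inv)
}

#' Two-NN intrinsic dimension
#'
#' Ratios of second- to first-nearest-neighbor distances
#' \eqn{\mu_i = r_{i,2}/r_{i,1}} follow a Pareto law with shape equal to the
#' intrinsic dimension. D is estimated by regressing
#' \eqn{-\log(1 - F(\mu))} on \eqn{\log \mu} through the origin after
#' discarding the largest `discard_fraction` of the ratios. Points with a
#' duplicate (zero first-neighbor distance) are excluded with their count
#' reported via warning.
#'
#' @param points Numeric matrix (>= 100 points).
#' @param discard_fraction Fraction of the largest ratios dropped (default
#'   0.1; must be < 0.5).
#' @return Estimated dimension.
#' @export
twonn <- function(points, discard_fraction = 0.1) {
  points <- as_point_cloud(points)
  if (nrow(points) < 100) stop("twonn needs at least 100 points")
  if (discard_fraction < 0 || discard_fraction >= 0.5)
    stop("discard_fraction must be in [0, 0.5)")
  r <- cpp_knn_dists(points, 2L)
  zero <- r[, 1] <= 0
  if (any(zero)) {
    warning(sum(zero), " point(s) with zero first-neighbor distance excluded")
    r <- r[!zero, , drop = FALSE]
  }
  mu <- sort(r[, 2] / r[, 1])
  n <- length(mu)
  keep <- seq_len(floor(n * (1 - discard_fraction)))
  mu <- mu[keep]
  ff <- keep / n
  x <- log(mu)
  y <- -log(1 - ff)
  ok <- x > 0
  sum(x[ok] * y[ok]) / sum(x[ok]^2)   # least squares through the origin
}

#' Two-NN with decimation
#'
#' Runs [twonn()] on seeded random subsamples at each retention fraction,
#' averaged over `n_rep` repetitions. Decimation dilutes small-scale noise by
#' increasing typical nearest-neighbor distances; the returned value is the
#' estimate at the plateau of the estimate-vs-fraction curve (the largest
#' fraction whose estimate differs by less than 5% from the next-smaller
#' fraction; if no plateau forms, the smallest fraction's estimate).
#'
#' @param points Numeric matrix.
#' @param fractions Retention fractions in (0, 1], tried in decreasing order.
#' @param n_rep Repetitions per fraction.
#' @param seed Integer seed.
#' @param discard_fraction Passed to [twonn()].
#' @return List with `estimate`, and the per-fraction `curve` data frame.
#' @export
twonn_decimated <- function(points, fractions = c(1, 0.5, 0.25, 0.125, 0.0625),
                            n_rep = 3, seed = 1, discard_fraction = 0.1) {
  points <- as_point_cloud(points)
  p <- nrow(points)
  fractions <- sort(unique(fractions), decreasing = TRUE)
  stopifnot(all(fractions > 0), all(fractions <= 1))
  res <- withr::with_seed(seed, {
    vapply(fractions, function(f) {
      n_keep <- floor(p * f)
      if (n_keep < 100) return(NA_real_)
      reps <- vapply(seq_len(n_rep), function(i) {
        idx <- sample.int(p, n_keep)
        twonn(points[idx, , drop = FALSE], discard_fraction)
      }, numeric(1))
      mean(reps)
    }, numeric(1))
  })
  keep <- is.finite(res)
  if (!all(keep))
    warning("fraction(s) leaving < 100 points skipped: ",
            paste(fractions[!keep], collapse = ", "))
  fr <- fractions[keep]
  est <- res[keep]
  if (length(est) == 0) stop("no usable decimation fraction")
  plateau <- est[length(est)]
  if (length(est) >= 2) {
    for (i in seq_len(length(est) - 1)) {
      if (abs(est[i] - est[i + 1]) < 0.05 * abs(est[i + 1])) {
        plateau <- est[i]
        break
      }
      plateau <- est[length(est)]
    }
  }
  list(estimate = plateau, curve = data.frame(fraction = fr, estimate = est))
}

#' Cross-validated PCA projection onto the stimulus-related subspace
#'
#' Given two repetitions of the same stimulus set (rows stimulus-aligned),
#' ranks the principal axes of the repetition average by their
#' cross-repetition covariance — an unbiased estimate of stimulus-related
#' variance, since independent noise does not survive the cross product — and
#' projects the data onto the smallest leading subspace containing at least
#' `variance_fraction` of the total (positive) stimulus-related variance.
#'
#' @param responses_rep1,responses_rep2 Matrices of identical shape
#'   (stimuli x neurons).
#' @param variance_fraction Stimulus-related variance to retain (default
#'   0.99).
#' @return The averaged responses projected onto the retained axes
#'   (stimuli x retained-dimensions matrix), with attributes `n_dims` and
#'   `cross_variance` (per-axis cross-repetition covariance).
#' @export
cvpca_project <- function(responses_rep1, responses_rep2,
                          variance_fraction = 0.99) {
  a <- as_point_cloud(responses_rep1)
  b <- as_point_cloud(responses_rep2)
  if (!all(dim(a) == dim(b))) stop("repetitions must have identical shapes")
  stopifnot(variance_fraction > 0, variance_fraction <= 1)
  a_c <- sweep(a, 2, colMeans(a))
  b_c <- sweep(b, 2, colMeans(b))
  avg <- (a_c + b_c) / 2
  sv <- svd(avg)
  pc_a <- a_c %*% sv$v
  pc_b <- b_c %*% sv$v
  n <- nrow(a)
  cross <- colSums(pc_a * pc_b) / (n - 1)
  ord <- order(cross, decreasing = TRUE)
  pos <- pmax(cross[ord], 0)
  tot <- sum(pos)
  if (tot <= 0) {
    n_dims <- 1L     # pure noise: nothing stimulus-related beyond one axis
  } else {
    n_dims <- which(cumsum(pos) / tot >= variance_fraction)[1]
  }
  proj <- avg %*% sv$v[, ord[seq_len(n_dims)], drop = FALSE]
  attr(proj, "n_dims") <- n_dims
  attr(proj, "cross_variance") <- cross
  proj
}
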