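#' Draw neighborhood centers
#'
#' `m` distinct row indices drawn uniformly without replacement, reproducible
#' for a fixed seed.
#'
#' @param points Numeric matrix of points.
#' @param m Number of centers (`<= nrow(points)`).
#' @param seed Integer seed.
#' @return Integer vector of `m` distinct indices.
#' @export
select_centers <- function(points, m, seed) {
  points <- as_point_cloud(points)
  p <- nrow(points)
  if (m < 1 || m > p) stop("`m` must be between 1 and the number of points")
  withr::with_seed(seed, sample.int(p, m))
}

#' K-nearest-neighbor neighborhood of a point
#'
#' The `k` points closest to the center under Euclidean distance, the center
#' itself excluded from the count (so the neighborhood holds `k` members plus
#' implicitly the center, which is always its own 0-th neighbor). Distance ties
#' are broken deterministically by row index; duplicate points (zero
#' distances) are retained.
#'
#' @param points Numeric matrix of points.
#' @param center_index Row index of the center.
#' @param k Neighborhood size, `2 <= k <= nrow(points) - 1`.
#' @return A list of class `neighborhood` with `center_index`, `k`,
#'   `member_indices` (the `k` neighbor rows, nearest first) and `points`
#'   (the `k x N` member coordinates).
#' @export
knn_neighborhood <- function(points, center_index, k) {
  points <- as_point_cloud(points)
  p <- nrow(points)
  if (k < 2 || k > p - 1) stop("`k` must be in [2, P-1]")
  if (center_index < 1 || center_index > p) stop("invalid center index")
  ctr <- points[center_index, ]
  d2 <- rowSums(points^2) + sum(ctr^2) - 2 * drop(points %*% ctr)
  d2[center_index] <- Inf
  ord <- order(d2, seq_len(p))     # ties broken by index
  members <- ord[seq_len(k)]
  structure(list(center_index = center_index, k = k,
                 member_indices = members,
                 points = points[members, , drop = FALSE]),
            class = "neighborhood")
}

#' Curvature statistic of a neighborhood
#'
#' The distance from the neighborhood's center of mass to its closest member,
#' normalized by the mean nearest-neighbor distance among members:
#' \deqn{\delta = \frac{\min_j \|b - x_j\|}{\frac{1}{K}\sum_j \min_{k \ne j}
#'   \|x_j - x_k\|}, \qquad b = \frac{1}{K}\sum_j x_j.}
#' For a flat, well-sampled patch the center of mass lies among the points and
#' \eqn{\delta \approx 1}; strong curvature displaces it off the manifold
#' (an entire sphere gives the extreme case: `b` is the sphere's center, far
#' from every surface point). \eqn{\delta > 2} is the conservative curvature
#' flag used by the lFCI pipeline. For neighborhoods larger than `max_exact`
#' members, the denominator is averaged over a seeded random subset of
#' `max_exact` members (the numerator is always exact).
#'
#' @param nbhd A `neighborhood` (see [knn_neighborhood()]) or a plain matrix
#'   of member coordinates.
#' @param max_exact Member cap for the exact nearest-neighbor average.
#' @return The scalar \eqn{\delta \ge 0}.
#' @export
delta <- function(nbhd, max_exact = 200) {
  x <- if (inherits(nbhd, "neighborhood")) nbhd$points else as_point_cloud(nbhd)
  k <- nrow(x)
  if (k < 3) stop("delta needs at least 3 points")
  b <- colMeans(x)
  num <- sqrt(min(colSums((t(x) - b)^2)))
  subset <- if (k <= max_exact) seq_len(k)
            else withr::with_seed(k, sample.int(k, max_exact))
  # nearest-neighbor distances via the Gram expansion
  # ||x_i - x_j||^2 = |x_i|^2 + |x_j|^2 - 2 x_i.x_j (BLAS-backed, which
  # dominates the elementwise loop for wide, e.g. neural, data)
  n2 <- rowSums(x^2)
  d2 <- n2[subset] - 2 * tcrossprod(x[subset, , drop = FALSE], x)
  d2 <- sweep(d2, 2, n2, "+")
  d2[cbind(seq_along(subset), subset)] <- Inf
  nn <- sqrt(pmax(apply(d2, 1, min), 0))
  denom <- mean(nn)
  if (denom < 1e-300)
    stop("degenerate neighborhood: all points coincide")
  num / denom
}

#' Local FCI estimate on one neighborhood
#'
#' Runs the FCI fit on the member points of a neighborhood (centered on the
#' neighborhood's own center of mass) and computes the curvature statistic
#' [delta()] on the same points. The `reliable` flag is left `NA` until
#' thresholding by [filter_reliable()].
#'
#' @param nbhd A `neighborhood` from [knn_neighborhood()].
#' @param n_radii Radii per local fit.
#' @param max_pairs Pair-subsampling cap per local fit (seeded by the caller).
#' @return One-row data frame: `center_index`, `k`, `d_local`, `delta`,
#'   `gof`, `reliable`.
#' @export
local_fci <- function(nbhd, n_radii = 64, max_pairs = 2e5) {
  stopifnot(inherits(nbhd, "neighborhood"))
  if (nbhd$k < 5) stop("local FCI needs at least 5 members")
  fit <- fit_fci(nbhd$points, n_radii = n_radii, max_pairs = max_pairs)
  data.frame(center_index = nbhd$center_index, k = nbhd$k,
             d_local = fit$d_id, delta = delta(nbhd), gof = fit$gof,
             reliable = NA)
}

#' Default neighborhood-size grid
#'
#' 12 log-spaced integers from 50 to `min(p - 1, 10^4)`.
#'
#' @param p Number of points in the dataset.
#' @param n_k Number of grid values.
#' @param k_min,k_max Grid end points (`k_max` is clipped to `p - 1`).
#' @return Ascending integer vector of neighborhood sizes.
#' @export
default_k_grid <- function(p, n_k = 12, k_min = 50, k_max = 10000) {
  hi <- min(p - 1, k_max)
  if (hi <= k_min) return(unique(pmin(pmax(2, c(k_min, hi)), p - 1)))
  unique(round(exp(seq(log(k_min), log(hi), length.out = n_k))))
}

#' Multiscale local FCI estimates
#'
#' Computes one local estimate per (center, K) pair: `m` seeded random centers,
#' each analyzed at every neighborhood size in `k_grid`. This is the data
#' behind the multiscale ID plot.
#'
#' @param points Numeric matrix (or [manifold_sample]).
#' @param k_grid Ascending integer vector of neighborhood sizes
#'   (default [default_k_grid()]).
#' @param m Number of centers.
#' @param seed Integer seed (centers and pair subsampling).
#' @param n_radii,max_pairs Per-fit settings, see [local_fci()].
#' @return Data frame of local estimates, one row per (center, K).
#' @export
multiscale_estimates <- function(points, k_grid = NULL, m = 100, seed = 1,
                                 n_radii = 64, max_pairs = 2e5) {
  points <- as_point_cloud(points)
  p <- nrow(points)
  if (is.null(k_grid)) k_grid <- default_k_grid(p)
  if (length(k_grid) == 0) stop("`k_grid` must not be empty")
  if (is.unsorted(k_grid)) stop("`k_grid` must be ascending")
  if (max(k_grid) > p - 1) stop("max(k_grid) must be <= P - 1")
  centers <- select_centers(points, m, seed)
  rows <- withr::with_seed(seed + 1L, {
    out <- vector("list", length(centers) * length(k_grid))
    i <- 0L
    for (ci in centers) {
      nb_max <- knn_neighborhood(points, ci, max(k_grid))
      for (k in k_grid) {
        i <- i + 1L
        nb <- if (k == nb_max$k) nb_max else
          structure(list(center_index = ci, k = k,
                         member_indices = nb_max$member_indices[seq_len(k)],
                         points = nb_max$points[seq_len(k), , drop = FALSE]),
                    class = "neighborhood")
        out[[i]] <- local_fci(nb, n_radii = n_radii, max_pairs = max_pairs)
      }
    }
    do.call(rbind, out)
  })
  rows
}

#' Goodness-of-fit reliability threshold
#'
#' Groups the local GoF values by neighborhood size K and returns the
#' threshold \eqn{\gamma}:
#' * `"min_p99"` (default): the smallest 99th percentile across the per-K GoF
#'   distributions;
#' * `"lowest_median"`: the 99th percentile of the GoF distribution at the
#'   scale K with the lowest median GoF.
#' The two rules coincide on well-behaved data; both are conservative
#' references for "comparatively poor fit quality".
#'
#' Only curvature-credible scales define the threshold: estimates with
#' \eqn{\delta >} `delta_max` are excluded first, and a scale K is eligible
#' only if it retains at least `min_support` of the best-retaining scale's
#' count. Without this guard, a scale whose neighborhoods are wholesale
#' curvature-dominated (e.g. K close to the dataset size on a curved
#' manifold, where each "local" fit is just a well-fitting global fit with
#' huge \eqn{\delta}) can set an absurdly strict \eqn{\gamma} that no honest
#' local fit reaches. If every estimate fails the \eqn{\delta} cut, the
#' threshold falls back to all finite GoF values.
#'
#' @param estimates Data frame from [multiscale_estimates()].
#' @param rule Threshold variant.
#' @param delta_max Curvature bound used for eligibility (default 2).
#' @param min_support Minimum per-scale retention, as a fraction of the
#'   best-retaining scale's count (default 0.5).
#' @return The scalar threshold \eqn{\gamma}.
#' @export
gof_threshold <- function(estimates, rule = c("min_p99", "lowest_median"),
                          delta_max = 2, min_support = 0.5) {
  rule <- match.arg(rule)
  est <- estimates[is.finite(estimates$gof), ]
  if (nrow(est) == 0) stop("no finite GoF values")
  ok <- est[est$delta <= delta_max, ]
  if (nrow(ok) > 0) {
    cnt <- table(ok$k)
    eligible <- as.numeric(names(cnt)[cnt >= min_support * max(cnt)])
    est <- ok[ok$k %in% eligible, ]
  }
  p99 <- tapply(est$gof, est$k, stats::quantile, probs = 0.99, names = FALSE)
  if (rule == "min_p99") return(min(p99))
  med <- tapply(est$gof, est$k, stats::median)
  k_best <- names(med)[which.min(med)]
  unname(p99[[k_best]])
}

#' Filter local estimates by curvature and fit quality
#'
#' Sets the `reliable` flag (\eqn{\delta \le 2} and GoF \eqn{\le \gamma}) and
#' returns the reliable subset. An empty reliable set is an error: it signals
#' that every analyzed scale is curved or badly fitted, and the K grid or
#' threshold rule should be revisited rather than silently reporting nothing.
#'
#' @param estimates Data frame from [multiscale_estimates()].
#' @param gamma GoF threshold from [gof_threshold()].
#' @param delta_max Curvature bound (default 2).
#' @return The reliable subset, with `reliable` set; the full flagged table is
#'   attached as attribute `"all"`.
#' @export
filter_reliable <- function(estimates, gamma, delta_max = 2) {
  if (gamma < 0) stop("`gamma` must be >= 0")
  ok <- is.finite(estimates$d_local) & is.finite(estimates$gof) &
    estimates$delta <= delta_max & estimates$gof <= gamma
  estimates$reliable <- ok
  kept <- estimates[ok, , drop = FALSE]
  if (nrow(kept) == 0)
    stop("no reliable local estimates (all delta > ", delta_max,
         " or GoF > ", signif(gamma, 3),
         "); revisit the K grid or the GoF threshold rule")
  attr(kept, "all") <- estimates
  kept
}

#' Histogram-mode ID report from reliable local estimates
#'
#' Bins the reliable local IDs with bin width
#' `max(0.05, mad(d) / 5)` — a robust-spread rule, so that a minority of
#' outlying local fits (e.g. noise-floor neighborhoods that pass the
#' reliability filters with very large `d_local`) cannot widen the bins and
#' wash out the dominant peak — takes the center of the highest bin as the
#' overall estimate `d_star` (ties broken toward the lower bin), and reports
#' the 10th and 90th percentiles of the local estimates as the plausible
#' range. Fewer than 10 reliable estimates yields a warning-grade,
#' low-confidence report.
#'
#' @param reliable Data frame of reliable estimates from [filter_reliable()].
#' @param gamma The GoF threshold used (recorded in the report).
#' @return An object of class `id_report`: `d_star`, `p10`, `p90`,
#'   `n_reliable`, `n_total`, `k_grid`, `gof_threshold`, `low_confidence`,
#'   and the `histogram` (bin centers with counts).
#' @export
id_histogram_report <- function(reliable, gamma = NA_real_) {
  d <- reliable$d_local
  d <- d[is.finite(d)]
  if (length(d) == 0) stop("no finite local estimates")
  low_confidence <- length(d) < 10
  if (low_confidence)
    warning("fewer than 10 reliable estimates; report is low-confidence")
  width <- max(0.05, stats::mad(d) / 5)
  lo <- floor(min(d) / width) * width
  breaks <- seq(lo, max(d) + width, by = width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  best <- which.max(h$counts)          # which.max takes the first (lowest) tie
  all_tab <- attr(reliable, "all")
  structure(list(
    d_star = h$mids[best],
    p10 = stats::quantile(d, 0.10, names = FALSE),
    p90 = stats::quantile(d, 0.90, names = FALSE),
    n_reliable = length(d),
    n_total = if (!is.null(all_tab)) nrow(all_tab) else length(d),
    k_grid = sort(unique(reliable$k)),
    gof_threshold = gamma,
    low_confidence = low_confidence,
    histogram = data.frame(bin_center = h$mids, count = h$counts)
  ), class = "id_report")
}

#' @export
print.id_report <- function(x, ...) {
  cat(sprintf("lFCI ID estimate: %.3f [%.3f, %.3f]\n", x$d_star, x$p10, x$p90))
  cat(sprintf("  reliable estimates: %d / %d  (GoF threshold %.4g)\n",
              x$n_reliable, x$n_total, x$gof_threshold))
  if (isTRUE(x$low_confidence)) cat("  WARNING: low confidence (< 10 reliable)\n")
  if (isTRUE(x$global_fallback))
    cat("  NOTE: curvature at all scales; d_star is the global FCI estimate\n")
  invisible(x)
}

#' Local FCI (lFCI) intrinsic-dimension pipeline
#'
#' The full five-step procedure: (1) local FCI fits on `m` random centers
#' across the multiscale `k_grid`; (2) GoF reliability threshold \eqn{\gamma}
#' across scales; (3) discard estimates with curvature \eqn{\delta > 2} or
#' GoF \eqn{> \gamma}; (4) histogram of the surviving local IDs, whose highest
#' peak is the overall estimate; (5) 10th/90th percentile band. If every
#' estimate is flagged as curved (\eqn{\delta > 2} at all scales), the global
#' FCI estimate is returned instead with an explicit caveat flag
#' (`global_fallback = TRUE`).
#'
#' @inheritParams multiscale_estimates
#' @param gof_rule Threshold variant, see [gof_threshold()].
#' @return An `id_report` (see [id_histogram_report()]) with the multiscale
#'   table attached as element `estimates`.
#' @examples
#' roll <- swiss_roll(p = 2000, seed = 7)
#' rep <- lfci(roll$points, m = 20, seed = 7)
#' rep$d_star
#' @export
lfci <- function(points, k_grid = NULL, m = 100, seed = 1,
                 gof_rule = c("min_p99", "lowest_median"),
                 n_radii = 64, max_pairs = 2e5) {
  gof_rule <- match.arg(gof_rule)
  points <- as_point_cloud(points)
  est <- multiscale_estimates(points, k_grid = k_grid, m = m, seed = seed,
                              n_radii = n_radii, max_pairs = max_pairs)
  gamma <- gof_threshold(est, rule = gof_rule)
  if (all(est$delta > 2, na.rm = TRUE)) {
    # extreme curvature at every scale: fall back to the global estimate
    fit <- fit_fci(points)
    est$reliable <- FALSE
    rep <- structure(list(
      d_star = fit$d_id, p10 = NA_real_, p90 = NA_real_,
      n_reliable = 0L, n_total = nrow(est),
      k_grid = sort(unique(est$k)), gof_threshold = gamma,
      low_confidence = TRUE, global_fallback = TRUE,
      histogram = NULL), class = "id_report")
    rep$estimates <- est
    return(rep)
  }
  kept <- filter_reliable(est, gamma)
  rep <- id_histogram_report(kept, gamma = gamma)
  rep$global_fallback <- FALSE
  rep$estimates <- attr(kept, "all")
  rep
}
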