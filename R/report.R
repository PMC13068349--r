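#' Run one or several intrinsic-dimension estimators on a point cloud
#'
#' Dispatches to the configured estimators and collects their results into a
#' `comparison_report` — one entry per method with the estimate, a plausible
#' range where the method provides one, the parameters used, the runtime in
#' seconds, and a status. A failing estimator is recorded with
#' `status = "error"` and its message; the remaining methods still run.
#'
#' Available methods: `"fci"` (global FCI), `"lfci"` (local FCI pipeline),
#' `"pca"` (variance-threshold PCA), `"pr"` (participation ratio), `"pa"`
#' (parallel analysis), `"corrdim"` (correlation dimension), `"mle"`
#' (maximum-likelihood k-NN), `"twonn"` (Two-NN), `"twonn_dec"` (Two-NN with
#' decimation), or `"all"` for every one of them.
#'
#' @param points Numeric matrix or [manifold_sample] (dataset provenance is
#'   recorded from the latter).
#' @param methods Character vector of method names, or `"all"`.
#' @param seed Integer seed, forwarded to the stochastic methods and recorded
#'   in the report.
#' @param params Named list of per-method parameter overrides, e.g.
#'   `list(lfci = list(m = 50), mle = list(k = 10))`. Unknown method names or
#'   parameters are an error.
#' @return An object of class `comparison_report`: list with
#'   `schema_version`, `seed`, `dataset` (provenance), and `entries` (one
#'   named list per method).
#' @examples
#' x <- uniform_hyperplane(d = 2, n_ambient = 3, p = 400, seed = 1)
#' rep <- run_estimate(x, methods = c("pr", "pca"), seed = 1)
#' rep$entries$pr$estimate
#' @export
run_estimate <- function(points, methods = "all", seed = 1, params = list()) {
  known <- c("fci", "lfci", "pca", "pr", "pa", "corrdim", "mle",
             "twonn", "twonn_dec")
  if (identical(methods, "all")) methods <- known
  bad <- setdiff(methods, known)
  if (length(bad) > 0)
    stop("unknown method(s): ", paste(bad, collapse = ", "))
  bad_p <- setdiff(names(params), known)
  if (length(bad_p) > 0)
    stop("parameters given for unknown method(s): ",
         paste(bad_p, collapse = ", "))

  dataset <- if (inherits(points, "manifold_sample")) {
    list(generator = points$generator_name, params = points$params,
         true_id = points$true_id)
  } else {
    x <- as_point_cloud(points)
    list(generator = "external", n_points = nrow(x), n_dims = ncol(x),
         checksum = signif(sum(x) + sum(x^2), 12))
  }
  x <- as_point_cloud(points)

  runners <- list(
    fci = function(pp) {
      fit <- do.call(fit_fci, c(list(x), pp))
      list(estimate = fit$d_id, range = NULL,
           details = list(gof = fit$gof, converged = fit$converged))
    },
    lfci = function(pp) {
      rep <- do.call(lfci, c(list(x, seed = seed), pp))
      list(estimate = rep$d_star, range = c(rep$p10, rep$p90),
           details = list(gof_threshold = rep$gof_threshold,
                          n_reliable = rep$n_reliable,
                          n_total = rep$n_total,
                          global_fallback = isTRUE(rep$global_fallback)))
    },
    pca = function(pp) list(estimate = do.call(pca_id, c(list(x), pp))),
    pr = function(pp) list(estimate = do.call(participation_ratio,
                                              c(list(x), pp))),
    pa = function(pp) list(estimate = do.call(parallel_analysis,
                                              c(list(x, seed = seed), pp))),
    corrdim = function(pp) list(estimate = do.call(corrdim, c(list(x), pp))),
    mle = function(pp) list(estimate = do.call(mle_id, c(list(x), pp))),
    twonn = function(pp) list(estimate = do.call(twonn, c(list(x), pp))),
    twonn_dec = function(pp) {
      res <- do.call(twonn_decimated, c(list(x, seed = seed), pp))
      list(estimate = res$estimate,
           details = list(curve = res$curve))
    }
  )

  entries <- lapply(methods, function(mth) {
    pp <- params[[mth]]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(runners[[mth]](pp), error = function(e)
      list(estimate = NA_real_, error = conditionMessage(e)))
    entry <- list(method = mth,
                  estimate = res$estimate,
                  range = res$range,
                  parameters = if (length(pp)) pp else NULL,
                  details = res$details,
                  runtime_s = round(proc.time()[["elapsed"]] - t0, 3),
                  status = if (is.null(res$error)) "ok" else "error")
    if (!is.null(res$error)) entry$error <- res$error
    entry
  })
  names(entries) <- methods
  structure(list(schema_version = "1.0", seed = seed,
                 dataset = dataset, entries = entries),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report (schema %s, seed %d)\n",
              x$schema_version, x$seed))
  cat(sprintf("  dataset: %s\n", x$dataset$generator))
  for (e in x$entries) {
    if (e$status == "ok") {
      rng <- if (!is.null(e$range))
        sprintf("  [%.3f, %.3f]", e$range[1], e$range[2]) else ""
      cat(sprintf("  %-10s %8.3f%s   (%.2fs)\n",
                  e$method, e$estimate, rng, e$runtime_s))
    } else {
      cat(sprintf("  %-10s ERROR: %s\n", e$method, e$error))
    }
  }
  invisible(x)
}

#' Write / read a comparison report as JSON
#'
#' `write_report()` serializes a [run_estimate()] report to JSON;
#' `read_report()` parses it back. The round trip is lossless for every
#' recorded field (full numeric precision is written).
#'
#' @param report A `comparison_report`.
#' @param path Output (input) file path.
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   parsed `comparison_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(obj$schema_version))
    stop("not a comparison report: missing schema_version")
  for (nm in names(obj$entries)) {
    e <- obj$entries[[nm]]
    if (!is.null(e$range)) obj$entries[[nm]]$range <- as.numeric(e$range)
  }
  structure(obj, class = "comparison_report")
}

#' Render the multiscale estimate table as TSV
#'
#' Serializes the table of local estimates (the data behind the multiscale ID
#' plot) as tab-separated text with columns `center`, `K`, `d_local`,
#' `delta`, `gof`, `reliable`, sorted by `(K, center)`.
#'
#' @param estimates Data frame from [multiscale_estimates()] (or the
#'   `estimates` element of an [lfci()] report).
#' @param path Optional output file; if `NULL` the TSV is returned as a
#'   character vector of lines.
#' @return The TSV lines (invisibly, when `path` is given).
#' @export
render_multiscale_table <- function(estimates, path = NULL) {
  if (nrow(estimates) == 0) stop("no estimates to render")
  tab <- data.frame(center = estimates$center_index, K = estimates$k,
                    d_local = estimates$d_local, delta = estimates$delta,
                    gof = estimates$gof, reliable = estimates$reliable)
  tab <- tab[order(tab$K, tab$center), ]
  lines <- c(paste(names(tab), collapse = "\t"),
             vapply(seq_len(nrow(tab)), function(i)
               paste(format(unlist(tab[i, ], use.names = FALSE),
                            trim = TRUE, digits = 15), collapse = "\t"),
               character(1)))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Parse a multiscale TSV back into a data frame
#'
#' Inverse of [render_multiscale_table()].
#'
#' @param path TSV file written by [render_multiscale_table()].
#' @return Data frame with the same columns as [multiscale_estimates()].
#' @export
read_multiscale_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t")
  data.frame(center_index = as.integer(tab$center), k = as.integer(tab$K),
             d_local = tab$d_local, delta = tab$delta, gof = tab$gof,
             reliable = as.logical(tab$reliable))
}
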