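#' Validate a point cloud
#'
#' A point cloud is a plain numeric matrix with one sample per row and one
#' ambient coordinate per column; all entries must be finite. Data frames and
#' objects carrying a `points` element (e.g. [manifold_sample] objects) are
#' coerced.
#'
#' @param x Matrix, data frame, or an object with a `points` element.
#' @return A numeric matrix.
#' @export
as_point_cloud <- function(x) {
  if (is.list(x) && !is.data.frame(x) && !is.null(x$points)) x <- x$points
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("a point cloud must be a numeric matrix (P samples x N coordinates)")
  if (nrow(x) < 1 || ncol(x) < 1) stop("empty point cloud")
  if (any(!is.finite(x))) stop("point cloud contains non-finite entries")
  x
}

#' Read a point cloud from disk
#'
#' Delimited text (comma or tab autodetected, optional header row) or the
#' binary RDS container written by [write_point_cloud()].
#'
#' @param path File path.
#' @param format `"delimited"`, `"rds"`, or `"auto"` (by file extension:
#'   `.rds` is binary, anything else delimited).
#' @return A numeric matrix.
#' @export
read_point_cloud <- function(path, format = c("auto", "delimited", "rds")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "delimited"
  if (format == "rds") return(as_point_cloud(readRDS(path)))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  fields <- strsplit(first, if (sep == "") "[[:space:]]+" else sep)[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(fields))))
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(apply(df, 1, function(r) any(is.na(suppressWarnings(as.numeric(r))))))
    stop("non-numeric cell(s) at row ", paste(utils::head(bad, 3), collapse = ", "))
  }
  dimnames(m) <- NULL
  as_point_cloud(m)
}

#' Write a point cloud to disk
#'
#' @param points Numeric matrix.
#' @param path Output path.
#' @param format `"delimited"` (TSV, no header) or `"rds"` (binary,
#'   bit-exact round trip); `"auto"` picks by extension.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(points, path, format = c("auto", "delimited", "rds")) {
  format <- match.arg(format)
  points <- as_point_cloud(points)
  if (format == "auto")
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "delimited"
  if (format == "rds") {
    saveRDS(points, path)
  } else {
    utils::write.table(points, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
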