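#' Write a point cloud as whitespace-delimited XYZ text
#'
#' One `x y z` triple per line at fixed precision; `#` starts a comment.
#'
#' @param cloud A [point_cloud()].
#' @param path Output file path.
#' @param digits Decimal places per coordinate, default 6.
#' @param header Logical; write a `# x y z` comment line first.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(cloud, path, digits = 6, header = FALSE) {
  stopifnot(inherits(cloud, "point_cloud"))
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines("# x y z", con)
  if (n_points(cloud) > 0L) {
    fmt <- sprintf("%%.%df %%.%df %%.%df", digits, digits, digits)
    writeLines(sprintf(fmt, cloud$xyz[, 1], cloud$xyz[, 2], cloud$xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a whitespace-delimited XYZ text file
#'
#' Accepts the dialect written by [write_xyz()]: whitespace-separated
#' `x y z` per line, `#` comments and blank lines ignored.
#'
#' @param path Input file path.
#' @param device Device label for the returned cloud.
#' @return A [point_cloud()].
#' @export
read_xyz <- function(path, device = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  stripped <- sub("#.*$", "", lines)
  keep <- grepl("\\S", stripped)
  if (!any(keep))
    return(point_cloud(matrix(numeric(0), ncol = 3), device = device))
  toks <- strsplit(trimws(stripped[keep]), "\\s+")
  nums <- lapply(toks, function(x) suppressWarnings(as.numeric(x)))
  lineno <- which(keep)
  bad <- which(lengths(toks) != 3L | vapply(nums, anyNA, logical(1)))
  if (length(bad) > 0L)
    stop(sprintf("malformed XYZ record at line %d: '%s'",
                 lineno[bad[1]], lines[lineno[bad[1]]]))
  point_cloud(matrix(unlist(nums), ncol = 3, byrow = TRUE), device = device)
}
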