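#' Point cloud container
#'
#' A registered 3D point cloud in a shared scene frame (metres, Z up), tagged
#' with the device that produced it and, optionally, a per-point scan label.
#'
#' @param xyz Numeric matrix with three columns (x, y, z) in metres, or a
#'   data frame coercible to one. Zero-row matrices are allowed.
#' @param device Character scalar naming the device the cloud came from.
#' @param scan_id Optional per-point scan label: either a vector of length
#'   `nrow(xyz)` or a single label recycled to all points.
#' @return An object of class `point_cloud`: a list with elements `xyz`
#'   (n x 3 matrix), `device` and `scan_id` (character vector or `NULL`).
#' @examples
#' pc <- point_cloud(cbind(runif(10), runif(10), 0), device = "riegl")
#' n_points(pc)
#' @export
point_cloud <- function(xyz, device = "unknown", scan_id = NULL) {
  if (is.data.frame(xyz)) xyz <- as.matrix(xyz)
  if (length(xyz) == 0L) xyz <- matrix(numeric(0), ncol = 3)
  if (!is.matrix(xyz) || ncol(xyz) != 3L)
    stop("`xyz` must be a matrix with 3 columns (x, y, z)")
  storage.mode(xyz) <- "double"
  if (nrow(xyz) > 0L && !all(is.finite(xyz)))
    stop("point coordinates must be finite")
  if (!is.character(device) || length(device) != 1L)
    stop("`device` must be a single character label")
  if (!is.null(scan_id)) {
    scan_id <- as.character(scan_id)
    if (length(scan_id) == 1L) scan_id <- rep(scan_id, nrow(xyz))
    if (length(scan_id) != nrow(xyz))
      stop("`scan_id` must have one label per point")
  }
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(xyz = xyz, device = device, scan_id = scan_id),
            class = "point_cloud")
}

#' Number of points in a cloud
#' @param cloud A [point_cloud()].
#' @return Integer point count.
#' @export
n_points <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  nrow(cloud$xyz)
}

#' Axis-aligned bounds of a cloud
#' @param cloud A [point_cloud()].
#' @return A 2 x 3 matrix with rows `min` and `max`.
#' @export
cloud_bounds <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) == 0L)
    return(matrix(NA_real_, 2, 3, dimnames = list(c("min", "max"), c("x", "y", "z"))))
  rbind(min = apply(cloud$xyz, 2, min), max = apply(cloud$xyz, 2, max))
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points, device '%s'", n_points(x), x$device))
  if (!is.null(x$scan_id))
    cat(sprintf(", %d scan(s)", length(unique(x$scan_id))))
  cat("\n")
  if (n_points(x) > 0L) {
    b <- cloud_bounds(x)
    cat(sprintf("  x: [%.3f, %.3f]  y: [%.3f, %.3f]  z: [%.3f, %.3f]\n",
                b[1, 1], b[2, 1], b[1, 2], b[2, 2], b[1, 3], b[2, 3]))
  }
  invisible(x)
}

#' Merge registered scans from one device
#'
#' Concatenates point clouds that share a scene frame (registration is assumed
#' to have happened upstream). Per-point scan labels are preserved; clouds
#' without labels are numbered by their position in the list.
#'
#' @param clouds Non-empty list of [point_cloud()] objects with the same
#'   device tag.
#' @return A single [point_cloud()] whose point count is the sum of the
#'   inputs, with a `scan_id` per point.
#' @export
merge_scans <- function(clouds) {
  if (!is.list(clouds) || length(clouds) == 0L)
    stop("`clouds` must be a non-empty list of point clouds")
  if (!all(vapply(clouds, inherits, logical(1), "point_cloud")))
    stop("all elements of `clouds` must be point_cloud objects")
  devices <- unique(vapply(clouds, function(c) c$device, character(1)))
  if (length(devices) != 1L)
    stop("cannot merge scans from different devices: ",
         paste(devices, collapse = ", "))
  ids <- lapply(seq_along(clouds), function(i) {
    sid <- clouds[[i]]$scan_id
    if (is.null(sid)) rep(sprintf("scan%02d", i), n_points(clouds[[i]])) else sid
  })
  point_cloud(do.call(rbind, lapply(clouds, function(c) c$xyz)),
              device = devices, scan_id = unlist(ids, use.names = FALSE))
}

#' Clip a cloud to a rectangular plot
#'
#' Keeps points inside the axis-aligned box `[xmin, xmax] x [ymin, ymax]`,
#' the usual first step when working per research plot.
#'
#' @param cloud A [point_cloud()].
#' @param xlim,ylim Length-2 numeric ranges (m).
#' @return The clipped [point_cloud()].
#' @export
clip_cloud <- function(cloud, xlim, ylim) {
  stopifnot(inherits(cloud, "point_cloud"))
  keep <- cloud$xyz[, 1] >= xlim[1] & cloud$xyz[, 1] <= xlim[2] &
          cloud$xyz[, 2] >= ylim[1] & cloud$xyz[, 2] <= ylim[2]
  point_cloud(cloud$xyz[keep, , drop = FALSE], device = cloud$device,
              scan_id = cloud$scan_id[keep])
}

# Run `expr` with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Derive a per-task seed from a master seed; stays below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483647)
}
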