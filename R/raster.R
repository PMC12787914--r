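#' Rasterize a point cloud
#'
#' Per-cell minimum or maximum point elevation on a regular grid. Cells are
#' half-open `[x0, x0 + cs) x [y0, y0 + cs)` with the origin at the floor of
#' the cloud bounds (in cell units), so a point exactly on a boundary
#' belongs to the higher-index cell. Empty cells are `NA` (nodata).
#'
#' @param cloud A non-empty [point_cloud()].
#' @param cell_size Cell edge in metres, > 0 (default 0.5, crown scale at
#'   plantation spacing).
#' @param aggregation `"min"` (terrain; DTM) or `"max"` (surface; DSM).
#' @return An object of class `raster_grid`: list with `origin` (x0, y0),
#'   `cell_size`, `values` (nx x ny matrix, x indexing rows) and
#'   `aggregation`.
#' @export
rasterize <- function(cloud, cell_size = 0.5, aggregation = c("min", "max")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) == 0L) stop("`cloud` is empty")
  if (!is.numeric(cell_size) || cell_size <= 0) stop("`cell_size` must be > 0")
  xyz <- cloud$xyz
  x0 <- floor(min(xyz[, 1]) / cell_size) * cell_size
  y0 <- floor(min(xyz[, 2]) / cell_size) * cell_size
  ix <- floor((xyz[, 1] - x0) / cell_size) + 1L
  iy <- floor((xyz[, 2] - y0) / cell_size) + 1L
  nx <- max(ix); ny <- max(iy)
  vals <- matrix(NA_real_, nx, ny)
  idx <- ix + nx * (iy - 1L)
  agg <- tapply(xyz[, 3], idx, if (aggregation == "min") min else max)
  vals[as.integer(names(agg))] <- as.double(agg)
  structure(list(origin = c(x = x0, y = y0), cell_size = cell_size,
                 values = vals, aggregation = aggregation),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d cells of %.2f m (%s), origin (%.2f, %.2f), %d nodata\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$aggregation,
              x$origin[1], x$origin[2], sum(is.na(x$values))))
  invisible(x)
}

# Cell indices of query points; NA outside the grid extent.
raster_cell_index <- function(grid, xy) {
  ix <- floor((xy[, 1] - grid$origin[1]) / grid$cell_size) + 1L
  iy <- floor((xy[, 2] - grid$origin[2]) / grid$cell_size) + 1L
  out <- ifelse(ix >= 1L & ix <= nrow(grid$values) &
                iy >= 1L & iy <= ncol(grid$values),
                ix + nrow(grid$values) * (iy - 1L), NA_integer_)
  as.integer(out)
}

# Fill nodata cells from the nearest defined cell (by cell-centre distance).
fill_nearest <- function(grid) {
  v <- grid$values
  na_cells <- which(is.na(v))
  if (length(na_cells) == 0L) return(grid)
  def_cells <- which(!is.na(v))
  if (length(def_cells) == 0L) stop("raster has no defined cells to fill from")
  nx <- nrow(v)
  cx <- function(i) (i - 1L) %% nx
  cy <- function(i) (i - 1L) %/% nx
  for (i in na_cells) {
    d2 <- (cx(def_cells) - cx(i))^2 + (cy(def_cells) - cy(i))^2
    v[i] <- v[def_cells[which.min(d2)]]
  }
  grid$values <- v
  grid
}

#' Normalised surface model (DSM minus DTM)
#'
#' Cellwise difference of two congruent rasters. With `fill = TRUE`
#' (default), DTM nodata cells - typically ground hidden under dense crowns -
#' are filled from the nearest defined ground cell before subtracting, which
#' is benign on flat terrain; otherwise nodata propagates.
#'
#' @param dtm,dsm Congruent `raster_grid`s (same origin, cell size and
#'   dimensions).
#' @param fill Nearest-neighbour fill of DTM nodata before subtraction.
#' @return A `raster_grid` of heights above ground.
#' @export
ndsm <- function(dtm, dsm, fill = TRUE) {
  stopifnot(inherits(dtm, "raster_grid"), inherits(dsm, "raster_grid"))
  if (!isTRUE(all.equal(dtm$origin, dsm$origin)) ||
      dtm$cell_size != dsm$cell_size ||
      !identical(dim(dtm$values), dim(dsm$values)))
    stop("DTM and DSM grids are not congruent (origin/cell size/shape differ)")
  base <- if (fill) fill_nearest(dtm) else dtm
  out <- dtm
  out$values <- dsm$values - base$values
  out$aggregation <- "max"
  out
}

#' Build DTM, DSM and nDSM from a cloud
#'
#' @param cloud A [point_cloud()].
#' @param cell_size Cell edge in metres, default 0.5.
#' @param fill Passed to [ndsm()].
#' @return An object of class `terrain_models`: list with `dtm`, `dsm`,
#'   `ndsm` raster grids.
#' @export
terrain_models <- function(cloud, cell_size = 0.5, fill = TRUE) {
  dtm <- rasterize(cloud, cell_size, "min")
  dsm <- rasterize(cloud, cell_size, "max")
  structure(list(dtm = dtm, dsm = dsm, ndsm = ndsm(dtm, dsm, fill = fill)),
            class = "terrain_models")
}

# Raster value at query points; optional nearest fill for nodata cells.
sample_raster <- function(grid, xy, fill = FALSE) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  g <- if (fill) fill_nearest(grid) else grid
  idx <- raster_cell_index(g, xy)
  out <- rep(NA_real_, nrow(xy))
  out[!is.na(idx)] <- g$values[idx[!is.na(idx)]]
  out
}

#' Sample tree heights from an nDSM at stem positions
#'
#' Reads, for each stem, the nDSM value of the cell containing the stem
#' centroid. Stems over nodata cells are flagged missing; stems outside the
#' grid extent are an error.
#'
#' @param grid The nDSM `raster_grid` (or a `terrain_models` object, whose
#'   `ndsm` is used).
#' @param stem_xy n x 2 matrix of stem positions (m).
#' @return Data frame with `x`, `y`, `th` (m, `NA` when missing) and
#'   `missing`.
#' @export
sample_height_at <- function(grid, stem_xy) {
  if (inherits(grid, "terrain_models")) grid <- grid$ndsm
  stopifnot(inherits(grid, "raster_grid"))
  if (is.null(dim(stem_xy))) stem_xy <- matrix(stem_xy, ncol = 2)
  idx <- raster_cell_index(grid, stem_xy)
  if (anyNA(idx))
    stop("stem(s) outside the raster extent: ",
         paste(which(is.na(idx)), collapse = ", "))
  th <- grid$values[idx]
  data.frame(x = stem_xy[, 1], y = stem_xy[, 2], th = th, missing = is.na(th))
}

#' Tube length from two vertical segments
#'
#' Extracts two diametrically opposed vertical strips on a tube's surface (a
#' slab of width `segment_width` through the tube centre, split into its two
#' sides) and reports the mean of the strips' vertical extents, in
#' centimetres - a deterministic surrogate for manually picking the end
#' points of two vertical segments on the tube.
#'
#' @param cloud A [point_cloud()] of the scene.
#' @param tube The [tube_spec()] to measure.
#' @param segment_width Strip width in metres, > 0 (default 0.05).
#' @param prior_length Optional prior length (cm); if the estimate falls
#'   below 90% of it, the result is flagged (`flagged = TRUE`), indicating
#'   probable range-limited truncation.
#' @return List with `length_cm` (`NA` if the tube has no usable points),
#'   `n_strips` used (2, 1, or 0) and `flagged`.
#' @export
tube_length_from_segments <- function(cloud, tube, segment_width = 0.05,
                                      prior_length = NULL) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(tube, "tube_spec"))
  if (!is.numeric(segment_width) || segment_width <= 0)
    stop("`segment_width` must be > 0")
  r <- tube$diameter / 200
  dx <- cloud$xyz[, 1] - tube$center_xy[1]
  dy <- cloud$xyz[, 2] - tube$center_xy[2]
  near <- dx^2 + dy^2 <= (r + 3 * segment_width)^2
  slab <- near & abs(dy) <= segment_width / 2
  extents <- c()
  for (side in list(dx >= 0, dx < 0)) {
    z <- cloud$xyz[slab & side, 3]
    if (length(z) >= 2L) extents <- c(extents, max(z) - min(z))
  }
  if (length(extents) == 0L)
    return(list(length_cm = NA_real_, n_strips = 0L, flagged = TRUE))
  len <- mean(extents) * 100
  flagged <- !is.null(prior_length) && len < 0.9 * prior_length
  list(length_cm = len, n_strips = length(extents), flagged = flagged)
}
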