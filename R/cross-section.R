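#' Cross-section of a stem
#'
#' Planar (x, y) points projected from a height band above local ground.
#'
#' @param points n x 2 matrix of (x, y) coordinates in metres.
#' @param band Length-2 numeric, the height band `[z_lo, z_hi)` in metres
#'   above ground the points came from.
#' @param stem_id Optional stem label.
#' @return An object of class `cross_section`; its `detected` field is TRUE
#'   when the section has at least 3 points (enough for circle fitting).
#' @export
cross_section <- function(points, band = c(NA_real_, NA_real_), stem_id = NA) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (length(points) == 0L) points <- matrix(numeric(0), ncol = 2)
  if (!is.matrix(points) || ncol(points) != 2L)
    stop("`points` must be an n x 2 matrix")
  storage.mode(points) <- "double"
  structure(list(points = points, band = as.double(band),
                 stem_id = stem_id, n = nrow(points),
                 detected = nrow(points) >= 3L),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> %d points, band [%.3f, %.3f) m%s\n", x$n,
              x$band[1], x$band[2],
              if (x$detected) "" else " (undetected: < 3 points)"))
  invisible(x)
}

# Height of each point above local ground: constant plane or a DTM raster
# (nodata cells filled from the nearest defined cell).
height_above_ground <- function(xyz, ground) {
  if (is.numeric(ground) && length(ground) == 1L) return(xyz[, 3] - ground)
  if (inherits(ground, "terrain_models")) ground <- ground$dtm
  if (inherits(ground, "raster_grid"))
    return(xyz[, 3] - sample_raster(ground, xyz[, 1:2, drop = FALSE], fill = TRUE))
  stop("`ground` must be a numeric constant, a raster_grid DTM, or terrain_models")
}

# Partition planar points into connected components on a grid of `linkdist`
# cells (8-neighbourhood); returns an integer cluster label per point.
cluster_planar <- function(xy, linkdist = 0.3) {
  ix <- floor(xy[, 1] / linkdist); iy <- floor(xy[, 2] / linkdist)
  key <- paste(ix, iy)
  cells <- unique(key)
  cell_of <- match(key, cells)
  cx <- as.numeric(sub(" .*", "", cells))
  cy <- as.numeric(sub(".* ", "", cells))
  parent <- seq_along(cells)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    j <- match(paste(cx + dx, cy + dy), cells)
    hit <- which(!is.na(j))
    for (i in hit) {
      ri <- find(i); rj <- find(j[i])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_along(cells), find, integer(1))
  match(roots, unique(roots))[cell_of]
}

#' Extract breast-height cross-sections from a cloud
#'
#' Keeps points whose height above local ground falls in
#' `[center_height - thickness/2, center_height + thickness/2)`, projects
#' them to the ground plane, and partitions them into stems by planar
#' connected-component clustering. The default band is `[1.30, 1.35)` m -
#' a 5 cm slice centred between the two conventional breast-height
#' thresholds. Sections with fewer than 3 points are flagged undetected.
#'
#' @param cloud A [point_cloud()].
#' @param ground Local ground: a numeric constant elevation, a `raster_grid`
#'   DTM, or a `terrain_models` object.
#' @param center_height Band centre in metres above ground, default 1.325.
#' @param thickness Band thickness in metres, default 0.05.
#' @param cluster_dist Planar linking distance for stem clustering in metres,
#'   default 0.3 (safe at plantation spacing).
#' @return A list of [cross_section()] objects (possibly empty).
#' @export
extract_dbh_slice <- function(cloud, ground = 0, center_height = 1.325,
                              thickness = 0.05, cluster_dist = 0.3) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!is.numeric(thickness) || thickness <= 0) stop("`thickness` must be > 0")
  if (n_points(cloud) == 0L) stop("`cloud` is empty")
  if (is.null(ground)) stop("`ground` is required (constant or DTM)")
  h <- height_above_ground(cloud$xyz, ground)
  lo <- center_height - thickness / 2
  hi <- center_height + thickness / 2
  keep <- h >= lo & h < hi
  if (!any(keep)) return(list())
  xy <- cloud$xyz[keep, 1:2, drop = FALSE]
  cl <- cluster_planar(xy, cluster_dist)
  lapply(seq_len(max(cl)), function(k)
    cross_section(xy[cl == k, , drop = FALSE], band = c(lo, hi)))
}

#' Match cross-sections to known stem positions
#'
#' @param sections List of [cross_section()] objects.
#' @param stem_xy n x 2 matrix of stem positions.
#' @param max_dist Maximum centroid-to-stem distance (m), default 1.
#' @return Integer vector, one entry per stem: index into `sections` of the
#'   nearest section centroid within `max_dist`, or `NA` (stem undetected).
#' @export
match_sections_to_stems <- function(sections, stem_xy, max_dist = 1) {
  if (is.null(dim(stem_xy))) stem_xy <- matrix(stem_xy, ncol = 2)
  if (length(sections) == 0L) return(rep(NA_integer_, nrow(stem_xy)))
  cen <- t(vapply(sections, function(s) colMeans(s$points), numeric(2)))
  vapply(seq_len(nrow(stem_xy)), function(i) {
    d <- sqrt((cen[, 1] - stem_xy[i, 1])^2 + (cen[, 2] - stem_xy[i, 2])^2)
    j <- which.min(d)
    if (d[j] <= max_dist) j else NA_integer_
  }, integer(1))
}

#' Algebraic (Taubin) circle fit
#'
#' Non-iterative algebraic fit minimising approximately-normalised radial
#' residuals; exact on noiseless circles (and gives the circumcircle of
#' three points).
#'
#' @param section A [cross_section()] or an n x 2 coordinate matrix with at
#'   least 3 non-collinear points.
#' @return An object of class `fitted_circle`: list with `center` (x, y) and
#'   `radius` (m).
#' @export
fit_circle <- function(section) {
  xy <- if (inherits(section, "cross_section")) section$points else as.matrix(section)
  if (nrow(xy) < 3L) stop("circle fitting needs at least 3 points")
  xm <- mean(xy[, 1]); ym <- mean(xy[, 2])
  x <- xy[, 1] - xm; y <- xy[, 2] - ym
  z <- x^2 + y^2
  zm <- mean(z)
  if (zm < .Machine$double.eps)
    stop("degenerate point set: all points coincide")
  M <- cbind((z - zm) / (2 * sqrt(zm)), x, y)
  sv <- svd(M)
  v <- sv$v[, 3]
  A <- v[1] / (2 * sqrt(zm))
  if (abs(A) < 1e-12 * max(1, abs(v[2]), abs(v[3])))
    stop("cannot fit a circle: points are (nearly) collinear")
  B <- v[2]; C <- v[3]; D <- -zm * A
  cx <- -B / (2 * A); cy <- -C / (2 * A)
  r2 <- (B^2 + C^2) / (4 * A^2) - D / A
  if (!is.finite(r2) || r2 <= 0) stop("circle fit failed (non-positive radius)")
  structure(list(center = c(x = cx + xm, y = cy + ym), radius = sqrt(r2)),
            class = "fitted_circle")
}

#' Unwrap a cross-section about a fitted circle
#'
#' Expresses each point by its azimuth about the circle centre (theta, in
#' degrees over [0, 360)) and its radial deviation from the reference radius
#' (in millimetres), sorted by theta. This is the representation in which
#' the contour model and the noise band are computed.
#'
#' @param section A [cross_section()].
#' @param circle A `fitted_circle` from [fit_circle()].
#' @return An object of class `unwrapped_profile`: list with `theta`
#'   (degrees), `deviation` (mm), `radius` (m) and `n`.
#' @export
unwrap_to_polar <- function(section, circle) {
  stopifnot(inherits(circle, "fitted_circle"))
  xy <- if (inherits(section, "cross_section")) section$points else as.matrix(section)
  dx <- as.numeric(xy[, 1] - circle$center[1])
  dy <- as.numeric(xy[, 2] - circle$center[2])
  r <- sqrt(dx^2 + dy^2)
  if (any(r < .Machine$double.eps))
    stop("a point lies exactly at the circle centre; azimuth undefined")
  theta <- (atan2(dy, dx) * 180 / pi) %% 360
  ord <- order(theta)
  structure(list(theta = theta[ord],
                 deviation = (r[ord] - circle$radius) * 1000,
                 radius = circle$radius, n = length(r)),
            class = "unwrapped_profile")
}

#' Fit a periodic Fourier contour model
#'
#' Least-squares fit of
#' `dev(theta) = a0 + sum_k a_k cos(k theta) + b_k sin(k theta)` to an
#' unwrapped profile. The model is 360-degree periodic by construction, so
#' it has no discontinuity at the angular boundary - the reason a global
#' harmonic model is preferred over local smoothers for closed contours.
#'
#' @param profile An [unwrap_to_polar()] result.
#' @param K Number of harmonics; the profile must have at least `2K + 1`
#'   points. Default 8.
#' @return An object of class `fourier_model`: list with `a0`, `a`, `b`
#'   (each in mm) and `K`.
#' @export
fit_fourier <- function(profile, K = 8) {
  stopifnot(inherits(profile, "unwrapped_profile"), K >= 1,
            length(profile$theta) == length(profile$deviation))
  n <- length(profile$theta)
  if (n < 2 * K + 1)
    stop(sprintf("need at least 2K + 1 = %d points for K = %d harmonics, have %d",
                 2 * K + 1, K, n))
  th <- profile$theta * pi / 180
  X <- cbind(1, do.call(cbind, lapply(seq_len(K), function(k)
    cbind(cos(k * th), sin(k * th)))))
  beta <- qr.coef(qr(X), profile$deviation)
  beta[is.na(beta)] <- 0
  structure(list(a0 = beta[1],
                 a = beta[seq(2, 2 * K, by = 2)],
                 b = beta[seq(3, 2 * K + 1, by = 2)],
                 K = as.integer(K)),
            class = "fourier_model")
}

#' Evaluate a Fourier contour model
#'
#' @param model A [fit_fourier()] result.
#' @param theta Angles in degrees.
#' @return Modelled deviations in mm.
#' @export
predict_fourier <- function(model, theta) {
  stopifnot(inherits(model, "fourier_model"))
  th <- theta * pi / 180
  out <- rep(model$a0, length(th))
  for (k in seq_len(model$K))
    out <- out + model$a[k] * cos(k * th) + model$b[k] * sin(k * th)
  out
}

#' 95% residual noise band
#'
#' Residuals are the differences between the unwrapped deviations and the
#' Fourier contour model; the band is the interval containing 95% of them,
#' whose width in millimetres is the per-device noise statistic: systematic
#' shape departures are absorbed by the contour model, so the band width
#' reflects random measurement noise.
#'
#' @param profile The [unwrap_to_polar()] result the model was fitted on.
#' @param model The [fit_fourier()] model.
#' @param method `"central"` (default): the equal-tail 2.5-97.5 percentile
#'   interval; `"shortest"`: the narrowest interval containing 95% of
#'   residuals.
#' @param level Coverage, default 0.95.
#' @return An object of class `noise_band`: list with `width95` (mm),
#'   `n_points`, and `bounds` (lo, hi in mm). A warning is issued below 40
#'   residuals (quantiles unstable), but the band is still computed.
#' @export
residual_band95 <- function(profile, model, method = c("central", "shortest"),
                            level = 0.95) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "unwrapped_profile"))
  res <- profile$deviation - predict_fourier(model, profile$theta)
  n <- length(res)
  if (n < 40L)
    warning("fewer than 40 residuals: the 95% band quantiles are unstable")
  if (method == "central") {
    q <- stats::quantile(res, c((1 - level) / 2, 1 - (1 - level) / 2),
                         names = FALSE, type = 7)
  } else {
    s <- sort(res)
    k <- ceiling(level * n)
    if (k >= n) q <- range(s)
    else {
      w <- s[k:n] - s[1:(n - k + 1)]
      i <- which.min(w)
      q <- c(s[i], s[i + k - 1])
    }
  }
  structure(list(width95 = q[2] - q[1], n_points = n,
                 bounds = c(lo = q[1], hi = q[2])),
            class = "noise_band")
}

#' @export
print.noise_band <- function(x, ...) {
  cat(sprintf("<noise_band> width 95%%: %.2f mm (%d points; [%.2f, %.2f] mm)\n",
              x$width95, x$n_points, x$bounds[1], x$bounds[2]))
  invisible(x)
}

#' Outer-perimeter polygon of a cross-section
#'
#' A deterministic surrogate for manually tracing the outer contour of a
#' stem slice: points are grouped into angular bins about the circle centre,
#' each bin is represented by an upper quantile of its point radii (the
#' outer contour), empty bins are filled by circular interpolation, and the
#' bin representatives are joined into a closed polygon.
#'
#' @param section A [cross_section()].
#' @param circle Optional `fitted_circle`; fitted from the section if `NULL`.
#' @param n_bins Number of angular bins, default 72 (5-degree bins).
#' @param prob Per-bin radius quantile, default 0.9.
#' @param interpolate Fill empty bins by circular interpolation (default
#'   TRUE); with `FALSE`, any empty bin is an error.
#' @param smooth_k Harmonic cutoff for low-pass smoothing of the bin-radius
#'   sequence before the polygon is closed (default 8; 0 disables). A raw
#'   quantile-per-bin contour is jagged under sensor noise and its length
#'   overstates the perimeter; a human tracing the outer contour draws a
#'   smooth outline, which the low-pass step emulates while retaining
#'   genuine low-order shape (ellipticity, lobes) up to harmonic `smooth_k`.
#' @return An object of class `perimeter_polygon`: list with `vertices`
#'   (closed (n_bins + 1) x 2 matrix) and `perimeter` (m).
#' @export
perimeter_polygon <- function(section, circle = NULL, n_bins = 72, prob = 0.9,
                              interpolate = TRUE, smooth_k = 8) {
  xy <- if (inherits(section, "cross_section")) section$points else as.matrix(section)
  if (nrow(xy) == 0L) stop("section has no points")
  if (is.null(circle)) circle <- fit_circle(xy)
  dx <- xy[, 1] - circle$center[1]; dy <- xy[, 2] - circle$center[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- (atan2(dy, dx)) %% (2 * pi)
  bin <- pmin(n_bins, floor(theta / (2 * pi) * n_bins) + 1L)
  occupied <- sort(unique(bin))
  if (length(occupied) <= 1L)
    stop("all points fall in a single angular bin; no perimeter can be traced")
  rad <- rep(NA_real_, n_bins)
  rad[occupied] <- vapply(occupied, function(b)
    stats::quantile(r[bin == b], prob, names = FALSE, type = 7), numeric(1))
  if (anyNA(rad)) {
    if (!interpolate)
      stop(sprintf("%d of %d angular bins are empty and interpolation is disabled",
                   sum(is.na(rad)), n_bins))
    # circular linear interpolation across empty bins
    idx <- which(!is.na(rad))
    ext_x <- c(idx - n_bins, idx, idx + n_bins)
    ext_y <- rep(rad[idx], 3)
    rad <- stats::approx(ext_x, ext_y, xout = seq_len(n_bins))$y
  }
  if (smooth_k > 0 && smooth_k < floor((n_bins - 1) / 2)) {
    f <- stats::fft(rad)
    f[(smooth_k + 2):(n_bins - smooth_k)] <- 0
    rad <- Re(stats::fft(f, inverse = TRUE)) / n_bins
  }
  ang <- (seq_len(n_bins) - 0.5) / n_bins * 2 * pi
  vx <- circle$center[1] + rad * cos(ang)
  vy <- circle$center[2] + rad * sin(ang)
  verts <- cbind(x = c(vx, vx[1]), y = c(vy, vy[1]))
  per <- sum(sqrt(diff(verts[, 1])^2 + diff(verts[, 2])^2))
  structure(list(vertices = verts, perimeter = per),
            class = "perimeter_polygon")
}

#' Diameter from perimeter
#'
#' Converts a traced outer-perimeter length to an equivalent circular
#' diameter, reported in centimetres.
#'
#' @param poly A [perimeter_polygon()] (or a bare perimeter length in m).
#' @return Diameter in cm.
#' @export
dbh_from_perimeter <- function(poly) {
  per <- if (inherits(poly, "perimeter_polygon")) poly$perimeter else as.double(poly)
  if (!is.finite(per) || per <= 0) stop("perimeter must be > 0")
  per / pi * 100
}

#' Per-stem DBH estimates from a point cloud
#'
#' Convenience pipeline: extract the breast-height slice, match the resulting
#' sections to known stem positions, and for each detected stem fit the
#' reference circle, trace the outer-perimeter polygon and convert its length
#' to a diameter.
#'
#' @inheritParams extract_dbh_slice
#' @param stem_xy n x 2 matrix of stem positions (m).
#' @param n_bins,prob Passed to [perimeter_polygon()].
#' @param max_dist Matching distance for [match_sections_to_stems()].
#' @return Data frame with one row per stem: `x`, `y`, `detected`,
#'   `n_points`, `dbh_cm` (`NA` when undetected).
#' @export
stem_diameters <- function(cloud, stem_xy, ground = 0, center_height = 1.325,
                           thickness = 0.05, cluster_dist = 0.3, n_bins = 72,
                           prob = 0.9, max_dist = 1) {
  if (is.null(dim(stem_xy))) stem_xy <- matrix(stem_xy, ncol = 2)
  sections <- extract_dbh_slice(cloud, ground, center_height, thickness,
                                cluster_dist)
  m <- match_sections_to_stems(sections, stem_xy, max_dist)
  out <- data.frame(x = stem_xy[, 1], y = stem_xy[, 2],
                    detected = FALSE, n_points = 0L, dbh_cm = NA_real_)
  for (i in seq_len(nrow(stem_xy))) {
    if (is.na(m[i])) next
    sec <- sections[[m[i]]]
    out$n_points[i] <- sec$n
    if (!sec$detected) next
    est <- tryCatch({
      circ <- fit_circle(sec)
      poly <- perimeter_polygon(sec, circ, n_bins = n_bins, prob = prob)
      dbh_from_perimeter(poly)
    }, error = function(e) NA_real_)
    if (!is.na(est)) {
      out$detected[i] <- TRUE
      out$dbh_cm[i] <- est
    }
  }
  out
}

#' Cross-section noise band in one call
#'
#' Fits the reference circle, unwraps the section, fits the Fourier contour
#' model and returns the 95% residual band.
#'
#' @param section A [cross_section()].
#' @param K Number of harmonics, default 8.
#' @param method Band type, see [residual_band95()].
#' @return A `noise_band`.
#' @export
section_noise_band <- function(section, K = 8, method = "central") {
  circ <- fit_circle(section)
  prof <- unwrap_to_polar(section, circ)
  mod <- fit_fourier(prof, K = K)
  residual_band95(prof, mod, method = method)
}
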