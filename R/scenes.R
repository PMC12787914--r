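#' Tube specification
#'
#' An upright cylinder standing on the floor, as used in the indoor
#' calibration scene.
#'
#' @param id Character label.
#' @param diameter Outside diameter in centimetres, > 0.
#' @param length Tube length in centimetres, > 0.
#' @param center_xy Numeric length-2 footprint centre (m).
#' @param base_z Base elevation (m), default 0.
#' @return An object of class `tube_spec`.
#' @export
tube_spec <- function(id, diameter, length, center_xy, base_z = 0) {
  if (!is.numeric(diameter) || diameter <= 0) stop("`diameter` must be > 0")
  if (!is.numeric(length) || length <= 0) stop("`length` must be > 0")
  center_xy <- as.double(center_xy)
  if (base::length(center_xy) != 2L) stop("`center_xy` must have length 2")
  structure(list(id = as.character(id), diameter = as.double(diameter),
                 length = as.double(length), center_xy = center_xy,
                 base_z = as.double(base_z)),
            class = "tube_spec")
}

#' Tree specification
#'
#' A simple parametric tree: a tapered conical stem carrying the breast-height
#' diameter, plus a conical crown whose apex defines the tree top.
#'
#' @param id Character label.
#' @param dbh Diameter at breast height (1.3 m) in centimetres, > 0.
#' @param height Total tree height in metres.
#' @param stem_xy Numeric length-2 stem position (m).
#' @param taper Relative diameter shrink per metre of height (fraction of the
#'   breast-height diameter lost per metre). The default 0.2/1.3 makes the
#'   base diameter 1.2 x DBH.
#' @param crown_radius Crown radius (m) at the crown base.
#' @param crown_base Height (m) of the crown base; must satisfy
#'   `height > crown_base >= 0`.
#' @return An object of class `tree_spec`.
#' @export
tree_spec <- function(id, dbh, height, stem_xy, taper = 0.2 / 1.3,
                      crown_radius = 1.5, crown_base = 0.5 * height) {
  if (!is.numeric(dbh) || dbh <= 0) stop("`dbh` must be > 0")
  if (!is.numeric(height) || !is.numeric(crown_base) ||
      crown_base < 0 || height <= crown_base)
    stop("must have height > crown_base >= 0")
  if (!is.numeric(taper) || taper <= 0) stop("`taper` must be > 0")
  if (!is.numeric(crown_radius) || crown_radius <= 0)
    stop("`crown_radius` must be > 0")
  stem_xy <- as.double(stem_xy)
  if (length(stem_xy) != 2L) stop("`stem_xy` must have length 2")
  structure(list(id = as.character(id), dbh = as.double(dbh),
                 height = as.double(height), stem_xy = stem_xy,
                 taper = as.double(taper), crown_radius = as.double(crown_radius),
                 crown_base = as.double(crown_base)),
            class = "tree_spec")
}

#' Reference tube table for the indoor calibration scene
#'
#' The twelve calibration tubes used throughout the package's worked
#' examples: diameters 2.6-50.5 cm, lengths 100-290 cm, laid out on a fixed
#' non-overlapping grid inside a 7 x 7 m floor.
#'
#' @return A data frame with columns `id`, `diameter` (cm), `length` (cm),
#'   `x`, `y` (m).
#' @export
lab_tube_table <- function() {
  xs <- rep(c(0.9, 2.65, 4.4, 6.15), 3)
  ys <- rep(c(1.2, 3.5, 5.8), each = 4)
  data.frame(
    id = sprintf("ID%02d", 1:12),
    diameter = c(11.10, 16.00, 16.00, 16.00, 16.00, 16.00,
                 16.00, 25.30, 25.30, 50.50, 2.60, 2.60),
    length = c(145, 100, 100, 100, 100, 100, 100, 180, 158, 216, 290, 290),
    x = xs, y = ys,
    stringsAsFactors = FALSE
  )
}

#' Build the indoor calibration scene
#'
#' Upright tubes on a flat floor at z = 0. The default table is
#' [lab_tube_table()].
#'
#' @param tube_table Data frame with columns `id`, `diameter` (cm),
#'   `length` (cm), `x`, `y` (m); must be non-empty, with positive sizes and
#'   pairwise non-overlapping footprints.
#' @return A `scene` object: list with `objects` (list of [tube_spec()]),
#'   `ground_z` and `extent`.
#' @export
make_lab_scene <- function(tube_table = lab_tube_table()) {
  if (!is.data.frame(tube_table) || nrow(tube_table) == 0L)
    stop("`tube_table` must be a non-empty data frame")
  need <- c("id", "diameter", "length", "x", "y")
  miss <- setdiff(need, names(tube_table))
  if (length(miss) > 0L)
    stop("`tube_table` is missing columns: ", paste(miss, collapse = ", "))
  if (any(tube_table$diameter <= 0) || any(tube_table$length <= 0))
    stop("tube diameters and lengths must be positive")
  n <- nrow(tube_table)
  if (n > 1L) {
    r <- tube_table$diameter / 200  # cm -> m radius
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- sqrt((tube_table$x[i] - tube_table$x[j])^2 +
                (tube_table$y[i] - tube_table$y[j])^2)
      if (d < r[i] + r[j])
        stop(sprintf("tubes %s and %s have overlapping footprints",
                     tube_table$id[i], tube_table$id[j]))
    }
  }
  objects <- lapply(seq_len(n), function(i)
    tube_spec(tube_table$id[i], tube_table$diameter[i], tube_table$length[i],
              c(tube_table$x[i], tube_table$y[i])))
  structure(list(objects = objects, ground_z = 0,
                 extent = c(xmin = min(tube_table$x) - 1, xmax = max(tube_table$x) + 1,
                            ymin = min(tube_table$y) - 1, ymax = max(tube_table$y) + 1)),
            class = "scene")
}

#' Generate a synthetic plantation scene
#'
#' A rectangular grid of trees at fixed spacing on flat ground. Breast-height
#' diameters are lognormal with the requested mean and standard deviation;
#' heights follow the standard allometric form
#' `TH = a + b * log(DBH) + noise`, with the intercept chosen so the mean
#' height matches `th_mean`.
#'
#' @param n_rows,n_cols Grid dimensions; their product must be >= 1.
#' @param spacing Grid spacing in metres, > 0 (plantation default 4 m).
#' @param dbh_mean,dbh_sd Mean and SD of DBH in cm (defaults 25.6 and 4.0).
#' @param th_mean,th_sd Mean tree height (m) and residual SD about the
#'   allometric curve (defaults 15.7 and 0.5).
#' @param b_allom Allometric slope on `log(DBH)` (m per log-cm), default 6.
#' @param crown_radius Crown radius in metres, default 1.5.
#' @param crown_base_frac Crown base as a fraction of tree height, default 0.5.
#' @param seed Integer seed; identical seeds give identical scenes.
#' @return A `scene` object with `objects` a list of [tree_spec()].
#' @export
make_plantation_scene <- function(n_rows, n_cols, spacing = 4,
                                  dbh_mean = 25.6, dbh_sd = 4.0,
                                  th_mean = 15.7, th_sd = 0.5, b_allom = 6,
                                  crown_radius = 1.5, crown_base_frac = 0.5,
                                  seed = 1) {
  if (!is.numeric(n_rows) || !is.numeric(n_cols) || n_rows < 1 || n_cols < 1)
    stop("`n_rows` and `n_cols` must be >= 1")
  if (!is.numeric(spacing) || spacing <= 0) stop("`spacing` must be > 0")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n <- n_rows * n_cols
  # lognormal parameterized by arithmetic mean/sd
  sdlog <- sqrt(log(1 + (dbh_sd / dbh_mean)^2))
  meanlog <- log(dbh_mean) - sdlog^2 / 2
  a_allom <- th_mean - b_allom * meanlog
  with_seed(seed, {
    dbh <- exp(stats::rnorm(n, meanlog, sdlog))
    th <- a_allom + b_allom * log(dbh) + stats::rnorm(n, 0, th_sd)
  })
  ix <- rep(seq_len(n_cols), times = n_rows)
  iy <- rep(seq_len(n_rows), each = n_cols)
  objects <- lapply(seq_len(n), function(i) {
    h <- max(th[i], 2)  # guard against pathological draws at extreme settings
    tree_spec(sprintf("T%03d", i), dbh = dbh[i], height = h,
              stem_xy = c((ix[i] - 1) * spacing, (iy[i] - 1) * spacing),
              crown_radius = crown_radius, crown_base = crown_base_frac * h)
  })
  structure(list(objects = objects, ground_z = 0,
                 extent = c(xmin = -spacing, xmax = (n_cols - 1) * spacing + spacing,
                            ymin = -spacing, ymax = (n_rows - 1) * spacing + spacing)),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  kinds <- table(vapply(x$objects, function(o) class(o)[1], character(1)))
  cat("<scene>", paste(sprintf("%d %s(s)", kinds, names(kinds)), collapse = ", "),
      sprintf("on flat ground z = %g\n", x$ground_z))
  invisible(x)
}

#' True object positions, diameters and heights of a scene
#'
#' Accessors for the ground truth a synthetic scene carries: object centre
#' positions (n x 2 matrix, m), reference diameters (tube diameter or tree
#' DBH, cm) and reference heights (tube length or tree height, m).
#'
#' @param scene A `scene`.
#' @return See description; one entry/row per scene object.
#' @export
scene_positions <- function(scene) {
  do.call(rbind, lapply(scene$objects, function(o)
    if (inherits(o, "tube_spec")) o$center_xy else o$stem_xy))
}

#' @rdname scene_positions
#' @export
scene_diameters <- function(scene) {
  vapply(scene$objects, function(o)
    if (inherits(o, "tube_spec")) o$diameter else o$dbh, numeric(1))
}

#' @rdname scene_positions
#' @export
scene_heights <- function(scene) {
  vapply(scene$objects, function(o)
    if (inherits(o, "tube_spec")) o$length / 100 else o$height, numeric(1))
}
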