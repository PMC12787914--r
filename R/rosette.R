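#' Rosette (non-repetitive) scan directions
#'
#' Generates the direction sequence of a two-frequency rosette beam-steering
#' pattern. Each angular axis follows the sum of two cosines whose frequency
#' ratio is irrational (sqrt(2)), so successive sweeps never retrace and the
#' angular coverage keeps growing with dwell time - a qualitative stand-in
#' for prism-pair scanners, validated through its coverage behaviour rather
#' than against any particular device's kinematics.
#'
#' @param profile A [device_profile()] with `pattern == "rosette"`.
#' @param duration Dwell time in seconds; must be >= 0 (0 gives an empty
#'   direction set, negative durations are an error).
#' @param seed Integer seed controlling the pattern phases; the direction
#'   sequence is deterministic given (profile, duration, seed).
#' @return An n x 3 matrix of unit direction vectors in the sensor frame
#'   (+x boresight), with `n = floor(points_per_second * duration)`. All
#'   directions lie inside the profile's angular field of view.
#' @export
rosette_directions <- function(profile, duration, seed = 1) {
  stopifnot(inherits(profile, "device_profile"))
  if (profile$pattern != "rosette")
    stop("`profile` must have pattern 'rosette'")
  scan_directions(profile, duration, seed)
}

# Direction sequence for any supported pattern; n = floor(pps * duration).
scan_directions <- function(profile, duration, seed = 1) {
  stopifnot(inherits(profile, "device_profile"))
  if (!is.numeric(duration) || duration < 0)
    stop("`duration` must be non-negative")
  n <- floor(profile$points_per_second * duration)
  if (n == 0L) return(matrix(numeric(0), ncol = 3,
                             dimnames = list(NULL, c("x", "y", "z"))))
  t <- (seq_len(n) - 0.5) / profile$points_per_second
  half_h <- profile$fov_h / 2
  half_v <- profile$fov_v / 2
  ae <- switch(profile$pattern,
    rosette = {
      # base frequencies: incommensurate pairs per axis, distinct across axes
      f <- 50 * c(1, sqrt(2), sqrt(3), sqrt(6))
      ph <- with_seed(seed, stats::runif(4, 0, 2 * pi))
      az <- (half_h / 2) * (cos(2 * pi * f[1] * t + ph[1]) +
                            cos(2 * pi * f[2] * t + ph[2]))
      el <- (half_v / 2) * (cos(2 * pi * f[3] * t + ph[3]) +
                            cos(2 * pi * f[4] * t + ph[4]))
      cbind(az, el)
    },
    raster_lines = {
      # one azimuth sweep across the FOV with a fast vertical triangle wave
      ph <- with_seed(seed, stats::runif(1))
      az <- -half_h + profile$fov_h * (seq_len(n) - 0.5) / n
      saw <- ((100 * t + ph) %% 1)
      el <- half_v * (2 * abs(2 * saw - 1) - 1)
      cbind(az, el)
    },
    uniform = {
      # solid-angle-uniform directions within the FOV window
      with_seed(seed, {
        az <- stats::runif(n, -half_h, half_h)
        s <- sin(half_v * pi / 180)
        el <- asin(stats::runif(n, -s, s)) * 180 / pi
        cbind(az, el)
      })
    })
  az <- ae[, 1] * pi / 180
  el <- ae[, 2] * pi / 180
  cbind(x = cos(el) * cos(az), y = cos(el) * sin(az), z = sin(el))
}

#' Angular coverage fraction of a direction set
#'
#' Fraction of cells of an `n_grid` x `n_grid` azimuth-elevation grid spanning
#' the profile's field of view that contain at least one direction. Used to
#' check that non-repetitive patterns keep filling the FOV as dwell time
#' grows.
#'
#' @param directions Matrix of unit direction vectors (sensor frame).
#' @param profile The [device_profile()] that produced them.
#' @param n_grid Grid resolution per axis, default 100.
#' @return Coverage fraction in [0, 1].
#' @export
coverage_fraction <- function(directions, profile, n_grid = 100) {
  if (nrow(directions) == 0L) return(0)
  az <- atan2(directions[, 2], directions[, 1]) * 180 / pi
  el <- asin(pmin(1, pmax(-1, directions[, 3]))) * 180 / pi
  ix <- pmin(n_grid, pmax(1, ceiling((az + profile$fov_h / 2) / profile$fov_h * n_grid)))
  iy <- pmin(n_grid, pmax(1, ceiling((el + profile$fov_v / 2) / profile$fov_v * n_grid)))
  length(unique(ix + n_grid * (iy - 1L))) / (n_grid * n_grid)
}
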