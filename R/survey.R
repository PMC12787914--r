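# Per-plot acquisition time (s) by device, mirroring the relative field
# effort of each device class: a multi-setup tripod scan is slow, a handheld
# walk is fast, the smartphone walk is in between. Simulated surveys scale
# these down by `time_scale` to keep ray counts tractable.
acquisition_time <- c(riegl = 1260, stonex = 240, lca_tls = 780, iphone = 480)

#' Device-appropriate pose plan for a plot survey
#'
#' Builds the scan poses a field crew would use for each device class on a
#' rectangular plot: tripod scanners (riegl, stonex) scan from the four plot
#' corners; the narrow-FOV rosette scanner (lca_tls) uses the corners with
#' two inward-pointing orientations each (its field of view cannot cover the
#' plot in one setup); the smartphone (iphone) is walked along lanes between
#' the tree rows, pointing alternately at the adjacent rows, with the
#' profile's default registration jitter attached to every scan (its scans
#' are merged without SLAM).
#'
#' @param device One of `"riegl"`, `"stonex"`, `"lca_tls"`, `"iphone"`.
#' @param scene The plot `scene` (stem positions define the plot extent).
#' @param time_scale Divisor applied to the device's nominal per-plot
#'   acquisition time; the scaled time is split evenly across poses.
#'   Default 200.
#' @param height Scanner height (m) for tripod devices, default 1.5.
#' @return List of [scan_pose()] objects.
#' @export
survey_poses <- function(device, scene, time_scale = 200, height = 1.5) {
  stopifnot(device %in% names(acquisition_time), inherits(scene, "scene"))
  pos <- scene_positions(scene)
  xr <- range(pos[, 1]); yr <- range(pos[, 2])
  total <- acquisition_time[[device]] / time_scale
  jit <- default_registration_jitter(device)
  if (device %in% c("riegl", "stonex")) {
    corners <- rbind(c(xr[1] - 2, yr[1] - 2), c(xr[2] + 2, yr[1] - 2),
                     c(xr[2] + 2, yr[2] + 2), c(xr[1] - 2, yr[2] + 2))
    return(lapply(seq_len(4), function(i)
      scan_pose(c(corners[i, ], height), duration = total / 4,
                jitter_t = jit[1], jitter_r = jit[2])))
  }
  if (device == "lca_tls") {
    corners <- rbind(c(xr[1] - 2, yr[1] - 2), c(xr[2] + 2, yr[1] - 2),
                     c(xr[2] + 2, yr[2] + 2), c(xr[1] - 2, yr[2] + 2))
    center <- c(mean(xr), mean(yr))
    poses <- list()
    for (i in seq_len(4)) for (dyaw in c(-18, 18)) {
      yaw <- atan2(center[2] - corners[i, 2], center[1] - corners[i, 1]) * 180 / pi
      poses[[length(poses) + 1L]] <-
        scan_pose(c(corners[i, ], height), yaw = yaw + dyaw,
                  duration = total / 8, jitter_t = jit[1], jitter_r = jit[2])
    }
    return(poses)
  }
  # iphone: walking lanes between rows, two sideways looks per station
  rows_y <- sort(unique(round(pos[, 2], 6)))
  lanes <- c(rows_y[1] - 1.5,
             if (length(rows_y) > 1) (rows_y[-1] + rows_y[-length(rows_y)]) / 2,
             rows_y[length(rows_y)] + 1.5)
  xs <- seq(xr[1] - 1, xr[2] + 1, by = 2)
  n <- length(lanes) * length(xs) * 2
  poses <- list()
  for (ly in lanes) for (x in xs) for (yaw in c(90, -90)) {
    poses[[length(poses) + 1L]] <-
      scan_pose(c(x, ly, 1.3), yaw = yaw, duration = total / n,
                jitter_t = jit[1], jitter_r = jit[2])
  }
  poses
}

#' Simulate a canopy-height survey of a plot
#'
#' Combined acquisition designed for terrain-and-surface modelling: tripod
#' scans around the plot perimeter (which see the ground under the crowns)
#' plus a grid of overhead scans extending beyond the plot corners (which
#' see every crown apex from opposing directions). The merged cloud is
#' clipped to the plot plus a 2 m margin, ready for [terrain_models()].
#'
#' @param scene A plantation `scene`.
#' @param seed Integer master seed.
#' @param range_sigma Radial noise (m) of the simulated scanner, default 0.
#' @param pps_ground,pps_air Emission rates for the perimeter and overhead
#'   scans (defaults 2.5e5 and 4e5; one scan second each).
#' @param z_air Overhead scanner altitude (m), default 35.
#' @return A clipped, merged [point_cloud()].
#' @export
simulate_canopy_survey <- function(scene, seed = 1, range_sigma = 0,
                                   pps_ground = 2.5e5, pps_air = 4e5,
                                   z_air = 35) {
  pos <- scene_positions(scene)
  xr <- range(pos[, 1]); yr <- range(pos[, 2])
  mx <- mean(xr); my <- mean(yr)
  tls <- device_profile("canopy_survey", pps_ground, 360, 100, range_sigma,
                        200, pattern = "uniform")
  air <- device_profile("canopy_survey", pps_air, 100, 100, range_sigma,
                        200, pattern = "uniform")
  stations <- rbind(c(xr[1] - 2, yr[1] - 2), c(mx, yr[1] - 2),
                    c(xr[2] + 2, yr[1] - 2), c(xr[2] + 2, my),
                    c(xr[2] + 2, yr[2] + 2), c(mx, yr[2] + 2),
                    c(xr[1] - 2, yr[2] + 2), c(xr[1] - 2, my))
  gposes <- lapply(seq_len(nrow(stations)), function(i)
    scan_pose(c(stations[i, ], 1.5), duration = 0.5))
  oposes <- list()
  for (x in c(xr[1] - 4, mx, xr[2] + 4)) for (y in c(yr[1] - 4, my, yr[2] + 4))
    oposes[[length(oposes) + 1L]] <- scan_pose(c(x, y, z_air), pitch = -90,
                                               duration = 1)
  cl <- merge_scans(list(
    simulate_survey(scene, gposes, tls, seed = derive_seed(seed, 301L)),
    simulate_survey(scene, oposes, air, seed = derive_seed(seed, 302L))))
  clip_cloud(cl, xr + c(-2, 2), yr + c(-2, 2))
}

#' Simulated per-device DBH benchmark on one plot
#'
#' Runs the full chain for each device: pose plan, multi-scan survey,
#' breast-height slice, circle fit, perimeter polygon, DBH - then scores the
#' estimates against the scene's true breast-height diameters. Stems the
#' device failed to detect are excluded from RMSE and bias (but reported).
#'
#' @param scene A plantation `scene`.
#' @param profiles Named list of [device_profile()]s, default
#'   [default_profiles()].
#' @param seed Integer master seed.
#' @param time_scale Passed to [survey_poses()].
#' @return Data frame with one row per device: `device`, `n_detected`,
#'   `n_stems`, `rmse_cm`, `bias_cm`.
#' @export
device_dbh_benchmark <- function(scene, profiles = default_profiles(),
                                 seed = 1, time_scale = 200) {
  stems <- scene_positions(scene)
  truth <- scene_diameters(scene)
  rows <- lapply(names(profiles), function(dev) {
    poses <- survey_poses(dev, scene, time_scale = time_scale)
    cloud <- simulate_survey(scene, poses, profiles[[dev]],
                             seed = derive_seed(seed, match(dev, names(profiles))))
    est <- stem_diameters(cloud, stems, ground = scene$ground_z)
    err <- est$dbh_cm - truth
    det <- est$detected & !is.na(err)
    data.frame(device = dev, n_detected = sum(det), n_stems = length(truth),
               rmse_cm = if (any(det)) rmse(err[det]) else NA_real_,
               bias_cm = if (any(det)) bias(err[det]) else NA_real_)
  })
  do.call(rbind, rows)
}
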