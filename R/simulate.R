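# Rotation matrix from yaw/pitch/roll in degrees. Boresight is +x; yaw about
# +z (CCW from above), positive pitch tilts the boresight upward, roll about
# the boresight. Applied as R = Rz(yaw) Ry(-pitch) Rx(roll).
rotation_matrix <- function(yaw, pitch, roll) {
  d2r <- pi / 180
  cy <- cos(yaw * d2r);  sy <- sin(yaw * d2r)
  cp <- cos(-pitch * d2r); sp <- sin(-pitch * d2r)
  cr <- cos(roll * d2r); sr <- sin(roll * d2r)
  Rz <- matrix(c(cy, sy, 0, -sy, cy, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cp, 0, -sp, 0, 1, 0, sp, 0, cp), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cr, sr, 0, -sr, cr), 3, 3)
  Rz %*% Ry %*% Rx
}

# Nearest positive ray parameter against a finite vertical cylinder.
ray_cylinder <- function(o, D, center, radius, z0, z1, eps = 1e-9) {
  px <- o[1] - center[1]; py <- o[2] - center[2]
  a <- D[, 1]^2 + D[, 2]^2
  b <- 2 * (px * D[, 1] + py * D[, 2])
  cc <- px^2 + py^2 - radius^2
  disc <- b^2 - 4 * a * cc
  t_best <- rep(Inf, nrow(D))
  ok <- disc >= 0 & a > eps
  if (!any(ok)) return(t_best)
  sq <- sqrt(pmax(disc[ok], 0))
  for (sgn in c(-1, 1)) {
    t <- (-b[ok] + sgn * sq) / (2 * a[ok])
    z <- o[3] + t * D[ok, 3]
    valid <- t > eps & z >= z0 & z <= z1
    t_best[ok][valid] <- pmin(t_best[ok][valid], t[valid])
  }
  t_best
}

# Nearest positive ray parameter against a vertical cone: radius
# slope*(apex_z - z), restricted to z in [zlo, zhi] (zhi <= apex_z).
ray_cone <- function(o, D, apex_xy, apex_z, slope, zlo, zhi, eps = 1e-9) {
  px <- o[1] - apex_xy[1]; py <- o[2] - apex_xy[2]; w <- apex_z - o[3]
  a <- D[, 1]^2 + D[, 2]^2 - slope^2 * D[, 3]^2
  b <- 2 * (px * D[, 1] + py * D[, 2] + slope^2 * w * D[, 3])
  cc <- px^2 + py^2 - slope^2 * w^2
  t_best <- rep(Inf, nrow(D))
  quad <- abs(a) > eps
  disc <- b^2 - 4 * a * cc
  ok <- quad & disc >= 0
  if (any(ok)) {
    sq <- sqrt(pmax(disc[ok], 0))
    for (sgn in c(-1, 1)) {
      t <- (-b[ok] + sgn * sq) / (2 * a[ok])
      z <- o[3] + t * D[ok, 3]
      valid <- t > eps & z >= zlo & z <= zhi
      t_best[ok][valid] <- pmin(t_best[ok][valid], t[valid])
    }
  }
  lin <- !quad & abs(b) > eps
  if (any(lin)) {
    t <- -cc / b[lin]
    z <- o[3] + t * D[lin, 3]
    valid <- t > eps & z >= zlo & z <= zhi
    t_best[lin][valid] <- pmin(t_best[lin][valid], t[valid])
  }
  t_best
}

# Bounding sphere (center, radius) of a scene object, for ray prefiltering.
object_bound <- function(obj) {
  if (inherits(obj, "tube_spec")) {
    h <- obj$length / 100
    list(center = c(obj$center_xy, obj$base_z + h / 2),
         radius = sqrt((obj$diameter / 200)^2 + (h / 2)^2))
  } else {
    r <- max(obj$dbh / 200 * (1 + 1.3 * obj$taper), obj$crown_radius)
    list(center = c(obj$stem_xy, obj$height / 2),
         radius = sqrt(r^2 + (obj$height / 2)^2))
  }
}

# Ray parameters for one scene object (tube or tree); Inf where missed.
ray_object <- function(o, D, obj) {
  if (inherits(obj, "tube_spec")) {
    ray_cylinder(o, D, obj$center_xy, obj$diameter / 200,
                 obj$base_z, obj$base_z + obj$length / 100)
  } else if (inherits(obj, "tree_spec")) {
    r_bh <- obj$dbh / 200
    stem_apex <- 1.3 + 1 / obj$taper
    t_stem <- ray_cone(o, D, obj$stem_xy, stem_apex, r_bh * obj$taper,
                       0, min(stem_apex - 1e-9, obj$height))
    k <- obj$crown_radius / (obj$height - obj$crown_base)
    t_crown <- ray_cone(o, D, obj$stem_xy, obj$height, k,
                        obj$crown_base, obj$height)
    pmin(t_stem, t_crown)
  } else stop("unsupported scene object of class ", class(obj)[1])
}

#' Simulate one scan of a scene
#'
#' Ray-casts the device's direction sequence from a scan pose against the
#' scene's ground plane and object surfaces (cylindrical tubes, conical stems
#' and crowns). The first hit within the device's maximum range is kept, its
#' range is perturbed by Gaussian noise of the profile's `range_sigma`,
#' Bernoulli dropout is applied, and objects thinner than the profile's
#' detection floor return no hits at all. The resulting points are expressed
#' in the scene frame; if the pose carries registration jitter, a small rigid
#' perturbation (rotation about the scanner position plus a translation) is
#' applied to the whole scan, emulating residual registration error.
#'
#' @param scene A `scene` from [make_lab_scene()] or [make_plantation_scene()].
#' @param pose A [scan_pose()].
#' @param profile A [device_profile()].
#' @param seed Integer seed; identical (scene, pose, profile, seed) give
#'   bit-identical clouds.
#' @param scan_id Optional scan label stored per point.
#' @return A [point_cloud()] in the scene frame.
#' @export
simulate_scan <- function(scene, pose, profile, seed = 1, scan_id = NULL) {
  stopifnot(inherits(scene, "scene"), inherits(pose, "scan_pose"),
            inherits(profile, "device_profile"))
  if (length(scene$objects) == 0L) stop("scene has no objects")
  D <- scan_directions(profile, pose$duration, derive_seed(seed, 1L))
  if (nrow(D) == 0L)
    return(point_cloud(matrix(numeric(0), ncol = 3),
                       device = profile$name, scan_id = scan_id))
  R <- rotation_matrix(pose$yaw, pose$pitch, pose$roll)
  D <- D %*% t(R)
  o <- pose$position

  t_min <- rep(Inf, nrow(D))
  for (obj in scene$objects) {
    dia_m <- if (inherits(obj, "tube_spec")) obj$diameter / 100 else obj$dbh / 100
    if (dia_m < profile$detection_floor_diameter) next  # censored object
    # bounding-sphere prefilter: only solve the surface equations for rays
    # whose direction cone can intersect the object at all
    bnd <- object_bound(obj)
    v <- bnd$center - o
    d2 <- sum(v^2)
    rb <- bnd$radius * 1.02
    if (d2 > rb^2) {
      cosa <- sqrt(max(0, 1 - rb^2 / d2))
      cand <- which(as.vector(D %*% v) / sqrt(d2) >= cosa)
    } else cand <- seq_len(nrow(D))
    if (length(cand) == 0L) next
    tc <- ray_object(o, D[cand, , drop = FALSE], obj)
    upd <- tc < t_min[cand]
    t_min[cand[upd]] <- tc[upd]
  }
  down <- D[, 3] < -1e-12
  t_ground <- rep(Inf, nrow(D))
  t_ground[down] <- (scene$ground_z - o[3]) / D[down, 3]
  t_min <- pmin(t_min, t_ground)

  hit <- is.finite(t_min) & t_min <= profile$max_range
  t_hit <- t_min[hit]
  Dh <- D[hit, , drop = FALSE]
  xyz <- with_seed(derive_seed(seed, 2L), {
    if (profile$range_sigma > 0)
      t_hit <- t_hit + stats::rnorm(length(t_hit), 0, profile$range_sigma)
    if (profile$dropout_rate > 0) {
      keep <- stats::runif(length(t_hit)) >= profile$dropout_rate
      t_hit <- t_hit[keep]; Dh <- Dh[keep, , drop = FALSE]
    }
    pts <- cbind(o[1] + t_hit * Dh[, 1], o[2] + t_hit * Dh[, 2],
                 o[3] + t_hit * Dh[, 3])
    if (pose$jitter_t > 0 || pose$jitter_r > 0) {
      ang <- stats::rnorm(3, 0, pose$jitter_r)
      dt <- stats::rnorm(3, 0, pose$jitter_t)
      Rj <- rotation_matrix(ang[1], ang[2], ang[3])
      pts <- sweep(pts, 2, o) %*% t(Rj)
      pts <- sweep(pts, 2, o + dt, "+")
    }
    pts
  })
  point_cloud(xyz, device = profile$name, scan_id = scan_id)
}

#' Simulate a multi-scan survey and merge it
#'
#' Runs [simulate_scan()] for each pose with a per-scan seed derived from the
#' master seed and merges the scans into one registered cloud.
#'
#' @param scene A `scene`.
#' @param poses List of [scan_pose()] objects.
#' @param profile A [device_profile()].
#' @param seed Integer master seed.
#' @return A merged [point_cloud()] with per-point scan labels.
#' @export
simulate_survey <- function(scene, poses, profile, seed = 1) {
  stopifnot(is.list(poses), length(poses) > 0L)
  clouds <- lapply(seq_along(poses), function(i)
    simulate_scan(scene, poses[[i]], profile, seed = derive_seed(seed, 100L + i),
                  scan_id = sprintf("scan%02d", i)))
  merge_scans(clouds)
}
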