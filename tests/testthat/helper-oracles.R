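# Synthetic cross-section: n points on a circle of radius R (m) with radial
# Gaussian noise sigma (m), optionally restricted to an azimuth arc (deg).
circle_section <- function(n, R = 0.128, sigma = 0, center = c(0, 0),
                           arc = c(0, 360), theta = NULL) {
  if (is.null(theta)) theta <- runif(n, arc[1], arc[2]) * pi / 180
  else theta <- theta * pi / 180
  r <- R + if (sigma > 0) rnorm(length(theta), 0, sigma) else 0
  cross_section(cbind(center[1] + r * cos(theta), center[2] + r * sin(theta)),
                band = c(1.30, 1.35))
}

# Brute-force least-squares circle fit by iteratively refined grid search
# over (cx, cy, r); independent of the algebraic fit under test.
grid_circle_fit <- function(xy, center0, r0, span = 0.02, steps = 3) {
  best <- c(center0, r0)
  obj <- function(p) {
    d <- sqrt((xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2)
    sum((d - p[3])^2)
  }
  for (s in seq_len(steps)) {
    g <- seq(-span, span, length.out = 11)
    cand <- expand.grid(cx = best[1] + g, cy = best[2] + g, r = best[3] + g)
    vals <- apply(cand, 1, obj)
    best <- as.numeric(cand[which.min(vals), ])
    span <- span / 5
  }
  list(center = best[1:2], radius = best[3], resolution = span * 5 / 10)
}

# Circumcircle of three points from the perpendicular-bisector construction.
circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
         (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
         (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
}

# Printed values of the packaged laboratory benchmark tables.
lab_printed <- list(
  diameter = list(rmse = c(iphone = 1.76, lca_tls = 1.23, riegl = 0.62, stonex = 1.47),
                  bias = c(iphone = 1.17, lca_tls = 1.03, riegl = 0.60, stonex = 1.28)),
  height = list(rmse = c(iphone = 38.02, lca_tls = 5.21, riegl = 2.41, stonex = 7.36),
                bias = c(iphone = -16.06, lca_tls = 4.48, riegl = 2.19, stonex = 6.37))
)
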