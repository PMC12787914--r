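test_that("the height band keeps the expected fraction of a uniform stem", {
  # cylinder surface sampled uniformly over 0-2 m; band [1.30, 1.35) keeps
  # 5 cm / 2 m = 2.5% of points (oracle: direct height-filter count)
  set.seed(4)
  n <- 2e5
  th <- runif(n, 0, 2 * pi); z <- runif(n, 0, 2)
  cl <- point_cloud(cbind(0.1 * cos(th), 0.1 * sin(th), z))
  secs <- extract_dbh_slice(cl, ground = 0, center_height = 1.325,
                            thickness = 0.05)
  oracle <- sum(z >= 1.30 & z < 1.35)
  expect_length(secs, 1L)
  expect_equal(secs[[1]]$n, oracle)
  expect_equal(secs[[1]]$n / n, 0.025, tolerance = 0.05)
  expect_equal(secs[[1]]$band, c(1.30, 1.35))
})

test_that("a band above the object yields an empty slice, not an error", {
  set.seed(5)
  th <- runif(500, 0, 2 * pi)
  cl <- point_cloud(cbind(0.1 * cos(th), 0.1 * sin(th), runif(500, 0, 1)))
  expect_length(extract_dbh_slice(cl, 0, center_height = 1.325), 0L)
  expect_error(extract_dbh_slice(cl, 0, thickness = 0), "thickness")
  expect_error(extract_dbh_slice(cl, NULL), "ground")
})

test_that("slices are partitioned into one section per stem", {
  set.seed(6)
  mk <- function(cx, cy) cbind(cx + 0.1 * cos(runif(300, 0, 2 * pi)),
                               cy + 0.1 * sin(runif(300, 0, 2 * pi)),
                               runif(300, 1.30, 1.35))
  cl <- point_cloud(rbind(mk(0, 0), mk(4, 0), mk(0, 4)))
  secs <- extract_dbh_slice(cl, 0)
  expect_length(secs, 3L)
  m <- match_sections_to_stems(secs, rbind(c(0, 0), c(4, 0), c(0, 4), c(8, 8)))
  expect_equal(sum(is.na(m)), 1L)
  expect_true(is.na(m[4]))
  expect_length(unique(m[1:3]), 3L)
})

test_that("the algebraic fit recovers exact circles to machine precision", {
  sec <- circle_section(100, R = 0.25, center = c(1, 2),
                        theta = seq(0, 359, length.out = 100))
  fit <- fit_circle(sec)
  expect_lt(max(abs(fit$center - c(1, 2))), 1e-9)
  expect_lt(abs(fit$radius - 0.25), 1e-9)
})

test_that("three points give their circumcircle", {
  p <- matrix(c(0.3, 0.1, 1.2, 0.9, 0.7, 1.8), ncol = 2, byrow = TRUE)
  fit <- fit_circle(p)
  oracle <- circumcircle(p[1, ], p[2, ], p[3, ])
  expect_equal(unname(fit$center), oracle$center, tolerance = 1e-9)
  expect_equal(fit$radius, oracle$radius, tolerance = 1e-9)
})

test_that("noisy-circle fit agrees with a grid-search least-squares oracle", {
  set.seed(7)
  sigma <- 0.002; n <- 2000; R <- 0.25
  sec <- circle_section(n, R = R, sigma = sigma, center = c(1, 2))
  fit <- fit_circle(sec)
  expect_lt(abs(fit$radius - R), 3 * sigma / sqrt(n))
  oracle <- grid_circle_fit(sec$points, fit$center + 0.005, fit$radius - 0.005)
  expect_lt(abs(fit$radius - oracle$radius), 5 * oracle$resolution)
  expect_lt(max(abs(fit$center - oracle$center)), 5 * oracle$resolution)
})

test_that("degenerate point sets are rejected", {
  line <- cbind(seq(0, 1, length.out = 50), 2 * seq(0, 1, length.out = 50))
  expect_error(fit_circle(line), "collinear")
  expect_error(fit_circle(line[1:2, ]), "at least 3")
})

test_that("unwrapping matches its polar definition", {
  sec <- circle_section(90, R = 0.2, theta = seq(0, 356, by = 4))
  fit <- fit_circle(sec)
  prof <- unwrap_to_polar(sec, fit)
  expect_true(all(abs(prof$deviation) < 1e-9))
  expect_true(!is.unsorted(prof$theta))
  # single point due east at radius + 1 mm: theta = 0, deviation = 1 mm
  circ <- structure(list(center = c(x = 0, y = 0), radius = 0.2),
                    class = "fitted_circle")
  p1 <- unwrap_to_polar(cross_section(cbind(0.201, 0)), circ)
  expect_equal(p1$theta, 0)
  expect_equal(p1$deviation, 1, tolerance = 1e-9)
  expect_error(unwrap_to_polar(cross_section(cbind(0, 0)), circ), "centre")
})

test_that("an ellipse unwraps to a dominant second harmonic", {
  e <- 0.02; R <- 0.2
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  xy <- cbind(R * (1 + e) * cos(th), R * (1 - e) * sin(th))
  fit <- fit_circle(xy)
  prof <- unwrap_to_polar(cross_section(xy), fit)
  # DFT oracle on the (uniform) angular grid
  dev <- prof$deviation
  amp <- Mod(stats::fft(dev))[2:7] / length(dev) * 2
  expect_gt(amp[2], 5 * max(amp[-2]))
})

test_that("Fourier contour fitting matches closed forms", {
  th <- seq(0, 359.5, by = 0.5)
  prof <- structure(list(theta = th, deviation = rep(2.5, length(th)),
                         radius = 0.2, n = length(th)),
                    class = "unwrapped_profile")
  for (K in c(4, 8)) {
    m <- fit_fourier(prof, K = K)
    expect_equal(m$a0, 2.5, tolerance = 1e-9)
    expect_lt(max(abs(c(m$a, m$b))), 1e-9)
  }
  prof2 <- prof
  prof2$deviation <- 3 * cos(2 * th * pi / 180)
  m2 <- fit_fourier(prof2, K = 4)
  expect_equal(m2$a[2], 3, tolerance = 1e-9)
  expect_lt(max(abs(prof2$deviation - predict_fourier(m2, th))), 1e-9)
  expect_error(fit_fourier(structure(list(theta = th[1:10],
                                          deviation = rep(0, 10), n = 10),
                                     class = "unwrapped_profile"), K = 8),
               "2K \\+ 1")
})

test_that("white-noise deviations are barely absorbed by the harmonics", {
  set.seed(8)
  n <- 5000; K <- 8; sigma <- 1
  th <- sort(runif(n, 0, 360))
  prof <- structure(list(theta = th, deviation = rnorm(n, 0, sigma),
                         radius = 0.2, n = n), class = "unwrapped_profile")
  m <- fit_fourier(prof, K = K)
  fitted_var <- mean((predict_fourier(m, th) - mean(prof$deviation))^2)
  # projection oracle: each of 2K harmonic coefficients absorbs ~ sigma^2 * 2/n
  expect_lt(fitted_var + (mean(prof$deviation))^2,
            (2 * K + 1) / n * sigma^2 * 1.5)
})

test_that("the 95% band matches analytic interval widths", {
  th <- seq(0, 359.99, length.out = 1e5)
  mk_prof <- function(dev) structure(list(theta = th, deviation = dev,
                                          radius = 0.2, n = length(th)),
                                     class = "unwrapped_profile")
  m0 <- fit_fourier(mk_prof(rep(0, length(th))), K = 4)
  expect_equal(residual_band95(mk_prof(rep(0, length(th))), m0)$width95, 0)
  set.seed(9)
  # Gaussian residuals: central 95% interval is 2 x 1.96 sigma = 3.92 mm
  pg <- mk_prof(rnorm(length(th), 0, 1))
  bg <- residual_band95(pg, fit_fourier(pg, K = 4))
  expect_equal(bg$width95, 3.92, tolerance = 0.05 / 3.92)
  # Uniform(-1, 1): central 95% is 0.95 x range = 1.90 mm
  pu <- mk_prof(runif(length(th), -1, 1))
  bu <- residual_band95(pu, fit_fourier(pu, K = 4))
  expect_equal(bu$width95, 1.90, tolerance = 0.02 / 1.90)
  expect_equal(bg$n_points, length(th))
  small <- structure(list(theta = seq(0, 348, by = 12),
                          deviation = rnorm(30), radius = 0.2, n = 30),
                     class = "unwrapped_profile")
  expect_warning(residual_band95(small, fit_fourier(small, K = 4)), "unstable")
})

test_that("noise-band width grows monotonically with simulated noise", {
  set.seed(10)
  widths <- vapply(c(1, 5, 10, 20), function(sig_mm) {
    sec <- circle_section(3000, R = 0.128, sigma = sig_mm / 1000)
    section_noise_band(sec, K = 8)$width95
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
  expect_equal(widths / 3.92, c(1, 5, 10, 20), tolerance = 0.1)
})

test_that("perimeter polygons match closed-form geometry", {
  # dense noiseless circle: n-gon perimeter 2 n R sin(pi / n), within 0.5%
  set.seed(11)
  R <- 0.2
  sec <- circle_section(20000, R = R)
  poly <- perimeter_polygon(sec, n_bins = 72)
  expect_equal(poly$perimeter, 2 * pi * R, tolerance = 0.005)
  expect_equal(nrow(poly$vertices), 73L)
  expect_equal(poly$vertices[1, ], poly$vertices[73, ])
  # square cross-section of side s: perimeter converges to 4 s within 2%
  s <- 0.4; m <- 20000
  t <- runif(m, 0, 4); side <- floor(t); u <- t - side; h <- s / 2
  sq <- cbind(ifelse(side == 0, -h + s * u, ifelse(side == 1, h,
              ifelse(side == 2, h - s * u, -h))),
              ifelse(side == 0, -h, ifelse(side == 1, -h + s * u,
              ifelse(side == 2, h, h - s * u))))
  psq <- perimeter_polygon(cross_section(sq), n_bins = 72)
  expect_equal(psq$perimeter, 4 * s, tolerance = 0.02)
})

test_that("degenerate angular coverage is rejected", {
  narrow <- circle_section(100, R = 0.2, arc = c(1, 3))
  expect_error(perimeter_polygon(narrow,
                                 circle = structure(list(center = c(x = 0, y = 0),
                                                         radius = 0.2),
                                                    class = "fitted_circle")),
               "single angular bin")
  sparse <- circle_section(300, R = 0.2, arc = c(0, 12))
  expect_error(perimeter_polygon(sparse,
                                 circle = structure(list(center = c(x = 0, y = 0),
                                                         radius = 0.2),
                                                    class = "fitted_circle"),
                                 interpolate = FALSE),
               "empty")
})

test_that("perimeter-to-diameter conversion follows closed forms", {
  expect_equal(dbh_from_perimeter(pi * 0.505), 50.5)
  expect_equal(dbh_from_perimeter(1), 31.83, tolerance = 1e-4)
  expect_error(dbh_from_perimeter(0), "> 0")
  # a regular hexagon of circumradius R has perimeter 6R: the implied
  # diameter 6R/pi = 1.9099R understates 2R by ~4.5% - the documented
  # coarseness bias of polygonal tracing
  R <- 0.3
  hexagon <- 6 * R
  expect_equal(dbh_from_perimeter(hexagon) / 100 / (2 * R), 6 / (2 * pi),
               tolerance = 1e-9)
})

test_that("radius, band width and DBH are rigid-motion equivariant", {
  set.seed(12)
  sec <- circle_section(2000, R = 0.128, sigma = 0.003)
  ang <- 37 * pi / 180
  Rm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  rotated <- cross_section(sec$points %*% Rm, band = sec$band)
  shifted <- cross_section(sweep(sec$points, 2, c(12.3, -4.5), "+"),
                           band = sec$band)
  f1 <- fit_circle(sec); f2 <- fit_circle(rotated); f3 <- fit_circle(shifted)
  expect_equal(f2$radius, f1$radius, tolerance = 1e-9)
  expect_equal(f3$radius, f1$radius, tolerance = 1e-9)
  b1 <- section_noise_band(sec)
  expect_equal(section_noise_band(rotated)$width95, b1$width95,
               tolerance = 1e-9)
  expect_equal(section_noise_band(shifted)$width95, b1$width95,
               tolerance = 1e-9)
  d1 <- dbh_from_perimeter(perimeter_polygon(sec, f1))
  # translation leaves the angular binning untouched: exact equality
  expect_equal(dbh_from_perimeter(perimeter_polygon(shifted, f3)), d1,
               tolerance = 1e-9)
  # rotation re-aligns the angular bins; with noisy data the re-binned
  # outer contour can differ by a small discretization term
  expect_equal(dbh_from_perimeter(perimeter_polygon(rotated, f2)), d1,
               tolerance = 2e-3)
  # on noiseless data the polygon is rotation-exact as well
  clean <- circle_section(2000, R = 0.128)
  fc <- fit_circle(clean)
  clean_rot <- cross_section(clean$points %*% Rm)
  expect_equal(dbh_from_perimeter(perimeter_polygon(clean_rot, fit_circle(clean_rot))),
               dbh_from_perimeter(perimeter_polygon(clean, fc)),
               tolerance = 1e-9)
})

test_that("end-to-end DBH recovery on a noiseless dense cylinder", {
  set.seed(13)
  for (D_cm in c(10, 25.3, 50.5)) {
    sec <- circle_section(10000, R = D_cm / 200)
    est <- dbh_from_perimeter(perimeter_polygon(sec, n_bins = 72))
    expect_lt(abs(est - D_cm) / D_cm, 0.01)
  }
})
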