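# shape_metrics: closed forms, invariances, and the composite measurement

test_that("polygon area: unit square, near-circle, orientation symmetry", {
  sq <- list(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(polygon_area(sq, 1), 1.0)
  expect_equal(polygon_area(sq, 3), 9.0)           # um^2 scaling

  gon <- regular_polygon(360, radius = 100)
  expect_lt(abs(polygon_area(gon, 1) / (pi * 1e4) - 1), 0.001)

  cw <- list(x = rev(sq$x), y = rev(sq$y))
  expect_equal(polygon_area(cw, 1), 1.0)

  expect_error(polygon_area(list(x = c(0, 1), y = c(0, 1)), 1),
               class = "invalid_argument")
})

test_that("polygon perimeter: unit square, near-circle, homogeneity", {
  sq <- list(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(polygon_perimeter(sq, 1), 4.0)
  gon <- regular_polygon(360, radius = 100)
  expect_lt(abs(polygon_perimeter(gon, 1) / (2 * pi * 100) - 1), 1e-4)
  sq2 <- list(x = 2 * sq$x, y = 2 * sq$y)
  expect_equal(polygon_perimeter(sq2, 1), 2 * polygon_perimeter(sq, 1))
})

test_that("equivalent perimeter and diameter closed forms", {
  expect_equal(equivalent_perimeter(pi), 2 * pi)
  expect_equal(equivalent_perimeter(10000), 2 * sqrt(10000 * pi))
  expect_equal(equivalent_perimeter(4 * 123), 2 * equivalent_perimeter(123))
  expect_equal(equivalent_diameter(pi), 2)
  expect_equal(equivalent_diameter(pi * 150^2), 300)
  expect_error(equivalent_perimeter(0), class = "invalid_argument")
  expect_error(equivalent_diameter(-1), class = "invalid_argument")
})

test_that("EPI closed forms: circle, square, hexagon", {
  expect_equal(excess_perimeter_index(10, 10), 0)
  # square side a: P_o = 4a, S = a^2
  a <- 3.7
  epi_sq <- excess_perimeter_index(4 * a, equivalent_perimeter(a^2))
  expect_equal(epi_sq, 2 / sqrt(pi) - 1, tolerance = 1e-12)
  # regular hexagon side s
  s <- 2.2
  S_hex <- 3 * sqrt(3) / 2 * s^2
  epi_hex <- excess_perimeter_index(6 * s, equivalent_perimeter(S_hex))
  expect_equal(epi_hex, 3 / sqrt(pi * 3 * sqrt(3) / 2) - 1, tolerance = 1e-12)
  expect_equal(round(epi_hex, 3), 0.050)
  expect_error(excess_perimeter_index(-1, 2), class = "invalid_argument")
})

test_that("EPI >= 0 for random simple polygons (isoperimetric property)", {
  set.seed(424)
  for (i in 1:200) {
    p <- random_star_polygon(128)
    S <- polygon_area(p, 1)
    epi <- excess_perimeter_index(polygon_perimeter(p, 1),
                                  equivalent_perimeter(S))
    expect_gte(epi, 0)
  }
})

test_that("roughness: circle limit, ellipse brute force, monotone in amplitude", {
  gon <- regular_polygon(360, radius = 50)
  expect_lt(roughness(gon), 1e-4)

  th <- seq(0, 2 * pi, length.out = 361)[-361]
  ell <- list(x = 2 * cos(th), y = sin(th))
  # brute-force oracle: sd/mean of centroid-to-vertex radii (centroid at 0)
  r <- sqrt(ell$x^2 + ell$y^2)
  expect_equal(roughness(ell), sd(r) / mean(r), tolerance = 1e-6)

  cfg <- test_config()
  r_lo <- attr(render_spheroid_image(110, 0.05, cfg, day_seed = 3),
               "truth_polygon")
  r_hi <- attr(render_spheroid_image(110, 0.20, cfg, day_seed = 3),
               "truth_polygon")
  expect_gt(roughness(r_hi), roughness(r_lo))

  expect_error(roughness(regular_polygon(8)), class = "invalid_argument")
})

test_that("spherical volume closed form and cubic scaling", {
  expect_equal(spheroid_volume(2), 4 * pi / 3)
  expect_equal(spheroid_volume(100), (4 / 3) * pi * 50^3)
  expect_equal(spheroid_volume(100), 523598.8, tolerance = 1e-6)
  expect_equal(spheroid_volume(2 * 37), 8 * spheroid_volume(37))
  expect_error(spheroid_volume(0), class = "invalid_argument")
})

test_that("measure_image: circle pipeline values and internal consistency", {
  cfg <- test_config()
  rec <- measure_image(render_spheroid_image(120, 0, cfg, day_seed = 6))
  expect_gte(rec$EPI, -0.02)
  expect_lte(rec$EPI, 0.03)
  expect_lt(rec$roughness, 0.01)
  expect_lt(abs(rec$d_um / 240 - 1), 0.02)
  expect_equal(rec$P_e_um, 2 * sqrt(pi * rec$S_um2))
  expect_equal(rec$d_um, 2 * sqrt(rec$S_um2 / pi))
  expect_equal(rec$V_um3, (4 / 3) * pi * (rec$d_um / 2)^3)
  expect_equal(rec$EPI, (rec$P_o_um - rec$P_e_um) / rec$P_e_um)

  inv <- measure_image(render_spheroid_image(120, 0.2, cfg, day_seed = 6))
  expect_gt(inv$EPI, rec$EPI)
})

test_that("EPI and roughness are stable under 2x resolution change", {
  cfg1 <- test_config()
  cfg2 <- test_config(pixel_size_um = 1.25, image_size_px = 480L)
  r1 <- measure_image(render_spheroid_image(130, 0.15, cfg1, day_seed = 12))
  r2 <- measure_image(render_spheroid_image(130, 0.15, cfg2, day_seed = 12))
  expect_lt(abs(r1$EPI - r2$EPI), 0.03)
  expect_lt(abs(r1$roughness - r2$roughness), 0.01)
})

test_that("measurement errors carry well and day context", {
  blank <- spheroid_image(matrix(0.8, 64, 64), 2.5, well_id = "W033",
                          day = 4L)
  err <- tryCatch(measure_image(blank), error = identity)
  expect_s3_class(err, "no_spheroid_found")
  expect_match(conditionMessage(err), "W033")
  expect_match(conditionMessage(err), "4")
})
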