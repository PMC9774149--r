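# spheroid_phantom: growth law, rendering, readouts, plate generation

test_that("growth recurrence matches a hand-iterated oracle", {
  r0 <- 100
  cfg <- phantom_config(base_radius_um = r0, growth_rate_per_day = 0.2,
                        r_max_um = 4 * r0, drug_emax = 0.9,
                        drug_ec50_uM = 0.05, hill_coef = 1,
                        invasion_rate_per_day = 0.03)
  dose <- 0.05
  inhib <- 0.9 * dose / (dose + 0.05)     # = 0.45
  expect_equal(inhib, 0.45)
  r <- r0; a <- 0
  rs <- r; as <- a
  for (t in 1:6) {
    r <- r + 0.2 * r * (1 - r / (4 * r0)) * (1 - inhib)
    a <- a + 0.03 * (1 - inhib)
    rs <- c(rs, r); as <- c(as, a)
  }
  traj <- simulate_growth(cfg, "normoxia", dose, days = 1:7)
  expect_equal(traj$radius_um, rs, tolerance = 1e-12)
  expect_equal(traj$protrusion_amp, as, tolerance = 1e-12)
  # viable volume: sphere minus necrotic core beyond the diffusion rim
  core <- pmax(0, rs - cfg$viable_rim_um)
  expect_equal(traj$viable_volume_um3, (4 / 3) * pi * (rs^3 - core^3))
})

test_that("growth limits: zero dose grows, saturating dose with Emax 1 is static", {
  cfg <- phantom_config(drug_emax = 1)
  t0 <- simulate_growth(cfg, "normoxia", 0)
  expect_true(all(diff(t0$radius_um) >= 0))
  thi <- simulate_growth(cfg, "normoxia", 1e9)
  expect_equal(thi$radius_um, rep(cfg$base_radius_um, 10))
  expect_error(simulate_growth(cfg, "normoxia", -1), class = "invalid_argument")
})

test_that("final radius is non-increasing in dose and hypoxia factors of 1 are inert", {
  cfg <- phantom_config(drug_emax = 0.8)
  finals <- vapply(c(0, 0.001, 0.01, 0.1, 1, 10),
                   function(d) {
                     tr <- simulate_growth(cfg, "normoxia", d)
                     tr$radius_um[length(tr$radius_um)]
                   }, numeric(1))
  expect_true(all(diff(finals) <= 0))

  cfg1 <- phantom_config(hypoxia_growth_factor = 1,
                         hypoxia_invasion_factor = 1,
                         hypoxia_drug_factor = 1)
  a <- simulate_growth(cfg1, "normoxia", 0.05)
  b <- simulate_growth(cfg1, "hypoxia", 0.05)
  expect_identical(a$radius_um, b$radius_um)
  expect_identical(a$protrusion_amp, b$protrusion_amp)
})

test_that("hypoxia scales growth, invasion and drug effect as configured", {
  cfg <- phantom_config(hypoxia_growth_factor = 0.5,
                        hypoxia_invasion_factor = 0.5,
                        hypoxia_drug_factor = 2, drug_emax = 0.4)
  n <- simulate_growth(cfg, "normoxia", 0)
  h <- simulate_growth(cfg, "hypoxia", 0)
  expect_lt(h$radius_um[10], n$radius_um[10])
  expect_lt(h$protrusion_amp[10], n$protrusion_amp[10])
  # at saturating dose hypoxia doubles Emax: stronger inhibition
  nt <- simulate_growth(cfg, "normoxia", 100)
  ht <- simulate_growth(cfg, "hypoxia", 100)
  expect_lt(ht$radius_um[10] / cfg$base_radius_um,
            nt$radius_um[10] / cfg$base_radius_um)
})

test_that("rendering: circle truth, determinism, overflow, amp ordering", {
  cfg <- test_config()
  img <- render_spheroid_image(100, 0, cfg, day_seed = 5)
  tp <- attr(img, "truth_polygon")
  ctr <- (cfg$image_size_px - 1) / 2
  radii <- sqrt((tp[, 1] - ctr)^2 + (tp[, 2] - ctr)^2) * cfg$pixel_size_um
  expect_equal(radii, rep(100, nrow(tp)), tolerance = 1e-9)
  expect_lt(abs(oracle_epi(tp[, 1], tp[, 2])), 1e-5)

  img2 <- render_spheroid_image(100, 0, cfg, day_seed = 5)
  expect_identical(img$pixels, img2$pixels)

  lo <- render_spheroid_image(100, 0.05, cfg, day_seed = 9)
  hi <- render_spheroid_image(100, 0.20, cfg, day_seed = 9)
  epi_lo <- oracle_epi(attr(lo, "truth_polygon")[, 1],
                       attr(lo, "truth_polygon")[, 2])
  epi_hi <- oracle_epi(attr(hi, "truth_polygon")[, 1],
                       attr(hi, "truth_polygon")[, 2])
  expect_gt(epi_hi, epi_lo)

  expect_error(render_spheroid_image(500, 0.2, cfg), class = "render_overflow")
})

test_that("truth-polygon EPI increases over a protrusion grid", {
  cfg <- test_config()
  epis <- vapply(c(0, 0.05, 0.1, 0.15, 0.2), function(a) {
    img <- render_spheroid_image(110, a, cfg, day_seed = 21)
    tp <- attr(img, "truth_polygon")
    oracle_epi(tp[, 1], tp[, 2])
  }, numeric(1))
  expect_true(all(diff(epis) > 0))
})

test_that("viability readout is linear in viable volume with positive channels", {
  cfg <- test_config(absorbance_noise_sd = 0)
  traj <- simulate_growth(cfg, "normoxia", 0, days = 1:5)
  rd <- simulate_viability_readout(traj, cfg, seed = 1)
  samp <- rd[rd$well_type == "sample", ]
  expect_equal(samp$A570 - samp$A600,
               cfg$viability_per_volume * traj$viable_volume_um3,
               tolerance = 1e-12)
  expect_true(all(rd$A570 > 0) && all(rd$A600 > 0))
  expect_true(any(rd$well_type == "blank"))
  blanks <- rd[rd$well_type == "blank", ]
  expect_equal(blanks$A570 - blanks$A600, rep(0, nrow(blanks)))

  # doubling viable volume doubles the noise-free signal
  traj2 <- traj
  traj2$viable_volume_um3 <- 2 * traj$viable_volume_um3
  rd2 <- simulate_viability_readout(traj2, cfg, seed = 1, n_blanks = 0)
  expect_equal(rd2$A570 - rd2$A600, 2 * (samp$A570 - samp$A600),
               tolerance = 1e-12)
})

test_that("generate_plate: counts, default doses, determinism", {
  cfg <- test_config(image_size_px = 96L, base_radius_um = 60,
                     r_max_um = 90)
  d1 <- withr::local_tempdir()
  plate <- generate_plate(cfg, d1, doses_uM = c(0, 0.1), conditions = "normoxia",
                          n_replicates = 3, days = 1:7)
  expect_length(list.files(file.path(d1, "images")), 2 * 3 * 7)
  expect_equal(nrow(plate$absorbance), 2 * 3 * 7)
  expect_equal(nrow(plate$layout), 6)

  expect_length(spherotrack:::default_dose_list(), 9)
  expect_true(0 %in% spherotrack:::default_dose_list())

  d2 <- withr::local_tempdir()
  generate_plate(cfg, d2, doses_uM = c(0, 0.1), conditions = "normoxia",
                 n_replicates = 3, days = 1:7)
  expect_identical(readBin(file.path(d1, "truth.csv"), "raw", 1e6),
                   readBin(file.path(d2, "truth.csv"), "raw", 1e6))
  f1 <- file.path(d1, "images", "W004_03.tif")
  f2 <- file.path(d2, "images", "W004_03.tif")
  expect_identical(readBin(f1, "raw", 5e6), readBin(f2, "raw", 5e6))
})

test_that("per-well seeds are stable and distinct", {
  expect_identical(well_seed(7, "W001"), well_seed(7, "W001"))
  expect_false(well_seed(7, "W001") == well_seed(7, "W002"))
  expect_false(well_seed(7, "W001") == well_seed(8, "W001"))
})
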