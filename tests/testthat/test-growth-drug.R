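# growth_and_drug: RTV, TGI, viability normalization, classification, 4PL

truth_metrics <- function(truth) {
  # morphometric records derived from generator ground truth (no imaging)
  d <- 2 * truth$radius_um
  data.frame(well_id = truth$well, day = truth$day,
             S_um2 = pi * truth$radius_um^2,
             EPI = truth$protrusion_amp, roughness = truth$protrusion_amp / 2,
             d_um = d, V_um3 = (4 / 3) * pi * (d / 2)^3,
             stringsAsFactors = FALSE)
}

test_that("RTV and TGI arithmetic, including negative TGI", {
  expect_equal(relative_tumor_volume(5, 5), 1)
  expect_equal(relative_tumor_volume(8, 1), 8)
  expect_error(relative_tumor_volume(0, 1), class = "invalid_argument")
  expect_equal(tumor_growth_inhibition(4, 4), 0)
  expect_equal(tumor_growth_inhibition(4, 1), 75)
  expect_equal(tumor_growth_inhibition(2, 3), -50)
  expect_lte(tumor_growth_inhibition(3, 0), 100)
  expect_error(tumor_growth_inhibition(0, 1), class = "invalid_argument")
})

test_that("diameter ratio defaults to day 7 over day 1", {
  s <- data.frame(well_id = "W001", day = c(1, 4, 7),
                  d_um = c(200, 260, 320))
  expect_equal(diameter_ratio(s), 1.6)
  expect_equal(diameter_ratio(s, 4, 1), 1.3)
  expect_equal(diameter_ratio(data.frame(day = 1:7, d_um = rep(5, 7))), 1.0)
  err <- tryCatch(diameter_ratio(s, 10, 1), error = identity)
  expect_s3_class(err, "invalid_argument")
  expect_match(conditionMessage(err), "W001")
})

test_that("shrinking treated phantom has diameter ratio < 1", {
  # hypoxia potentiation pushes effective Emax above 1: shrinkage regime
  cfg <- phantom_config(drug_emax = 0.9, hypoxia_drug_factor = 1.5,
                        growth_rate_per_day = 0.3)
  traj <- simulate_growth(cfg, "hypoxia", 100, days = 1:7)
  s <- data.frame(day = traj$days, d_um = 2 * traj$radius_um)
  expect_lt(diameter_ratio(s), 1)
  # untreated ratio matches ground truth
  t0 <- simulate_growth(cfg, "normoxia", 0, days = 1:7)
  s0 <- data.frame(day = t0$days, d_um = 2 * t0$radius_um)
  expect_equal(diameter_ratio(s0), t0$radius_um[7] / t0$radius_um[1],
               tolerance = 1e-12)
})

test_that("viability normalization: identity, linearity, gain and blanks", {
  ctl <- data.frame(A570 = c(0.8, 0.82, 0.78), A600 = c(0.2, 0.21, 0.19))
  expect_equal(normalize_viability(ctl, ctl)$viability_percent, 100)

  half <- ctl; half$A570 <- ctl$A600 + (ctl$A570 - ctl$A600) / 2
  expect_equal(normalize_viability(half, ctl)$viability_percent, 50)

  gain <- 2.7
  g <- function(df) data.frame(A570 = gain * df$A570, A600 = gain * df$A600)
  expect_equal(normalize_viability(g(half), g(ctl))$viability_percent,
               normalize_viability(half, ctl)$viability_percent)

  blank <- data.frame(A570 = c(0.3, 0.3), A600 = c(0.25, 0.25))
  shifted_s <- half; shifted_s$A570 <- shifted_s$A570 + 0.05
  shifted_c <- ctl; shifted_c$A570 <- shifted_c$A570 + 0.05
  v <- normalize_viability(shifted_s, shifted_c, blank)
  expect_equal(v$viability_percent, 50)

  deg <- data.frame(A570 = c(0.2, 0.2), A600 = c(0.3, 0.25))
  expect_error(normalize_viability(half, deg), class = "degenerate_control")
})

test_that("invasiveness classification is a strict threshold rule", {
  expect_identical(classify_invasiveness(0.4), "less-invasive")
  expect_identical(classify_invasiveness(0.6), "invasive")
  expect_identical(classify_invasiveness(0.5), "invasive")
  expect_identical(classify_invasiveness(c(0.1, 0.9), threshold = 0.5),
                   c("less-invasive", "invasive"))
  expect_identical(classify_invasiveness(0.4, threshold = 0.3), "invasive")
  expect_error(classify_invasiveness(NaN), class = "invalid_argument")
})

test_that("4PL fitting: recovery, not-reached, anomalous direction", {
  doses <- c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1, 5)
  truth <- 10 + (100 - 10) / (1 + (doses / 0.05)^1)
  v <- withr::with_seed(99, truth + rnorm(length(doses), 0, 3))
  fit <- fit_dose_response(doses, v)
  expect_identical(fit$status, "ok")
  expect_lt(abs(fit$ic50 / 0.05 - 1), 0.25)
  expect_false(fit$anomalous_direction)

  flat <- withr::with_seed(5, 95 + rnorm(length(doses), 0, 2))
  nf <- fit_dose_response(doses, flat)
  expect_identical(nf$status, "ic50-not-reached")
  expect_true(is.na(nf$ic50))

  up <- fit_dose_response(doses, c(60, 65, 72, 80, 84, 90, 95, 99))
  expect_true(up$anomalous_direction)

  expect_error(fit_dose_response(c(0.1, 0.5, 1), c(90, 70, 50)),
               class = "insufficient_data")
})

test_that("TGI from volumes equals the diameter-ratio identity and is unit invariant", {
  cfg <- test_config()
  plate <- generate_plate(cfg, withr::local_tempdir(),
                          doses_uM = c(0, 0.01, 0.1, 1),
                          conditions = "normoxia", n_replicates = 4,
                          days = c(1, 7), write_images = FALSE)
  m <- truth_metrics(plate$truth)
  s <- summarize_plate(m, plate$absorbance, plate$layout)
  # identity: TGI = 100 * (1 - mean((d7/d1)^3)_t / mean((d7/d1)^3)_c)
  mm <- merge(m, plate$layout, by.x = "well_id", by.y = "well")
  dr3 <- sapply(split(mm, mm$well_id), function(w)
    (w$d_um[w$day == 7] / w$d_um[w$day == 1])^3)
  grp <- sapply(split(mm, mm$well_id), function(w) w$dose_uM[1])
  for (i in seq_len(nrow(s$tgi))) {
    dz <- s$tgi$dose_uM[i]
    tgi_d <- 100 * (1 - mean(dr3[grp == dz]) / mean(dr3[grp == 0]))
    expect_equal(s$tgi$TGI_percent[i], tgi_d, tolerance = 1e-9)
  }
  # unit invariance: metrics in mm^3 give identical TGI
  m2 <- m; m2$V_um3 <- m$V_um3 * 1e-9
  s2 <- summarize_plate(m2, plate$absorbance, plate$layout)
  expect_equal(s2$tgi$TGI_percent, s$tgi$TGI_percent, tolerance = 1e-12)
})

test_that("zero drug effect gives near-zero TGI and ~100% viability", {
  cfg <- test_config(drug_emax = 0)
  plate <- generate_plate(cfg, withr::local_tempdir(),
                          doses_uM = c(0, 0.01, 0.1, 1, 5),
                          conditions = "normoxia", n_replicates = 6,
                          days = c(1, 7), write_images = FALSE)
  s <- summarize_plate(truth_metrics(plate$truth), plate$absorbance,
                       plate$layout)
  expect_true(all(abs(s$tgi$TGI_percent) < 10))
  vt <- s$timecourse[s$timecourse$day == 7, ]
  expect_true(all(abs(vt$viability_mean - 100) < 15))
})

test_that("inhibition ordering is recovered and hypoxia potentiation holds", {
  cfg <- test_config(drug_emax = 0.9, drug_ec50_uM = 0.02,
                     hypoxia_drug_factor = 1.1,
                     hypoxia_growth_factor = 1,
                     absorbance_noise_sd = 0)
  plate <- generate_plate(cfg, withr::local_tempdir(),
                          n_replicates = 6, days = c(1, 7),
                          write_images = FALSE)
  s <- summarize_plate(truth_metrics(plate$truth), plate$absorbance,
                       plate$layout)
  for (cond in c("normoxia", "hypoxia")) {
    tg <- s$tgi[s$tgi$condition == cond, ]
    tg <- tg[order(tg$dose_uM), ]
    expect_equal(cor(tg$dose_uM, tg$TGI_percent, method = "spearman"), 1.0)
  }
  nm <- s$tgi[s$tgi$condition == "normoxia", ]
  hy <- s$tgi[s$tgi$condition == "hypoxia", ]
  mg <- merge(nm, hy, by = "dose_uM", suffixes = c("_n", "_h"))
  expect_true(all(mg$TGI_percent_h >= mg$TGI_percent_n - 1e-9))
})

test_that("layout wells without metrics are excluded with a warning", {
  cfg <- test_config()
  plate <- generate_plate(cfg, withr::local_tempdir(),
                          doses_uM = c(0, 0.1), conditions = "normoxia",
                          n_replicates = 2, days = c(1, 7),
                          write_images = FALSE)
  m <- truth_metrics(plate$truth)
  m <- m[m$well_id != "W001", ]
  expect_warning(
    s <- summarize_plate(m, plate$absorbance, plate$layout),
    "W001")
  expect_false("W001" %in% s$timecourse$well)
})
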