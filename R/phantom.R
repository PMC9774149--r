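# Synthetic spheroid phantoms: growth trajectories, brightfield-like renders,
# absorbance readouts, and whole-plate datasets with known ground truth.

#' Phantom generator configuration
#'
#' Bundles every knob of the synthetic spheroid world: logistic radial growth
#' with Hill-type drug inhibition, a random-phase cosine protrusion boundary,
#' hypoxia condition scalings, an Alamar-Blue-like absorbance model, and the
#' imaging geometry. Defaults emulate a matrix-embedded spheroid assay:
#' spheroids enter imaging at ~300 um diameter after 4 days of formation, are
#' followed daily, and respond to a covalent KRAS-G12C inhibitor with
#' sub-0.1 uM half-effect.
#'
#' @param base_radius_um Initial spheroid radius at the first imaged day (um).
#' @param growth_rate_per_day Dimensionless logistic growth rate.
#' @param r_max_um Carrying-capacity radius (um); must be >= `base_radius_um`.
#' @param invasion_rate_per_day Daily increment of the protrusion amplitude
#'   (dimensionless fraction of radius per day).
#' @param n_protrusions Integer number of cosine lobes on the boundary;
#'   0 gives a perfect circle.
#' @param drug_emax Maximum fractional growth inhibition in `[0, 1]`.
#' @param drug_ec50_uM Dose with half-maximal effect (uM).
#' @param hill_coef Hill exponent (> 0).
#' @param hypoxia_growth_factor,hypoxia_invasion_factor,hypoxia_drug_factor
#'   Multiplicative scalings (> 0) applied to growth rate, invasion rate and
#'   Emax under hypoxia. Hypoxic solid-tumor cores grow and invade more slowly
#'   while KRAS-pathway drug effect is potentiated, hence defaults < 1, < 1,
#'   > 1. The scaled effective Emax may exceed 1, in which case high doses
#'   shrink the spheroid rather than merely arresting it.
#' @param viability_per_volume Absorbance-difference units (A570 - A600) per
#'   um^3 of viable tissue.
#' @param noise_sd Additive Gaussian image noise, as a fraction of the
#'   intensity range.
#' @param absorbance_noise_sd Gaussian noise of each absorbance channel.
#' @param pixel_size_um Microns per pixel.
#' @param image_size_px Side of the square raster in pixels.
#' @param viable_rim_um Oxygen/nutrient diffusion limit: tissue deeper than
#'   this below the surface is counted as necrotic in the viable volume.
#' @param necrotic_core_radius_um Radius above which a darker central core is
#'   rendered (intensity feature only; boundary geometry is unaffected).
#' @param seed Master integer seed.
#' @return An object of class `phantom_config` (a validated named list).
#' @export
#' @examples
#' cfg <- phantom_config(seed = 7)
#' traj <- simulate_growth(cfg, "normoxia", dose_uM = 0)
#' traj$radius_um
phantom_config <- function(base_radius_um = 150,
                           growth_rate_per_day = 0.3,
                           r_max_um = 400,
                           invasion_rate_per_day = 0.02,
                           n_protrusions = 6L,
                           drug_emax = 0.9,
                           drug_ec50_uM = 0.02,
                           hill_coef = 1,
                           hypoxia_growth_factor = 0.6,
                           hypoxia_invasion_factor = 0.6,
                           hypoxia_drug_factor = 1.5,
                           viability_per_volume = 3e-8,
                           noise_sd = 0.02,
                           absorbance_noise_sd = 0.01,
                           pixel_size_um = 2.5,
                           image_size_px = 480L,
                           viable_rim_um = 150,
                           necrotic_core_radius_um = 200,
                           seed = 1L) {
  check_number(base_radius_um, "base_radius_um", min = 0)
  check_number(growth_rate_per_day, "growth_rate_per_day", min = 0)
  check_number(r_max_um, "r_max_um", min = base_radius_um)
  check_number(invasion_rate_per_day, "invasion_rate_per_day", min = 0)
  check_number(n_protrusions, "n_protrusions", min = 0)
  check_number(drug_emax, "drug_emax", min = 0, max = 1)
  check_number(drug_ec50_uM, "drug_ec50_uM", min = .Machine$double.eps)
  check_number(hill_coef, "hill_coef", min = .Machine$double.eps)
  check_number(hypoxia_growth_factor, "hypoxia_growth_factor", min = 0)
  check_number(hypoxia_invasion_factor, "hypoxia_invasion_factor", min = 0)
  check_number(hypoxia_drug_factor, "hypoxia_drug_factor", min = 0)
  check_number(viability_per_volume, "viability_per_volume", min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(absorbance_noise_sd, "absorbance_noise_sd", min = 0)
  check_number(pixel_size_um, "pixel_size_um", min = .Machine$double.eps)
  check_number(image_size_px, "image_size_px", min = 16)
  check_number(viable_rim_um, "viable_rim_um", min = 0)
  check_number(necrotic_core_radius_um, "necrotic_core_radius_um", min = 0)
  check_number(seed, "seed")
  structure(list(
    base_radius_um = base_radius_um,
    growth_rate_per_day = growth_rate_per_day,
    r_max_um = r_max_um,
    invasion_rate_per_day = invasion_rate_per_day,
    n_protrusions = as.integer(n_protrusions),
    drug_emax = drug_emax,
    drug_ec50_uM = drug_ec50_uM,
    hill_coef = hill_coef,
    hypoxia_growth_factor = hypoxia_growth_factor,
    hypoxia_invasion_factor = hypoxia_invasion_factor,
    hypoxia_drug_factor = hypoxia_drug_factor,
    viability_per_volume = viability_per_volume,
    noise_sd = noise_sd,
    absorbance_noise_sd = absorbance_noise_sd,
    pixel_size_um = pixel_size_um,
    image_size_px = as.integer(image_size_px),
    viable_rim_um = viable_rim_um,
    necrotic_core_radius_um = necrotic_core_radius_um,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Preset phantom phenotypes
#'
#' Convenience presets mirroring the three qualitative behaviours seen in
#' embedded-spheroid assays: a strongly invasive line that ignores a G12C
#' inhibitor (CT-26-like, G12D mutant), a smooth non-invasive line
#' (HT-29-like), and a moderately responsive invasive line (NCI-H23-like).
#'
#' @param phenotype One of `"NCI-H23-like"`, `"CT-26-like"`, `"HT-29-like"`.
#' @param ... Overrides passed on to [phantom_config()].
#' @return A `phantom_config`.
#' @export
phantom_phenotype <- function(phenotype = c("NCI-H23-like", "CT-26-like",
                                            "HT-29-like"), ...) {
  phenotype <- match.arg(phenotype)
  base <- switch(phenotype,
    "NCI-H23-like" = list(),
    "CT-26-like" = list(invasion_rate_per_day = 0.035, drug_emax = 0.05,
                        growth_rate_per_day = 0.35,
                        hypoxia_growth_factor = 0.45),
    "HT-29-like" = list(invasion_rate_per_day = 0, n_protrusions = 0L,
                        drug_emax = 0.2)
  )
  do.call(phantom_config, utils::modifyList(base, list(...)))
}

hill_inhibition <- function(dose, emax, ec50, h) {
  if (dose <= 0) return(0)
  emax * dose^h / (dose^h + ec50^h)
}

#' Simulate a spheroid growth trajectory
#'
#' Discrete-daily logistic growth of the equivalent radius with multiplicative
#' Hill drug inhibition, plus linear accretion of the protrusion amplitude:
#' \deqn{r_{t+1} = r_t + g\, r_t (1 - r_t/r_{max})(1 - I), \quad
#'       I = E_{max} C^h / (C^h + EC_{50}^h)}
#' \deqn{a_{t+1} = a_t + \nu (1 - I)}
#' Under hypoxia, `g`, `nu` and `Emax` are each multiplied by their condition
#' factors (Emax clamped at 1). The viable volume assumes a spherical body
#' with a necrotic centre beyond the diffusion rim:
#' `V_viable = (4/3) pi r^3 (1 - ((r - rim)_+ / r)^3)`.
#'
#' @param config A [phantom_config()].
#' @param condition `"normoxia"` or `"hypoxia"`.
#' @param dose_uM Drug dose in uM (>= 0); 0 is vehicle.
#' @param days Strictly increasing integer days; defaults to 1:10.
#' @return A `growth_trajectory`: list with `days`, `radius_um`,
#'   `protrusion_amp`, `viable_volume_um3`, `condition`, `dose_uM`.
#' @export
simulate_growth <- function(config, condition = c("normoxia", "hypoxia"),
                            dose_uM = 0, days = 1:10) {
  stopifnot(inherits(config, "phantom_config"))
  condition <- match.arg(condition)
  if (!is.numeric(dose_uM) || length(dose_uM) != 1L || !is.finite(dose_uM) ||
      dose_uM < 0)
    stop_spherotrack("`dose_uM` must be a single finite non-negative number",
                     "invalid_argument")
  days <- as.integer(days)
  if (length(days) < 1L || any(diff(days) <= 0))
    stop_spherotrack("`days` must be strictly increasing", "invalid_argument")

  g <- config$growth_rate_per_day
  nu <- config$invasion_rate_per_day
  emax <- config$drug_emax
  if (condition == "hypoxia") {
    g <- g * config$hypoxia_growth_factor
    nu <- nu * config$hypoxia_invasion_factor
    # effective Emax may exceed 1 under hypoxia: inhibition > 1 flips the
    # growth increment negative, the shrinking-spheroid regime
    emax <- emax * config$hypoxia_drug_factor
  }
  inhib <- hill_inhibition(dose_uM, emax, config$drug_ec50_uM,
                           config$hill_coef)

  full_days <- seq(days[1], days[length(days)])
  r <- numeric(length(full_days))
  a <- numeric(length(full_days))
  r[1] <- config$base_radius_um
  a[1] <- 0
  for (i in seq_along(full_days)[-1]) {
    r[i] <- max(0, r[i - 1] +
      g * r[i - 1] * (1 - r[i - 1] / config$r_max_um) * (1 - inhib))
    a[i] <- max(0, a[i - 1] + nu * (1 - inhib))
  }
  keep <- match(days, full_days)
  r <- r[keep]; a <- a[keep]
  rim <- config$viable_rim_um
  core <- pmax(0, r - rim)
  viable <- (4 / 3) * pi * (r^3 - core^3)
  structure(list(
    days = days, radius_um = r, protrusion_amp = a,
    viable_volume_um3 = viable, condition = condition, dose_uM = dose_uM
  ), class = "growth_trajectory")
}

# Boundary radius r(theta) = R * (1 + a * sum_j cos(k_j theta + phi_j) / m)
# with modes k_j = j + 2 (j = 1..m): lobed, never a pure ellipse/translation.
boundary_radius_fun <- function(radius_um, protrusion_amp, n_modes, phases) {
  if (n_modes == 0L || protrusion_amp == 0) {
    function(theta) rep(radius_um, length(theta))
  } else {
    ks <- seq_len(n_modes) + 2
    function(theta) {
      mod <- rowSums(vapply(seq_len(n_modes),
                            function(j) cos(ks[j] * theta + phases[j]),
                            numeric(length(theta))))
      radius_um * (1 + protrusion_amp * mod / n_modes)
    }
  }
}

#' Render a brightfield-like phantom image
#'
#' Rasterizes a dark spheroid on a bright background. The boundary is the
#' polar curve `r(theta) = R (1 + a sum_j cos(k_j theta + phi_j)/m)` with
#' phases drawn from a stream seeded by `day_seed`, so the maximal radial
#' deviation is bounded by `a`. Spheroids larger than the rendered necrotic
#' threshold get a darker central disk (intensity only). Additive Gaussian
#' noise of sd `config$noise_sd` is applied and intensities clipped to
#' `[0, 1]`.
#'
#' @param radius_um Mean boundary radius (um).
#' @param protrusion_amp Dimensionless protrusion amplitude `a >= 0`.
#' @param config A [phantom_config()].
#' @param day_seed Integer seed for phases and noise.
#' @param well_id,day Metadata stored on the image.
#' @return A [spheroid_image()] with attributes `truth_polygon` (720-vertex
#'   ground-truth boundary in pixel coordinates) and `truth_radius_um`.
#' @export
render_spheroid_image <- function(radius_um, protrusion_amp, config,
                                  day_seed = config$seed,
                                  well_id = "W000", day = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  check_number(radius_um, "radius_um", min = 0)
  check_number(protrusion_amp, "protrusion_amp", min = 0)
  n <- config$image_size_px
  px <- config$pixel_size_um
  half_um <- (n / 2 - 2) * px
  if (radius_um * (1 + protrusion_amp) > half_um)
    stop_spherotrack(
      sprintf("spheroid (max radius %.0f um) exceeds field of view (%.0f um)",
              radius_um * (1 + protrusion_amp), half_um),
      "render_overflow")

  m <- config$n_protrusions
  img <- with_seed(day_seed, {
    phases <- if (m > 0) stats::runif(m, 0, 2 * pi) else numeric(0)
    rfun <- boundary_radius_fun(radius_um, protrusion_amp, m, phases)
    ctr <- (n - 1) / 2
    xs <- (seq_len(n) - 1) - ctr           # pixel centers at integers
    dx <- matrix(xs, n, n, byrow = TRUE)   # column index -> x
    dy <- matrix(xs, n, n)                 # row index -> y (down)
    rho <- sqrt(dx^2 + dy^2) * px
    theta <- atan2(dy, dx)
    inside <- rho <= rfun(as.vector(theta))
    pix <- matrix(0.85, n, n)
    pix[inside] <- 0.45
    if (radius_um >= config$necrotic_core_radius_um) {
      core <- rho <= 0.5 * radius_um
      pix[core & inside] <- 0.25
    }
    if (config$noise_sd > 0)
      pix <- pix + stats::rnorm(n * n, 0, config$noise_sd)
    pix[pix < 0] <- 0
    pix[pix > 1] <- 1

    theta_t <- seq(0, 2 * pi, length.out = 721)[-721]
    rt <- rfun(theta_t) / px
    truth <- cbind(x = ctr + rt * cos(theta_t), y = ctr + rt * sin(theta_t))
    im <- spheroid_image(pix, pixel_size_um = px, well_id = well_id,
                         day = day)
    attr(im, "truth_polygon") <- truth
    attr(im, "truth_radius_um") <- radius_um
    attr(im, "truth_protrusion_amp") <- protrusion_amp
    im
  })
  img
}

#' Simulate an Alamar-Blue-like absorbance readout
#'
#' The reduced-dye signal is linear in viable volume:
#' `A570 - A600 = viability_per_volume * V_viable + noise`. Both channels sit
#' on a positive medium baseline. Blank rows (no tissue) are appended for
#' background subtraction checks.
#'
#' @param traj A `growth_trajectory` from [simulate_growth()].
#' @param config A [phantom_config()].
#' @param seed Integer seed for the absorbance noise.
#' @param n_blanks Number of blank wells per day appended (default 2).
#' @return A data.frame with columns `day`, `A570`, `A600`, `well_type`
#'   (`"sample"` or `"blank"`).
#' @export
simulate_viability_readout <- function(traj, config, seed = config$seed,
                                       n_blanks = 2L) {
  stopifnot(inherits(traj, "growth_trajectory"),
            inherits(config, "phantom_config"))
  if (length(traj$days) == 0L)
    stop_spherotrack("trajectory is empty", "invalid_argument")
  baseline <- 0.15
  sd <- config$absorbance_noise_sd
  with_seed(seed, {
    sig <- config$viability_per_volume * traj$viable_volume_um3
    n <- length(sig)
    a600 <- baseline + stats::rnorm(n, 0, sd)
    a570 <- baseline + sig + stats::rnorm(n, 0, sd)
    out <- data.frame(day = traj$days, A570 = a570, A600 = a600,
                      well_type = "sample", stringsAsFactors = FALSE)
    if (n_blanks > 0L) {
      bd <- rep(traj$days, each = n_blanks)
      nb <- length(bd)
      blk <- data.frame(
        day = bd,
        A570 = baseline + stats::rnorm(nb, 0, sd),
        A600 = baseline + stats::rnorm(nb, 0, sd),
        well_type = "blank", stringsAsFactors = FALSE)
      out <- rbind(out, blk)
    }
    out$A570 <- pmax(out$A570, 1e-6)
    out$A600 <- pmax(out$A600, 1e-6)
    out
  })
}

default_dose_list <- function() c(0, 0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1, 5)

#' Generate a full phantom plate dataset
#'
#' Builds a directory tree emulating one embedded-spheroid drug-response
#' experiment: per-well per-day images, a plate layout, an absorbance table,
#' and a ground-truth table. Per-well seeds are a stable hash of
#' `(config$seed, well id)`, so any well regenerates independently.
#' Replicate-to-replicate biological variability is modelled as lognormal
#' jitter (sd 3%) on the starting radius and growth rate.
#'
#' @param config A [phantom_config()].
#' @param out_dir Output directory (created if missing).
#' @param doses_uM Dose grid in uM; default the 9-level design
#'   `0 (vehicle), 0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1, 5`.
#' @param conditions Subset of `c("normoxia", "hypoxia")`.
#' @param n_replicates Spheroids per dose x condition group (default 6).
#' @param days Imaged days (default 1:7).
#' @param cell_line_label Free-text label stored in the layout.
#' @param image_format `"tiff"` (16-bit) or `"png"` (8-bit; needs the png
#'   package).
#' @param write_images Set `FALSE` to skip rasters (tables only), e.g. when
#'   only the ground truth is needed.
#' @return Invisibly, a list with the layout/absorbance/truth data.frames and
#'   the file paths written.
#' @export
generate_plate <- function(config, out_dir,
                           doses_uM = default_dose_list(),
                           conditions = c("normoxia", "hypoxia"),
                           n_replicates = 6L,
                           days = 1:7,
                           cell_line_label = "NCI-H23-like",
                           image_format = c("tiff", "png"),
                           write_images = TRUE) {
  stopifnot(inherits(config, "phantom_config"))
  image_format <- match.arg(image_format)
  if (n_replicates < 1L)
    stop_spherotrack("`n_replicates` must be >= 1", "invalid_argument")
  if (any(doses_uM < 0))
    stop_spherotrack("doses must be non-negative", "invalid_argument")
  conditions <- match.arg(conditions, several.ok = TRUE)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(out_dir, "images")
  if (write_images) dir.create(img_dir, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop_spherotrack(sprintf("cannot create output directory '%s'", out_dir),
                     "io_error")

  grid <- expand.grid(replicate = seq_len(n_replicates),
                      dose_uM = doses_uM, condition = conditions,
                      stringsAsFactors = FALSE)
  grid$well <- sprintf("W%03d", seq_len(nrow(grid)))
  layout <- grid[, c("well", "dose_uM", "condition", "replicate")]
  layout$cell_line_label <- cell_line_label
  layout <- layout[, c("well", "cell_line_label", "dose_uM", "condition",
                       "replicate")]

  abs_rows <- vector("list", nrow(grid))
  truth_rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    w <- grid$well[i]
    sw <- well_seed(config$seed, w)
    cfg_w <- with_seed(sw, {
      jr <- exp(stats::rnorm(1, 0, 0.03))
      jg <- exp(stats::rnorm(1, 0, 0.03))
      cw <- config
      cw$base_radius_um <- config$base_radius_um * jr
      cw$growth_rate_per_day <- config$growth_rate_per_day * jg
      cw
    })
    traj <- simulate_growth(cfg_w, grid$condition[i], grid$dose_uM[i],
                            days = days)
    rd <- simulate_viability_readout(traj, cfg_w,
                                     seed = well_seed(sw, "absorbance"),
                                     n_blanks = 0L)
    rd <- rd[rd$well_type == "sample", c("day", "A570", "A600")]
    abs_rows[[i]] <- cbind(well = w, rd)
    truth_rows[[i]] <- data.frame(
      well = w, day = traj$days, radius_um = traj$radius_um,
      protrusion_amp = traj$protrusion_amp,
      viable_volume_um3 = traj$viable_volume_um3,
      stringsAsFactors = FALSE)
    if (write_images) {
      for (k in seq_along(traj$days)) {
        d <- traj$days[k]
        img <- render_spheroid_image(
          traj$radius_um[k], traj$protrusion_amp[k], cfg_w,
          day_seed = well_seed(sw, sprintf("day%02d", d)),
          well_id = w, day = d)
        fn <- file.path(img_dir, sprintf("%s_%02d.%s", w, d,
                                         if (image_format == "tiff") "tif"
                                         else "png"))
        write_spheroid_image(img, fn, format = image_format)
      }
    }
  }
  absorbance <- do.call(rbind, abs_rows)
  truth <- do.call(rbind, truth_rows)

  paths <- list(layout = file.path(out_dir, "layout.csv"),
                absorbance = file.path(out_dir, "absorbance.csv"),
                truth = file.path(out_dir, "truth.csv"),
                images = if (write_images) img_dir else NULL)
  utils::write.csv(layout, paths$layout, row.names = FALSE, quote = FALSE)
  utils::write.csv(absorbance, paths$absorbance, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(truth, paths$truth, row.names = FALSE, quote = FALSE)
  invisible(list(layout = layout, absorbance = absorbance, truth = truth,
                 paths = paths))
}
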