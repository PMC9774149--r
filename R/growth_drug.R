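# Endpoint aggregation: relative tumor volume (RTV), tumor growth inhibition
# (TGI), diameter ratios, Alamar-Blue viability normalization, invasiveness
# classification, and four-parameter logistic dose-response summaries.

#' Relative tumor volume
#'
#' `RTV = V_terminal / V_original` — terminal spheroid volume relative to the
#' same well's first-day volume, cancelling seeding-size differences.
#'
#' @param V_terminal,V_original Volumes (> 0), any common unit.
#' @return RTV (dimensionless).
#' @export
relative_tumor_volume <- function(V_terminal, V_original) {
  if (!is.numeric(V_terminal) || !is.numeric(V_original) ||
      any(!is.finite(V_terminal)) || any(!is.finite(V_original)) ||
      any(V_terminal <= 0) || any(V_original <= 0))
    stop_spherotrack("volumes must be positive and finite",
                     "invalid_argument")
  V_terminal / V_original
}

#' Tumor growth inhibition
#'
#' `TGI = (RTV_control - RTV_treatment) / RTV_control * 100` (percent).
#' Negative TGI means the treated group grew more than control.
#'
#' @param RTV_control Mean control RTV (> 0).
#' @param RTV_treatment Mean treated RTV (>= 0).
#' @return TGI in percent.
#' @export
tumor_growth_inhibition <- function(RTV_control, RTV_treatment) {
  if (!is.numeric(RTV_control) || any(!is.finite(RTV_control)) ||
      any(RTV_control <= 0))
    stop_spherotrack("`RTV_control` must be positive and finite",
                     "invalid_argument")
  if (!is.numeric(RTV_treatment) || any(!is.finite(RTV_treatment)) ||
      any(RTV_treatment < 0))
    stop_spherotrack("`RTV_treatment` must be non-negative and finite",
                     "invalid_argument")
  (RTV_control - RTV_treatment) / RTV_control * 100
}

#' Diameter ratio between two days
#'
#' Ratio of equivalent diameters `d(day_a) / d(day_b)` for one well's series;
#' the default contrasts day 7 against day 1.
#'
#' @param series Data.frame with columns `day` and `d_um` (one well).
#' @param day_a,day_b Days to compare (defaults 7 and 1).
#' @return Dimensionless ratio.
#' @export
diameter_ratio <- function(series, day_a = 7L, day_b = 1L) {
  if (!is.data.frame(series) || !all(c("day", "d_um") %in% names(series)))
    stop_spherotrack("`series` needs columns `day` and `d_um`",
                     "invalid_argument")
  ia <- match(day_a, series$day); ib <- match(day_b, series$day)
  if (is.na(ia) || is.na(ib))
    stop_spherotrack(
      sprintf("day %s and/or %s missing from series%s", day_a, day_b,
              if (!is.null(series$well_id[1]) && !is.na(series$well_id[1]))
                paste0(" (well ", series$well_id[1], ")") else ""),
      "invalid_argument")
  series$d_um[ia] / series$d_um[ib]
}

viability_signal <- function(pairs) {
  if (!is.data.frame(pairs) || !all(c("A570", "A600") %in% names(pairs)))
    stop_spherotrack("absorbance pairs need columns `A570` and `A600`",
                     "invalid_argument")
  pairs$A570 - pairs$A600
}

#' Normalize Alamar-Blue viability to control
#'
#' The reduction signal is the background-subtracted `A570 - A600`.
#' Viability is the sample-to-control ratio of mean signals, in percent, with
#' the replicate SEM propagated through the ratio.
#'
#' @param sample,control Data.frames of absorbance pairs (`A570`, `A600`),
#'   one row per replicate.
#' @param blank Optional blank-well pairs; their mean signal is subtracted
#'   from every well.
#' @return List with `viability_percent` and `sem`.
#' @export
normalize_viability <- function(sample, control, blank = NULL) {
  s <- viability_signal(sample)
  ctl <- viability_signal(control)
  if (length(ctl) < 1L)
    stop_spherotrack("need at least one control replicate",
                     "invalid_argument")
  if (!is.null(blank) && nrow(blank) > 0) {
    b <- mean(viability_signal(blank))
    s <- s - b
    ctl <- ctl - b
  }
  ms <- mean(s); mc <- mean(ctl)
  if (mc <= 0)
    stop_spherotrack("control signal is non-positive: degenerate control",
                     "degenerate_control")
  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  viability <- 100 * ms / mc
  rel <- sqrt((sem(s) / ms)^2 + (sem(ctl) / mc)^2)
  list(viability_percent = viability,
       sem = if (is.finite(rel)) abs(viability) * rel else NA_real_)
}

#' Classify invasiveness from terminal EPI
#'
#' Strict rule: `less-invasive` iff `EPI < threshold` (default 0.5),
#' otherwise `invasive`; the boundary value itself classifies as invasive.
#'
#' @param EPI_terminal Finite EPI value(s).
#' @param threshold Classification threshold (default 0.5).
#' @return Character vector of `"invasive"` / `"less-invasive"`.
#' @export
classify_invasiveness <- function(EPI_terminal, threshold = 0.5) {
  if (!is.numeric(EPI_terminal) || any(!is.finite(EPI_terminal)))
    stop_spherotrack("`EPI_terminal` must be finite", "invalid_argument")
  check_number(threshold, "threshold")
  ifelse(EPI_terminal < threshold, "less-invasive", "invasive")
}

fourpl <- function(dose, bottom, top, ic50, slope) {
  bottom + (top - bottom) / (1 + (dose / ic50)^slope)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit on log dose:
#' `v(C) = bottom + (top - bottom) / (1 + (C/IC50)^slope)`.
#' If neither the observations nor the fitted curve cross 50%, the status is
#' `ic50-not-reached` and no IC50 is reported — the honest outcome for weakly
#' responsive lines. A positive dose-viability association is flagged as an
#' anomalous direction.
#'
#' @param doses Positive doses (uM), >= 4 distinct values; vehicle (dose 0)
#'   is excluded here and should anchor normalization at 100% upstream.
#' @param viabilities Percent viability at each dose.
#' @return A `dose_response_fit`: list with `status` (`"ok"`,
#'   `"ic50-not-reached"`, `"fit-failed"`), `bottom`, `top`, `ic50`, `slope`,
#'   `ic50_ci` (95%, log-normal, when available), `rmse`,
#'   `anomalous_direction`.
#' @export
fit_dose_response <- function(doses, viabilities) {
  keep <- is.finite(doses) & is.finite(viabilities) & doses > 0
  doses <- doses[keep]; viabilities <- viabilities[keep]
  if (length(unique(doses)) < 4L)
    stop_spherotrack("need >= 4 distinct positive doses",
                     "insufficient_data")
  ld <- log10(doses)
  anom <- stats::cor(ld, viabilities, method = "spearman") > 0.5

  ss <- function(p) {
    v <- fourpl(doses, p[1], p[2], 10^p[3], exp(p[4]))
    sum((v - viabilities)^2)
  }
  init <- c(min(viabilities), max(viabilities), stats::median(ld), 0)
  fit <- try(stats::optim(init, ss, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12)),
             silent = TRUE)
  if (inherits(fit, "try-error") || !is.finite(fit$value)) {
    return(structure(list(status = "fit-failed", bottom = NA_real_,
                          top = NA_real_, ic50 = NA_real_, slope = NA_real_,
                          ic50_ci = c(NA_real_, NA_real_), rmse = NA_real_,
                          anomalous_direction = anom,
                          diagnostics = "optimizer error"),
                     class = "dose_response_fit"))
  }
  p <- fit$par
  bottom <- p[1]; top <- p[2]; ic50 <- 10^p[3]; slope <- exp(p[4])
  n <- length(doses)
  rmse <- sqrt(fit$value / n)
  fitted_min <- min(fourpl(c(doses, max(doses)), bottom, top, ic50, slope))
  if (min(viabilities) > 50 && fitted_min > 50) {
    return(structure(list(status = "ic50-not-reached", bottom = bottom,
                          top = top, ic50 = NA_real_, slope = slope,
                          ic50_ci = c(NA_real_, NA_real_), rmse = rmse,
                          anomalous_direction = anom, diagnostics = NULL),
                     class = "dose_response_fit"))
  }
  # 95% CI on log10(IC50) from the numerical Hessian of the SSE surface
  ci <- c(NA_real_, NA_real_)
  hess <- try(stats::optimHess(p, ss), silent = TRUE)
  if (!inherits(hess, "try-error") && n > 4) {
    sigma2 <- fit$value / (n - 4)
    cov <- try(solve(hess / 2) * sigma2, silent = TRUE)
    if (!inherits(cov, "try-error") && is.finite(cov[3, 3]) &&
        cov[3, 3] > 0) {
      se <- sqrt(cov[3, 3])
      ci <- 10^(p[3] + c(-1.96, 1.96) * se)
    }
  }
  structure(list(status = "ok", bottom = bottom, top = top, ic50 = ic50,
                 slope = slope, ic50_ci = ci, rmse = rmse,
                 anomalous_direction = anom, diagnostics = NULL),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit> status:", x$status, "\n")
  if (identical(x$status, "ok"))
    cat(sprintf("  IC50 = %.4g uM (95%% CI %.4g-%.4g), slope %.3g, top %.3g, bottom %.3g, RMSE %.3g\n",
                x$ic50, x$ic50_ci[1], x$ic50_ci[2], x$slope, x$top,
                x$bottom, x$rmse))
  invisible(x)
}

group_mean_sem <- function(df, value_col, by_cols) {
  agg <- stats::aggregate(df[[value_col]], df[by_cols], function(v) {
    v <- v[is.finite(v)]
    c(mean = mean(v), sem = if (length(v) > 1)
      stats::sd(v) / sqrt(length(v)) else 0, n = length(v))
  })
  out <- cbind(agg[by_cols], as.data.frame(agg$x))
  names(out) <- c(by_cols, paste0(value_col, c("_mean", "_sem", "_n")))
  out
}

#' Summarize a plate into drug-response endpoint tables
#'
#' Joins per-image morphometrics with the plate layout and absorbance table
#' and reproduces the standard figure panels of an embedded-spheroid drug
#' study: per-day group means +/- SEM of viability, diameter, roughness and
#' EPI; terminal-day cross-sections with invasiveness classification and
#' diameter ratios; TGI per dose within each oxygen condition (vehicle group
#' of the same condition as control); and a 4PL dose-response fit per
#' condition.
#'
#' @param metrics Data.frame from [measure_image()] rows (or `metrics.csv`).
#' @param absorbance Data.frame with `well`, `day`, `A570`, `A600`.
#' @param layout Data.frame from [load_plate_layout()].
#' @param terminal_day Terminal day for RTV/TGI (default 7).
#' @param baseline_day First culture day (default 1).
#' @param epi_threshold Invasiveness threshold (default 0.5).
#' @return List of data.frames: `timecourse`, `day_terminal`, `tgi`,
#'   `dose_response`.
#' @export
summarize_plate <- function(metrics, absorbance, layout,
                            terminal_day = 7L, baseline_day = 1L,
                            epi_threshold = 0.5) {
  need <- function(df, cols, what)
    if (!all(cols %in% names(df)))
      stop_spherotrack(sprintf("%s must have columns: %s", what,
                               paste(cols, collapse = ", ")),
                       "invalid_argument")
  need(layout, c("well", "dose_uM", "condition", "replicate"), "layout")
  need(metrics, c("well_id", "day", "S_um2", "EPI", "roughness", "d_um",
                  "V_um3"), "metrics")
  need(absorbance, c("well", "day", "A570", "A600"), "absorbance")

  missing_wells <- setdiff(layout$well, unique(metrics$well_id))
  if (length(missing_wells))
    warning(sprintf("wells in layout without metrics, excluded: %s",
                    paste(missing_wells, collapse = ", ")))
  m <- merge(metrics, layout, by.x = "well_id", by.y = "well")

  # --- viability, normalized within (condition, day) to the vehicle group ---
  a <- merge(absorbance, layout, by = "well")
  a$signal <- a$A570 - a$A600
  a$viability <- NA_real_
  for (cond in unique(a$condition)) {
    for (d in unique(a$day[a$condition == cond])) {
      sel <- a$condition == cond & a$day == d
      ctl <- a$signal[sel & a$dose_uM == 0]
      if (length(ctl) == 0 || mean(ctl) <= 0) next
      a$viability[sel] <- 100 * a$signal[sel] / mean(ctl)
    }
  }

  by3 <- c("condition", "dose_uM", "day")
  tc <- Reduce(function(u, v) merge(u, v, by = by3, all = TRUE), list(
    group_mean_sem(a, "viability", by3),
    group_mean_sem(m, "d_um", by3),
    group_mean_sem(m, "roughness", by3),
    group_mean_sem(m, "EPI", by3)))
  tc <- tc[order(tc$condition, tc$dose_uM, tc$day), ]
  rownames(tc) <- NULL

  # --- per-well RTV and diameter ratio ---
  rtv_rows <- lapply(split(m, m$well_id), function(w) {
    it <- match(terminal_day, w$day); ib <- match(baseline_day, w$day)
    if (is.na(it) || is.na(ib)) return(NULL)
    data.frame(well = w$well_id[1], condition = w$condition[1],
               dose_uM = w$dose_uM[1],
               RTV = relative_tumor_volume(w$V_um3[it], w$V_um3[ib]),
               d_ratio = w$d_um[it] / w$d_um[ib],
               EPI_terminal = w$EPI[it], stringsAsFactors = FALSE)
  })
  rtv <- do.call(rbind, rtv_rows)
  if (is.null(rtv) || !nrow(rtv))
    stop_spherotrack(sprintf(
      "no well has both day %d and day %d metrics", baseline_day,
      terminal_day), "invalid_argument")

  tgi_rows <- list()
  for (cond in unique(rtv$condition)) {
    rc <- rtv[rtv$condition == cond, ]
    ctl <- rc$RTV[rc$dose_uM == 0]
    if (!length(ctl)) {
      warning(sprintf("no vehicle wells under %s: TGI skipped", cond))
      next
    }
    for (dz in sort(unique(rc$dose_uM[rc$dose_uM > 0]))) {
      trt <- rc$RTV[rc$dose_uM == dz]
      tgi_rows[[length(tgi_rows) + 1L]] <- data.frame(
        dose_uM = dz, condition = cond,
        RTV_control = mean(ctl), RTV_treatment = mean(trt),
        TGI_percent = tumor_growth_inhibition(mean(ctl), mean(trt)),
        n_control = length(ctl), n_treatment = length(trt),
        stringsAsFactors = FALSE)
    }
  }
  tgi <- if (length(tgi_rows)) do.call(rbind, tgi_rows) else
    data.frame(dose_uM = numeric(0), condition = character(0),
               RTV_control = numeric(0), RTV_treatment = numeric(0),
               TGI_percent = numeric(0), n_control = integer(0),
               n_treatment = integer(0))

  # --- terminal-day cross-section ---
  vt <- a[a$day == terminal_day, ]
  day_t <- merge(
    merge(group_mean_sem(rtv, "RTV", c("condition", "dose_uM")),
          group_mean_sem(rtv, "d_ratio", c("condition", "dose_uM")),
          by = c("condition", "dose_uM")),
    group_mean_sem(rtv, "EPI_terminal", c("condition", "dose_uM")),
    by = c("condition", "dose_uM"))
  if (nrow(vt) && any(is.finite(vt$viability)))
    day_t <- merge(day_t,
                   group_mean_sem(vt, "viability", c("condition", "dose_uM")),
                   by = c("condition", "dose_uM"), all.x = TRUE)
  day_t$invasiveness <- classify_invasiveness(day_t$EPI_terminal_mean,
                                              epi_threshold)
  day_t <- day_t[order(day_t$condition, day_t$dose_uM), ]
  rownames(day_t) <- NULL

  # --- dose-response per condition, terminal-day viability ---
  dr_rows <- list()
  for (cond in unique(vt$condition)) {
    sub <- vt[vt$condition == cond & vt$dose_uM > 0 &
                is.finite(vt$viability), ]
    if (!nrow(sub)) next
    gm <- stats::aggregate(viability ~ dose_uM, sub, mean)
    fit <- if (length(unique(gm$dose_uM)) >= 4)
      try(fit_dose_response(gm$dose_uM, gm$viability), silent = TRUE)
    else NULL
    if (is.null(fit) || inherits(fit, "try-error")) next
    dr_rows[[length(dr_rows) + 1L]] <- data.frame(
      condition = cond, status = fit$status, ic50_uM = fit$ic50,
      slope = fit$slope, top = fit$top, bottom = fit$bottom,
      rmse = fit$rmse, stringsAsFactors = FALSE)
  }
  dose_response <- if (length(dr_rows)) do.call(rbind, dr_rows) else
    data.frame(condition = character(0), status = character(0),
               ic50_uM = numeric(0), slope = numeric(0), top = numeric(0),
               bottom = numeric(0), rmse = numeric(0))

  list(timecourse = tc, day_terminal = day_t, tgi = tgi,
       dose_response = dose_response)
}
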