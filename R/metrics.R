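# Per-image morphometrics: area, perimeter, equivalent perimeter, excess
# perimeter index (EPI), equivalent diameter, boundary roughness, and the
# spherical volume approximation.
#
# EPI = (P_o - P_e)/P_e with P_e = 2*sqrt(pi*S): the fractional excess of the
# measured boundary over the circle of equal area. Zero for a circle, > 0 for
# any other simple curve (isoperimetric inequality), rising with invasive
# protrusions.

as_contour_xy <- function(contour) {
  if (inherits(contour, "spheroid_contour"))
    return(list(x = contour$x, y = contour$y))
  if (is.matrix(contour) && ncol(contour) == 2L)
    return(list(x = contour[, 1], y = contour[, 2]))
  if (is.list(contour) && !is.null(contour$x) && !is.null(contour$y))
    return(list(x = contour$x, y = contour$y))
  stop_spherotrack("not a contour: need spheroid_contour, 2-col matrix, or list(x, y)",
                   "invalid_argument")
}

#' Polygon area of a closed contour
#'
#' Shoelace area of the closed polygon (closure edge implicit), converted to
#' square microns. Clockwise input is reoriented internally; the result is
#' always positive.
#'
#' @param contour A `spheroid_contour`, 2-column matrix, or `list(x, y)` in
#'   pixel units.
#' @param pixel_size_um Microns per pixel.
#' @return Area in um^2.
#' @export
polygon_area <- function(contour, pixel_size_um = 1) {
  p <- as_contour_xy(contour)
  if (length(p$x) < 3L)
    stop_spherotrack("degenerate polygon (< 3 vertices)", "invalid_argument")
  check_number(pixel_size_um, "pixel_size_um", min = .Machine$double.eps)
  abs(signed_area(p$x, p$y)) * pixel_size_um^2
}

#' Polygon perimeter of a closed contour
#'
#' Sum of consecutive vertex distances including the closure edge, in um.
#'
#' @inheritParams polygon_area
#' @return Perimeter `P_o` in um.
#' @export
polygon_perimeter <- function(contour, pixel_size_um = 1) {
  p <- as_contour_xy(contour)
  if (length(p$x) < 3L)
    stop_spherotrack("degenerate polygon (< 3 vertices)", "invalid_argument")
  check_number(pixel_size_um, "pixel_size_um", min = .Machine$double.eps)
  dx <- diff(c(p$x, p$x[1]))
  dy <- diff(c(p$y, p$y[1]))
  sum(sqrt(dx^2 + dy^2)) * pixel_size_um
}

#' Equivalent perimeter
#'
#' Perimeter of the circle whose area equals `S`: `P_e = 2*sqrt(pi*S)`.
#'
#' @param S Area in um^2 (> 0).
#' @return `P_e` in um.
#' @export
equivalent_perimeter <- function(S) {
  if (!is.numeric(S) || any(!is.finite(S)) || any(S <= 0))
    stop_spherotrack("`S` must be positive and finite", "invalid_argument")
  2 * sqrt(pi * S)
}

#' Excess perimeter index
#'
#' `EPI = (P_o - P_e) / P_e`: dimensionless, scale-invariant, 0 for a circle
#' and >= 0 for every simple closed curve.
#'
#' @param P_o Measured perimeter (> 0).
#' @param P_e Equivalent perimeter (> 0).
#' @return EPI (dimensionless).
#' @export
excess_perimeter_index <- function(P_o, P_e) {
  if (!is.numeric(P_o) || !is.numeric(P_e) || any(!is.finite(P_o)) ||
      any(!is.finite(P_e)) || any(P_o <= 0) || any(P_e <= 0))
    stop_spherotrack("perimeters must be positive and finite",
                     "invalid_argument")
  (P_o - P_e) / P_e
}

#' Equivalent-circle diameter
#'
#' `d = 2*sqrt(S/pi)`, the diameter of the circle of equal area — robust for
#' non-circular invasive outlines and consistent with the equivalent
#' perimeter.
#'
#' @param S Area in um^2 (> 0).
#' @return Diameter in um.
#' @export
equivalent_diameter <- function(S) {
  if (!is.numeric(S) || any(!is.finite(S)) || any(S <= 0))
    stop_spherotrack("`S` must be positive and finite", "invalid_argument")
  2 * sqrt(S / pi)
}

#' Boundary roughness
#'
#' Coefficient of variation `sd(r)/mean(r)` of vertex distances from the
#' polygon's area centroid: scale-invariant, ~0 for a circle, increasing with
#' protrusions.
#'
#' @param contour A contour with at least 16 vertices.
#' @return Roughness (dimensionless).
#' @export
roughness <- function(contour) {
  p <- as_contour_xy(contour)
  n <- length(p$x)
  if (n < 16L)
    stop_spherotrack("contour must have >= 16 vertices", "invalid_argument")
  x <- p$x; y <- p$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- 0.5 * sum(cross)
  if (abs(a) < .Machine$double.eps)
    stop_spherotrack("degenerate polygon (zero area)", "invalid_argument")
  cx <- sum((x + xn) * cross) / (6 * a)
  cy <- sum((y + yn) * cross) / (6 * a)
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  stats::sd(r) / mean(r)
}

#' Spherical volume from diameter
#'
#' `V = (4/3) * pi * (d/2)^3`: the sphere approximation used to convert a
#' focal-plane diameter into a volume.
#'
#' @param d Diameter in um (> 0).
#' @return Volume in um^3.
#' @export
spheroid_volume <- function(d) {
  if (!is.numeric(d) || any(!is.finite(d)) || any(d <= 0))
    stop_spherotrack("`d` must be positive and finite", "invalid_argument")
  (4 / 3) * pi * (d / 2)^3
}

#' Measure one image end to end
#'
#' Runs segmentation, contour extraction and all shape metrics, producing one
#' morphometric record. Errors carry the well and day context.
#'
#' @param image A [spheroid_image()].
#' @param settings A [segmentation_settings()].
#' @return One-row data.frame: `well_id`, `day`, `S_um2`, `P_o_um`, `P_e_um`,
#'   `EPI`, `roughness`, `d_um`, `V_um3`.
#' @export
measure_image <- function(image, settings = segmentation_settings()) {
  stopifnot(inherits(image, "spheroid_image"))
  ctx <- sprintf("well %s day %s", image$well_id, image$day)
  rec <- withCallingHandlers(
    {
      mask <- segment_spheroid(image, settings)
      contour <- extract_contour(mask)
      measure_contour(contour)
    },
    spherotrack_error = function(e) {
      e$message <- paste0("[", ctx, "] ", conditionMessage(e))
      stop(e)
    })
  rec$well_id <- image$well_id
  rec$day <- image$day
  rec[, c("well_id", "day", "S_um2", "P_o_um", "P_e_um", "EPI",
          "roughness", "d_um", "V_um3")]
}

#' Morphometrics of a single contour
#'
#' @param contour A `spheroid_contour` (carries its pixel size).
#' @param pixel_size_um Override for plain-coordinate contours.
#' @return One-row data.frame of all shape metrics.
#' @export
measure_contour <- function(contour, pixel_size_um = NULL) {
  px <- pixel_size_um %||%
    (if (inherits(contour, "spheroid_contour")) contour$pixel_size_um else 1)
  S <- polygon_area(contour, px)
  P_o <- polygon_perimeter(contour, px)
  P_e <- equivalent_perimeter(S)
  d <- equivalent_diameter(S)
  data.frame(
    well_id = NA_character_, day = NA_integer_,
    S_um2 = S, P_o_um = P_o, P_e_um = P_e,
    EPI = excess_perimeter_index(P_o, P_e),
    roughness = roughness(contour),
    d_um = d, V_um3 = spheroid_volume(d),
    stringsAsFactors = FALSE)
}
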