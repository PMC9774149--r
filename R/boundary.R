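# Boundary detection: tile stitching, classical brightfield segmentation
# (smooth -> Otsu on the inverted image -> close -> fill -> largest
# component), and sub-pixel iso-contour extraction.
#
# This stage replaces a proprietary learned boundary detector with a
# documented classical pipeline; the contract is a single closed sub-pixel
# contour per image, which is what all downstream shape metrics consume.

# ---- low-level raster ops ---------------------------------------------------

# separable Gaussian blur via banded kernel matrices; rows renormalized so
# borders keep unit mass (replicate-equivalent)
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  hw <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-hw:hw, sd = sigma_px)
  band <- function(n) {
    K <- matrix(0, n, n)
    for (d in -hw:hw) {
      idx <- seq_len(n - abs(d))
      K[cbind(idx + max(0, -d), idx + max(0, d))] <- k[d + hw + 1]
    }
    K / rowSums(K)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

# Otsu's between-class variance maximization on a 256-bin histogram
otsu_threshold <- function(v) {
  h <- tabulate(pmin(256L, pmax(1L, as.integer(v * 255) + 1L)), 256L)
  w <- cumsum(h)
  mu <- cumsum(h * (seq_len(256) - 1))
  n <- w[256]; mu_t <- mu[256]
  wb <- w[-256]; wf <- n - wb
  valid <- wb > 0 & wf > 0
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (mu_t * wb[valid] / n - mu[-256][valid])^2 /
    (wb[valid] / n * wf[valid] / n) / n^2
  (which.max(bcv) - 0.5) / 255
}

shift_logical <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

disk_offsets <- function(radius_px) {
  r <- max(0L, as.integer(floor(radius_px)))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius_px^2, , drop = FALSE]
}

binary_dilate <- function(m, offs) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(offs)))
    out <- out | shift_logical(m, offs$dr[i], offs$dc[i])
  out
}

binary_erode <- function(m, offs) {
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (i in seq_len(nrow(offs)))
    out <- out & shift_logical(m, offs$dr[i], offs$dc[i])
  out
}

# vectorized-frontier BFS over 4-connected TRUE pixels
flood_fill <- function(mask, seeds) {
  nr <- nrow(mask); n <- length(mask)
  visited <- logical(n)
  seeds <- seeds[mask[seeds]]
  visited[seeds] <- TRUE
  frontier <- seeds
  while (length(frontier)) {
    up <- frontier[frontier %% nr != 1L] - 1L
    down <- frontier[frontier %% nr != 0L] + 1L
    left <- frontier - nr
    right <- frontier + nr
    cand <- c(up, down, left[left >= 1L], right[right <= n])
    cand <- unique(cand[mask[cand] & !visited[cand]])
    visited[cand] <- TRUE
    frontier <- cand
  }
  matrix(visited, nr, ncol(mask))
}

keep_largest_component <- function(mask) {
  remaining <- mask
  best <- NULL; best_n <- 0L
  while (any(remaining)) {
    seed <- which(remaining)[1L]
    comp <- flood_fill(remaining, seed)
    n <- sum(comp)
    if (n > best_n) { best <- comp; best_n <- n }
    remaining <- remaining & !comp
  }
  best %||% mask
}

fill_holes <- function(mask) {
  bg <- !mask
  nr <- nrow(mask); nc <- ncol(mask)
  border <- unique(c(seq_len(nr), seq_len(nr) + (nc - 1L) * nr,
                     (seq_len(nc) - 1L) * nr + 1L, seq_len(nc) * nr))
  reached <- flood_fill(bg, border)
  mask | (bg & !reached)
}

# ---- operations -------------------------------------------------------------

#' Stitch four image tiles into one mosaic
#'
#' Assembles a 2x2 acquisition (no overlap, no registration) into a single
#' image twice the tile size in each dimension.
#'
#' @param tiles List of exactly 4 [spheroid_image()]s with identical shapes
#'   and pixel sizes.
#' @param layout Integer 2x2 matrix giving, for each mosaic quadrant, the
#'   index of the tile placed there. Default row-major: top-left, top-right,
#'   bottom-left, bottom-right.
#' @return A [spheroid_image()] mosaic.
#' @export
stitch_tiles <- function(tiles, layout = matrix(1:4, 2, 2, byrow = TRUE)) {
  if (!is.list(tiles) || length(tiles) != 4L)
    stop_spherotrack("`tiles` must be a list of exactly 4 images",
                     "invalid_argument")
  if (!all(vapply(tiles, inherits, logical(1), "spheroid_image")))
    stop_spherotrack("all tiles must be spheroid_image objects",
                     "invalid_argument")
  dims <- vapply(tiles, function(t) dim(t$pixels), integer(2))
  if (any(dims != dims[, 1]))
    stop_spherotrack("tiles must share one shape", "invalid_argument")
  pxs <- vapply(tiles, `[[`, numeric(1), "pixel_size_um")
  if (max(pxs) - min(pxs) > 1e-9)
    stop_spherotrack("tiles must share one pixel size", "invalid_argument")
  if (!identical(dim(layout), c(2L, 2L)) || !setequal(layout, 1:4))
    stop_spherotrack("`layout` must be a 2x2 permutation of 1:4",
                     "invalid_argument")
  top <- cbind(tiles[[layout[1, 1]]]$pixels, tiles[[layout[1, 2]]]$pixels)
  bot <- cbind(tiles[[layout[2, 1]]]$pixels, tiles[[layout[2, 2]]]$pixels)
  spheroid_image(rbind(top, bot), pxs[1],
                 well_id = tiles[[1]]$well_id, day = tiles[[1]]$day)
}

#' Segmentation settings
#'
#' @param sigma_um Gaussian pre-smoothing scale in um (default 2).
#' @param close_radius_um Morphological closing disk radius in um (default 5).
#' @param min_area_um2 Minimum acceptable spheroid area in um^2
#'   (default 2000).
#' @return A named list of class `segmentation_settings`.
#' @export
segmentation_settings <- function(sigma_um = 2, close_radius_um = 5,
                                  min_area_um2 = 2000) {
  check_number(sigma_um, "sigma_um", min = 0)
  check_number(close_radius_um, "close_radius_um", min = 0)
  check_number(min_area_um2, "min_area_um2", min = 0)
  structure(list(sigma_um = sigma_um, close_radius_um = close_radius_um,
                 min_area_um2 = min_area_um2),
            class = "segmentation_settings")
}

#' Segment the spheroid from a brightfield image
#'
#' Classical pipeline: Gaussian smoothing, global Otsu threshold on the
#' inverted image (the spheroid is dark on a bright field), morphological
#' closing, hole filling, and retention of the largest connected component.
#'
#' @param image A [spheroid_image()].
#' @param params A [segmentation_settings()].
#' @return A `spheroid_mask`: list with logical `mask` (TRUE = spheroid),
#'   `provenance` (settings and chosen threshold), and image metadata.
#' @export
segment_spheroid <- function(image, params = segmentation_settings()) {
  stopifnot(inherits(image, "spheroid_image"))
  if (!inherits(params, "segmentation_settings"))
    params <- do.call(segmentation_settings, as.list(params))
  px <- image$pixel_size_um
  inv <- 1 - image$pixels
  inv <- inv - min(inv)                     # intensity-shift invariance
  rng <- max(inv)
  if (rng < 0.05)
    stop_spherotrack("image is blank or saturated: no contrast",
                     "no_spheroid_found")
  inv <- inv / rng
  sm <- gaussian_blur(inv, params$sigma_um / px)
  thr <- otsu_threshold(sm)
  mask <- sm > thr
  offs <- disk_offsets(params$close_radius_um / px)
  if (nrow(offs) > 1) {
    mask <- binary_erode(binary_dilate(mask, offs), offs)
  }
  mask <- fill_holes(mask)
  mask <- keep_largest_component(mask)
  min_px <- params$min_area_um2 / px^2
  if (is.null(mask) || sum(mask) < min_px)
    stop_spherotrack(
      sprintf("no foreground component of area >= %g um^2 found",
              params$min_area_um2),
      "no_spheroid_found")
  structure(list(mask = mask,
                 provenance = list(settings = unclass(params),
                                   threshold = thr),
                 pixel_size_um = px, well_id = image$well_id,
                 day = image$day),
            class = "spheroid_mask")
}

#' Extract the sub-pixel boundary contour of a mask
#'
#' The binary mask is lightly smoothed (1-px Gaussian) and its 0.5 iso-level
#' traced marching-squares style; the closed contour enclosing the largest
#' area is returned, oriented so the shoelace area of the stored (x, y)
#' coordinates is positive. Vertices are in pixel units with integer
#' coordinates at pixel centers.
#'
#' @param mask A `spheroid_mask` from [segment_spheroid()].
#' @param smooth_sigma_px Gaussian sigma for mask smoothing (default 1).
#' @return A `spheroid_contour`: list with numeric `x`, `y` (closure
#'   implicit), `pixel_size_um`, `well_id`, `day`.
#' @export
extract_contour <- function(mask, smooth_sigma_px = 1) {
  stopifnot(inherits(mask, "spheroid_mask"))
  m <- mask$mask
  nr <- nrow(m); nc <- ncol(m)
  if (any(m[1, ]) || any(m[nr, ]) || any(m[, 1]) || any(m[, nc]))
    stop_spherotrack("spheroid touches the image border: boundary clipped",
                     "boundary_clipped")
  z <- gaussian_blur(m * 1, smooth_sigma_px)
  cl <- grDevices::contourLines(x = 0:(nr - 1), y = 0:(nc - 1), z = z,
                                levels = 0.5)
  if (length(cl) == 0L)
    stop_spherotrack("no iso-contour found", "no_spheroid_found")
  closed <- vapply(cl, function(cc) {
    length(cc$x) > 3 && cc$x[1] == cc$x[length(cc$x)] &&
      cc$y[1] == cc$y[length(cc$y)]
  }, logical(1))
  if (!any(closed))
    stop_spherotrack("only open contours found: boundary clipped",
                     "boundary_clipped")
  areas <- vapply(cl, function(cc) {
    if (length(cc$x) < 4) return(0)
    abs(signed_area(cc$x[-length(cc$x)], cc$y[-length(cc$y)]))
  }, numeric(1))
  areas[!closed] <- 0
  best <- cl[[which.max(areas)]]
  # grid dim 1 (contourLines x) runs along matrix rows = image y;
  # dim 2 runs along columns = image x
  y <- best$x[-length(best$x)]
  x <- best$y[-length(best$y)]
  if (signed_area(x, y) < 0) { x <- rev(x); y <- rev(y) }
  if (length(x) < 8L)
    stop_spherotrack("contour degenerate (< 8 vertices)", "no_spheroid_found")
  structure(list(x = x, y = y, pixel_size_um = mask$pixel_size_um,
                 well_id = mask$well_id, day = mask$day),
            class = "spheroid_contour")
}
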