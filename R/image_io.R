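# Grayscale image container and file I/O.
#
# No TIFF reader is available in the dependency footprint, so a minimal
# baseline TIFF 6.0 codec (grayscale, 8/16-bit, uncompressed) lives here.
# PNG is supported when the optional `png` package is installed.

#' Grayscale spheroid image
#'
#' A single-channel raster with physical pixel size. Pixels are stored as a
#' numeric matrix in `[0, 1]`, row index = y (increasing downward), column
#' index = x; pixel centers sit at integer coordinates with origin top-left.
#'
#' @param pixels Numeric matrix in `[0, 1]`.
#' @param pixel_size_um Microns per pixel (> 0).
#' @param well_id Character well identifier.
#' @param day Integer acquisition day.
#' @return An object of class `spheroid_image`.
#' @export
spheroid_image <- function(pixels, pixel_size_um, well_id = NA_character_,
                           day = NA_integer_) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    stop_spherotrack("`pixels` must be a non-empty numeric matrix",
                     "invalid_argument")
  check_number(pixel_size_um, "pixel_size_um", min = .Machine$double.eps)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 well_id = well_id, day = as.integer(day)),
            class = "spheroid_image")
}

#' @export
print.spheroid_image <- function(x, ...) {
  cat(sprintf("<spheroid_image> %d x %d px, %.3g um/px, well %s day %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              x$well_id, x$day))
  invisible(x)
}

# ---- little-endian byte helpers --------------------------------------------

le_bytes <- function(value, nbytes) {
  out <- raw(nbytes)
  for (i in seq_len(nbytes)) {
    out[i] <- as.raw(value %% 256)
    value <- value %/% 256
  }
  out
}

le_value <- function(bytes, signed = FALSE) {
  v <- sum(as.numeric(bytes) * 256^(seq_along(bytes) - 1))
  v
}

# ---- TIFF write -------------------------------------------------------------

tiff_ifd_entry <- function(tag, type, count, value) {
  # value already raw(4) or a number to be packed
  if (!is.raw(value)) value <- le_bytes(value, 4)
  c(le_bytes(tag, 2), le_bytes(type, 2), le_bytes(count, 4), value)
}

#' Write a spheroid image to disk
#'
#' TIFF output is 16-bit grayscale, uncompressed, little-endian, with the
#' pixel size recorded as X/Y resolution in pixels per centimeter. PNG output
#' is 8-bit grayscale via the `png` package (pixel size not embedded).
#'
#' @param image A [spheroid_image()].
#' @param path Output file path.
#' @param format `"tiff"` or `"png"`.
#' @param bits Bit depth for TIFF (8 or 16).
#' @return Invisibly, `path`.
#' @export
write_spheroid_image <- function(image, path, format = c("tiff", "png"),
                                 bits = 16L) {
  stopifnot(inherits(image, "spheroid_image"))
  format <- match.arg(format)
  if (format == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop_spherotrack("PNG output requires the 'png' package", "io_error")
    mp <- image$pixels
    mp[mp < 0] <- 0
    mp[mp > 1] <- 1
    png::writePNG(mp, target = path)
    return(invisible(path))
  }
  if (!bits %in% c(8L, 16L))
    stop_spherotrack("TIFF bit depth must be 8 or 16", "invalid_argument")
  m <- image$pixels
  m[m < 0] <- 0
  m[m > 1] <- 1
  h <- nrow(m); w <- ncol(m)
  maxv <- 2^bits - 1
  v <- as.vector(t(m))                         # row-major
  v <- round(v * maxv)
  if (bits == 16L) {
    data <- as.raw(rbind(v %% 256, v %/% 256)) # per-value little-endian
  } else {
    data <- as.raw(v)
  }
  nbytes <- length(data)
  # file: header(8) | pixel data | IFD | 2 rationals (8 bytes each)
  ifd_off <- 8 + nbytes
  ntags <- 12L
  ifd_len <- 2 + ntags * 12 + 4
  rat_off <- ifd_off + ifd_len
  ppcm <- 10000 / image$pixel_size_um          # pixels per cm
  rat <- c(le_bytes(round(ppcm * 1000), 4), le_bytes(1000, 4))
  short_val <- function(x) c(le_bytes(x, 2), raw(2))
  entries <- c(
    tiff_ifd_entry(256, 4, 1, w),
    tiff_ifd_entry(257, 4, 1, h),
    tiff_ifd_entry(258, 3, 1, short_val(bits)),
    tiff_ifd_entry(259, 3, 1, short_val(1)),      # no compression
    tiff_ifd_entry(262, 3, 1, short_val(1)),      # BlackIsZero
    tiff_ifd_entry(273, 4, 1, 8),                 # single strip at offset 8
    tiff_ifd_entry(277, 3, 1, short_val(1)),
    tiff_ifd_entry(278, 4, 1, h),
    tiff_ifd_entry(279, 4, 1, nbytes),
    tiff_ifd_entry(282, 5, 1, rat_off),           # XResolution
    tiff_ifd_entry(283, 5, 1, rat_off + 8),       # YResolution
    tiff_ifd_entry(296, 3, 1, short_val(3))       # unit: centimeter
  )
  out <- c(charToRaw("II"), le_bytes(42, 2), le_bytes(ifd_off, 4),
           data,
           le_bytes(ntags, 2), entries, le_bytes(0, 4),
           rat, rat)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

# ---- TIFF read --------------------------------------------------------------

read_tiff_gray <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 8)
    stop_spherotrack("not a TIFF file (too short)", "io_error")
  order <- rawToChar(raw_all[1:2])
  le <- identical(order, "II")
  if (!le && !identical(order, "MM"))
    stop_spherotrack("not a TIFF file (bad byte order mark)", "io_error")
  num <- function(bytes) {
    b <- as.numeric(bytes)
    if (le) sum(b * 256^(seq_along(b) - 1)) else sum(b * 256^(rev(seq_along(b)) - 1))
  }
  if (num(raw_all[3:4]) != 42)
    stop_spherotrack("not a TIFF file (bad magic)", "io_error")
  ifd <- num(raw_all[5:8])
  n_entries <- num(raw_all[ifd + (1:2)])
  tags <- list()
  type_size <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)
  for (i in seq_len(n_entries)) {
    base <- ifd + 2 + (i - 1) * 12
    tag <- num(raw_all[base + (1:2)])
    type <- num(raw_all[base + (3:4)])
    count <- num(raw_all[base + (5:8)])
    sz <- type_size[type] * count
    val_bytes <- if (sz <= 4) raw_all[base + (9:12)][seq_len(max(sz, 1))]
                 else raw_all[num(raw_all[base + (9:12)]) + seq_len(sz)]
    vals <- switch(as.character(type),
      "3" = vapply(seq_len(count), function(k)
              num(val_bytes[(k - 1) * 2 + (1:2)]), numeric(1)),
      "4" = vapply(seq_len(count), function(k)
              num(val_bytes[(k - 1) * 4 + (1:4)]), numeric(1)),
      "5" = vapply(seq_len(count), function(k)
              num(val_bytes[(k - 1) * 8 + (1:4)]) /
              max(1, num(val_bytes[(k - 1) * 8 + (5:8)])), numeric(1)),
      num(val_bytes))
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default))
        stop_spherotrack(sprintf("TIFF missing required tag %d", tag),
                         "io_error")
      default
    } else v
  }
  w <- need(256); h <- need(257)
  bits <- need(258, 8)
  if (need(259, 1) != 1)
    stop_spherotrack("only uncompressed TIFF is supported", "io_error")
  photometric <- need(262, 1)
  if (need(277, 1) != 1)
    stop_spherotrack("only single-sample grayscale TIFF is supported",
                     "io_error")
  offsets <- need(273)
  counts <- need(279)
  data <- unlist(lapply(seq_along(offsets), function(k)
    raw_all[offsets[k] + seq_len(counts[k])]))
  if (bits == 16) {
    b <- as.numeric(data)
    lo <- b[seq(1, length(b), 2)]; hi <- b[seq(2, length(b), 2)]
    v <- if (le) lo + 256 * hi else 256 * lo + hi
    maxv <- 65535
  } else if (bits == 8) {
    v <- as.numeric(data); maxv <- 255
  } else stop_spherotrack("unsupported TIFF bit depth", "io_error")
  if (length(v) < w * h)
    stop_spherotrack("TIFF pixel data truncated", "io_error")
  m <- matrix(v[seq_len(w * h)] / maxv, nrow = h, ncol = w, byrow = TRUE)
  if (photometric == 0) m <- 1 - m
  px <- NA_real_
  xres <- tags[["282"]]; unit <- need(296, 2)
  if (!is.null(xres) && xres > 0)
    px <- if (unit == 3) 10000 / xres else if (unit == 2) 25400 / xres
          else NA_real_
  list(pixels = m, pixel_size_um = px)
}

#' Read a spheroid image from disk
#'
#' Accepts uncompressed grayscale TIFF (8/16-bit, either endianness) or PNG
#' (via the `png` package). Well id and day are parsed from filenames of the
#' form `{well}_{day}.tif` when not supplied.
#'
#' @param path Image file path.
#' @param pixel_size_um Microns per pixel; required for PNG, optional for
#'   TIFF carrying resolution metadata.
#' @param well_id,day Optional metadata overrides.
#' @return A [spheroid_image()].
#' @export
read_spheroid_image <- function(path, pixel_size_um = NULL,
                                well_id = NULL, day = NULL) {
  if (!file.exists(path))
    stop_spherotrack(sprintf("no such file: '%s'", path), "io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    r <- read_tiff_gray(path)
    px <- pixel_size_um %||% r$pixel_size_um
    m <- r$pixels
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop_spherotrack("PNG input requires the 'png' package", "io_error")
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    px <- pixel_size_um
  } else {
    stop_spherotrack(sprintf("unsupported image format '%s'", ext),
                     "io_error")
  }
  if (is.null(px) || !is.finite(px))
    stop_spherotrack("pixel size unavailable; pass `pixel_size_um`",
                     "io_error")
  base <- tools::file_path_sans_ext(basename(path))
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  if (is.null(well_id) && length(parts) >= 2)
    well_id <- paste(parts[-length(parts)], collapse = "_")
  pd <- suppressWarnings(as.integer(parts[length(parts)]))
  if (is.null(day) && length(parts) >= 2 && !is.na(pd)) day <- pd
  spheroid_image(m, px, well_id %||% NA_character_, day %||% NA_integer_)
}
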