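# Shared fixtures and independent oracles.
#
# The oracle functions below are deliberately re-derived here (plain shoelace
# / distance sums) so pipeline checks against ground-truth polygons do not
# reuse the package's own code path.

oracle_area <- function(x, y, scale = 1) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(0.5 * sum(x * yn - xn * y)) * scale^2
}

oracle_perimeter <- function(x, y, scale = 1) {
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2)) * scale
}

oracle_epi <- function(x, y) {
  S <- oracle_area(x, y)
  (oracle_perimeter(x, y) - 2 * sqrt(pi * S)) / (2 * sqrt(pi * S))
}

regular_polygon <- function(n, radius = 1, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  list(x = cx + radius * cos(th), y = cy + radius * sin(th))
}

# small, fast phantom world used across tests (240 px, 2.5 um/px)
test_config <- function(...) {
  defaults <- list(base_radius_um = 120, r_max_um = 280,
                   image_size_px = 240L, pixel_size_um = 2.5,
                   noise_sd = 0, seed = 101L)
  do.call(phantom_config, utils::modifyList(defaults, list(...)))
}

# random star polygon in the phantom's boundary family; simple by
# construction because the radial deviation is < 1
random_star_polygon <- function(n_vertices = 256) {
  m <- sample(1:8, 1)
  a <- stats::runif(1, 0, 0.9)
  ks <- sample(1:12, m)
  ph <- stats::runif(m, 0, 2 * pi)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  mod <- rowSums(vapply(seq_len(m), function(j) cos(ks[j] * th + ph[j]),
                        numeric(length(th))))
  r <- 1 + a * mod / m
  list(x = r * cos(th), y = r * sin(th))
}
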