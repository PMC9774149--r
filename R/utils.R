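# Internal helpers: argument checking, seeded RNG scopes, stable well hashing.

stop_spherotrack <- function(msg, class, ..., call. = FALSE) {
  cond <- structure(
    class = c(class, "spherotrack_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL, ...)
  )
  stop(cond)
}

check_number <- function(x, name, min = -Inf, max = Inf, allow_zero_len = FALSE) {
  if (length(x) != 1L && !allow_zero_len)
    stop_spherotrack(sprintf("`%s` must be a single number", name), "invalid_argument")
  if (!is.numeric(x) || any(!is.finite(x)))
    stop_spherotrack(sprintf("`%s` must be finite numeric", name), "invalid_argument")
  if (any(x < min) || any(x > max))
    stop_spherotrack(sprintf("`%s` must be in [%g, %g]", name, min, max),
                     "invalid_argument")
  invisible(x)
}

#' Evaluate code with a temporary RNG state
#'
#' Seeds the session RNG, runs `code`, and restores the previous RNG state so
#' package functions are deterministic without clobbering the caller's stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# 32-bit FNV-1a over the UTF-8 bytes of a string, done in doubles.
# Products are split into 16-bit halves so every intermediate stays below 2^53.
fnv1a32 <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in as.integer(charToRaw(s))) {
    h <- bitwXor_dbl(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((lo * p) %% 4294967296 + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  h
}

# bitwXor for doubles holding unsigned 32-bit values
bitwXor_dbl <- function(a, b) {
  ah <- a %/% 2147483648; al <- a %% 2147483648
  bh <- b %/% 2147483648; bl <- b %% 2147483648
  xor_low <- bitwXor(as.integer(al %/% 1), as.integer(bl))
  ((ah + bh) %% 2) * 2147483648 + (xor_low %% 2147483648) +
    (if (xor_low < 0) 2147483648 else 0)
}

#' Deterministic per-well seed
#'
#' Derives a reproducible 31-bit seed from a master seed and a well identifier,
#' so any single well of a plate can be regenerated in isolation.
#'
#' @param master_seed Integer master seed.
#' @param well_id Character well identifier.
#' @return Integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' well_seed(42, "W001")
well_seed <- function(master_seed, well_id) {
  check_number(master_seed, "master_seed")
  h <- fnv1a32(paste0(well_id, "#", format(master_seed, scientific = FALSE)))
  as.integer(h %% 2147483646) + 1L
}

# shoelace signed area of an open-stored closed polygon (closure implicit)
signed_area <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
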