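#' Wrap values onto the half-open unit interval
#'
#' The stimulus domain is the circle represented as `[0, 1)`; all coordinates
#' are reduced modulo 1.
#'
#' @param x numeric vector.
#' @return `x mod 1`, in `[0, 1)`.
#' @export
wrap_unit <- function(x) {
  y <- x %% 1
  y[y == 1] <- 0
  y
}

#' Circular distance on the unit circle
#'
#' @param x,y numeric vectors of positions in `[0, 1)`.
#' @return elementwise distance, at most 0.5.
#' @export
circular_distance <- function(x, y) {
  d <- abs(wrap_unit(x) - wrap_unit(y))
  pmin(d, 1 - d)
}

# Derive a reproducible integer sub-seed (< 2^31) from a master seed and a
# list of labels, so that each randomised component (preferred locations,
# stimuli, spikes, decoding candidates, ...) has its own named stream.
derive_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), function(x) paste(format(x), collapse = "|"),
                         character(1)), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (b in utf8ToInt(labels)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr with the RNG seeded at `seed` (if non-NULL), restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_near_integer <- function(x, tol = 1e-9) abs(x - round(x)) < tol
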