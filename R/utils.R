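# Internal helpers shared across modules.

# Gravitational acceleration [m/s^2] used throughout the added-mass model.
GRAVITY <- 9.81

#' Evaluate an expression with a temporarily fixed RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so that seeded generators are deterministic without clobbering
#' the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Derive a named substream seed from a master seed
#'
#' Every source of randomness in the pipeline draws its seed from the single
#' configured master seed through a named substream, so an end-to-end run is
#' reproducible from one integer.
#'
#' @param seed Master integer seed.
#' @param stream Character stream label (e.g. `"trial3"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  # Weyl-style mixing kept in double precision (< 2^53), reduced mod 2^31-1.
  as.integer((abs(seed) %% 65521 * 69621 + h * 7919 + 12345) %% 2147483647)
}

# Trapezoidal integral of y over x (both numeric vectors, x increasing).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# Central-difference derivative of y with respect to x on a (possibly
# non-uniform) grid; one-sided at the ends.
grad1 <- function(y, x) {
  n <- length(y)
  d <- numeric(n)
  d[1L] <- (y[2L] - y[1L]) / (x[2L] - x[1L])
  d[n] <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
  if (n > 2L) {
    d[2:(n - 1L)] <- (y[3:n] - y[1:(n - 2L)]) / (x[3:n] - x[1:(n - 2L)])
  }
  d
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
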