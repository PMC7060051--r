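# Small shared helpers: circular arithmetic on the 45-degree direction grid,
# input checking, and seed handling.

DIR_GRID <- seq(0, 315, by = 45)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angles into [0, 360)
#' @param x angles in degrees.
#' @return angles in degrees, wrapped to [0, 360).
#' @keywords internal
wrap360 <- function(x) ((x %% 360) + 360) %% 360

#' Wrap angles into [-180, 180)
#' @param x angles in degrees.
#' @return wrapped angles.
#' @keywords internal
wrap180 <- function(x) {
  y <- wrap360(x)
  ifelse(y >= 180, y - 360, y)
}

#' Absolute circular difference in degrees, in [0, 180]
#' @param a,b angles in degrees.
#' @keywords internal
circ_diff <- function(a, b) abs(wrap180(a - b))

#' Circular mean of angles in degrees
#' @param theta angles in degrees.
#' @param w optional nonnegative weights.
#' @return mean direction in [0, 360), or `NA` when the resultant is ~zero.
#' @keywords internal
circ_mean_deg <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta))
  rad <- theta * pi / 180
  s <- sum(w * sin(rad))
  c <- sum(w * cos(rad))
  if (sqrt(s^2 + c^2) < 1e-12 * max(sum(abs(w)), 1)) return(NA_real_)
  wrap360(atan2(s, c) * 180 / pi)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

check_on_grid <- function(direction, name = "direction") {
  bad <- wrap360(direction) %% 45 != 0
  if (any(bad)) {
    stop(sprintf("`%s` must lie on the 45-degree grid; got %s", name,
                 paste(direction[bad], collapse = ", ")), call. = FALSE)
  }
  invisible(wrap360(direction))
}

#' Deterministic child seed
#'
#' Derives stage-specific seeds below 2^31 from one master seed, so that
#' independent stochastic stages never share random streams.
#'
#' @param seed integer master seed.
#' @param k stage index.
#' @return integer seed.
#' @export
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 11 * k) %% 2147483647)
}
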