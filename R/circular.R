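#' Circular position and angle helpers
#'
#' The task circle has 360 positions labelled 1--360. `wrap_position()` maps
#' any real-valued angle onto that label range, `signed_circular_error()`
#' returns the minimal signed arc between two positions, and
#' `circular_distance()` its absolute value.
#'
#' @param x Numeric vector of (possibly unwrapped) positions in degrees.
#' @return `wrap_position()`: positions in (0, 360], i.e. 1--360 for integer
#'   input.
#' @examples
#' wrap_position(361)          # 1
#' signed_circular_error(10, 350)  # +20
#' circular_distance(180, 360)     # 180
#' @export
wrap_position <- function(x) {
  r <- ((x - 1) %% 360) + 1
  # %% can return 360 - eps for tiny negative remainders; fold the overshoot
  ifelse(r > 360, r - 360, r)
}

#' @rdname wrap_position
#' @param x_to,x_from Positions in degrees; the error is the signed arc from
#'   `x_from` to `x_to`.
#' @return `signed_circular_error()`: signed degrees in (-180, 180]; the
#'   antipode (distance exactly 180) is returned as +180.
#' @export
signed_circular_error <- function(x_to, x_from) {
  d <- (x_to - x_from) %% 360
  ifelse(d > 180, d - 360, d)
}

#' @rdname wrap_position
#' @return `circular_distance()`: degrees in [0, 180].
#' @export
circular_distance <- function(x_to, x_from) {
  abs(signed_circular_error(x_to, x_from))
}
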