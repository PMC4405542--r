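#' Wrap an angle into [-pi, pi)
#'
#' All angles in the package are radians measured counter-clockwise from the
#' reference direction (east, the +x axis). This helper reduces any finite
#' angle modulo 2*pi into the half-open interval \code{[-pi, pi)}, the
#' canonical support of a step angle.
#'
#' @param theta numeric vector of angles in radians.
#' @return numeric vector of the same length with values in \code{[-pi, pi)}.
#' @examples
#' wrap_angle(3 * pi)   # -pi
#' wrap_angle(-pi)      # -pi (left endpoint belongs to the interval)
#' @export
wrap_angle <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta)))
    stop("invalid-angle: 'theta' must be finite numeric", call. = FALSE)
  w <- (theta + pi) %% (2 * pi) - pi
  # %% can return 2*pi for inputs just below -pi due to rounding
  w[w >= pi] <- -pi
  w
}

# Numerical floor below which a compromise vector is treated as degenerate
# (its direction is indeterminate; the consensus density is still defined
# because kappa * length -> 0 gives the uniform circle).
.ell_floor <- 1e-12

#' Compromise (mean-direction) vector of a biased correlated random walk
#'
#' Builds the vector sum of the unit persistence vector pointing along the
#' previous step angle and one unit vector per movement taxis scaled by its
#' bias weight:
#' east = cos(y_prev) + sum_k beta_k cos(psi_k),
#' north = sin(y_prev) + sum_k beta_k sin(psi_k).
#' The expected step direction is the direction of this vector (two-argument
#' arctangent) and the agreement between persistence and the taxes is its
#' Euclidean length.
#'
#' @param y_prev previous step angle (radians).
#' @param psi numeric vector of target bearings (radians), one per taxis.
#' @param beta numeric vector of non-negative bias weights, same length as
#'   \code{psi}.
#' @return a list of class \code{compromise_vector} with components
#'   \code{east}, \code{north}, \code{length}, \code{mu} (wrapped direction)
#'   and \code{degenerate} (TRUE when the length is below the numerical
#'   floor, in which case \code{mu} is reported as 0).
#' @examples
#' mean_direction(0, pi / 2, 1)$mu   # pi/4, the equal-weight compromise
#' mean_direction(1.3, 0.2, 0)$mu    # 1.3, pure persistence when beta = 0
#' @export
mean_direction <- function(y_prev, psi, beta) {
  stopifnot(length(psi) == length(beta), length(psi) >= 1L)
  if (any(!is.finite(beta))) stop("invalid-bias: beta must be finite", call. = FALSE)
  east <- cos(y_prev) + sum(beta * cos(psi))
  north <- sin(y_prev) + sum(beta * sin(psi))
  ell <- sqrt(east^2 + north^2)
  degenerate <- ell < .ell_floor
  mu <- if (degenerate) 0 else wrap_angle(atan2(north, east))
  structure(list(east = east, north = north, length = ell, mu = mu,
                 degenerate = degenerate),
            class = "compromise_vector")
}

#' Agreement length of the single-taxis compromise vector
#'
#' The concentration of the consensus model is kappa times this length
#' ell = sqrt((sin(y_prev) + beta sin(psi))^2 + (cos(y_prev) + beta cos(psi))^2).
#' It is maximal, 1 + beta, when the target lies straight ahead
#' (psi = y_prev) and minimal, |1 - beta|, when it lies straight behind.
#'
#' @param y_prev previous step angle (radians).
#' @param psi target bearing (radians).
#' @param beta non-negative bias weight.
#' @return non-negative numeric, vectorized over the angle arguments.
#' @export
consensus_length <- function(y_prev, psi, beta) {
  if (any(beta < 0)) stop("invalid-bias: beta must be >= 0", call. = FALSE)
  sqrt((sin(y_prev) + beta * sin(psi))^2 + (cos(y_prev) + beta * cos(psi))^2)
}
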