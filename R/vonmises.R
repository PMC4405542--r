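#' Logarithm of the modified Bessel function I0
#'
#' \code{log(I0(x))} evaluated through the exponentially scaled Bessel
#' function, so it stays finite for arguments far beyond the overflow point
#' of \code{besselI(x, 0)} (roughly x > 700).
#'
#' @param x non-negative numeric vector.
#' @return numeric vector, \code{log(I0(x))}.
#' @export
log_bessel_i0 <- function(x) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("invalid-argument: x must be finite and >= 0", call. = FALSE)
  log(besselI(x, 0, expon.scaled = TRUE)) + x
}

# Mean resultant length A1(kappa) = I1(kappa)/I0(kappa), scaled evaluation.
bessel_ratio_a1 <- function(x) {
  besselI(x, 1, expon.scaled = TRUE) / besselI(x, 0, expon.scaled = TRUE)
}

#' Log-density of the von Mises distribution
#'
#' log f(y) = kappa * cos(y - mu) - log(2 pi I0(kappa)), the circular
#' analogue of the normal density; kappa = 0 is the uniform circle.
#'
#' @param y angle(s) at which to evaluate (radians).
#' @param mu mean direction (radians).
#' @param kappa non-negative concentration parameter.
#' @return numeric vector of log-densities.
#' @export
log_vm_density <- function(y, mu, kappa) {
  if (any(kappa < 0)) stop("invalid-concentration: kappa must be >= 0", call. = FALSE)
  kappa * cos(y - mu) - log(2 * pi) - log_bessel_i0(kappa)
}

#' Sample from the von Mises distribution
#'
#' Best-Fisher rejection sampling (wrapped-Cauchy envelope). kappa = 0
#' short-circuits to uniform draws on [-pi, pi). Uses R's global RNG stream,
#' so results are reproducible under \code{set.seed}.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa non-negative concentration.
#' @return numeric vector of n angles in \code{[-pi, pi)}.
#' @export
sample_von_mises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 1, kappa >= 0)
  if (kappa == 0) return(wrap_angle(stats::runif(n, -pi, pi)))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    u2 <- stats::runif(m)
    keep <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    nk <- sum(keep)
    if (nk > 0L) {
      u3 <- stats::runif(nk)
      theta <- sign(u3 - 0.5) * acos(f[keep])
      out[(got + 1L):(got + nk)] <- theta
      got <- got + nk
    }
  }
  wrap_angle(mu + out)
}
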