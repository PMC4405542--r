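# Pixel-trail SSF design: a trail is a string of successive grid pixels
# (10 x 10 map-unit cells). From the pixel occupied at time t the animal can
# move to any of the 8 neighbors except the one occupied at time t-1, so
# each interior trail position yields one case and the 6 remaining neighbors
# as exhaustive controls.

# Continuous center of a (row, col) pixel; row 1 is the north edge.
pixel_center <- function(row, col, n_rows, pixel_size = 10) {
  cbind(x = (col - 0.5) * pixel_size,
        y = (n_rows - row + 0.5) * pixel_size)
}

.neighbor_offsets <- cbind(dr = rep(-1:1, each = 3), dc = rep(-1:1, 3))[-5, ]

#' Case-control design along a pixel trail
#'
#' For every interior position of an 8-connected pixel path, builds one
#' stratum with the observed move as the case and the 6 other admissible
#' neighbors (the 8-neighborhood minus the previously occupied pixel) as
#' controls. Angles run from pixel center to pixel center; covariates are
#' the cosines of the turning angle and of the angle(s) to the target(s).
#'
#' @param path two-column matrix or data frame of (row, col) pixel indices,
#'   1-based, row 1 at the north edge; consecutive pixels must be distinct
#'   8-neighbors and must not backtrack immediately.
#' @param psi1 numeric vector of first-taxis bearings (radians), one per
#'   path position (e.g. toward the target meadow); evaluated at the step's
#'   start position.
#' @param psi2 optional second-taxis bearings (e.g. toward the nearest
#'   canopy gap), same length.
#' @param n_rows,n_cols grid dimensions; the path must stay inside.
#' @param pixel_size side of a pixel in map units (default 10).
#' @param trail_id label attached to the strata (for clustering).
#' @return an \code{ssf_design} with 7 alternatives per stratum.
#' @export
trail_ssf_design <- function(path, psi1, psi2 = NULL, n_rows = NULL,
                             n_cols = NULL, pixel_size = 10,
                             trail_id = "trail1") {
  path <- as.matrix(path)
  n <- nrow(path)
  stopifnot(ncol(path) == 2, n >= 3, length(psi1) == n,
            is.null(psi2) || length(psi2) == n)
  if (!is.null(n_rows) &&
      (any(path[, 1] < 1 | path[, 1] > n_rows) ||
       any(path[, 2] < 1 | path[, 2] > n_cols)))
    stop("out-of-bounds: path leaves the grid", call. = FALSE)
  dmove <- diff(path)
  if (any(abs(dmove) > 1) || any(dmove[, 1] == 0 & dmove[, 2] == 0))
    stop("path pixels must be distinct 8-neighbors", call. = FALSE)
  if (any(path[-(1:2), 1] == path[seq_len(n - 2), 1] &
          path[-(1:2), 2] == path[seq_len(n - 2), 2]))
    stop("path backtracks: pixel at t+1 equals pixel at t-1", call. = FALSE)
  nr <- if (is.null(n_rows)) max(path[, 1]) + 1L else n_rows
  S <- n - 2L                                  # one stratum per interior move
  sid <- rep(seq_len(S), each = 8L)
  off <- rep(seq_len(8L), times = S)
  nbr_r <- path[sid + 1L, 1] + .neighbor_offsets[off, 1]
  nbr_c <- path[sid + 1L, 2] + .neighbor_offsets[off, 2]
  keep <- !(nbr_r == path[sid, 1] & nbr_c == path[sid, 2])   # drop t-1 pixel
  sid <- sid[keep]; nbr_r <- nbr_r[keep]; nbr_c <- nbr_c[keep]
  is_case <- nbr_r == path[sid + 2L, 1] & nbr_c == path[sid + 2L, 2]
  if (sum(is_case) != S)
    stop("internal: observed move not among admissible neighbors", call. = FALSE)
  cc <- pixel_center(path[sid + 1L, 1], path[sid + 1L, 2], nr, pixel_size)
  pc <- pixel_center(path[sid, 1], path[sid, 2], nr, pixel_size)
  ac <- pixel_center(nbr_r, nbr_c, nr, pixel_size)
  ang <- atan2(ac[, "y"] - cc[, "y"], ac[, "x"] - cc[, "x"])
  y_prev <- atan2(cc[, "y"] - pc[, "y"], cc[, "x"] - pc[, "x"])
  des <- data.frame(
    stratum_id = sid,
    is_case = as.integer(is_case),
    angle = wrap_angle(ang),
    cos_turn = cos(ang - y_prev),
    cos_target1 = cos(ang - psi1[sid + 1L]),
    cos_target2 = if (is.null(psi2)) NA_real_ else cos(ang - psi2[sid + 1L]),
    animal_id = trail_id
  )
  des <- des[order(des$stratum_id, -des$is_case), , drop = FALSE]
  rownames(des) <- NULL
  class(des) <- c("ssf_design", "data.frame")
  des
}

#' Pool several SSF designs into one with unique stratum ids
#'
#' @param designs list of \code{ssf_design} objects (e.g. one per trail).
#' @return a single \code{ssf_design} with strata renumbered consecutively.
#' @export
pool_designs <- function(designs) {
  off <- 0L
  out <- lapply(designs, function(d) {
    d$stratum_id <- d$stratum_id + off
    off <<- max(d$stratum_id)
    d
  })
  des <- do.call(rbind, out)
  rownames(des) <- NULL
  class(des) <- c("ssf_design", "data.frame")
  des
}

#' Simulate a pixel trail by discrete neighbor choice
#'
#' From each pixel the walker selects one of the 7 admissible neighbors (8
#' minus the previous pixel) with probability proportional to
#' exp(kappa1 cos(y - y_prev) + kappa2 cos(y - psi1) + kappa3 cos(y - psi2)),
#' the same discrete-choice law the trail SSF design conditions on, so
#' \code{\link{fit_ssf}} on the resulting strata is exactly the maximum
#' likelihood estimator of the kappa's.
#'
#' @param start (row, col) of the first pixel.
#' @param target (x, y) map-unit coordinates of the first-taxis attractor.
#' @param gaps optional matrix of (x, y) points for the second taxis; the
#'   bearing used at each step is toward the nearest gap point.
#' @param kappa numeric (kappa1, kappa2) or (kappa1, kappa2, kappa3).
#' @param n_steps number of moves to simulate.
#' @param n_rows,n_cols grid dimensions (moves stay inside).
#' @param pixel_size side of a pixel in map units.
#' @param y0 initial previous bearing (radians); default drawn uniformly.
#' @return a list with \code{path} (matrix of pixel indices), \code{psi1}
#'   and \code{psi2} (per-position bearings, NULL without gaps).
#' @export
simulate_trail <- function(start, target, gaps = NULL, kappa,
                           n_steps = 30L, n_rows = 100L, n_cols = 100L,
                           pixel_size = 10, y0 = NULL) {
  nb <- length(kappa) - 1L
  stopifnot(nb %in% c(1L, 2L), is.null(gaps) || nb == 2L)
  if (is.null(y0)) y0 <- stats::runif(1, -pi, pi)
  path <- matrix(NA_integer_, n_steps + 1L, 2L)
  path[1L, ] <- start
  psi1 <- numeric(n_steps + 1L)
  psi2 <- if (nb == 2L) numeric(n_steps + 1L) else NULL
  prev <- c(NA_integer_, NA_integer_)
  y_prev <- y0
  for (i in seq_len(n_steps + 1L)) {
    cur <- path[i, ]
    cc <- pixel_center(cur[1], cur[2], n_rows, pixel_size)
    psi1[i] <- atan2(target[2] - cc[, "y"], target[1] - cc[, "x"])
    if (nb == 2L) {
      dg <- (gaps[, 1] - cc[, "x"])^2 + (gaps[, 2] - cc[, "y"])^2
      g <- gaps[which.min(dg), ]
      psi2[i] <- atan2(g[2] - cc[, "y"], g[1] - cc[, "x"])
    }
    if (i == n_steps + 1L) break
    nbr <- sweep(.neighbor_offsets, 2, cur, "+")
    ok <- nbr[, 1] >= 1 & nbr[, 1] <= n_rows & nbr[, 2] >= 1 & nbr[, 2] <= n_cols
    if (!any(is.na(prev)))
      ok <- ok & !(nbr[, 1] == prev[1] & nbr[, 2] == prev[2])
    cand <- nbr[ok, , drop = FALSE]
    ac <- pixel_center(cand[, 1], cand[, 2], n_rows, pixel_size)
    ang <- atan2(ac[, "y"] - cc[, "y"], ac[, "x"] - cc[, "x"])
    eta <- kappa[1] * cos(ang - y_prev) + kappa[2] * cos(ang - psi1[i])
    if (nb == 2L) eta <- eta + kappa[3] * cos(ang - psi2[i])
    pr <- exp(eta - max(eta))
    j <- sample.int(nrow(cand), 1L, prob = pr)
    prev <- cur
    path[i + 1L, ] <- cand[j, ]
    y_prev <- ang[j]
  }
  list(path = path, psi1 = psi1, psi2 = psi2)
}
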