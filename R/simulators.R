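# Trajectory simulators for the Monte Carlo study: continuous-plane walks
# driven by the consensus and angular von Mises models, and a discrete
# habitat-choice walker on a categorical landscape whose noise is *not* of
# the von Mises form (the robustness model).

#' Simulate a consensus-model BCRW
#'
#' Each step angle is drawn from vM(mu_t, kappa * ell_t) with mu_t and
#' ell_t from the compromise vector at bias weight beta; all steps have
#' fixed length, and the target bearing is recomputed from the current
#' position before each step.
#'
#' @param T number of steps.
#' @param kappa base concentration (kappa1 of the consensus density).
#' @param beta bias weight (kappa2 / kappa1).
#' @param step_len step length in map units.
#' @param start length-2 (x, y) start position.
#' @param target length-2 (x, y) attractor.
#' @param y0 initial previous bearing; default uniform on [-pi, pi).
#' @param animal_id label for the output.
#' @return data frame of positions (animal_id, t, x, y), t = 0..T.
#' @export
simulate_consensus <- function(T, kappa, beta, step_len = 60,
                               start, target, y0 = NULL,
                               animal_id = "A1") {
  stopifnot(T >= 2, kappa > 0, beta >= 0)
  if (is.null(y0)) y0 <- stats::runif(1, -pi, pi)
  pos <- matrix(NA_real_, T + 1L, 2L)
  pos[1L, ] <- start
  y_prev <- y0
  for (t in seq_len(T)) {
    psi <- atan2(target[2] - pos[t, 2], target[1] - pos[t, 1])
    md <- mean_direction(y_prev, psi, beta)
    y <- sample_von_mises(1L, md$mu, kappa * md$length)
    pos[t + 1L, ] <- pos[t, ] + step_len * c(cos(y), sin(y))
    y_prev <- y
  }
  data.frame(animal_id = animal_id, t = 0:T, x = pos[, 1], y = pos[, 2])
}

#' Simulate an angular-model BCRW
#'
#' The step angle is the compromise direction mu_t plus von Mises noise of
#' constant concentration: y_t = wrap(mu_t + vM(0, error_kappa)).
#'
#' @inheritParams simulate_consensus
#' @param error_kappa concentration of the angular error.
#' @return data frame of positions (animal_id, t, x, y).
#' @export
simulate_angular <- function(T, beta, error_kappa, step_len = 60,
                             start, target, y0 = NULL, animal_id = "A1") {
  stopifnot(T >= 2, error_kappa > 0, beta >= 0)
  if (is.null(y0)) y0 <- stats::runif(1, -pi, pi)
  pos <- matrix(NA_real_, T + 1L, 2L)
  pos[1L, ] <- start
  y_prev <- y0
  for (t in seq_len(T)) {
    psi <- atan2(target[2] - pos[t, 2], target[1] - pos[t, 1])
    md <- mean_direction(y_prev, psi, beta)
    y <- wrap_angle(md$mu + sample_von_mises(1L, 0, error_kappa))
    pos[t + 1L, ] <- pos[t, ] + step_len * c(cos(y), sin(y))
    y_prev <- y
  }
  data.frame(animal_id = animal_id, t = 0:T, x = pos[, 1], y = pos[, 2])
}

#' Simulate a discrete habitat-choice walk on a landscape
#'
#' At each step, the candidate pixels are the habitat-2 and habitat-3
#' pixels closest to the animal among those strictly more than
#' \code{min_dist} units away: all such pixels within the shell
#' (\code{min_dist}, \code{max_dist}], with the shell widened outward until
#' it contains at least one pixel. One candidate k is then selected with
#' probability proportional to
#' exp(kappa1 cos(y(k) - y_prev) + kappa2 cos(y(k) - psi_t)), where y(k) is
#' the bearing to the candidate and psi_t the bearing to the landscape
#' center. Step lengths therefore vary around \code{min_dist}; the step
#' noise is availability-driven, not von Mises -- this is the robustness
#' model of the estimator comparison.
#'
#' @param landscape a \code{landscape} containing habitats 2 and 3.
#' @param start length-2 (x, y) start position in map units.
#' @param T number of steps.
#' @param kappa1,kappa2 persistence and target-bias concentrations.
#' @param min_dist minimum displacement per step (units; default 60).
#' @param max_dist outer radius of the candidate shell (default
#'   \code{1.5 * min_dist}); widened by \code{min_dist / 2} when empty.
#' @param y0 initial previous bearing; default uniform.
#' @param animal_id label for the output.
#' @return data frame of positions (animal_id, t, x, y).
#' @export
simulate_discrete_choice <- function(landscape, start, T, kappa1, kappa2,
                                     min_dist = 60, max_dist = 1.5 * min_dist,
                                     y0 = NULL, animal_id = "A1") {
  stopifnot(inherits(landscape, "landscape"), T >= 2, max_dist > min_dist)
  if (is.null(y0)) y0 <- stats::runif(1, -pi, pi)
  h2 <- .habitat_pixels(landscape, 2L)
  h3 <- .habitat_pixels(landscape, 3L)
  px <- c(h2$px, h3$px)
  py <- c(h2$py, h3$py)
  pos <- matrix(NA_real_, T + 1L, 2L)
  pos[1L, ] <- start
  y_prev <- y0
  tgt <- landscape$target
  for (t in seq_len(T)) {
    cand <- tryCatch(
      annulus_candidates(px, py, pos[t, 1], pos[t, 2],
                         min_dist, max_dist, min_dist / 2),
      error = function(e)
        stop("stranded-walker: no habitat-2/3 pixel beyond min_dist",
             call. = FALSE))
    dx <- px[cand] - pos[t, 1]
    dy <- py[cand] - pos[t, 2]
    yk <- atan2(dy, dx)
    psi <- atan2(tgt[2] - pos[t, 2], tgt[1] - pos[t, 1])
    eta <- kappa1 * cos(yk - y_prev) + kappa2 * cos(yk - psi)
    pr <- exp(eta - max(eta))
    j <- sample.int(length(cand), 1L, prob = pr)
    pos[t + 1L, ] <- c(px[cand[j]], py[cand[j]])
    y_prev <- yk[j]
  }
  data.frame(animal_id = animal_id, t = 0:T, x = pos[, 1], y = pos[, 2])
}

#' Define a Monte Carlo scenario
#'
#' @param model "discrete_choice", "consensus" or "angular".
#' @param kappa1,kappa2 the concentration pair of the scenario; the bias
#'   ratio is beta = kappa2 / kappa1.
#' @param error_kappa angular-model error concentration (required when
#'   \code{model = "angular"}; the study pairs (2,2), (2,0.5), (0.5,0.5)
#'   with error concentrations 3, 2, 0.75).
#' @param T steps per animal (default 61, giving 120 usable records from
#'   two animals).
#' @param step_len fixed step length for the continuous models (units).
#' @param extent side of the (conceptual) square arena in units; starts are
#'   drawn in its NW and SE quarter-quadrants and the target is its center.
#' @return a list of class \code{sim_scenario}.
#' @export
sim_scenario <- function(model = c("consensus", "angular", "discrete_choice"),
                         kappa1, kappa2, error_kappa = NULL,
                         T = 61L, step_len = 60, extent = 1024) {
  model <- match.arg(model)
  if (model == "angular" && is.null(error_kappa))
    stop("angular scenario needs error_kappa", call. = FALSE)
  structure(list(model = model, kappa1 = kappa1, kappa2 = kappa2,
                 beta = kappa2 / kappa1, error_kappa = error_kappa,
                 T = as.integer(T), step_len = step_len, extent = extent),
            class = "sim_scenario")
}

#' Simulate one two-animal replicate of a scenario
#'
#' Two independent animals; starting locations are drawn uniformly in the
#' northwest and southeast quarter-quadrants of the arena, the directional
#' bias points at the arena center, and each animal is observed for T
#' steps, so T = 61 yields 120 usable likelihood records.
#'
#' @param scenario a \code{sim_scenario}.
#' @param landscape a \code{landscape}; required when the scenario model is
#'   "discrete_choice", ignored otherwise.
#' @return a \code{step_series} pooling both animals.
#' @export
run_two_animal_replicate <- function(scenario, landscape = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  ext <- if (!is.null(landscape))
    nrow(landscape$grid) * landscape$pixel_size else scenario$extent
  target <- if (!is.null(landscape)) landscape$target else c(ext / 2, ext / 2)
  half <- ext / 2
  starts <- rbind(
    c(stats::runif(1, 0, half), stats::runif(1, half, ext)),   # NW quadrant
    c(stats::runif(1, half, ext), stats::runif(1, 0, half)))   # SE quadrant
  series <- lapply(1:2, function(a) {
    pos <- switch(scenario$model,
      consensus = simulate_consensus(
        scenario$T, kappa = scenario$kappa1, beta = scenario$beta,
        step_len = scenario$step_len, start = starts[a, ], target = target,
        animal_id = paste0("A", a)),
      angular = simulate_angular(
        scenario$T, beta = scenario$beta, error_kappa = scenario$error_kappa,
        step_len = scenario$step_len, start = starts[a, ], target = target,
        animal_id = paste0("A", a)),
      discrete_choice = {
        if (is.null(landscape))
          stop("discrete_choice scenario needs a landscape", call. = FALSE)
        simulate_discrete_choice(
          landscape, start = starts[a, ], T = scenario$T,
          kappa1 = scenario$kappa1, kappa2 = scenario$kappa2,
          animal_id = paste0("A", a))
      })
    steps_from_positions(pos, target = target)
  })
  out <- rbind(series[[1]], series[[2]])
  class(out) <- c("step_series", "data.frame")
  out
}
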