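#' Step series: the sufficient data for all three likelihoods
#'
#' A \code{step_series} is a data frame with one row per movement step and
#' columns \code{animal_id}, \code{t} (step index within animal), \code{y}
#' (step angle, radians), \code{y_prev} (previous step angle; NA for the
#' first step of each animal), \code{psi1} (bearing to the first target),
#' optionally \code{psi2} (second taxis), \code{d} (step length) and
#' \code{usable} (TRUE when \code{y_prev} is defined, i.e. the row
#' contributes to a likelihood).
#'
#' @param df data frame with at least \code{animal_id}, \code{t}, \code{y},
#'   \code{psi1}; \code{y_prev} is derived when absent.
#' @return the validated data frame with class \code{step_series}.
#' @export
step_series <- function(df) {
  req <- c("animal_id", "t", "y", "psi1")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("step_series needs columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"psi2" %in% names(df)) df$psi2 <- NA_real_
  if (!"d" %in% names(df)) df$d <- NA_real_
  df <- df[order(df$animal_id, df$t), , drop = FALSE]
  for (id in unique(df$animal_id)) {
    tt <- df$t[df$animal_id == id]
    if (any(diff(tt) <= 0))
      stop("step index 't' must be strictly increasing within animal ", id,
           call. = FALSE)
  }
  if (!"y_prev" %in% names(df)) {
    df$y_prev <- ave(df$y, df$animal_id,
                     FUN = function(v) c(NA_real_, v[-length(v)]))
  }
  df$usable <- !is.na(df$y_prev)
  ang <- c("y", "y_prev", "psi1", "psi2")
  for (a in ang) df[[a]][!is.na(df[[a]])] <- wrap_angle(df[[a]][!is.na(df[[a]])])
  rownames(df) <- NULL
  class(df) <- c("step_series", "data.frame")
  df
}

#' Convert planar positions to a step series
#'
#' Positions are continuous planar coordinates with x pointing east and y
#' pointing north; angles are measured counter-clockwise from east. Step t
#' joins position t to position t+1; the target bearing of a step is taken
#' from the step's start position, the point where the direction is chosen.
#'
#' @param positions data frame with columns \code{animal_id}, \code{t},
#'   \code{x}, \code{y}, ordered or orderable by \code{t} within animal.
#' @param target length-2 numeric (x, y) of the attractor, or NULL if
#'   \code{psi1} will be supplied separately.
#' @param target2 optional second attractor (x, y) for a two-taxis model.
#' @return a \code{step_series}; an animal with P positions yields P - 1
#'   steps of which P - 2 are usable.
#' @export
steps_from_positions <- function(positions, target, target2 = NULL) {
  req <- c("animal_id", "t", "x", "y")
  if (!all(req %in% names(positions)))
    stop("positions need columns animal_id, t, x, y", call. = FALSE)
  positions <- positions[order(positions$animal_id, positions$t), , drop = FALSE]
  parts <- lapply(split(positions, positions$animal_id), function(p) {
    np <- nrow(p)
    if (np < 2L) return(NULL)
    dx <- diff(p$x); dy <- diff(p$y)
    data.frame(
      animal_id = p$animal_id[-np],
      t = seq_len(np - 1L),
      y = atan2(dy, dx),
      psi1 = atan2(target[2] - p$y[-np], target[1] - p$x[-np]),
      psi2 = if (is.null(target2)) NA_real_ else
        atan2(target2[2] - p$y[-np], target2[1] - p$x[-np]),
      d = sqrt(dx^2 + dy^2)
    )
  })
  step_series(do.call(rbind, parts))
}

# Rows of a step series that contribute to a likelihood.
usable_steps <- function(data) {
  stopifnot(inherits(data, "step_series") || is.data.frame(data))
  data[data$usable %in% TRUE, , drop = FALSE]
}
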