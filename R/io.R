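# Delimited-text trajectory I/O. Two layouts are accepted:
#   positions: animal_id, t, x, y          (continuous planar coordinates)
#   angles:    animal_id, t, y_angle, psi1[, psi2]
# '#'-prefixed header comments carry key=value metadata; 'units' declares
# degrees or radians for angle files (radians internally, always).

#' Read a trajectory file into a step series
#'
#' @param path file path (tab- or whitespace-delimited, header row,
#'   optional '#' comment lines with \code{key=value} metadata).
#' @param target length-2 (x, y) attractor, required for position files
#'   unless a \code{target=x,y} header comment is present.
#' @param target2 optional second attractor for position files.
#' @return a \code{step_series}.
#' @export
read_trajectory <- function(path, target = NULL, target2 = NULL) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- .parse_meta(meta_lines)
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          stringsAsFactors = FALSE)
  if (all(c("x", "y") %in% names(df))) {
    if (is.null(target) && !is.null(meta$target))
      target <- as.numeric(strsplit(meta$target, ",")[[1]])
    if (is.null(target))
      stop("position file needs a target (argument or 'target=' header)",
           call. = FALSE)
    for (id in unique(df$animal_id)) {
      tt <- df$t[df$animal_id == id]
      if (any(diff(tt) <= 0))
        stop("parse error: non-monotone t for animal ", id, " near line ",
             which(df$animal_id == id)[which(diff(tt) <= 0)[1] + 1L] +
               length(meta_lines) + 1L, call. = FALSE)
    }
    return(steps_from_positions(df, target, target2))
  }
  if (all(c("y_angle", "psi1") %in% names(df))) {
    units <- if (!is.null(meta$units)) meta$units else "radians"
    if (!units %in% c("radians", "degrees"))
      stop("parse error: units must be radians or degrees", call. = FALSE)
    conv <- if (units == "degrees") pi / 180 else 1
    lim <- if (units == "degrees") 360 else 2 * pi
    acols <- intersect(c("y_angle", "psi1", "psi2"), names(df))
    for (a in acols) {
      bad <- which(abs(df[[a]]) > lim)
      if (length(bad))
        stop("parse error: out-of-range angle in column ", a, " line ",
             bad[1] + length(meta_lines) + 1L, call. = FALSE)
      df[[a]] <- df[[a]] * conv
    }
    names(df)[names(df) == "y_angle"] <- "y"
    return(step_series(df))
  }
  stop("parse error: unknown columns (need x,y or y_angle,psi1)", call. = FALSE)
}

.parse_meta <- function(comment_lines) {
  out <- list()
  for (l in comment_lines) {
    m <- regmatches(l, regexec("^#\\s*([A-Za-z_0-9]+)\\s*=\\s*(.+)$", l))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- trimws(m[3])
  }
  out
}

#' Write positions or a step series as a trajectory file
#'
#' @param x a positions data frame (animal_id, t, x, y) or a
#'   \code{step_series} (written in the angle layout).
#' @param path output file.
#' @param units "radians" or "degrees" for the angle layout.
#' @param meta named list written as \code{# key=value} header comments
#'   (e.g. the generating parameters and seed).
#' @export
write_trajectory <- function(x, path, units = c("radians", "degrees"),
                             meta = list()) {
  units <- match.arg(units)
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "step_series")) {
    conv <- if (units == "degrees") 180 / pi else 1
    out <- data.frame(animal_id = x$animal_id, t = x$t,
                      y_angle = x$y * conv, psi1 = x$psi1 * conv)
    if (!all(is.na(x$psi2))) out$psi2 <- x$psi2 * conv
    meta <- c(list(units = units), meta)
  } else {
    out <- x[, c("animal_id", "t", "x", "y")]
  }
  for (k in names(meta)) writeLines(sprintf("# %s=%s", k, meta[[k]]), con)
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a fit result as a plain-text parameter table
#'
#' @param fit a \code{bcrw_fit}.
#' @param path output file.
#' @param meta named list of '# key=value' header comments.
#' @export
write_fit <- function(fit, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) writeLines(sprintf("# %s=%s", k, meta[[k]]), con)
  se_m <- if (!is.null(fit$vcov_model)) sqrt(pmax(diag(fit$vcov_model), 0))
          else rep(NA_real_, length(fit$estimates))
  se_s <- if (!is.null(fit$vcov_sandwich)) sqrt(pmax(diag(fit$vcov_sandwich), 0))
          else rep(NA_real_, length(fit$estimates))
  tab <- data.frame(parameter = names(fit$estimates),
                    estimate = unname(fit$estimates),
                    se_model = unname(se_m), se_robust = unname(se_s))
  if (!is.null(fit$beta) && fit$method != "angular")
    tab <- rbind(tab, data.frame(parameter = names(fit$beta),
                                 estimate = unname(fit$beta),
                                 se_model = unname(fit$beta_se),
                                 se_robust = NA_real_))
  writeLines(sprintf("# method=%s loglik=%.8g converged=%s n_obs=%d",
                     fit$method, fit$loglik, fit$converged, fit$n_obs), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
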