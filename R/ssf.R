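# Step selection functions: case-control construction and conditional
# logistic (discrete-choice) maximization of the SSF likelihood, in which
# each observed step angle is compared against J control angles sharing the
# same (y_prev, psi) anchors.

#' Sample control step angles
#'
#' Empirical scheme: J draws with replacement per stratum from the pooled
#' observed step angles (the resampling used in the Monte Carlo study);
#' duplicates are legitimate resamples and are kept. Uniform scheme: J iid
#' draws on [-pi, pi), the regime in which SSF estimation converges to the
#' consensus maximum likelihood.
#'
#' @param observed_angles pool of observed step angles (radians); also sets
#'   the default number of strata.
#' @param J controls per stratum.
#' @param scheme "empirical" or "uniform".
#' @param n_strata number of strata to generate controls for.
#' @param animal_id optional per-angle labels; with \code{per_animal = TRUE}
#'   each stratum resamples only from its own animal's angles.
#' @param per_animal restrict the empirical pool within animal.
#' @return numeric matrix, \code{n_strata} rows by \code{J} columns.
#' @export
sample_controls <- function(observed_angles, J,
                            scheme = c("empirical", "uniform"),
                            n_strata = length(observed_angles),
                            animal_id = NULL, per_animal = FALSE) {
  scheme <- match.arg(scheme)
  if (scheme == "empirical" && length(observed_angles) == 0L)
    stop("no-controls: empirical scheme needs a nonempty pool", call. = FALSE)
  stopifnot(J >= 1, n_strata >= 1)
  if (scheme == "uniform")
    return(matrix(stats::runif(n_strata * J, -pi, pi), n_strata, J))
  if (per_animal) {
    if (is.null(animal_id) || length(animal_id) != length(observed_angles) ||
        n_strata != length(observed_angles))
      stop("per_animal pooling needs one animal_id per observed angle", call. = FALSE)
    out <- matrix(NA_real_, n_strata, J)
    for (i in seq_len(n_strata)) {
      pool <- observed_angles[animal_id == animal_id[i]]
      out[i, ] <- pool[sample.int(length(pool), J, replace = TRUE)]
    }
    return(out)
  }
  matrix(observed_angles[sample.int(length(observed_angles), n_strata * J,
                                    replace = TRUE)],
         n_strata, J)
}

#' Build the case-control design for the SSF likelihood
#'
#' One stratum per usable record: the observed step angle is the case and
#' the supplied control angles are the alternatives, all sharing the
#' stratum's own (y_prev, psi) anchors. Covariates are the cosines of the
#' turning angle and of the angle(s) to the target(s).
#'
#' @param data a \code{step_series}.
#' @param controls numeric matrix of control angles, one row per usable
#'   record of \code{data} (see \code{\link{sample_controls}}).
#' @return a data frame of class \code{ssf_design}, long format: one row per
#'   alternative with columns \code{stratum_id}, \code{is_case},
#'   \code{angle}, \code{cos_turn}, \code{cos_target1}, \code{cos_target2}
#'   (NA without a second taxis) and \code{animal_id}.
#' @export
build_design <- function(data, controls) {
  u <- usable_steps(data)
  controls <- as.matrix(controls)
  if (nrow(controls) != nrow(u))
    stop("design-mismatch: need one row of controls per usable record",
         call. = FALSE)
  J <- ncol(controls)
  n <- nrow(u)
  ang <- cbind(u$y, controls)                       # column 1 is the case
  sid <- rep(seq_len(n), times = J + 1L)
  angles <- as.vector(ang)
  des <- data.frame(
    stratum_id = sid,
    is_case = rep(c(1L, rep(0L, J)), each = n),
    angle = wrap_angle(angles),
    cos_turn = cos(angles - u$y_prev[sid]),
    cos_target1 = cos(angles - u$psi1[sid]),
    cos_target2 = if (all(is.na(u$psi2))) NA_real_ else
      cos(angles - u$psi2[sid]),
    animal_id = u$animal_id[sid]
  )
  des <- des[order(des$stratum_id, -des$is_case), , drop = FALSE]
  rownames(des) <- NULL
  class(des) <- c("ssf_design", "data.frame")
  des
}

# Covariate matrix of a design for a given number of taxes.
.design_X <- function(design, n_biases) {
  X <- cbind(design$cos_turn, design$cos_target1)
  if (n_biases == 2L) {
    if (all(is.na(design$cos_target2)))
      stop("two-taxis fit requested but cos_target2 is absent", call. = FALSE)
    X <- cbind(X, design$cos_target2)
  }
  colnames(X) <- paste0("kappa", seq_len(n_biases + 1L))
  X
}

# Conditional-logistic log-likelihood, gradient, per-stratum scores and
# Hessian, all from one pass (log-sum-exp stabilized).
.clogit_parts <- function(kappa, X, sid, case) {
  eta <- drop(X %*% kappa)
  mx <- stats::ave(eta, sid, FUN = max)
  w <- exp(eta - mx)
  den <- rowsum(w, sid)                       # one row per stratum, sorted ids
  first <- !duplicated(sid)
  ll <- sum(eta[case]) - sum(log(den)) - sum(mx[first])
  p <- w / den[match(sid, sort(unique(sid)))]
  pX <- X * p
  m <- rowsum(pX, sid)                         # E[x] per stratum
  scores <- X[case, , drop = FALSE] - m
  H <- -crossprod(X, pX) + crossprod(m)
  list(ll = ll, grad = colSums(scores), scores = scores, hessian = H)
}

#' Fit the SSF by conditional logistic regression
#'
#' Direct maximization of the case-control likelihood: each stratum
#' contributes exp(case linear predictor) over the sum across the case and
#' its J controls, with linear predictor
#' kappa1 cos(turn) + kappa2 cos(target1) [+ kappa3 cos(target2)].
#' The likelihood is concave; analytic gradients and Hessian are used.
#' Standard errors come from the conditional-logistic information matrix,
#' and bias ratios beta_k = kappa_{k+1}/kappa_1 carry delta-method SEs.
#'
#' @param design an \code{ssf_design} from \code{\link{build_design}} or
#'   \code{\link{trail_ssf_design}}.
#' @param n_biases 1 or 2 movement taxes.
#' @param cluster optional vector (one entry per design row) for clustered
#'   sandwich scores; default clusters by stratum.
#' @return a \code{bcrw_fit} with \code{method = "ssf"}.
#' @export
fit_ssf <- function(design, n_biases = 1L, cluster = NULL) {
  n_strata <- length(unique(design$stratum_id))
  if (n_strata < 2L) stop("need at least 2 strata", call. = FALSE)
  design <- design[order(design$stratum_id, -design$is_case), , drop = FALSE]
  X <- .design_X(design, n_biases)
  sid <- design$stratum_id
  case <- design$is_case == 1L
  if (any(rowsum(as.integer(case), sid) != 1L))
    stop("each stratum must contain exactly one case", call. = FALSE)
  # uninformative design: no covariate varies within any stratum
  n_alt <- tabulate(factor(sid))
  within_ss <- rowsum(X^2, sid) - rowsum(X, sid)^2 / n_alt
  if (max(within_ss) < 1e-20) {
    J <- tabulate(match(sid, unique(sid)))[1] - 1L
    est <- rep(0, n_biases + 1L)
    fit <- structure(list(method = "ssf", estimates = est,
                          loglik = -n_strata * log(J + 1),
                          vcov_model = NULL, vcov_sandwich = NULL,
                          converged = FALSE, at_bound = FALSE,
                          unidentifiable = TRUE, n_obs = n_strata,
                          kappa = est, beta = rep(NA_real_, n_biases),
                          beta_se = rep(NA_real_, n_biases)),
                     class = "bcrw_fit")
    return(fit)
  }
  fn <- function(k) -.clogit_parts(k, X, sid, case)$ll
  gr <- function(k) -.clogit_parts(k, X, sid, case)$grad
  opt <- stats::optim(rep(0, n_biases + 1L), fn, gr, method = "L-BFGS-B",
                      lower = rep(-.kappa_box, n_biases + 1L),
                      upper = rep(.kappa_box, n_biases + 1L),
                      control = list(factr = 10, maxit = 500))
  kappa <- opt$par
  at_bound <- any(abs(abs(kappa) - .kappa_box) < 1e-6)
  parts <- .clogit_parts(kappa, X, sid, case)
  clus <- if (is.null(cluster)) NULL else cluster[!duplicated(sid)]
  fit <- .finish_fit(paste0("kappa", seq_len(n_biases + 1L)), kappa,
                     parts$ll, parts$hessian, parts$scores, clus,
                     converged = opt$convergence == 0 && !at_bound,
                     at_bound = at_bound, n_obs = n_strata, method = "ssf")
  fit$unidentifiable <- FALSE
  fit
}

#' Serialize an SSF design to a delimited table
#'
#' Long-format tab-separated file (stratum_id, is_case, cos_turn,
#' cos_target1, cos_target2, angle, animal_id), directly consumable by any
#' conditional-logistic routine for cross-validation of the built-in fitter.
#'
#' @param design an \code{ssf_design}.
#' @param path output file.
#' @param header_comment optional character vector written as '#'-prefixed
#'   comment lines (parameterization, seed).
#' @export
write_ssf_design <- function(design, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.table(design, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
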