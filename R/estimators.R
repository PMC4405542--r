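# Maximum-likelihood fitting of the angular and consensus BCRW models.
#
# Both models are von Mises step-angle regressions. The angular model keeps
# a constant concentration kappa about the compromise direction mu_t; the
# consensus model lets the concentration grow with the agreement length
# ell_t, which puts it in the exponential family with natural parameters
# (kappa1, kappa2[, kappa3]) and sufficient statistics
# cos(y_t - y_{t-1}), cos(y_t - psi_kt).

# --- internal: matrices of anchor angles for the usable rows ---------------
.anchor_matrix <- function(data, n_biases) {
  u <- usable_steps(data)
  if (n_biases == 2L && all(is.na(u$psi2)))
    stop("two-taxis fit requested but psi2 is absent", call. = FALSE)
  A <- cbind(u$y_prev, u$psi1)
  if (n_biases == 2L) A <- cbind(A, u$psi2)
  list(y = u$y, A = A, animal = u$animal_id, n = nrow(u))
}

# Resultant of the kappa-weighted anchor vectors, R_t = kappa1 * ell_t.
.kappa_resultant <- function(kappa, A) {
  ex <- drop(cos(A) %*% kappa)
  ny <- drop(sin(A) %*% kappa)
  list(ex = ex, ny = ny, r = sqrt(ex^2 + ny^2))
}

#' Log-likelihood of the consensus BCRW model
#'
#' sum_t [ kappa1 cos(y_t - y_{t-1}) + kappa2 cos(y_t - psi_1t)
#'         (+ kappa3 cos(y_t - psi_2t)) - log(2 pi I0(kappa1 * ell_t)) ],
#' where kappa1 * ell_t is the length of the kappa-weighted resultant of the
#' anchor directions. The density is well-defined for any real kappa's
#' (negative values model repulsion); only usable rows contribute.
#'
#' @param kappa numeric vector (kappa1, kappa2) or (kappa1, kappa2, kappa3).
#' @param data a \code{step_series}.
#' @return the log-likelihood (scalar).
#' @export
loglik_consensus <- function(kappa, data) {
  nb <- length(kappa) - 1L
  stopifnot(nb %in% c(1L, 2L))
  am <- .anchor_matrix(data, nb)
  res <- .kappa_resultant(kappa, am$A)
  sum(cos(am$y - am$A) %*% kappa) - am$n * log(2 * pi) - sum(log_bessel_i0(res$r))
}

# Per-record score vectors of the consensus log-likelihood (rows = records).
.scores_consensus <- function(kappa, am) {
  res <- .kappa_resultant(kappa, am$A)
  a1 <- ifelse(res$r < .ell_floor, 0, bessel_ratio_a1(res$r))
  # dR/dkappa_j = (ex cos A_j + ny sin A_j) / R  (0 in the degenerate limit)
  rsafe <- pmax(res$r, .ell_floor)
  drd <- (res$ex * cos(am$A) + res$ny * sin(am$A)) / rsafe
  cos(am$y - am$A) - a1 * drd
}

#' Log-likelihood of the angular BCRW model
#'
#' sum_t [ kappa cos(y_t - mu_t) - log(2 pi I0(kappa)) ] with mu_t the
#' direction of the compromise vector at the supplied bias weights.
#'
#' @param params numeric vector (beta, kappa) or (beta1, beta2, kappa);
#'   kappa last, strictly positive.
#' @param data a \code{step_series}.
#' @return the log-likelihood (scalar).
#' @export
loglik_angular <- function(params, data) {
  nb <- length(params) - 1L
  stopifnot(nb %in% c(1L, 2L))
  beta <- params[seq_len(nb)]
  kappa <- params[nb + 1L]
  if (kappa <= 0) stop("invalid-concentration: kappa must be > 0", call. = FALSE)
  am <- .anchor_matrix(data, nb)
  mu <- .angular_mu(beta, am$A)
  sum(kappa * cos(am$y - mu$mu)) - am$n * (log(2 * pi) + log_bessel_i0(kappa))
}

# Compromise direction for all records at once; weight 1 on y_prev.
.angular_mu <- function(beta, A) {
  w <- c(1, beta)
  ex <- drop(cos(A) %*% w)
  ny <- drop(sin(A) %*% w)
  ell2 <- ex^2 + ny^2
  mu <- ifelse(sqrt(ell2) < .ell_floor, 0, atan2(ny, ex))
  list(mu = mu, ex = ex, ny = ny, ell2 = pmax(ell2, .ell_floor^2))
}

# Per-record scores of the angular log-likelihood w.r.t. (beta..., kappa).
.scores_angular <- function(params, am) {
  nb <- ncol(am$A) - 1L
  beta <- params[seq_len(nb)]
  kappa <- params[nb + 1L]
  mu <- .angular_mu(beta, am$A)
  sinres <- sin(am$y - mu$mu)
  g <- matrix(0, nrow = am$n, ncol = nb + 1L)
  for (k in seq_len(nb)) {
    psi <- am$A[, k + 1L]
    dmu <- (mu$ex * sin(psi) - mu$ny * cos(psi)) / mu$ell2
    g[, k] <- kappa * sinres * dmu
  }
  g[, nb + 1L] <- cos(am$y - mu$mu) - bessel_ratio_a1(kappa)
  g
}

#' Sandwich (robust) covariance from scores and a Hessian
#'
#' H^{-1} (sum_c G_c G_c^T) H^{-1}, where G_c is the score summed within
#' cluster c. Clustering by animal is the conservative default for serially
#' dependent steps; passing no cluster treats records as independent.
#'
#' @param scores matrix of per-record score contributions (rows = records).
#' @param hessian Hessian of the log-likelihood at the optimum (negative
#'   definite there).
#' @param cluster optional vector of cluster labels, one per record.
#' @return symmetric covariance matrix.
#' @export
sandwich_vcov <- function(scores, hessian, cluster = NULL) {
  scores <- as.matrix(scores)
  bread <- tryCatch(solve(-hessian), error = function(e)
    stop("non-identifiable-fit: singular hessian", call. = FALSE))
  g <- if (is.null(cluster)) scores else rowsum(scores, group = cluster)
  meat <- crossprod(g)
  v <- bread %*% meat %*% bread
  (v + t(v)) / 2
}

#' Delta-method standard errors of bias ratios beta_k = kappa_{k+1}/kappa_1
#'
#' Propagates the covariance of the concentration estimates through the
#' ratio: the gradient of kappa_{k+1}/kappa_1 is (-kappa_{k+1}/kappa_1^2)
#' in position 1 and 1/kappa_1 in position k+1.
#'
#' @param kappa estimated concentration vector (kappa1 first), or a
#'   \code{bcrw_fit} from \code{\link{fit_consensus}} or \code{\link{fit_ssf}}.
#' @param vcov covariance matrix of the kappa estimates (ignored when a fit
#'   object is given, unless supplied to override).
#' @return numeric vector of standard errors, one per bias.
#' @export
delta_method_beta_se <- function(kappa, vcov = NULL) {
  if (inherits(kappa, "bcrw_fit")) {
    fit <- kappa
    if (is.null(vcov))
      vcov <- if (!is.null(fit$vcov_sandwich)) fit$vcov_sandwich else fit$vcov_model
    kappa <- fit$kappa
  }
  k1 <- kappa[1]
  if (abs(k1) < 1e-8)
    stop("undefined-ratio: kappa1 is numerically zero", call. = FALSE)
  nb <- length(kappa) - 1L
  vapply(seq_len(nb), function(k) {
    grad <- numeric(length(kappa))
    grad[1] <- -kappa[k + 1L] / k1^2
    grad[k + 1L] <- 1 / k1
    sqrt(drop(t(grad) %*% vcov %*% grad))
  }, numeric(1))
}

.kappa_box <- 500

#' Fit the consensus BCRW model by maximum likelihood
#'
#' Quasi-Newton maximization of \code{\link{loglik_consensus}} with analytic
#' gradients; the exponential-family likelihood is smooth in the kappa's and
#' well-defined for negative values, so the parameters are unconstrained up
#' to a wide box (|kappa| <= 500) that flags runaway concentrations.
#'
#' @param data a \code{step_series} with at least 10 usable records.
#' @param n_biases 1 (single taxis) or 2 (adds psi2).
#' @param cluster_scores cluster sandwich scores by animal (default TRUE).
#' @return a \code{bcrw_fit}: kappa estimates, beta ratios with delta-method
#'   SEs, log-likelihood, model-based and sandwich covariances, flags.
#' @export
fit_consensus <- function(data, n_biases = 1L, cluster_scores = TRUE) {
  am <- .anchor_matrix(data, n_biases)
  if (am$n < 10L) stop("need at least 10 usable records", call. = FALSE)
  start <- c(1, rep(0, n_biases))
  fn <- function(k) -loglik_consensus(k, data)
  gr <- function(k) -colSums(.scores_consensus(k, am))
  opt <- stats::optim(start, fn, gr, method = "L-BFGS-B",
                      lower = rep(-.kappa_box, n_biases + 1L),
                      upper = rep(.kappa_box, n_biases + 1L),
                      control = list(factr = 10, maxit = 500))
  kappa <- opt$par
  at_bound <- any(abs(abs(kappa) - .kappa_box) < 1e-6)
  H <- pracma::hessian(function(k) loglik_consensus(k, data), kappa)
  sc <- .scores_consensus(kappa, am)
  .finish_fit(kappa_names(n_biases, "consensus"), kappa, -opt$val, H, sc,
              if (cluster_scores) am$animal else NULL,
              converged = opt$convergence == 0 && !at_bound,
              at_bound = at_bound, n_obs = am$n, method = "consensus")
}

#' Fit the angular BCRW model by maximum likelihood
#'
#' Maximizes \code{\link{loglik_angular}} over (beta[, beta2], kappa) with
#' analytic gradients. Internally beta is softplus-transformed (bias weights
#' are non-negative by construction) and kappa is log-transformed with an
#' upper box at 500; noise-free data drive kappa to that bound, which is
#' flagged rather than hidden.
#'
#' @inheritParams fit_consensus
#' @return a \code{bcrw_fit}; estimates are reported on the (beta, kappa)
#'   scale, with sandwich SEs for beta taken directly from the covariance.
#' @export
fit_angular <- function(data, n_biases = 1L, cluster_scores = TRUE) {
  am <- .anchor_matrix(data, n_biases)
  if (am$n < 10L) stop("need at least 10 usable records", call. = FALSE)
  gap <- wrap_angle(am$A[, 2] - am$A[, 1])
  if (max(abs(gap)) < 1e-10)
    stop("unidentifiable: target bearing coincides with previous bearing on every step",
         call. = FALSE)
  softplus <- function(b) ifelse(b > 30, b, log1p(exp(b)))
  to_nat <- function(p) c(softplus(p[seq_len(n_biases)]), exp(p[n_biases + 1L]))
  # start at beta = 0 (b large negative would pin the gradient; use softplus(0))
  start <- c(rep(-1, n_biases), 0)
  fn <- function(p) -loglik_angular(to_nat(p), data)
  gr <- function(p) {
    nat <- to_nat(p)
    g <- colSums(.scores_angular(nat, am))
    jac <- c(1 - exp(-nat[seq_len(n_biases)]), nat[n_biases + 1L])
    -(g * jac)
  }
  opt <- stats::optim(start, fn, gr, method = "L-BFGS-B",
                      lower = c(rep(-40, n_biases), log(1e-6)),
                      upper = c(rep(40, n_biases), log(.kappa_box)),
                      control = list(factr = 10, maxit = 500))
  est <- to_nat(opt$par)
  at_bound <- abs(est[n_biases + 1L] - .kappa_box) < 1e-3
  H <- pracma::hessian(function(p) loglik_angular(p, data), est)
  sc <- .scores_angular(est, am)
  fit <- .finish_fit(kappa_names(n_biases, "angular"), est, -opt$val, H, sc,
                     if (cluster_scores) am$animal else NULL,
                     converged = opt$convergence == 0 && !at_bound,
                     at_bound = at_bound, n_obs = am$n, method = "angular")
  # beta is a direct parameter here: its SE needs no delta method
  vc <- if (!is.null(fit$vcov_sandwich)) fit$vcov_sandwich else fit$vcov_model
  fit$beta <- est[seq_len(n_biases)]
  fit$beta_se <- sqrt(pmax(diag(vc)[seq_len(n_biases)], 0))
  fit
}

kappa_names <- function(n_biases, method) {
  if (method == "angular")
    c(paste0("beta", seq_len(n_biases)), "kappa")
  else
    paste0("kappa", seq_len(n_biases + 1L))
}

# Shared tail of all fitters: covariances, beta ratios, packaging.
.finish_fit <- function(par_names, est, loglik, H, scores, cluster,
                        converged, at_bound, n_obs, method) {
  names(est) <- par_names
  vcov_model <- tryCatch(solve(-H), error = function(e) NULL)
  vcov_sandwich <- tryCatch(sandwich_vcov(scores, H, cluster),
                            error = function(e) NULL)
  dimnames(H) <- list(par_names, par_names)
  if (!is.null(vcov_model)) dimnames(vcov_model) <- dimnames(H)
  if (!is.null(vcov_sandwich)) dimnames(vcov_sandwich) <- dimnames(H)
  fit <- structure(list(
    method = method, estimates = est, loglik = loglik,
    vcov_model = vcov_model, vcov_sandwich = vcov_sandwich,
    converged = converged, at_bound = at_bound, n_obs = n_obs),
    class = "bcrw_fit")
  if (method %in% c("consensus", "ssf")) {
    fit$kappa <- est
    k1 <- est[1]
    nb <- length(est) - 1L
    if (abs(k1) > 1e-8) {
      fit$beta <- est[-1] / k1
      names(fit$beta) <- paste0("beta", seq_len(nb))
      vc <- if (method == "ssf") {
        if (!is.null(vcov_model)) vcov_model else vcov_sandwich
      } else {
        if (!is.null(vcov_sandwich)) vcov_sandwich else vcov_model
      }
      fit$beta_se <- if (is.null(vc)) rep(NA_real_, nb) else
        delta_method_beta_se(est, vc)
    } else {
      fit$beta <- rep(NA_real_, nb)
      fit$beta_se <- rep(NA_real_, nb)
    }
  } else {
    fit$kappa <- est[length(est)]
  }
  fit
}

#' @export
print.bcrw_fit <- function(x, ...) {
  cat(sprintf("BCRW fit (%s model), %d likelihood records\n", x$method, x$n_obs))
  se_m <- if (!is.null(x$vcov_model)) sqrt(pmax(diag(x$vcov_model), 0)) else NA
  se_s <- if (!is.null(x$vcov_sandwich)) sqrt(pmax(diag(x$vcov_sandwich), 0)) else NA
  tab <- data.frame(estimate = x$estimates, se_model = se_m, se_robust = se_s)
  print(round(tab, 4))
  if (!is.null(x$beta) && x$method != "angular") {
    bt <- data.frame(estimate = x$beta, se_delta = x$beta_se)
    rownames(bt) <- names(x$beta)
    cat("bias ratios beta_k = kappa_{k+1}/kappa_1:\n")
    print(round(bt, 4))
  }
  cat(sprintf("log-likelihood %.3f; converged: %s%s\n", x$loglik,
              x$converged, if (x$at_bound) " (at box bound)" else ""))
  invisible(x)
}
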