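test_that("angular log-likelihood matches closed forms and a term-by-term oracle", {
  one <- step_series(data.frame(animal_id = "A", t = 1:2,
                                y = c(0.5, 0.5), psi1 = c(0.2, 0.2)))
  expect_equal(loglik_angular(c(0, 1), one),
               1 - log(2 * pi * besselI(1, 0)))
  set.seed(107)
  d <- make_series(10)
  beta <- 0.6; kappa <- 1.7
  u <- d[d$usable, ]
  oracle <- sum(vapply(seq_len(nrow(u)), function(i) {
    md <- mean_direction(u$y_prev[i], u$psi1[i], beta)
    kappa * cos(u$y[i] - md$mu) - log(2 * pi * besselI(kappa, 0))
  }, numeric(1)))
  expect_equal(loglik_angular(c(beta, kappa), d), oracle, tolerance = 1e-12)
  expect_error(loglik_angular(c(0.5, -1), d), "invalid-concentration")
})

test_that("the two algebraic forms of the consensus likelihood agree pointwise", {
  set.seed(108)
  d <- make_series(10)
  u <- d[d$usable, ]
  k1 <- 1.4; k2 <- 0.9
  # (mu, kappa * ell) parameterization, built from the compromise vector
  oracle <- sum(vapply(seq_len(nrow(u)), function(i) {
    md <- mean_direction(u$y_prev[i], u$psi1[i], k2 / k1)
    log_vm_density(u$y[i], md$mu, k1 * md$length)
  }, numeric(1)))
  expect_equal(loglik_consensus(c(k1, k2), d), oracle, tolerance = 1e-10)
})

test_that("consensus likelihood limits: no bias reduces to the CRW, all-zero kappa to uniform", {
  set.seed(109)
  d <- make_series(15)
  kappa <- 2.3
  expect_equal(loglik_consensus(c(kappa, 0), d), loglik_angular(c(0, kappa), d),
               tolerance = 1e-12)
  expect_equal(loglik_consensus(c(0, 0), d), 15 * log(1 / (2 * pi)))
})

test_that("the consensus fitter recovers its own simulation and never beats the optimum", {
  set.seed(110)
  for (i in 1:5) {
    d <- consensus_replicate(2, 0.5)
    f <- fit_consensus(d)
    expect_true(f$converged)
    expect_gte(f$loglik, loglik_consensus(c(2, 0.5), d))
  }
  ks <- t(replicate(50, fit_consensus(consensus_replicate(2, 0.5))$kappa))
  expect_lt(abs(mean(ks[, 1]) - 2) / 2, 0.10)
  expect_lt(abs(mean(ks[, 2]) - 0.5) / 0.5, 0.10)
})

test_that("noise-free angular data drive kappa to the box bound with a flag", {
  set.seed(111)
  n <- 40
  psi <- runif(n, -pi, pi)
  y <- numeric(n); y_prev <- 0.3
  for (i in seq_len(n)) {
    y[i] <- mean_direction(y_prev, psi[i], 0.7)$mu
    y_prev <- y[i]
  }
  d <- step_series(data.frame(animal_id = "A", t = seq_len(n), y = y, psi1 = psi))
  f <- fit_angular(d)
  expect_true(f$at_bound)
  expect_false(f$converged)
  expect_equal(unname(f$estimates["kappa"]), 500, tolerance = 1e-3)
})

test_that("under a true CRW the angular bias estimate is null within 3 SE in most replicates", {
  set.seed(112)
  hits <- replicate(100, {
    d <- consensus_replicate(2, 0)      # kappa2 = 0: pure CRW
    f <- fit_angular(d)
    abs(f$beta[1]) < 3 * f$beta_se[1]
  })
  expect_gte(mean(hits), 0.90)
})

test_that("the angular fitter refuses data where the target always lies straight ahead", {
  set.seed(113)
  d <- make_series(20)
  d$psi1 <- d$y_prev
  d$psi1[!d$usable] <- 0
  expect_error(fit_angular(step_series(d)), "unidentifiable")
})

test_that("sandwich covariance reduces to the scalar formula and matches the information at truth", {
  g <- matrix(c(0.3, -1.1, 0.4, 0.2, 0.9), ncol = 1)
  H <- matrix(-2.5, 1, 1)
  expect_equal(drop(sandwich_vcov(g, H)), sum(g^2) / 2.5^2)
  # correctly specified model, large n: sandwich and model SEs agree
  set.seed(114)
  pos <- simulate_consensus(5001, kappa = 2, beta = 0.25,
                            start = c(0, 0), target = c(5e6, 5e6))
  d <- steps_from_positions(pos, target = c(5e6, 5e6))
  f <- fit_consensus(d, cluster_scores = FALSE)
  se_m <- sqrt(diag(f$vcov_model)); se_s <- sqrt(diag(f$vcov_sandwich))
  expect_true(all(abs(se_s - se_m) / se_m < 0.15))
  expect_error(sandwich_vcov(g, matrix(0, 1, 1)), "non-identifiable-fit")
})

test_that("a misspecified fit still yields a positive semi-definite sandwich", {
  set.seed(115)
  d <- run_two_animal_replicate(sim_scenario("angular", 2, 0.5, error_kappa = 2))
  f <- fit_consensus(d)               # consensus fit to angular-model data
  expect_true(all(eigen(f$vcov_sandwich, symmetric = TRUE)$values > -1e-10))
})

test_that("delta-method SEs obey the closed forms and are scale-free in kappa", {
  expect_equal(delta_method_beta_se(c(2, 0), diag(c(0.04, 0.09))),
               sqrt(0.09) / 2)
  v <- matrix(c(0.04, 0.01, 0.01, 0.02), 2)
  k <- c(2, 0.5)
  se1 <- delta_method_beta_se(k, v)
  se2 <- delta_method_beta_se(3 * k, 9 * v)
  expect_equal(se1, se2, tolerance = 1e-12)
  expect_error(delta_method_beta_se(c(0, 1), v), "undefined-ratio")
})

test_that("estimates are invariant to rotating the reference direction", {
  set.seed(116)
  d <- consensus_replicate(2, 0.5)
  rot <- d
  for (a in c("y", "y_prev", "psi1"))
    rot[[a]][!is.na(rot[[a]])] <- wrap_angle(rot[[a]][!is.na(rot[[a]])] + 0.8)
  f1 <- fit_consensus(d); f2 <- fit_consensus(rot)
  expect_equal(f1$kappa, f2$kappa, tolerance = 1e-5)
  a1 <- fit_angular(d); a2 <- fit_angular(rot)
  expect_equal(a1$estimates, a2$estimates, tolerance = 1e-4)
})
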