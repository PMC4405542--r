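test_that("control sampling honors its scheme, pool and seed", {
  set.seed(117)
  u <- sample_controls(numeric(0), J = 2000, scheme = "uniform", n_strata = 1)
  expect_gt(kuiper_test(drop(u))$p_value, 0.01)
  one <- sample_controls(0.73, J = 5, scheme = "empirical", n_strata = 3)
  expect_true(all(one == 0.73))
  set.seed(42); c1 <- sample_controls(runif(120, -pi, pi), 10)
  set.seed(42); c2 <- sample_controls(runif(120, -pi, pi), 10)
  expect_identical(c1, c2)
  expect_error(sample_controls(numeric(0), 5, "empirical"), "no-controls")
})

test_that("the case-control design has one case per stratum and exact cosine covariates", {
  d <- step_series(data.frame(animal_id = "A", t = 1:3,
                              y = c(0.4, 0.4, 1), psi1 = c(0.4, 0.4, 0.4)))
  ctrl <- matrix(c(0.4 + pi, 1, 0, 2), nrow = 2)   # 2 usable records, J = 2
  des <- build_design(d, ctrl)
  expect_equal(nrow(des), 6)
  expect_equal(as.integer(tapply(des$is_case, des$stratum_id, sum)), c(1L, 1L))
  # record 2: y = y_prev = psi1 = 0.4 -> case covariates (1, 1)
  case1 <- des[des$stratum_id == 1 & des$is_case == 1, ]
  expect_equal(case1$cos_turn, 1)
  expect_equal(case1$cos_target1, 1)
  # its first control is antipodal to y_prev -> persistence covariate -1
  ctl1 <- des[des$stratum_id == 1 & des$is_case == 0, ][1, ]
  expect_equal(ctl1$cos_turn, -1)
  expect_error(build_design(d, ctrl[1, , drop = FALSE]), "design-mismatch")
})

test_that("two animals observed for 61 steps yield 120 strata", {
  set.seed(118)
  d <- consensus_replicate()
  expect_equal(sum(d$usable), 120)
  des <- build_design(d, sample_controls(d$y[d$usable], 10))
  expect_equal(length(unique(des$stratum_id)), 120)
})

test_that("an uninformative design is flagged and its likelihood is the null constant", {
  d <- step_series(data.frame(animal_id = "A", t = 1:13,
                              y = rep(0.2, 13), psi1 = rep(0.2, 13)))
  ctrl <- matrix(0.2, nrow = 12, ncol = 3)         # controls equal the case
  f <- fit_ssf(build_design(d, ctrl))
  expect_true(f$unidentifiable)
  expect_false(f$converged)
  expect_equal(f$loglik, -12 * log(4))
})

test_that("the conditional-logistic optimizer agrees with a brute-force grid on a toy design", {
  set.seed(119)
  d <- make_series(5)
  ctrl <- sample_controls(runif(40, -pi, pi), J = 3, n_strata = 5)
  des <- build_design(d, ctrl)
  u <- d[d$usable, ]
  # independent brute-force evaluation of the case-control likelihood
  grid_ll <- function(k1, k2) {
    ll <- 0
    for (i in 1:5) {
      angs <- c(u$y[i], ctrl[i, ])
      eta <- k1 * cos(angs - u$y_prev[i]) + k2 * cos(angs - u$psi1[i])
      ll <- ll + eta[1] - log(sum(exp(eta)))
    }
    ll
  }
  k1g <- seq(-3, 3, by = 0.05); k2g <- seq(-3, 3, by = 0.05)
  vals <- outer(k1g, k2g, Vectorize(grid_ll))
  best <- which(vals == max(vals), arr.ind = TRUE)
  f <- fit_ssf(des)
  expect_lt(abs(k1g[best[1]] - f$kappa[1]), 0.05 + 1e-9)
  expect_lt(abs(k2g[best[2]] - f$kappa[2]), 0.05 + 1e-9)
  expect_equal(f$loglik, grid_ll(f$kappa[1], f$kappa[2]), tolerance = 1e-10)
})

test_that("the built-in fitter matches an independent conditional-logistic routine", {
  skip_if_not_installed("survival")
  set.seed(120)
  d <- consensus_replicate()
  des <- build_design(d, sample_controls(d$y[d$usable], 10))
  f <- fit_ssf(des)
  withr::local_package("survival")
  cl <- survival::clogit(is_case ~ cos_turn + cos_target1 +
                           strata(stratum_id), data = des)
  expect_equal(unname(f$kappa), unname(coef(cl)), tolerance = 1e-5)
  expect_equal(unname(sqrt(diag(f$vcov_model))),
               unname(sqrt(diag(vcov(cl)))), tolerance = 1e-4)
})

test_that("SSF estimates are invariant to a common rotation of all angles", {
  set.seed(121)
  d <- consensus_replicate()
  ctrl <- sample_controls(d$y[d$usable], 10)
  f1 <- fit_ssf(build_design(d, ctrl))
  rot <- d
  for (a in c("y", "y_prev", "psi1"))
    rot[[a]][!is.na(rot[[a]])] <- wrap_angle(rot[[a]][!is.na(rot[[a]])] + 1.1)
  f2 <- fit_ssf(build_design(rot, wrap_angle(ctrl + 1.1)))
  expect_equal(f1$kappa, f2$kappa, tolerance = 1e-6)
})

test_that("large-J uniform control denominators converge to the Bessel normalizer", {
  set.seed(122)
  gaps <- replicate(100, {
    k1 <- runif(1, 0.2, 3); k2 <- runif(1, 0, 2)
    yp <- runif(1, -pi, pi); ps <- runif(1, -pi, pi)
    del <- runif(1e4, -pi, pi)
    m <- mean(exp(k1 * cos(del - yp) + k2 * cos(del - ps)))
    R <- k1 * consensus_length(yp, ps, k2 / k1)
    abs(log(m) - log_bessel_i0(R))
  })
  expect_lt(mean(gaps), 0.01)
})
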