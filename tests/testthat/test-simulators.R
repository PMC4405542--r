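test_that("landscape proportions are exact up to integer pixel counts and seeds reproduce", {
  set.seed(125)
  land <- simulate_landscape(256, 256, c(0.8, 0.1, 0.1), corr_range = 20)
  counts <- table(factor(land$grid, levels = 1:3))
  expect_true(all(counts > 0))
  expect_lte(abs(counts[1] - round(0.8 * 256^2)), 1)
  expect_lte(abs(counts[2] - round(0.1 * 256^2)), 1)
  set.seed(99); g1 <- simulate_landscape(64, 64)$grid
  set.seed(99); g2 <- simulate_landscape(64, 64)$grid
  expect_identical(g1, g2)
  expect_error(simulate_landscape(1, 1), "invalid-dimensions")
})

test_that("zero correlation range gives spatially independent habitat codes", {
  set.seed(126)
  land <- simulate_landscape(200, 200, corr_range = 0)
  g <- land$grid
  # lag-1 correlation of the code values, both grid directions
  r_row <- cor(as.vector(g[-1, ]), as.vector(g[-200, ]))
  r_col <- cor(as.vector(g[, -1]), as.vector(g[, -200]))
  expect_lt(abs(r_row), 0.05)
  expect_lt(abs(r_col), 0.05)
})

test_that("a positive correlation range produces spatially aggregated habitat", {
  set.seed(127)
  g <- simulate_landscape(200, 200, corr_range = 20)$grid
  r_row <- cor(as.vector(g[-1, ]), as.vector(g[-200, ]))
  expect_gt(r_row, 0.5)
})

test_that("landscapes round-trip through the plain-text grid format", {
  set.seed(128)
  land <- simulate_landscape(32, 48, c(0.5, 0.3, 0.2), corr_range = 5)
  f <- tempfile(fileext = ".txt")
  write_landscape(land, f)
  back <- read_landscape(f)
  expect_identical(back$grid, land$grid)
  expect_equal(back$pixel_size, land$pixel_size)
  expect_equal(back$target, land$target)
})

test_that("consensus walks have fixed step length and the stated turning law at beta = 0", {
  set.seed(129)
  pos <- simulate_consensus(50000, kappa = 2, beta = 0,
                            start = c(0, 0), target = c(1e9, 1e9))
  d <- steps_from_positions(pos, target = c(1e9, 1e9))
  expect_true(all(abs(d$d - 60) < 1e-6))
  turn <- wrap_angle(d$y[d$usable] - d$y_prev[d$usable])
  expect_lt(abs(circ_mean(turn)), 0.02)
  k_hat <- kappa_from_rbar(circ_rbar(turn))
  expect_lt(abs(k_hat - 2) / 2, 0.03)
})

test_that("strong consensus attraction produces a near-deterministic beeline", {
  set.seed(130)
  pos <- simulate_consensus(30, kappa = 200, beta = 50, start = c(0, 0),
                            target = c(1200, 0), y0 = 2)
  dist <- sqrt((pos$x - 1200)^2 + pos$y^2)
  within <- which(dist <= 60)[1]
  expect_false(is.na(within))
  expect_true(all(diff(dist[1:within]) < 0))
})

test_that("angular walks with huge error concentration track the compromise direction", {
  set.seed(131)
  pos <- simulate_angular(1000, beta = 0.7, error_kappa = 1e4,
                          start = c(0, 0), target = c(1e7, 1e7))
  d <- steps_from_positions(pos, target = c(1e7, 1e7))
  u <- d[d$usable, ]
  mu <- vapply(seq_len(nrow(u)), function(i)
    mean_direction(u$y_prev[i], u$psi1[i], 0.7)$mu, numeric(1))
  expect_lt(max(abs(wrap_angle(u$y - mu))), 0.05)
  set.seed(7); p1 <- simulate_angular(20, 0.5, 2, start = c(0, 0), target = c(1e4, 0))
  set.seed(7); p2 <- simulate_angular(20, 0.5, 2, start = c(0, 0), target = c(1e4, 0))
  expect_identical(p1, p2)
})

test_that("angular walks with no bias are correlated random walks in law", {
  set.seed(132)
  pos <- simulate_angular(20000, beta = 0, error_kappa = 3,
                          start = c(0, 0), target = c(1e9, 1e9))
  d <- steps_from_positions(pos, target = c(1e9, 1e9))
  turn <- wrap_angle(d$y[d$usable] - d$y_prev[d$usable])
  expect_lt(abs(kappa_from_rbar(circ_rbar(turn)) - 3) / 3, 0.05)
})

test_that("discrete choice is uniform over candidates when both concentrations vanish", {
  set.seed(133)
  land <- simulate_landscape(128, 128, c(0.8, 0.1, 0.1), corr_range = 10)
  h2 <- bcrwssf:::.habitat_pixels(land, 2L)
  h3 <- bcrwssf:::.habitat_pixels(land, 3L)
  px <- c(h2$px, h3$px); py <- c(h2$py, h3$py)
  cand <- bcrwssf:::annulus_candidates(px, py, 64, 64, 20, 30, 10)
  n_cand <- length(cand)
  expect_gt(n_cand, 3)
  picks <- replicate(10000, {
    pos <- simulate_discrete_choice(land, start = c(64, 64), T = 2,
                                    kappa1 = 0, kappa2 = 0,
                                    min_dist = 20, max_dist = 30)
    paste(pos$x[2], pos$y[2])
  })
  freq <- table(picks)
  expect_equal(length(freq), n_cand)
  p0 <- 1 / n_cand
  se <- sqrt(p0 * (1 - p0) / 10000)
  expect_true(all(abs(freq / 10000 - p0) < 3 * se + 1e-9))
})

test_that("an overwhelming target bias concentrates first steps on the target bearing", {
  set.seed(134)
  land <- simulate_landscape(128, 128, c(0.8, 0.1, 0.1), corr_range = 10)
  start <- c(40, 40)
  psi <- atan2(land$target[2] - start[2], land$target[1] - start[1])
  steps <- replicate(1000, {
    pos <- simulate_discrete_choice(land, start = start, T = 2,
                                    kappa1 = 0, kappa2 = 50,
                                    min_dist = 20, max_dist = 30)
    atan2(pos$y[2] - start[2], pos$x[2] - start[1])
  })
  # softmax at kappa2 = 50 puts essentially all mass on bearings at the
  # target: mean alignment ~ 0.99, and no draw strays far
  expect_gte(mean(cos(steps - psi)), 0.97)
  expect_gte(min(cos(steps - psi)), 0.7)
})

test_that("two-animal replicates have 120 usable records, corner starts and central bias", {
  set.seed(135)
  sc <- sim_scenario("consensus", 2, 2)
  d <- run_two_animal_replicate(sc)
  expect_equal(sum(d$usable), 120)
  expect_equal(length(unique(d$animal_id)), 2)
  # strong shared bias: steps align with the target bearing on average
  u <- d[d$usable, ]
  expect_gt(mean(cos(u$y - u$psi1)), 0.2)
})
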