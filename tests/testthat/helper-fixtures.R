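# Shared fixtures: small step series built in code.

# A hand-made step series with n usable records and random anchors.
make_series <- function(n_usable = 20, two_taxes = FALSE, animal = "A1") {
  n <- n_usable + 1L
  df <- data.frame(
    animal_id = animal,
    t = seq_len(n),
    y = runif(n, -pi, pi),
    psi1 = runif(n, -pi, pi),
    d = 60
  )
  if (two_taxes) df$psi2 <- runif(n, -pi, pi)
  step_series(df)
}

# A consensus-model two-animal replicate under the study's conditions.
consensus_replicate <- function(kappa1 = 2, kappa2 = 0.5) {
  run_two_animal_replicate(sim_scenario("consensus", kappa1, kappa2))
}

# Circular mean direction of a sample.
circ_mean <- function(a) atan2(mean(sin(a)), mean(cos(a)))

# Mean resultant length of a sample.
circ_rbar <- function(a) sqrt(mean(cos(a))^2 + mean(sin(a))^2)

# Independent concentration estimate: invert rbar = I1(k)/I0(k).
kappa_from_rbar <- function(rbar) {
  uniroot(function(k) besselI(k, 1, TRUE) / besselI(k, 0, TRUE) - rbar,
          c(1e-8, 700), tol = 1e-10)$root
}
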