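# Monte Carlo driver: simulate replicates under each scenario, fit the
# angular, consensus and SSF estimators to each, and summarize the
# replicate-level estimates the way the study's boxplots do.

# Independent per-replicate seeds derived from one master seed (kept below
# 2^31 so they are valid R integer seeds).
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run the Monte Carlo estimator-comparison study
#'
#' For each scenario and replicate: simulate a two-animal trajectory, fit
#' the angular and consensus models by maximum likelihood, build an SSF
#' design with J empirical controls resampled from the replicate's own
#' observed step angles, fit it by conditional logistic regression, and
#' record the three bias-ratio estimates together with Kuiper's uniformity
#' p-value of the observed angles. Failed or at-bound fits are excluded
#' from the summaries with a logged count.
#'
#' @param scenarios list of \code{sim_scenario} objects (or a single one).
#' @param reps replicates per scenario.
#' @param J number of empirical control angles per stratum.
#' @param master_seed integer seed governing the whole run.
#' @param landscape optional \code{landscape} shared by all discrete-choice
#'   replicates; when NULL a fresh landscape is generated per replicate.
#' @param landscape_dim grid side used when regenerating landscapes.
#' @return a list of class \code{mc_summary}: \code{replicates} (long data
#'   frame of per-replicate estimates), \code{summary} (per scenario x
#'   estimator moments and quartiles of beta-hat), \code{uniformity}
#'   (per-scenario median Kuiper p), \code{n_failed}.
#' @export
run_study <- function(scenarios, reps = 500L, J = 10L, master_seed = 1L,
                      landscape = NULL, landscape_dim = 1024L) {
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  stopifnot(reps >= 1L)
  seeds <- matrix(derive_seeds(master_seed, length(scenarios) * reps),
                  nrow = reps)
  rows <- list()
  for (s in seq_along(scenarios)) {
    sc <- scenarios[[s]]
    label <- sprintf("%s(%g,%g)", sc$model, sc$kappa1, sc$kappa2)
    for (r in seq_len(reps)) {
      set.seed(seeds[r, s])
      land <- NULL
      if (sc$model == "discrete_choice") {
        land <- if (!is.null(landscape)) landscape else
          simulate_landscape(landscape_dim, landscape_dim)
      }
      est <- .fit_one_replicate(sc, land, J)
      rows[[length(rows) + 1L]] <-
        cbind(scenario = label, model = sc$model, rep = r,
              beta_true = sc$beta, est)
    }
  }
  replicates <- do.call(rbind, rows)
  ok <- replicates$converged & is.finite(replicates$beta_hat)
  n_failed <- sum(!ok)
  agg <- function(v, f) stats::aggregate(
    v, by = list(scenario = replicates$scenario[ok],
                 estimator = replicates$estimator[ok]), FUN = f)
  b <- replicates$beta_hat[ok]
  summ <- agg(b, mean)
  names(summ)[3] <- "mean"
  summ$median <- agg(b, stats::median)$x
  summ$sd <- agg(b, stats::sd)$x
  summ$q1 <- agg(b, function(z) stats::quantile(z, 0.25))$x
  summ$q3 <- agg(b, function(z) stats::quantile(z, 0.75))$x
  summ$n <- agg(b, length)$x
  kp <- replicates[replicates$estimator == "consensus", ]
  uniformity <- stats::aggregate(kp$kuiper_p, by = list(scenario = kp$scenario),
                                 FUN = stats::median)
  names(uniformity)[2] <- "median_p"
  structure(list(replicates = replicates, summary = summ,
                 uniformity = uniformity, n_failed = n_failed,
                 reps = reps, J = J, master_seed = master_seed),
            class = "mc_summary")
}

# One replicate: simulate, fit all three estimators, return a 3-row frame.
.fit_one_replicate <- function(scenario, landscape, J) {
  data <- run_two_animal_replicate(scenario, landscape)
  u <- usable_steps(data)
  kp <- kuiper_test(u$y)$p_value
  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  fa <- safe(fit_angular(data))
  fc <- safe(fit_consensus(data))
  fs <- safe({
    ctrl <- sample_controls(u$y, J, "empirical")
    fit_ssf(build_design(data, ctrl))
  })
  row <- function(name, fit) {
    if (is.null(fit))
      return(data.frame(estimator = name, beta_hat = NA_real_,
                        kappa1_hat = NA_real_, kappa2_hat = NA_real_,
                        converged = FALSE, kuiper_p = kp))
    k <- if (fit$method == "angular")
      c(fit$kappa, fit$beta[1] * fit$kappa) else fit$kappa[1:2]
    data.frame(estimator = name, beta_hat = unname(fit$beta[1]),
               kappa1_hat = unname(k[1]), kappa2_hat = unname(k[2]),
               converged = fit$converged, kuiper_p = kp)
  }
  rbind(row("angular", fa), row("consensus", fc), row("ssf", fs))
}

#' Kuiper uniformity p-values for pooled angle sets
#'
#' @param angle_sets a list of numeric angle vectors (e.g. the observed
#'   step angles of each replicate of a scenario).
#' @return list with \code{p_values} (one per set) and \code{median_p}.
#' @export
uniformity_check <- function(angle_sets) {
  if (is.numeric(angle_sets)) angle_sets <- list(angle_sets)
  p <- vapply(angle_sets, function(a) kuiper_test(a)$p_value, numeric(1))
  list(p_values = p, median_p = stats::median(p))
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("Monte Carlo study: %d replicates per scenario, J = %d (seed %d)\n",
              x$reps, x$J, x$master_seed))
  print(x$summary, digits = 4)
  if (x$n_failed > 0)
    cat(x$n_failed, "replicate fits failed or hit a bound (excluded)\n")
  invisible(x)
}

#' Write replicate-level and summary tables of a Monte Carlo run
#'
#' Tab-separated files with a '#' comment header embedding the run's full
#' parameterization and seed.
#'
#' @param study an \code{mc_summary}.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# reps=%d J=%d master_seed=%d", study$reps, study$J,
                 study$master_seed)
  f1 <- file.path(dir, "replicates.tsv")
  f2 <- file.path(dir, "summary.tsv")
  for (f in list(list(f1, study$replicates), list(f2, study$summary))) {
    con <- file(f[[1]], "w"); writeLines(hdr, con)
    utils::write.table(f[[2]], con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(c(f1, f2))
}
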