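# Monte-Carlo validation of the analytic machinery: simulates the
# data-generating process the delta-method formulas assume (Poisson count;
# design-effected survey proportion realized by beta-binomial clustering)
# and measures empirical standard errors and interval coverage.

#' Simulation design for Monte-Carlo validation
#'
#' Fixes the true state of a simulated multiplier study. The count is
#' Poisson with mean `mu_m = true_p * true_pse`; the survey proportion is
#' measured on `n` subjects grouped into clusters of `cluster_size`, with
#' between-cluster heterogeneity tuned so the sampling variance of the
#' pooled proportion is exactly `deff_target` times the binomial variance
#' (intraclass correlation rho = (deff_target - 1) / (cluster_size - 1)).
#' With `pop_n` finite (and `deff_target = 1`) the survey instead samples
#' without replacement from a synthetic roster of size `pop_n`, which
#' realizes the finite-population correction.
#'
#' @param true_pse True population size.
#' @param true_p True proportion in receipt of the service, in (0, 1).
#' @param n Survey sample size.
#' @param deff_target Design effect to realize, at least 1 and less than
#'   `cluster_size`.
#' @param cluster_size Subjects per simulated cluster, default 10. If it
#'   does not divide `n` the final cluster is truncated and the realized
#'   design effect recomputed (see the `realized_deff` field).
#' @param reps Number of Monte-Carlo replicates, at least 1000.
#' @param seed Integer random seed; every run is reproducible from it.
#' @param level Confidence level for the intervals under validation.
#' @param mu_m Poisson mean of the count; default `true_p * true_pse`.
#' @param pop_n `Inf` (default) or a finite roster size for the
#'   without-replacement mode.
#'
#' @return An object of class `sim_config`, including `rho` and
#'   `realized_deff` (equal to `deff_target` when `cluster_size` divides
#'   `n`).
#' @examples
#' sim_config(15000, 0.063, n = 1500, deff_target = 3, reps = 1000, seed = 1)
#' @export
sim_config <- function(true_pse, true_p, n, deff_target = 1,
                       cluster_size = 10, reps, seed, level = 0.95,
                       mu_m = true_p * true_pse, pop_n = Inf) {
  check_scalar(true_pse, "true_pse")
  if (true_pse <= 0) stop("'true_pse' must be positive", call. = FALSE)
  check_scalar(true_p, "true_p")
  if (true_p <= 0 || true_p >= 1) {
    stop("'true_p' must lie strictly in (0, 1), got ", true_p, call. = FALSE)
  }
  check_scalar(n, "n")
  if (n < 2 || n != round(n)) {
    stop("'n' must be an integer >= 2", call. = FALSE)
  }
  check_scalar(deff_target, "deff_target")
  if (deff_target < 1) {
    stop("'deff_target' must be >= 1, got ", deff_target, call. = FALSE)
  }
  check_scalar(cluster_size, "cluster_size")
  if (cluster_size < 1 || cluster_size != round(cluster_size)) {
    stop("'cluster_size' must be a positive integer", call. = FALSE)
  }
  rho <- if (deff_target == 1) 0 else
    (deff_target - 1) / (cluster_size - 1)
  if (rho < 0 || rho >= 1) {
    stop("implied intraclass correlation (deff_target - 1)/(cluster_size - 1)",
         " = ", signif(rho, 4), " must lie in [0, 1); increase cluster_size",
         call. = FALSE)
  }
  check_scalar(reps, "reps")
  if (reps < 1000) {
    stop("'reps' must be at least 1000 for coverage claims, got ", reps,
         call. = FALSE)
  }
  check_scalar(seed, "seed")
  check_scalar(level, "level")
  if (level <= 0 || level >= 1) {
    stop("'level' must lie in (0, 1)", call. = FALSE)
  }
  check_scalar(mu_m, "mu_m")
  if (mu_m <= 0) stop("'mu_m' must be positive", call. = FALSE)
  check_scalar(pop_n, "pop_n", allow_inf = TRUE)
  if (is.finite(pop_n)) {
    if (deff_target != 1) {
      stop("the finite-population mode simulates simple random sampling ",
           "without replacement; it requires deff_target = 1", call. = FALSE)
    }
    if (n > pop_n) {
      stop("'n' exceeds 'pop_n'", call. = FALSE)
    }
  }
  sizes <- cluster_sizes(n, cluster_size)
  realized <- sum(sizes * (1 + (sizes - 1) * rho)) / n
  structure(list(true_pse = true_pse, true_p = true_p, mu_m = mu_m,
                 n = as.integer(n), deff_target = deff_target,
                 cluster_size = as.integer(cluster_size), rho = rho,
                 realized_deff = realized,
                 reps = as.integer(reps), seed = as.integer(seed),
                 level = level, pop_n = pop_n),
            class = "sim_config")
}

cluster_sizes <- function(n, cluster_size) {
  full <- n %/% cluster_size
  rem <- n %% cluster_size
  c(rep(cluster_size, full), if (rem > 0) rem)
}

#' Draw Poisson service counts
#'
#' Simulates the count component: M ~ Poisson(mu_m), so over many draws the
#' sample mean and variance both converge to `mu_m`. Uses R's global random
#' number generator; seed it (or use [run_validation()]) for
#' reproducibility.
#'
#' @param mu_m Positive Poisson mean.
#' @param reps Number of draws.
#' @return Integer vector of length `reps`.
#' @export
draw_count <- function(mu_m, reps = 1) {
  check_scalar(mu_m, "mu_m")
  if (mu_m <= 0) stop("'mu_m' must be positive, got ", mu_m, call. = FALSE)
  stats::rpois(reps, mu_m)
}

#' Draw design-effected survey proportions
#'
#' Simulates the survey proportion under the config's design. With
#' `deff_target = 1` each draw is a plain binomial sample proportion. With
#' `deff_target > 1`, each cluster's success probability is drawn from a
#' beta distribution with mean `true_p` and variance
#' `rho * true_p * (1 - true_p)`, members of the cluster are Bernoulli
#' given that probability, and the pooled sample proportion is returned;
#' its sampling variance is then `deff_target * p(1-p) / n`, the design
#' effect by definition. In the finite-population mode the sample is drawn
#' without replacement from a roster of `pop_n` individuals of whom
#' `round(true_p * pop_n)` are service users (hypergeometric), realizing
#' the finite-population correction factor.
#'
#' @param config A [sim_config()].
#' @param reps Number of independent survey replicates to draw.
#' @return Numeric vector of sample proportions in `[0, 1]`.
#' @export
draw_proportion <- function(config, reps = 1) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$true_p
  n <- config$n
  if (is.finite(config$pop_n)) {
    users <- round(p * config$pop_n)
    return(stats::rhyper(reps, users, config$pop_n - users, n) / n)
  }
  if (config$rho == 0) {
    return(stats::rbinom(reps, n, p) / n)
  }
  sizes <- cluster_sizes(n, config$cluster_size)
  nclus <- length(sizes)
  # beta with mean p and variance rho*p*(1-p): shape total s = 1/rho - 1
  s <- 1 / config$rho - 1
  pj <- stats::rbeta(reps * nclus, p * s, (1 - p) * s)
  x <- stats::rbinom(reps * nclus, size = rep.int(sizes, reps), prob = pj)
  colSums(matrix(x, nrow = nclus)) / n
}

#' Monte-Carlo validation of the delta-method intervals
#'
#' Runs the full simulation: per replicate, draws a Poisson count and a
#' design-effected survey proportion, forms the multiplier estimate and its
#' analytic confidence interval exactly as an analyst would (plug-in: the
#' observed count and proportion stand in for their true values, the
#' config's design effect and population size supply the se(P) formula),
#' and measures how the analytic machinery performs: the empirical standard
#' errors of the proportion and of the estimate, and the empirical coverage
#' of the nominal interval.
#'
#' Replicates with a zero sample proportion leave the estimate undefined;
#' they are excluded and counted. If more than 1% of replicates are zero the
#' run aborts: the proportion is too small for the analytic method to be
#' trusted there.
#'
#' @param config A [sim_config()].
#'
#' @return An object of class `sim_result`: a list with `empirical_se_p`,
#'   `empirical_sd_pse`, `mean_pse`, `coverage`, `mc_se_of_coverage`,
#'   `reps_used`, `excluded_zero_p`, the analytic counterparts
#'   `analytic_se_p` and `analytic_sd_pse` evaluated at the true values,
#'   Monte-Carlo standard errors `mc_se_sd_p` and `mc_se_sd_pse` for the
#'   empirical standard deviations, and the `config`. Bitwise reproducible
#'   from `config$seed`.
#' @examples
#' cfg <- sim_config(15000, 0.2, n = 1000, reps = 2000, seed = 42)
#' run_validation(cfg)
#' @export
run_validation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- draw_count(config$mu_m, config$reps)
  phat <- draw_proportion(config, config$reps)

  zero <- phat == 0
  n_zero <- sum(zero)
  if (n_zero > 0.01 * config$reps) {
    stop("aborting validation: ", n_zero, " of ", config$reps,
         " replicates produced a zero sample proportion (> 1%). ",
         "The analytic method is unreliable at such a small proportion.",
         call. = FALSE)
  }
  m <- m[!zero]
  phat <- phat[!zero]
  reps_used <- length(phat)

  est <- m / phat
  # plug-in analytic interval, as a field analyst would compute it
  se_hat <- vapply(phat, function(ph)
    se_p_achieved(ph, config$n, config$deff_target, config$pop_n),
    numeric(1))
  v <- m / phat^2 + m^2 * se_hat^2 / phat^4
  z <- stats::qnorm(1 - (1 - config$level) / 2)
  half <- z * sqrt(v)
  covered <- (est - half) <= config$true_pse & config$true_pse <= (est + half)
  coverage <- mean(covered)

  analytic_se_p <- se_p_achieved(config$true_p, config$n,
                                 config$deff_target, config$pop_n)
  analytic_sd_pse <- sqrt(var_pse(count_estimate(config$mu_m, config$mu_m),
                                  config$true_p, analytic_se_p)$variance)

  structure(list(
    empirical_se_p = stats::sd(phat),
    empirical_sd_pse = stats::sd(est),
    mean_pse = mean(est),
    coverage = coverage,
    mc_se_of_coverage = sqrt(coverage * (1 - coverage) / reps_used),
    reps_used = reps_used,
    excluded_zero_p = n_zero,
    analytic_se_p = analytic_se_p,
    analytic_sd_pse = analytic_sd_pse,
    mc_se_sd_p = mc_se_of_sd(phat),
    mc_se_sd_pse = mc_se_of_sd(est),
    config = config
  ), class = "sim_result")
}

# MC standard error of a sample standard deviation, from the fourth
# central moment (no normality assumption): se(var) = sqrt((m4 - s^4)/r),
# se(sd) = se(var) / (2 sd).
mc_se_of_sd <- function(x) {
  r <- length(x)
  s2 <- stats::var(x)
  m4 <- mean((x - mean(x))^4)
  sqrt(max(m4 - s2^2, 0) / r) / (2 * sqrt(s2))
}

#' @export
print.sim_result <- function(x, ...) {
  cfg <- x$config
  cat("Monte-Carlo validation (", format(cfg$reps), " reps, seed ",
      cfg$seed, ")\n", sep = "")
  cat(sprintf("  design: p = %s, n = %d, DEFF = %s, N = %s\n",
              format(cfg$true_p), cfg$n, format(cfg$deff_target),
              format(cfg$pop_n)))
  cat(sprintf("  se(P):  analytic %s, empirical %s\n",
              format(signif(x$analytic_se_p, 4)),
              format(signif(x$empirical_se_p, 4))))
  cat(sprintf("  sd(PSE): analytic %s, empirical %s (ratio %.3f)\n",
              format(signif(x$analytic_sd_pse, 4)),
              format(signif(x$empirical_sd_pse, 4)),
              x$empirical_sd_pse / x$analytic_sd_pse))
  cat(sprintf("  coverage of the %g%% CI: %.4f (MC se %.4f)\n",
              100 * cfg$level, x$coverage, x$mc_se_of_coverage))
  if (x$excluded_zero_p > 0) {
    cat(sprintf("  %d replicate(s) with zero sample proportion excluded\n",
                x$excluded_zero_p))
  }
  invisible(x)
}

#' Write a simulation report CSV
#'
#' One row per validation run, columns `scenario, reps, empirical_se_p,
#' analytic_se_p, empirical_sd_pse, analytic_sd_pse, coverage, mc_se,
#' excluded_zero_p`.
#'
#' @param results A `sim_result` or a list of them.
#' @param path Output CSV path.
#' @param scenarios Optional character vector of scenario names.
#' @return `path`, invisibly.
#' @export
write_sim_report <- function(results, path, scenarios = NULL) {
  if (inherits(results, "sim_result")) results <- list(results)
  if (is.null(scenarios)) {
    scenarios <- vapply(results, function(r)
      sprintf("p=%s n=%d deff=%s", format(r$config$true_p), r$config$n,
              format(r$config$deff_target)), character(1))
  }
  rows <- Map(function(r, sc) {
    data.frame(scenario = sc, reps = r$config$reps,
               empirical_se_p = r$empirical_se_p,
               analytic_se_p = r$analytic_se_p,
               empirical_sd_pse = r$empirical_sd_pse,
               analytic_sd_pse = r$analytic_sd_pse,
               coverage = r$coverage, mc_se = r$mc_se_of_coverage,
               excluded_zero_p = r$excluded_zero_p,
               stringsAsFactors = FALSE)
  }, results, scenarios)
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
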