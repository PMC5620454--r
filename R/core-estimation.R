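# Core multiplier-method estimation: point estimate M/P, delta-method
# variance, sample-size formulas with design effect and finite-population
# correction, and normal-approximation confidence intervals.

#' Multiplier count with its Poisson variance model
#'
#' Describes the count component `M` of a multiplier study: the number of
#' unique individuals on a service roster over a reference period (service
#' multiplier method) or the number of unique objects distributed
#' (unique-object multiplier method). Under the default model the count is
#' Poisson, so its mean and variance are both `mu_m`.
#'
#' @param m Observed count, a single non-negative number.
#' @param mu_m Mean of the assumed Poisson law; defaults to `m`.
#' @param var_m Variance of the count; defaults to `mu_m` (Poisson).
#'   Supply a different value to explore over/under-dispersed counts.
#'
#' @return An object of class `count_estimate` with fields `m`, `mu_m`,
#'   `var_m`.
#' @examples
#' count_estimate(952)
#' count_estimate(952, var_m = 2 * 952) # overdispersed roster
#' @export
count_estimate <- function(m, mu_m = m, var_m = mu_m) {
  check_scalar(m, "m")
  check_scalar(mu_m, "mu_m")
  check_scalar(var_m, "var_m")
  if (m < 0) {
    stop("count 'm' must be non-negative, got ", m, call. = FALSE)
  }
  if (mu_m < 0) {
    stop("'mu_m' must be non-negative, got ", mu_m, call. = FALSE)
  }
  if (var_m < 0) {
    stop("'var_m' must be non-negative, got ", var_m, call. = FALSE)
  }
  structure(list(m = m, mu_m = mu_m, var_m = var_m),
            class = "count_estimate")
}

as_count_estimate <- function(x) {
  if (inherits(x, "count_estimate")) return(x)
  count_estimate(x)
}

#' Survey design specification for the proportion P
#'
#' Bundles the anticipated (or observed) proportion `p` reporting receipt of
#' the service or object with the RDS survey design used to measure it: the
#' sample size `n`, the design effect `deff`, and the assumed target
#' population size `pop_n` used for the finite-population correction. The
#' standard error of `p` is derived with [se_p_achieved()] unless supplied
#' directly through `se_p`.
#'
#' @param p Proportion in (0, 1].
#' @param n RDS survey sample size (positive integer). May be omitted when
#'   `se_p` is given directly.
#' @param deff Design effect, at least 1. RDS surveys typically have design
#'   effects between 2 and 4.
#' @param pop_n Assumed target population size `N`, a positive number or
#'   `Inf` (no finite-population correction).
#' @param se_p Standard error of `p`. Derived from `(p, n, deff, pop_n)`
#'   when `NULL`.
#'
#' @return An object of class `proportion_spec` with fields `p`, `n`,
#'   `deff`, `pop_n`, `se_p`.
#' @examples
#' proportion_spec(0.063, n = 1500, deff = 3, pop_n = 15000)
#' proportion_spec(0.05, se_p = 0.01)
#' @export
proportion_spec <- function(p, n = NULL, deff = 1, pop_n = Inf, se_p = NULL) {
  check_scalar(p, "p")
  if (p <= 0 || p > 1) {
    stop("proportion 'p' must lie in (0, 1], got ", p, call. = FALSE)
  }
  check_scalar(deff, "deff")
  if (deff < 1) {
    stop("design effect 'deff' must be >= 1, got ", deff, call. = FALSE)
  }
  check_scalar(pop_n, "pop_n", allow_inf = TRUE)
  if (pop_n <= 0) {
    stop("'pop_n' must be positive, got ", pop_n, call. = FALSE)
  }
  if (is.null(se_p)) {
    if (is.null(n)) {
      stop("supply either 'se_p' directly or a sample size 'n' to derive it",
           call. = FALSE)
    }
    se_p <- se_p_achieved(p, n, deff, pop_n)
  } else {
    check_scalar(se_p, "se_p")
    if (se_p < 0 || se_p >= 1) {
      stop("'se_p' must lie in [0, 1), got ", se_p, call. = FALSE)
    }
  }
  if (!is.null(n)) {
    check_scalar(n, "n")
    if (n < 1 || n != round(n)) {
      stop("sample size 'n' must be a positive integer, got ", n,
           call. = FALSE)
    }
    if (is.finite(pop_n) && n > pop_n) {
      stop("sample size n = ", n, " exceeds population size N = ", pop_n,
           call. = FALSE)
    }
  }
  structure(list(p = p, n = n, deff = deff, pop_n = pop_n, se_p = se_p),
            class = "proportion_spec")
}

#' Multiplier point estimate of population size
#'
#' The multiplier estimate divides the count of service users (or objects
#' distributed) by the proportion of a representative survey reporting
#' receipt: PSE = M / P.
#'
#' @param count A [count_estimate()] object, or a bare non-negative count.
#' @param p Proportion in (0, 1].
#'
#' @return The population size estimate M / P. Since `p <= 1`, the estimate
#'   is never below the count itself.
#' @examples
#' estimate_pse(750, 0.05)  # 15000
#' estimate_pse(6000, 0.4)  # 15000
#' @export
estimate_pse <- function(count, p) {
  count <- as_count_estimate(count)
  check_scalar(p, "p")
  if (p <= 0 || p > 1) {
    stop("proportion 'p' must lie in (0, 1], got ", p, call. = FALSE)
  }
  count$m / p
}

#' Simple-random-sample size for a proportion, inflated by a design effect
#'
#' Sample size needed to estimate a proportion `p` with standard error
#' `target_se` under simple random sampling, multiplied by the design effect
#' of the actual (RDS) design: n = ceiling(deff * p * (1 - p) / target_se^2).
#'
#' @param p Anticipated proportion, strictly inside (0, 1); the boundary
#'   values carry no binomial sampling variance and are rejected.
#' @param target_se Desired standard error of the estimated proportion.
#' @param deff Design effect, at least 1.
#'
#' @return Required sample size as an integer (ceiling of the real-valued
#'   solution).
#' @examples
#' required_n_srs(0.5, 0.05)            # 100
#' required_n_srs(0.5, 0.05, deff = 4)  # 400
#' @seealso [fpc_adjust_n()] to shrink the result for a finite population.
#' @export
required_n_srs <- function(p, target_se, deff = 1) {
  check_scalar(p, "p")
  if (p <= 0 || p >= 1) {
    stop("sample-size formula needs 0 < p < 1, got p = ", p, call. = FALSE)
  }
  check_scalar(target_se, "target_se")
  if (target_se <= 0) {
    stop("'target_se' must be positive, got ", target_se, call. = FALSE)
  }
  check_scalar(deff, "deff")
  if (deff < 1) {
    stop("design effect 'deff' must be >= 1, got ", deff, call. = FALSE)
  }
  as.integer(ceiling(deff * p * (1 - p) / target_se^2))
}

#' Finite-population correction of a required sample size
#'
#' Adjusts a sample size computed for an infinite population to a finite
#' target population of size `N`: n_adj = n0 / (1 + (n0 - 1) / N). The
#' adjusted size never exceeds `n0` or `N`, and tends to `n0` as N grows.
#' The result is kept real-valued; round up at the final planning step.
#'
#' @param n0 Unadjusted sample size (positive).
#' @param pop_n Population size `N`, positive or `Inf`.
#'
#' @return Adjusted sample size (real-valued).
#' @examples
#' fpc_adjust_n(100, Inf)   # 100
#' fpc_adjust_n(100, 100)   # 50.25
#' @export
fpc_adjust_n <- function(n0, pop_n) {
  check_scalar(n0, "n0")
  if (n0 <= 0) {
    stop("'n0' must be positive, got ", n0, call. = FALSE)
  }
  check_scalar(pop_n, "pop_n", allow_inf = TRUE)
  if (pop_n <= 0) {
    stop("'pop_n' must be positive, got ", pop_n, call. = FALSE)
  }
  if (is.infinite(pop_n)) return(n0)
  n0 / (1 + (n0 - 1) / pop_n)
}

#' Standard error of the survey proportion under the design
#'
#' Standard error of the estimated proportion for an RDS survey of size `n`
#' with design effect `deff`, corrected for a finite target population of
#' size `N`:
#' se(P) = sqrt(deff * p * (1 - p) / n) * sqrt((N - n) / (N - 1)).
#' With `pop_n = Inf` the finite-population factor is 1. The correction can
#' only reduce the standard error; at a census (`n == N`) it is exactly 0.
#'
#' @param p Proportion in (0, 1].
#' @param n Survey sample size.
#' @param deff Design effect, at least 1.
#' @param pop_n Population size `N`, positive or `Inf`.
#'
#' @return Standard error of the proportion, a non-negative number.
#' @examples
#' se_p_achieved(0.5, 100)                       # 0.05
#' se_p_achieved(0.063, 1500, deff = 3, pop_n = 15000)
#' @export
se_p_achieved <- function(p, n, deff = 1, pop_n = Inf) {
  if (inherits(p, "proportion_spec")) {
    spec <- p
    return(se_p_achieved(spec$p, spec$n, spec$deff, spec$pop_n))
  }
  check_scalar(p, "p")
  if (p <= 0 || p > 1) {
    stop("proportion 'p' must lie in (0, 1], got ", p, call. = FALSE)
  }
  check_scalar(n, "n")
  if (n < 1) {
    stop("sample size 'n' must be positive, got ", n, call. = FALSE)
  }
  check_scalar(deff, "deff")
  if (deff < 1) {
    stop("design effect 'deff' must be >= 1, got ", deff, call. = FALSE)
  }
  check_scalar(pop_n, "pop_n", allow_inf = TRUE)
  se0 <- sqrt(deff * p * (1 - p) / n)
  if (is.infinite(pop_n)) return(se0)
  if (n > pop_n) {
    stop("sample size n = ", n, " exceeds population size N = ", pop_n,
         call. = FALSE)
  }
  if (n < 2) {
    stop("finite-population correction needs n >= 2, got n = ", n,
         call. = FALSE)
  }
  se0 * sqrt((pop_n - n) / (pop_n - 1))
}

#' Delta-method variance of the multiplier estimate
#'
#' First-order delta-method variance of the ratio M / P, treating the count
#' and the survey proportion as independent:
#' var(M/P) = var(M) / p^2 + mu_M^2 * se(P)^2 / p^4.
#' The first term carries the Poisson uncertainty in the count, the second
#' the sampling uncertainty of the survey proportion. The p^4 in the second
#' term is why uncertainty blows up when P is small.
#'
#' @param count A [count_estimate()] object or a bare count.
#' @param p Proportion in (0, 1].
#' @param se_p Standard error of the proportion (e.g. from
#'   [se_p_achieved()]).
#'
#' @return A list with components `var_from_m`, `var_from_p`, and their sum
#'   `variance`.
#' @examples
#' var_pse(100, 1, 0)  # only the Poisson term: variance 100
#' var_pse(952, 0.063, se_p_achieved(0.063, 1500, 3, 15000))
#' @export
var_pse <- function(count, p, se_p) {
  count <- as_count_estimate(count)
  check_scalar(p, "p")
  if (p <= 0 || p > 1) {
    stop("proportion 'p' must lie in (0, 1], got ", p, call. = FALSE)
  }
  check_scalar(se_p, "se_p")
  if (se_p < 0) {
    stop("'se_p' must be non-negative, got ", se_p, call. = FALSE)
  }
  var_from_m <- count$var_m / p^2
  var_from_p <- count$mu_m^2 * se_p^2 / p^4
  list(var_from_m = var_from_m,
       var_from_p = var_from_p,
       variance = var_from_m + var_from_p)
}

#' Normal-approximation confidence interval for the estimate
#'
#' Attaches a symmetric normal-approximation interval,
#' estimate +/- z * sqrt(variance), to a partially built result. By default
#' the lower bound is reported as computed, even when negative; with
#' `truncate_lower = TRUE` it is floored at the count `m`, below which the
#' estimate cannot logically fall when `p <= 1`.
#'
#' @param result A list containing at least `estimate` and `variance`
#'   (e.g. the output of [pse()] or a hand-built list with `m`).
#' @param level Confidence level in (0, 1); default 0.95 uses
#'   z = `qnorm(0.975)` = 1.96.
#' @param truncate_lower Floor the lower bound at the count `m`
#'   (requires `result$m`).
#'
#' @return `result` with fields `level`, `z`, `ci_lower`, `ci_upper`,
#'   `ci_width` added or replaced.
#' @export
ci_pse <- function(result, level = 0.95, truncate_lower = FALSE) {
  if (is.null(result$variance)) {
    stop("no variance in result: compute var_pse() before ci_pse()",
         call. = FALSE)
  }
  check_scalar(level, "level")
  if (level <= 0 || level >= 1) {
    stop("'level' must lie in (0, 1), got ", level, call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(result$variance)
  lo <- result$estimate - half
  hi <- result$estimate + half
  if (truncate_lower) {
    if (is.null(result$m)) {
      stop("truncate_lower = TRUE needs the count 'm' in the result",
           call. = FALSE)
    }
    lo <- max(lo, result$m)
  }
  result$level <- level
  result$z <- z
  result$ci_lower <- lo
  result$ci_upper <- hi
  result$ci_width <- hi - lo
  result
}

#' Full multiplier population size estimate with variance and interval
#'
#' Convenience wrapper combining [estimate_pse()], [se_p_achieved()],
#' [var_pse()] and [ci_pse()]: point estimate M/P, delta-method variance
#' split into its count and proportion components, and the
#' normal-approximation confidence interval.
#'
#' @param m Count of unique service attenders / objects distributed, or a
#'   [count_estimate()] object.
#' @param p Proportion of the survey reporting receipt, in (0, 1].
#' @param se_p Standard error of `p`; if `NULL`, derived from
#'   `(p, n, deff, pop_n)`.
#' @param n,deff,pop_n Survey design used to derive `se_p` when it is not
#'   supplied directly; see [se_p_achieved()].
#' @param level Confidence level, default 0.95.
#' @param truncate_lower Floor the lower confidence bound at `m`.
#'
#' @return An object of class `pse_result`: a list with `m`, `p`, `se_p`,
#'   `estimate`, `var_from_m`, `var_from_p`, `variance`, `level`, `z`,
#'   `ci_lower`, `ci_upper`, `ci_width`.
#' @examples
#' pse(952, 0.063, n = 1500, deff = 3, pop_n = 15000)
#' @export
pse <- function(m, p, se_p = NULL, n = NULL, deff = 1, pop_n = Inf,
                level = 0.95, truncate_lower = FALSE) {
  count <- as_count_estimate(m)
  if (is.null(se_p)) {
    if (is.null(n)) {
      stop("supply either 'se_p' or a sample size 'n' to derive it",
           call. = FALSE)
    }
    se_p <- se_p_achieved(p, n, deff, pop_n)
  }
  est <- estimate_pse(count, p)
  v <- var_pse(count, p, se_p)
  result <- list(m = count$m, mu_m = count$mu_m, p = p, se_p = se_p,
                 n = n, deff = deff, pop_n = pop_n,
                 estimate = est,
                 var_from_m = v$var_from_m,
                 var_from_p = v$var_from_p,
                 variance = v$variance)
  result <- ci_pse(result, level = level, truncate_lower = truncate_lower)
  class(result) <- "pse_result"
  result
}

#' @export
print.pse_result <- function(x, digits = 1, ...) {
  cat("Multiplier-method population size estimate\n")
  cat(sprintf("  count M = %s, proportion P = %s (se = %s)\n",
              format(x$m), format(x$p), format(signif(x$se_p, 4))))
  cat(sprintf("  PSE = M/P = %s\n", format(round(x$estimate, digits))))
  cat(sprintf("  variance = %s (from M: %s, from P: %s)\n",
              format(signif(x$variance, 4)),
              format(signif(x$var_from_m, 4)),
              format(signif(x$var_from_p, 4))))
  cat(sprintf("  %g%% CI: [%s, %s]  width %s\n",
              100 * x$level,
              format(round(x$ci_lower, digits)),
              format(round(x$ci_upper, digits)),
              format(round(x$ci_width, digits))))
  invisible(x)
}

# single finite (or optionally infinite) numeric scalar
check_scalar <- function(x, name, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) ||
      (!allow_inf && !is.finite(x))) {
    stop("'", name, "' must be a single finite number", call. = FALSE)
  }
  invisible(x)
}
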