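# Scenario planning: reference-period tables, CI-width-versus-sample-size
# curves over grids of (p, n, deff), and the plausible-population-range
# helper built from census and prevalence figures.

#' Reference-period service counts
#'
#' Validates a table of unique-attender counts by reference period. Counts
#' must be non-decreasing with the length of the period: unique attenders
#' accumulate as the roster window widens.
#'
#' @param label Character vector of period labels (e.g. "6 months"), unique.
#' @param months Positive period lengths in months.
#' @param m Non-negative integer counts of unique attenders.
#'
#' @return A `data.frame` of class `period_counts` with columns `label`,
#'   `months`, `m`, ordered by `months`.
#' @examples
#' period_counts(c("1 month", "6 months"), c(1, 6), c(85, 952))
#' @export
period_counts <- function(label, months, m) {
  if (length(label) == 0) {
    stop("at least one reference period is required", call. = FALSE)
  }
  if (length(months) != length(label) || length(m) != length(label)) {
    stop("'label', 'months' and 'm' must have equal length", call. = FALSE)
  }
  label <- as.character(label)
  if (anyDuplicated(label)) {
    stop("period labels must be unique", call. = FALSE)
  }
  if (any(!is.finite(months)) || any(months <= 0)) {
    stop("'months' must be positive", call. = FALSE)
  }
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m))) {
    stop("counts 'm' must be non-negative integers", call. = FALSE)
  }
  ord <- order(months)
  if (is.unsorted(m[ord])) {
    stop("unique-attender counts must be non-decreasing with period length",
         call. = FALSE)
  }
  out <- data.frame(label = label[ord], months = months[ord], m = m[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("period_counts", "data.frame")
  out
}

#' Read reference-period counts from CSV
#'
#' Expects a comma-delimited UTF-8 file with header `label,months,count`.
#'
#' @param path Path to the CSV file.
#' @return A [period_counts()] table.
#' @export
read_period_counts <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("label", "months", "count")
  if (!all(need %in% names(raw))) {
    stop("period-count CSV must have columns 'label,months,count'; found: ",
         paste(names(raw), collapse = ","), call. = FALSE)
  }
  raw$months <- suppressWarnings(as.numeric(raw$months))
  raw$count <- suppressWarnings(as.numeric(raw$count))
  bad <- which(!is.finite(raw$months) | !is.finite(raw$count))
  if (length(bad)) {
    stop("malformed period-count CSV at data line ", bad[1],
         " of ", path, call. = FALSE)
  }
  period_counts(raw$label, raw$months, raw$count)
}

#' Anticipated proportions implied by reference-period counts
#'
#' For each reference period, the anticipated survey proportion is the count
#' divided by the assumed population size: p = m / assumed_pse. Both the
#' exact and display-rounded proportions are returned.
#'
#' @param counts A [period_counts()] table.
#' @param assumed_pse Assumed population size; must exceed every count.
#' @param decimals Decimal places for the rounded display column, default 3.
#'
#' @return A `data.frame` with columns `label`, `months`, `m`, `p` (exact)
#'   and `p_rounded`.
#' @examples
#' tab <- period_counts(c("1 month", "6 months"), c(1, 6), c(85, 952))
#' proportions_from_periods(tab, assumed_pse = 15000)
#' @export
proportions_from_periods <- function(counts, assumed_pse, decimals = 3) {
  stopifnot(inherits(counts, "period_counts"))
  check_scalar(assumed_pse, "assumed_pse")
  if (assumed_pse <= 0) {
    stop("'assumed_pse' must be positive", call. = FALSE)
  }
  if (any(counts$m >= assumed_pse)) {
    bad <- counts$label[counts$m >= assumed_pse][1]
    stop("count for period '", bad, "' is >= assumed_pse = ", assumed_pse,
         ": implied proportion would be >= 1", call. = FALSE)
  }
  if (any(counts$m == 0)) {
    warning("zero count for period(s) ",
            paste(sQuote(counts$label[counts$m == 0]), collapse = ", "),
            ": implied proportion 0 is unusable for planning")
  }
  p <- counts$m / assumed_pse
  data.frame(label = counts$label, months = counts$months, m = counts$m,
             p = p, p_rounded = round(p, decimals),
             stringsAsFactors = FALSE)
}

#' Planning grid for CI-width curves
#'
#' Defines the cross-product of scenarios to evaluate: candidate survey
#' sample sizes, anticipated proportions (given directly or derived from
#' reference-period counts), and design effects, all at a fixed assumed
#' population size. For each scenario the count is fixed so that
#' m / p = assumed_pse, and the finite-population correction uses the
#' assumed population itself (N = assumed_pse).
#'
#' @param assumed_pse Fixed assumed population size (e.g. 15000).
#' @param n_values Candidate RDS sample sizes, positive integers.
#' @param p_values Anticipated proportions in (0, 1); give either this or
#'   `periods`.
#' @param periods A [period_counts()] table from which proportions are
#'   derived via [proportions_from_periods()].
#' @param deff_values Design effects, each at least 1; default `c(2, 3, 4)`,
#'   the range reported for most RDS surveys.
#' @param level Confidence level for interval widths, default 0.95.
#'
#' @return An object of class `scenario_grid`.
#' @export
scenario_grid <- function(assumed_pse, n_values, p_values = NULL,
                          periods = NULL, deff_values = c(2, 3, 4),
                          level = 0.95) {
  check_scalar(assumed_pse, "assumed_pse")
  if (assumed_pse <= 0) stop("'assumed_pse' must be positive", call. = FALSE)
  if (is.null(p_values) == is.null(periods)) {
    stop("give exactly one of 'p_values' or 'periods'", call. = FALSE)
  }
  labels <- NULL
  if (!is.null(periods)) {
    tab <- proportions_from_periods(periods, assumed_pse)
    p_values <- tab$p
    labels <- tab$label
  }
  if (length(p_values) == 0 || any(p_values <= 0) || any(p_values >= 1)) {
    stop("'p_values' must be a non-empty vector with 0 < p < 1",
         call. = FALSE)
  }
  if (length(n_values) == 0 || any(n_values < 1) ||
      any(n_values != round(n_values))) {
    stop("'n_values' must be positive integers", call. = FALSE)
  }
  if (any(n_values > assumed_pse)) {
    stop("sample size ", max(n_values), " exceeds the assumed population ",
         assumed_pse, call. = FALSE)
  }
  if (length(deff_values) == 0 || any(deff_values < 1)) {
    stop("'deff_values' must all be >= 1", call. = FALSE)
  }
  check_scalar(level, "level")
  if (level <= 0 || level >= 1) {
    stop("'level' must lie in (0, 1)", call. = FALSE)
  }
  structure(list(assumed_pse = assumed_pse,
                 p_values = p_values, labels = labels,
                 n_values = sort(unique(n_values)),
                 deff_values = sort(unique(deff_values)),
                 level = level),
            class = "scenario_grid")
}

#' Confidence-interval width curves over a planning grid
#'
#' For every (deff, p, n) combination in the grid, fixes the count at
#' m = p * assumed_pse (so the point estimate is always the assumed
#' population size), derives se(P) with the finite-population correction at
#' N = assumed_pse, combines the variance components by the delta method,
#' and records the confidence interval and its width. Within any fixed
#' (p, deff) series the width strictly decreases with n; it increases with
#' deff and, at fixed PSE, decreases as p grows.
#'
#' @param grid A [scenario_grid()].
#'
#' @return A `data.frame` (class `curve_table`) with one row per
#'   combination, columns `deff`, `p`, `m`, `n`, `se_p`, `pse`, `ci_lower`,
#'   `ci_upper`, `ci_width` (plus `label` when the grid came from periods),
#'   ordered by (deff, p, n).
#' @examples
#' g <- scenario_grid(15000, n_values = c(500, 1500), p_values = c(0.05, 0.4),
#'                    deff_values = 3)
#' build_curves(g)
#' @export
build_curves <- function(grid) {
  stopifnot(inherits(grid, "scenario_grid"))
  cells <- expand.grid(n = grid$n_values, p_idx = seq_along(grid$p_values),
                       deff = grid$deff_values, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    n <- cells$n[i]
    p <- grid$p_values[cells$p_idx[i]]
    deff <- cells$deff[i]
    m <- p * grid$assumed_pse
    res <- tryCatch(
      pse(m, p, n = n, deff = deff, pop_n = grid$assumed_pse,
          level = grid$level),
      error = function(e) {
        stop("grid cell (p = ", p, ", n = ", n, ", deff = ", deff, "): ",
             conditionMessage(e), call. = FALSE)
      })
    data.frame(deff = deff, p = p, m = m, n = n, se_p = res$se_p,
               pse = res$estimate, ci_lower = res$ci_lower,
               ci_upper = res$ci_upper, ci_width = res$ci_width,
               label = if (is.null(grid$labels)) NA_character_ else
                 grid$labels[cells$p_idx[i]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$deff, out$p, out$n), , drop = FALSE]
  rownames(out) <- NULL
  if (is.null(grid$labels)) out$label <- NULL
  class(out) <- c("curve_table", "data.frame")
  out
}

#' Write / read a curve table as CSV
#'
#' The CSV has columns `deff,p,m,n,se_p,pse,ci_lower,ci_upper,ci_width`
#' (and `label` if present). Full double precision is preserved so a
#' write/read round trip reproduces the table exactly.
#'
#' @param curves A [build_curves()] table.
#' @param path Output path.
#' @return `write_curves` returns `path` invisibly; `read_curves` returns
#'   the `curve_table`.
#' @export
write_curves <- function(curves, path) {
  stopifnot(inherits(curves, "curve_table"))
  df <- as.data.frame(curves)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("deff", "p", "m", "n", "se_p", "pse",
            "ci_lower", "ci_upper", "ci_width")
  if (!all(need %in% names(out))) {
    stop("not a curve CSV: missing column(s) ",
         paste(setdiff(need, names(out)), collapse = ","), call. = FALSE)
  }
  out[need] <- lapply(out[need], as.double)
  class(out) <- c("curve_table", "data.frame")
  out
}

#' Plausible population range from census and prevalence figures
#'
#' Multiplies a prevalence range for the hidden population by the size of
#' the demographic group it refers to: denominator =
#' demo_fraction * total_pop; low/high = prevalence * denominator. Full
#' precision is kept until the final rounding to whole persons; the
#' unrounded endpoints are returned alongside.
#'
#' @param total_pop Total census population of the site.
#' @param demo_fraction Fraction of the population in the relevant
#'   demographic group (e.g. women aged 15-49), in (0, 1].
#' @param prev_low,prev_high Prevalence bounds in (0, 1), `prev_low <=
#'   prev_high`.
#'
#' @return A list with `low`, `high` (rounded to whole persons),
#'   `low_exact`, `high_exact`, and `denominator`.
#' @examples
#' plausible_population_range(2123132, 0.302, 0.007, 0.043)
#' @export
plausible_population_range <- function(total_pop, demo_fraction,
                                       prev_low, prev_high) {
  check_scalar(total_pop, "total_pop")
  if (total_pop <= 0) stop("'total_pop' must be positive", call. = FALSE)
  check_scalar(demo_fraction, "demo_fraction")
  if (demo_fraction <= 0 || demo_fraction > 1) {
    stop("'demo_fraction' must lie in (0, 1], got ", demo_fraction,
         call. = FALSE)
  }
  for (nm in c("prev_low", "prev_high")) {
    v <- get(nm)
    check_scalar(v, nm)
    if (v <= 0 || v > 1) {
      stop("'", nm, "' must lie in (0, 1], got ", v, call. = FALSE)
    }
  }
  if (prev_low > prev_high) {
    stop("'prev_low' must not exceed 'prev_high'", call. = FALSE)
  }
  denom <- demo_fraction * total_pop
  lo <- prev_low * denom
  hi <- prev_high * denom
  list(low = round(lo), high = round(hi),
       low_exact = lo, high_exact = hi,
       denominator = denom)
}

#' Planning report for a chosen scenario and its alternatives
#'
#' Builds the human-readable planning table: for the chosen (sample size,
#' reference period) scenario and every alternative in the grid, the
#' anticipated proportion, its standard error, the population size estimate
#' and its confidence interval. The chosen row is flagged.
#'
#' @param counts A [period_counts()] table.
#' @param grid A [scenario_grid()] built from those periods (its `labels`
#'   must cover `chosen_period`).
#' @param chosen_n Chosen sample size; must be one of the grid's `n_values`.
#' @param chosen_period Label of the chosen reference period.
#'
#' @return A `data.frame` like [build_curves()] output with an extra
#'   logical column `chosen`; the chosen row comes first.
#' @export
render_plan_report <- function(counts, grid, chosen_n, chosen_period) {
  stopifnot(inherits(counts, "period_counts"),
            inherits(grid, "scenario_grid"))
  if (is.null(grid$labels)) {
    stop("the grid must be built from reference periods ",
         "(scenario_grid(..., periods = ))", call. = FALSE)
  }
  if (!chosen_n %in% grid$n_values) {
    stop("chosen_n = ", chosen_n, " is not in the grid's n_values",
         call. = FALSE)
  }
  if (!chosen_period %in% grid$labels) {
    stop("unknown period label '", chosen_period, "'", call. = FALSE)
  }
  curves <- build_curves(grid)
  curves$chosen <- curves$n == chosen_n & curves$label == chosen_period
  ord <- order(!curves$chosen, curves$deff, curves$p, curves$n)
  out <- curves[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.curve_table <- function(x, ...) {
  cat("CI-width planning curves (", nrow(x), " scenarios)\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 4)
  print(df, row.names = FALSE)
  invisible(x)
}
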