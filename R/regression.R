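# Log-dose linear regression, slope test, and effective-dose estimation.

#' Fit the log-dose linear model
#'
#' Ordinary least squares of response (%MPE) on `x = log10(dose)`:
#' `y = a + b x + e`.  Returns the textbook summary quantities used by the
#' downstream effective-dose calculus:
#' residual sum of squares `Q = sum((y - a - b x)^2)`, residual variance
#' `s2 = Q / (N - 2)`, centred sum of squares `Sxx = sum((x - mean(x))^2)`
#' and slope variance `Vb = s2 / Sxx`.
#'
#' The log is always recomputed from the dose column; any log column in the
#' source data is ignored.
#'
#' @param table a [dose_effect_table()] (doses in nmol/site).
#' @return An object of class `dose_fit` with elements `b`, `a`, `Q`, `s2`,
#'   `Sxx`, `Vb`, `N`, `x_mean`, `y_mean`, `x_range`, `regimen`, `unit`.
#' @examples
#' fit <- fit_log_dose(load_fixture("sb_ipl"))
#' round(c(fit$b, fit$a), 1)  # 16.3, 20.9
#' @export
fit_log_dose <- function(table) {
  validate_dose_effect(table)
  if (nrow(table) < 4L)
    stop("insufficient data: need N >= 4", call. = FALSE)
  x <- log10(table$dose)
  y <- table$response
  if (length(unique(x)) < 2L)
    stop("degenerate design: a single dose level gives Sxx = 0", call. = FALSE)
  k <- ols_kernel(x, y)
  out <- c(k, list(x_range = range(x),
                   regimen = table$regimen[1L],
                   unit = table$unit[1L],
                   fitted = k$a + k$b * x,
                   residuals = y - (k$a + k$b * x)))
  class(out) <- "dose_fit"
  out
}

#' Test whether the fitted slope differs from zero
#'
#' `t_slope = b / sqrt(V(b))` against the two-sided critical value on
#' `N - 2` degrees of freedom (or the fixed large-sample 1.96 in
#' paper-compat mode).
#'
#' @param fit a `dose_fit`.
#' @param alpha two-sided significance level.
#' @param mode `"exact"` (Student critical value at N-2 df) or
#'   `"paper-compat"` (1.96).
#' @return An object of class `slope_test`: `t_slope`, `t_table`, `df`,
#'   `significant`.
#' @export
slope_test <- function(fit, alpha = 0.05, mode = c("exact", "paper-compat")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "dose_fit"))
  df <- fit$N - 2L
  t_table <- critical_t(alpha, df, mode)
  if (fit$Vb == 0) {
    warning("zero slope variance: perfect fit, reporting infinite t")
    t_slope <- if (fit$b == 0) 0 else Inf * sign(fit$b)
  } else {
    t_slope <- fit$b / sqrt(fit$Vb)
  }
  out <- list(t_slope = t_slope, t_table = t_table, df = df,
              significant = abs(t_slope) > t_table, alpha = alpha, mode = mode)
  class(out) <- "slope_test"
  out
}

#' Effective dose at a target effect, with delta-method variance
#'
#' Inverts the fitted line at effect `gamma`:
#' `log_ed = (gamma - a) / b`, `ed = 10^log_ed` (nmol/site).  The log-scale
#' variance is the delta-method expression
#' `V = s2 / b^2 * (1/N + (log_ed - mean(x))^2 / Sxx)`.
#'
#' A warning is issued when the ED lies outside the fitted dose range
#' (extrapolation).
#'
#' @param fit a `dose_fit`.
#' @param gamma target effect in %MPE (default 20).
#' @return An object of class `effective_dose`: `gamma`, `log_ed`, `ed`
#'   (nmol/site), `variance` (log10 scale), `df`, `extrapolated`.
#' @examples
#' ed <- effective_dose(fit_log_dose(load_fixture("sb_ipl")), gamma = 20)
#' round(ed$ed, 2)  # 0.88
#' @export
effective_dose <- function(fit, gamma = 20) {
  stopifnot(inherits(fit, "dose_fit"))
  check_scalar(gamma, "gamma")
  if (fit$b == 0)
    stop("undefined effective dose: slope is zero", call. = FALSE)
  log_ed <- (gamma - fit$a) / fit$b
  extrapolated <- log_ed < fit$x_range[1L] || log_ed > fit$x_range[2L]
  if (extrapolated)
    warning(sprintf("ED%g at log10(dose) = %.3f lies outside the fitted range [%.3f, %.3f]",
                    gamma, log_ed, fit$x_range[1L], fit$x_range[2L]))
  variance <- fit$s2 / fit$b^2 * (1 / fit$N + (log_ed - fit$x_mean)^2 / fit$Sxx)
  out <- list(gamma = gamma, log_ed = log_ed, ed = 10^log_ed,
              variance = variance, df = fit$N - 2L, unit = "nmol/site",
              extrapolated = extrapolated)
  class(out) <- "effective_dose"
  out
}

#' Tabular regression summary mirroring the classical report block
#'
#' One-row data frame with the running sums and derived statistics
#' (`sum_x`, `sum_y`, `N`, `x_mean`, `y_mean`, `sum_x2`, `sum_xy`, `b`, `a`,
#' `Vb`, `t_slope`, plus `log_ed`, `ed`, `V_ed` at the requested effect).
#'
#' @param fit a `dose_fit`.
#' @param gamma target effect for the ED columns.
#' @param alpha,mode passed to [slope_test()].
#' @return A one-row data.frame.
#' @export
regression_summary <- function(fit, gamma = 20, alpha = 0.05,
                               mode = c("exact", "paper-compat")) {
  mode <- match.arg(mode)
  st <- slope_test(fit, alpha, mode)
  ed <- suppressWarnings(effective_dose(fit, gamma))
  n <- fit$N
  data.frame(regimen = fit$regimen,
             N = n,
             sum_x = fit$x_mean * n,
             sum_y = fit$y_mean * n,
             x_mean = fit$x_mean, y_mean = fit$y_mean,
             sum_x2 = fit$Sxx + n * fit$x_mean^2,
             sum_xy = fit$b * fit$Sxx + n * fit$x_mean * fit$y_mean,
             b = fit$b, a = fit$a, Q = fit$Q, s2 = fit$s2,
             Sxx = fit$Sxx, Vb = fit$Vb,
             t_slope = st$t_slope, t_table = st$t_table,
             slope_significant = st$significant,
             gamma = gamma, log_ed = ed$log_ed, ed = ed$ed,
             V_ed = ed$variance,
             stringsAsFactors = FALSE)
}

#' @export
print.dose_fit <- function(x, ...) {
  cat(sprintf("Log-dose linear fit: %s (N = %d)\n", x$regimen, x$N))
  cat(sprintf("  y = %.4g + %.4g * log10(dose)   [%%MPE, dose in nmol/site]\n",
              x$a, x$b))
  cat(sprintf("  Q = %.4g, s2 = %.4g, Sxx = %.4g, V(b) = %.4g\n",
              x$Q, x$s2, x$Sxx, x$Vb))
  invisible(x)
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf("Slope test: t = %.3f vs t_table = %.3f (df = %d, %s mode): %s\n",
              x$t_slope, x$t_table, x$df, x$mode,
              if (x$significant) "slope differs from 0" else "not significant"))
  invisible(x)
}

#' @export
print.effective_dose <- function(x, ...) {
  cat(sprintf("ED%g = %.4g nmol/site (log10 = %.4g, V = %.4g log-scale)%s\n",
              x$gamma, x$ed, x$log_ed, x$variance,
              if (x$extrapolated) " [extrapolated]" else ""))
  invisible(x)
}
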