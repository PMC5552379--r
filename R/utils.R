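# Internal helpers shared across modules.

# Scalar validation: stop() with the argument name in the message.
check_scalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  if (finite && !is.finite(x))
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0 (got %g)", name, x), call. = FALSE)
  invisible(x)
}

#' Two-sided Student critical value, with a large-sample compatibility mode
#'
#' In `"paper-compat"` mode the critical value is fixed at 1.96 (the
#' large-sample two-sided 5% value historically used in tabulated summaries);
#' in `"exact"` mode it is `qt(1 - alpha/2, df)`.
#'
#' @param alpha two-sided significance level.
#' @param df degrees of freedom (ignored in paper-compat mode).
#' @param mode `"exact"` or `"paper-compat"`.
#' @return A single critical value.
#' @export
critical_t <- function(alpha = 0.05, df = Inf, mode = c("exact", "paper-compat")) {
  mode <- match.arg(mode)
  check_scalar(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (mode == "paper-compat") return(1.96)
  if (df <= 0) stop("`df` must be positive", call. = FALSE)
  stats::qt(1 - alpha / 2, df)
}

#' Convert doses between nmol/site and pmol/site
#'
#' @param x numeric dose(s).
#' @param from,to `"nmol/site"` or `"pmol/site"`.
#' @return Converted numeric vector.
#' @export
convert_dose <- function(x, from = "nmol/site", to = "nmol/site") {
  units <- c("nmol/site" = 1, "pmol/site" = 1e-3)
  if (!from %in% names(units) || !to %in% names(units))
    stop("units must be 'nmol/site' or 'pmol/site'", call. = FALSE)
  x * units[[from]] / units[[to]]
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Fast OLS of y on x returning the quantities the regression module exposes.
# Kept free of data-frame overhead because the simulators call it thousands
# of times in the Monte-Carlo tests.
ols_kernel <- function(x, y) {
  n <- length(x)
  xb <- mean(x)
  yb <- mean(y)
  sxx <- sum((x - xb)^2)
  b <- sum((x - xb) * (y - yb)) / sxx
  a <- yb - b * xb
  q <- sum((y - a - b * x)^2)
  s2 <- q / (n - 2)
  list(b = b, a = a, Q = q, s2 = s2, Sxx = sxx, Vb = s2 / sxx,
       N = n, x_mean = xb, y_mean = yb)
}
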