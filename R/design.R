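# Fixed-ratio mixture design: proportion factor and geometric dose ladder.

#' Variance-weighted proportion factor
#'
#' `f = V(B) / (V(A) + V(B))`, the weight that allocates the fixed-ratio
#' mixture between drug A and drug B from the log-scale variances of their
#' individual effective doses.  The less precisely estimated drug gets the
#' smaller share.  Symmetric: `f(u, v) + f(v, u) = 1` exactly.
#'
#' @param var_A,var_B positive log-scale ED variances of drugs A and B.
#' @return `f` in (0, 1).
#' @examples
#' proportion_factor(0.042, 0.025)  # ~0.37
#' @export
proportion_factor <- function(var_A, var_B) {
  check_scalar(var_A, "var_A", positive = TRUE)
  check_scalar(var_B, "var_B", positive = TRUE)
  var_B / (var_A + var_B)
}

ed_value <- function(x, name) {
  if (inherits(x, "effective_dose")) x$ed
  else check_scalar(x, name, positive = TRUE)
}
ed_variance <- function(x) {
  if (inherits(x, "effective_dose")) x$variance else NA_real_
}

#' Component doses of the fixed-ratio pair
#'
#' Splits the design point between the two drugs:
#' `a = f * ED_A`, `b = (1 - f) * ED_B`, total `c = a + b`.  The pair
#' (a, b) is the anchor of the combination dose ladder and the additive
#' point of the isobologram.
#'
#' @param ed_A,ed_B effective doses of drugs A and B (numbers in nmol/site,
#'   or [effective_dose()] objects).
#' @param f proportion factor in `[0, 1]` (boundary values give a
#'   single-drug "mixture").
#' @return An object of class `mixture_design`: `f`, `ed_A`, `ed_B`,
#'   `var_A`, `var_B` (NA when plain numbers were supplied), `component_a`,
#'   `component_b`, `total_c`.
#' @examples
#' component_doses(0.88, 0.025, f = 0.38)
#' @export
component_doses <- function(ed_A, ed_B, f) {
  A <- ed_value(ed_A, "ed_A"); B <- ed_value(ed_B, "ed_B")
  check_scalar(f, "f")
  if (f < 0 || f > 1) stop("`f` must lie in [0, 1]", call. = FALSE)
  out <- list(f = f, ed_A = A, ed_B = B,
              var_A = ed_variance(ed_A), var_B = ed_variance(ed_B),
              component_a = A * f, component_b = B * (1 - f))
  out$total_c <- out$component_a + out$component_b
  class(out) <- "mixture_design"
  out
}

#' Geometric dose ladder for the combination experiment
#'
#' Generates `n_pairs` dose pairs at the fixed component ratio of the design,
#' with totals forming a geometric series of ratio `step` anchored so that
#' the design point `(a, b)` is pair number `anchor` (the classical layout
#' puts it 4th of 6: three steps down, two steps up).
#'
#' @param design a [component_doses()] result.
#' @param n_pairs number of pairs (>= 2).
#' @param step geometric step between consecutive totals (> 1).
#' @param anchor index (1-based) of the pair that equals the design point;
#'   default is pair 4 (or the last pair when fewer are requested).
#' @return An object of class `dose_ladder`: a data.frame with columns
#'   `pair`, `dose_A`, `dose_B`, `total`, plus attributes `ratio` (step) and
#'   `component_ratio`.
#' @examples
#' d <- component_doses(0.88, 0.025, f = 0.38)
#' dose_ladder(d)$total
#' @export
dose_ladder <- function(design, n_pairs = 6L, step = 3, anchor = NULL) {
  stopifnot(inherits(design, "mixture_design"))
  if (n_pairs < 2L) stop("`n_pairs` must be >= 2", call. = FALSE)
  if (is.null(anchor)) anchor <- min(4L, n_pairs)
  check_scalar(step, "step")
  if (step <= 1) stop("`step` must be > 1", call. = FALSE)
  if (anchor < 1L || anchor > n_pairs)
    stop("`anchor` must index one of the pairs", call. = FALSE)
  k <- seq_len(n_pairs) - anchor
  out <- data.frame(pair = seq_len(n_pairs),
                    dose_A = design$component_a * step^k,
                    dose_B = design$component_b * step^k,
                    total = design$total_c * step^k)
  attr(out, "ratio") <- step
  attr(out, "component_ratio") <- design$component_a / design$component_b
  class(out) <- c("dose_ladder", "data.frame")
  out
}

#' Write a dose ladder as delimited text
#'
#' Column layout matches the classical combination-design table: pair index,
#' dose of drug A, dose of drug B, composed pair total (all nmol/site).
#'
#' @param ladder a [dose_ladder()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dose_ladder <- function(ladder, path) {
  stopifnot(inherits(ladder, "dose_ladder"))
  utils::write.csv(as.data.frame(ladder), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.mixture_design <- function(x, ...) {
  cat(sprintf("Fixed-ratio design: f = %.4g\n", x$f))
  cat(sprintf("  a = f*ED_A = %.4g, b = (1-f)*ED_B = %.4g, c = %.4g nmol/site\n",
              x$component_a, x$component_b, x$total_c))
  invisible(x)
}
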