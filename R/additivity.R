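# Additivity analysis: theoretical additive ED, composite t-test,
# interaction index and isobologram coordinates.

#' Theoretical additive effective dose of the mixture
#'
#' Loewe-additive prediction for the fixed-ratio mixture:
#' `Z_add = f * ED_A + (1 - f) * ED_B` on the natural dose scale, with
#' variance `V(Z_add) = f^2 V(A) + (1 - f)^2 V(B)` carried on the log scale.
#'
#' Note the deliberate mixed-scale convention: the additive dose combines
#' natural-scale EDs while the variances propagated into the composite t
#' statistic are the log-scale ED variances produced by
#' [effective_dose()].  This is the convention of the classical tabulated
#' calculus this package reproduces; see the methods vignette for
#' discussion and for the exact-df alternative.
#'
#' @param ed_A,ed_B [effective_dose()] objects, or positive numbers (then
#'   `var_A`/`var_B` must be given).
#' @param f proportion factor in `[0, 1]` (boundaries give the single-drug
#'   degenerate case).
#' @param var_A,var_B log-scale ED variances (overridden by the variance in
#'   an `effective_dose` input).
#' @return An object of class `additive_ed`: `z_add` (nmol/site),
#'   `var_z_add` (log scale), `df` (pooled `N_A + N_B - 4`, NA for plain
#'   numeric input).
#' @examples
#' theoretical_additive(0.88, 0.025, f = 0.38, var_A = 0.042, var_B = 0.025)
#' @export
theoretical_additive <- function(ed_A, ed_B, f, var_A = NULL, var_B = NULL) {
  A <- ed_value(ed_A, "ed_A"); B <- ed_value(ed_B, "ed_B")
  vA <- if (inherits(ed_A, "effective_dose")) ed_A$variance else var_A
  vB <- if (inherits(ed_B, "effective_dose")) ed_B$variance else var_B
  check_scalar(f, "f")
  if (f < 0 || f > 1) stop("`f` must lie in [0, 1]", call. = FALSE)
  if (is.null(vA) || is.null(vB))
    stop("supply `var_A`/`var_B` (or effective_dose objects)", call. = FALSE)
  df <- if (inherits(ed_A, "effective_dose") && inherits(ed_B, "effective_dose"))
    ed_A$df + ed_B$df else NA_integer_
  out <- list(z_add = f * A + (1 - f) * B,
              var_z_add = f^2 * vA + (1 - f)^2 * vB,
              f = f, df = df)
  class(out) <- "additive_ed"
  out
}

#' Composite t-test of the mixture ED against the additive prediction
#'
#' Compares the experimentally observed mixture ED (`Z_mix`) with the
#' theoretical additive ED (`Z_add`) on the log scale:
#' `t_critical = (log10 Z_add - log10 Z_mix) / sqrt(SEx^2 + SEy^2)` with
#' `SEx^2 = V(Z_add)` and `SEy^2 = V(Z_mix)` (log-scale variances), against
#' the variance-weighted tabulated value
#' `T_tabulated = (t_add SEx^2 + t_mix SEy^2) / (SEx^2 + SEy^2)`.
#'
#' `t_critical` is signed (positive when `Z_mix < Z_add`); significance is
#' judged on its absolute value so the sub-additive direction is also
#' detected.  The verdict is `"synergy"` only when the difference is
#' significant *and* `Z_mix < Z_add`; `"sub-additive"` when significant in
#' the other direction; otherwise `"additive"`.
#'
#' @param z_add,var_z_add additive ED (nmol/site) and its log-scale
#'   variance, or an [theoretical_additive()] object as `z_add`.
#' @param df_add degrees of freedom behind `z_add` (pooled single-drug df).
#' @param z_mix,var_z_mix experimental mixture ED and log-scale variance,
#'   or an [effective_dose()] object as `z_mix`.
#' @param df_mix degrees of freedom of the mixture fit (`N - 2`).
#' @param alpha two-sided significance level.
#' @param mode `"paper-compat"` fixes `t_add = t_mix = 1.96`; `"exact"` uses
#'   Student critical values at `df_add`/`df_mix`.
#' @return An object of class `additivity_result` holding the inputs,
#'   `t_critical`, `t_tabulated`, `significant`, `verdict`, and the
#'   interaction index `alpha_index = z_mix / z_add`.
#' @export
composite_t_test <- function(z_add, var_z_add = NULL, df_add = Inf,
                             z_mix, var_z_mix = NULL, df_mix = Inf,
                             alpha = 0.05, mode = c("paper-compat", "exact")) {
  mode <- match.arg(mode)
  if (inherits(z_add, "additive_ed")) {
    if (!is.na(z_add$df)) df_add <- z_add$df
    var_z_add <- z_add$var_z_add
    z_add <- z_add$z_add
  }
  if (inherits(z_mix, "effective_dose")) {
    df_mix <- z_mix$df
    var_z_mix <- z_mix$variance
    z_mix <- z_mix$ed
  }
  check_scalar(z_add, "z_add", positive = TRUE)
  check_scalar(z_mix, "z_mix", positive = TRUE)
  check_scalar(var_z_add, "var_z_add", positive = TRUE)
  check_scalar(var_z_mix, "var_z_mix", positive = TRUE)
  x <- log10(z_add); y <- log10(z_mix)
  se2x <- var_z_add; se2y <- var_z_mix
  t_critical <- (x - y) / sqrt(se2x + se2y)
  t_add <- critical_t(alpha, df_add, if (mode == "paper-compat") "paper-compat" else "exact")
  t_mix <- critical_t(alpha, df_mix, if (mode == "paper-compat") "paper-compat" else "exact")
  t_tabulated <- (t_add * se2x + t_mix * se2y) / (se2x + se2y)
  significant <- abs(t_critical) > t_tabulated
  verdict <- if (!significant) "additive"
             else if (z_mix < z_add) "synergy" else "sub-additive"
  out <- list(z_add = z_add, var_z_add = var_z_add, df_add = df_add,
              z_mix = z_mix, var_z_mix = var_z_mix, df_mix = df_mix,
              t_critical = t_critical, t_tabulated = t_tabulated,
              t_add = t_add, t_mix = t_mix,
              significant = significant, verdict = verdict,
              alpha_index = z_mix / z_add,
              alpha = alpha, mode = mode)
  class(out) <- "additivity_result"
  out
}

#' Interaction index
#'
#' `alpha = Z_mix / Z_add`: the ratio of the experimentally observed mixture
#' ED to the Loewe-additive prediction.  Values below 1 indicate synergy
#' (less total drug needed than additivity predicts), 1 additivity, above 1
#' sub-additivity.
#'
#' @param z_mix,z_add positive doses (nmol/site).
#' @return The dimensionless index.
#' @examples
#' interaction_index(0.025, 0.35)  # ~0.071
#' @export
interaction_index <- function(z_mix, z_add) {
  check_scalar(z_mix, "z_mix", positive = TRUE)
  check_scalar(z_add, "z_add", positive = TRUE)
  z_mix / z_add
}

#' Isobologram coordinates at the target effect level
#'
#' Coordinates in component-dose space (drug A on the abscissa, drug B on
#' the ordinate): the two single-drug intercepts, the additive point
#' `(f ED_A, (1-f) ED_B)` — which lies on the straight additivity isobole
#' joining the intercepts — and the observed point, the mixture ED split in
#' the same fixed ratio (components sum to `z_mix`).
#'
#' @param ed_A,ed_B single-drug EDs, nmol/site (numbers or
#'   [effective_dose()] objects).
#' @param f proportion factor in (0, 1).
#' @param z_add additive ED; defaults to `f*ed_A + (1-f)*ed_B`.
#' @param z_mix observed mixture ED, nmol/site.
#' @return An object of class `isobologram`: `axis_A_intercept`,
#'   `axis_B_intercept`, `additive_point`, `observed_point` (each point a
#'   named numeric `c(A=, B=)`).
#' @export
isobologram_coordinates <- function(ed_A, ed_B, f, z_add = NULL, z_mix) {
  A <- ed_value(ed_A, "ed_A"); B <- ed_value(ed_B, "ed_B")
  check_scalar(f, "f")
  if (f <= 0 || f >= 1) stop("`f` must lie in (0, 1)", call. = FALSE)
  check_scalar(z_mix, "z_mix", positive = TRUE)
  add_pt <- c(A = f * A, B = (1 - f) * B)
  if (is.null(z_add)) z_add <- sum(add_pt)
  check_scalar(z_add, "z_add", positive = TRUE)
  obs_pt <- z_mix * add_pt / sum(add_pt)
  out <- list(axis_A_intercept = c(A = A, B = 0),
              axis_B_intercept = c(A = 0, B = B),
              additive_point = add_pt,
              observed_point = obs_pt)
  class(out) <- "isobologram"
  out
}

#' One-row additivity report
#'
#' Mirrors the classical compilation table: routes, `Z_add`, `Z_mix`,
#' `t_critical`, `T_tabulated`, significance, verdict and the interaction
#' index.
#'
#' @param result an [composite_t_test()] result.
#' @param label description of the combined routes/regimens.
#' @return A one-row data.frame.
#' @export
additivity_report <- function(result, label = "A/B") {
  stopifnot(inherits(result, "additivity_result"))
  data.frame(combination = label,
             z_add = result$z_add, z_mix = result$z_mix,
             t_critical = result$t_critical,
             t_tabulated = result$t_tabulated,
             significant = result$significant,
             verdict = result$verdict,
             interaction_index = result$alpha_index,
             stringsAsFactors = FALSE)
}

#' @export
print.additivity_result <- function(x, ...) {
  cat(sprintf("Additivity comparison (%s mode)\n", x$mode))
  cat(sprintf("  Z_add = %.4g (V = %.4g), Z_mix = %.4g (V = %.4g) nmol/site\n",
              x$z_add, x$var_z_add, x$z_mix, x$var_z_mix))
  cat(sprintf("  t_critical = %.3f vs T_tabulated = %.3f -> %s\n",
              x$t_critical, x$t_tabulated, x$verdict))
  cat(sprintf("  interaction index = %.4g\n", x$alpha_index))
  invisible(x)
}

#' @export
print.isobologram <- function(x, ...) {
  cat("Isobologram coordinates (nmol/site):\n")
  cat(sprintf("  axis intercepts: A = %.4g, B = %.4g\n",
              x$axis_A_intercept[["A"]], x$axis_B_intercept[["B"]]))
  cat(sprintf("  additive point: (%.4g, %.4g); observed point: (%.4g, %.4g)\n",
              x$additive_point[["A"]], x$additive_point[["B"]],
              x$observed_point[["A"]], x$observed_point[["B"]]))
  invisible(x)
}
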