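# Synthetic dose-effect data with known ground truth.

#' Specification of a synthetic single-drug experiment
#'
#' Describes the generative model `y = a + b * log10(dose) + e`,
#' `e ~ N(0, sigma^2)`, with unequal group sizes per dose level.  Responses
#' are not clipped: %MPE below 0 or above 100 occurs in real data and the
#' model is linear.
#'
#' @param a intercept, %MPE.
#' @param b slope, %MPE per log10(nmol/site).
#' @param sigma residual standard deviation, %MPE (>= 0).
#' @param dose_levels positive doses, nmol/site.
#' @param n_per_dose animals per dose level (recycled to the dose levels).
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @param regimen label for the generated table.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(a, b, sigma, dose_levels, n_per_dose, seed = NULL,
                     regimen = "sim") {
  check_scalar(a, "a"); check_scalar(b, "b")
  check_scalar(sigma, "sigma")
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (any(!is.finite(dose_levels) | dose_levels <= 0))
    stop("all dose levels must be positive", call. = FALSE)
  n_per_dose <- rep_len(as.integer(n_per_dose), length(dose_levels))
  if (any(n_per_dose < 1L)) stop("counts must be >= 1", call. = FALSE)
  out <- list(a = a, b = b, sigma = sigma,
              dose_levels = as.numeric(dose_levels),
              n_per_dose = n_per_dose, seed = seed, regimen = regimen)
  class(out) <- "sim_spec"
  out
}

# Draw one table from a sim_spec using the *current* RNG stream.
draw_single <- function(spec) {
  dose <- rep(spec$dose_levels, spec$n_per_dose)
  y <- spec$a + spec$b * log10(dose)
  if (spec$sigma > 0) y <- y + stats::rnorm(length(dose), 0, spec$sigma)
  dose_effect_table(dose, y, regimen = spec$regimen)
}

#' Simulate a single-drug dose-effect table
#'
#' @param spec a [sim_spec()].
#' @return A [dose_effect_table()]; identical tables for identical seeds.
#' @examples
#' s <- sim_spec(a = 20.9, b = 16.3, sigma = 25.6,
#'               dose_levels = c(0.1, 0.4, 1, 2, 6),
#'               n_per_dose = c(14, 11, 16, 10, 9), seed = 1)
#' fit_log_dose(simulate_single(s))$b
#' @export
simulate_single <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_local_seed(spec$seed, draw_single(spec))
}

#' Specification of a synthetic fixed-ratio combination experiment
#'
#' The two single-drug arms follow their [sim_spec()]s.  The mixture arm is
#' generated on total dose `c` at the fixed component ratio produced by the
#' design pipeline: its true ED at the target effect is
#' `alpha_true * Z_add(truth)`, where `Z_add(truth)` combines the *true*
#' single-drug EDs with the proportion factor the pipeline computed, and its
#' responses follow `y = a_mix + slope_mix * log10(c) + e`, with `a_mix`
#' anchored so the line passes through (`ED_mix_true`, `gamma`).
#'
#' @param spec_A,spec_B [sim_spec()]s for the single drugs (their own seeds
#'   are ignored; the combination `seed` governs all randomness).
#' @param alpha_true generative interaction index (> 0; 1 = additive).
#' @param slope_mix slope of the mixture curve; default mean of the two
#'   single-drug slopes.
#' @param sigma_mix residual s.d. of the mixture arm; default mean of the
#'   single-drug sigmas.
#' @param n_per_dose_mix animals per mixture dose pair; default recycles
#'   `spec_A$n_per_dose`.
#' @param gamma target effect, %MPE.
#' @param n_pairs,step dose-ladder shape (see [dose_ladder()]).
#' @param seed integer seed driving the whole experiment.
#' @return An object of class `combo_sim_spec`.
#' @export
combo_sim_spec <- function(spec_A, spec_B, alpha_true = 1,
                           slope_mix = NULL, sigma_mix = NULL,
                           n_per_dose_mix = NULL, gamma = 20,
                           n_pairs = 6L, step = 3, seed = NULL) {
  stopifnot(inherits(spec_A, "sim_spec"), inherits(spec_B, "sim_spec"))
  check_scalar(alpha_true, "alpha_true", positive = TRUE)
  if (is.null(slope_mix)) slope_mix <- mean(c(spec_A$b, spec_B$b))
  if (is.null(sigma_mix)) sigma_mix <- mean(c(spec_A$sigma, spec_B$sigma))
  if (is.null(n_per_dose_mix)) n_per_dose_mix <- spec_A$n_per_dose
  out <- list(spec_A = spec_A, spec_B = spec_B, alpha_true = alpha_true,
              slope_mix = slope_mix, sigma_mix = sigma_mix,
              n_per_dose_mix = rep_len(as.integer(n_per_dose_mix), n_pairs),
              gamma = gamma, n_pairs = as.integer(n_pairs), step = step,
              seed = seed)
  class(out) <- "combo_sim_spec"
  out
}

# f from two effective_dose objects with the sigma = 0 fallback.
proportion_factor_safe <- function(ed_A, ed_B) {
  if (ed_A$variance + ed_B$variance <= 0) 0.5
  else proportion_factor(ed_A$variance, ed_B$variance)
}

#' Simulate a full fixed-ratio combination experiment
#'
#' Draws the two single-drug tables, fits them, and reruns the design
#' pipeline (proportion factor from the fitted ED variances, geometric dose
#' ladder); a single-drug draw whose slope is not significant is redrawn
#' (same RNG stream), up to `max_attempts` times.  The mixture table is then
#' generated over the ladder totals from the `alpha_true`-scaled additive
#' truth (see [combo_sim_spec()]).
#'
#' All randomness flows from `spec$seed`: one stream, seeded once, drawing
#' arm A, then arm B, then the mixture.
#'
#' @param spec a [combo_sim_spec()].
#' @param max_attempts redraw cap for non-significant single-drug slopes.
#' @return A list: `table_A`, `table_B`, `table_mix`, `design`
#'   ([component_doses()] from the fitted arms), `ladder`, `truth` (list with
#'   `ed_A_true`, `ed_B_true`, `f`, `z_add_true`, `ed_mix_true`,
#'   `alpha_true`), `attempts`.
#' @export
simulate_combination <- function(spec, max_attempts = 10L) {
  stopifnot(inherits(spec, "combo_sim_spec"))
  with_local_seed(spec$seed, {
    fit_A <- fit_B <- tab_A <- tab_B <- NULL
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf("no significant single-drug slopes in %d attempts", max_attempts),
             call. = FALSE)
      tab_A <- draw_single(spec$spec_A)
      tab_B <- draw_single(spec$spec_B)
      fit_A <- fit_log_dose(tab_A)
      fit_B <- fit_log_dose(tab_B)
      ok <- suppressWarnings(slope_test(fit_A)$significant &&
                               slope_test(fit_B)$significant)
      if (ok) break
    }
    ed_A <- suppressWarnings(effective_dose(fit_A, spec$gamma))
    ed_B <- suppressWarnings(effective_dose(fit_B, spec$gamma))
    f <- proportion_factor_safe(ed_A, ed_B)
    design <- component_doses(ed_A, ed_B, f)
    ladder <- dose_ladder(design, n_pairs = spec$n_pairs, step = spec$step)

    ed_A_true <- 10^((spec$gamma - spec$spec_A$a) / spec$spec_A$b)
    ed_B_true <- 10^((spec$gamma - spec$spec_B$a) / spec$spec_B$b)
    z_add_true <- f * ed_A_true + (1 - f) * ed_B_true
    ed_mix_true <- spec$alpha_true * z_add_true
    a_mix <- spec$gamma - spec$slope_mix * log10(ed_mix_true)

    mix_spec <- sim_spec(a = a_mix, b = spec$slope_mix, sigma = spec$sigma_mix,
                         dose_levels = ladder$total,
                         n_per_dose = spec$n_per_dose_mix,
                         regimen = "sim_mixture")
    tab_mix <- draw_single(mix_spec)
    list(table_A = tab_A, table_B = tab_B, table_mix = tab_mix,
         design = design, ladder = ladder,
         truth = list(ed_A_true = ed_A_true, ed_B_true = ed_B_true, f = f,
                      z_add_true = z_add_true, ed_mix_true = ed_mix_true,
                      alpha_true = spec$alpha_true),
         attempts = attempts)
  })
}

#' Estimate the interaction index from a simulated (or real) experiment
#'
#' Lightweight estimation pipeline used by the Monte-Carlo studies: fits the
#' three tables, computes the proportion factor from the fitted ED
#' variances (0.5 when both are numerically zero), the additive prediction,
#' the mixture ED, the composite t-test (skipped when a variance is zero)
#' and the interaction-index estimate.
#'
#' @param tables a list with `table_A`, `table_B`, `table_mix` (e.g. the
#'   output of [simulate_combination()]).
#' @param gamma target effect, %MPE.
#' @param alpha significance level for the composite test.
#' @param mode critical-value mode, see [composite_t_test()].
#' @return A list: `fit_A`, `fit_B`, `fit_mix`, `ed_A`, `ed_B`, `f`,
#'   `z_add`, `z_mix`, `alpha_hat`, `test` (an `additivity_result` or NULL
#'   when degenerate variances preclude it).
#' @export
estimate_combination <- function(tables, gamma = 20, alpha = 0.05,
                                 mode = c("paper-compat", "exact")) {
  mode <- match.arg(mode)
  fit_A <- fit_log_dose(tables$table_A)
  fit_B <- fit_log_dose(tables$table_B)
  fit_mix <- fit_log_dose(tables$table_mix)
  ed_A <- suppressWarnings(effective_dose(fit_A, gamma))
  ed_B <- suppressWarnings(effective_dose(fit_B, gamma))
  ed_mix <- suppressWarnings(effective_dose(fit_mix, gamma))
  f <- proportion_factor_safe(ed_A, ed_B)
  add <- theoretical_additive(ed_A$ed, ed_B$ed, f,
                              var_A = ed_A$variance, var_B = ed_B$variance)
  test <- if (add$var_z_add > 0 && ed_mix$variance > 0)
    composite_t_test(add$z_add, add$var_z_add, df_add = ed_A$df + ed_B$df,
                     z_mix = ed_mix$ed, var_z_mix = ed_mix$variance,
                     df_mix = ed_mix$df, alpha = alpha, mode = mode)
  else NULL
  list(fit_A = fit_A, fit_B = fit_B, fit_mix = fit_mix,
       ed_A = ed_A, ed_B = ed_B, f = f,
       z_add = add$z_add, z_mix = ed_mix$ed,
       alpha_hat = ed_mix$ed / add$z_add, test = test)
}
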