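# Full pipeline: single-drug fits -> design -> additivity comparison -> report.

resolve_table <- function(x, what) {
  if (inherits(x, "dose_effect_table")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (x %in% FIXTURE_NAMES) return(load_fixture(x))
    return(read_dose_effect(x))
  }
  stop(sprintf("`%s` must be a dose_effect_table, fixture name or file path", what),
       call. = FALSE)
}

#' Configuration for a full fixed-ratio analysis
#'
#' @param drug_a,drug_b,mixture dose-effect tables, packaged fixture names,
#'   or file paths; `drug_a`/`drug_b` are the single-drug arms, `mixture`
#'   the fixed-ratio combination arm (dose = composed pair total).
#' @param gamma target effect in %MPE, in (0, 100).
#' @param mode `"paper-compat"` (critical values fixed at 1.96) or
#'   `"exact"` (Student critical values at the data's df).
#' @param alpha significance level in (0, 1).
#' @param out_dir optional directory for report files.
#' @param allow_nonsignificant proceed even if a single-drug slope fails its
#'   t-test (the ED is then unreliable); default aborts.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(drug_a, drug_b, mixture, gamma = 20,
                            mode = c("paper-compat", "exact"), alpha = 0.05,
                            out_dir = NULL, allow_nonsignificant = FALSE) {
  mode <- match.arg(mode)
  check_scalar(gamma, "gamma")
  if (gamma <= 0 || gamma >= 100) stop("`gamma` must be in (0, 100)", call. = FALSE)
  check_scalar(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  out <- list(drug_a = drug_a, drug_b = drug_b, mixture = mixture,
              gamma = gamma, mode = mode, alpha = alpha, out_dir = out_dir,
              allow_nonsignificant = allow_nonsignificant)
  class(out) <- "analysis_config"
  out
}

#' Run the full fixed-ratio isobolographic analysis
#'
#' Fits both single-drug log-dose curves and the mixture curve, derives the
#' effective doses at `gamma`, the variance-weighted proportion factor, the
#' theoretical additive ED and its variance, runs the composite t-test of
#' `Z_mix` against `Z_add`, and computes the interaction index and
#' isobologram coordinates.  With `out_dir` set, writes the regression
#' summaries, the design ladder, a one-row comparison report and the
#' isobologram coordinates as delimited text.
#'
#' Aborts (unless `allow_nonsignificant`) when a single-drug slope does not
#' differ from zero, since the ED inversion is then unreliable.
#'
#' @param config an [analysis_config()].
#' @return An object of class `full_analysis`: `fits` (A, B, mix),
#'   `slope_tests`, `eds` (A, B, mix at `gamma`), `f`, `design`, `ladder`,
#'   `additive`, `result` (the `additivity_result`), `isobologram`,
#'   `report` (one-row data.frame), `config`.
#' @examples
#' \donttest{
#' res <- run_full_analysis(analysis_config("sb_ipl", "pha_ipl", "combo_ipl_ipl"))
#' res$result
#' }
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  tab <- list(A = resolve_table(config$drug_a, "drug_a"),
              B = resolve_table(config$drug_b, "drug_b"),
              mix = resolve_table(config$mixture, "mixture"))
  st_mode <- if (config$mode == "paper-compat") "paper-compat" else "exact"
  fits <- lapply(tab, fit_log_dose)
  tests <- lapply(fits, slope_test, alpha = config$alpha, mode = st_mode)
  for (arm in c("A", "B")) {
    if (!tests[[arm]]$significant) {
      msg <- sprintf("slope of single-drug arm %s (%s) does not differ from zero; ED%g unreliable",
                     arm, fits[[arm]]$regimen, config$gamma)
      if (config$allow_nonsignificant) warning(msg) else stop(msg, call. = FALSE)
    }
  }
  eds <- lapply(fits, function(f) suppressWarnings(effective_dose(f, config$gamma)))
  f <- proportion_factor(eds$A$variance, eds$B$variance)
  design <- component_doses(eds$A, eds$B, f)
  ladder <- dose_ladder(design)
  add <- theoretical_additive(eds$A, eds$B, f)
  result <- composite_t_test(add, z_mix = eds$mix,
                             alpha = config$alpha, mode = config$mode)
  iso <- isobologram_coordinates(eds$A, eds$B, f,
                                 z_add = add$z_add, z_mix = eds$mix$ed)
  label <- sprintf("%s + %s", fits$A$regimen, fits$B$regimen)
  report <- additivity_report(result, label = label)
  out <- list(fits = fits, slope_tests = tests, eds = eds, f = f,
              design = design, ladder = ladder, additive = add,
              result = result, isobologram = iso, report = report,
              config = config)
  class(out) <- "full_analysis"
  if (!is.null(config$out_dir)) write_analysis_reports(out, config$out_dir)
  out
}

write_analysis_reports <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summaries <- do.call(rbind, lapply(res$fits, regression_summary,
                                     gamma = res$config$gamma,
                                     alpha = res$config$alpha,
                                     mode = if (res$config$mode == "paper-compat")
                                       "paper-compat" else "exact"))
  utils::write.csv(summaries, file.path(dir, "regression_summaries.csv"),
                   row.names = FALSE)
  write_dose_ladder(res$ladder, file.path(dir, "design_ladder.csv"))
  utils::write.csv(res$report, file.path(dir, "additivity_report.csv"),
                   row.names = FALSE)
  iso <- res$isobologram
  iso_df <- data.frame(point = c("axis_A", "axis_B", "additive", "observed"),
                       dose_A = c(iso$axis_A_intercept[["A"]], iso$axis_B_intercept[["A"]],
                                  iso$additive_point[["A"]], iso$observed_point[["A"]]),
                       dose_B = c(iso$axis_A_intercept[["B"]], iso$axis_B_intercept[["B"]],
                                  iso$additive_point[["B"]], iso$observed_point[["B"]]))
  utils::write.csv(iso_df, file.path(dir, "isobologram.csv"), row.names = FALSE)
  invisible(dir)
}

#' @export
print.full_analysis <- function(x, ...) {
  cat("== Fixed-ratio isobolographic analysis ==\n")
  for (arm in names(x$fits)) {
    f <- x$fits[[arm]]; e <- x$eds[[arm]]
    cat(sprintf("%-4s %-18s N=%-3d b=%7.3f a=%7.3f ED%g=%.4g (V=%.4g)\n",
                arm, f$regimen, f$N, f$b, f$a, x$config$gamma, e$ed, e$variance))
  }
  cat(sprintf("proportion factor f = %.4g\n", x$f))
  print(x$result)
  invisible(x)
}
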