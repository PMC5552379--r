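# Dose-effect table container and I/O.
#
# A dose_effect_table is a plain data.frame (regimen, dose, unit, response,
# optional subject_id) with class "dose_effect_table".  Doses are always held
# internally in nmol/site; pmol/site inputs are converted at the I/O boundary.

FIXTURE_NAMES <- c("sb_ipl", "pha_ipl", "pha_it", "combo_ipl_ipl", "combo_ipl_it")

#' Construct a per-animal dose-effect table
#'
#' One row per animal: a positive dose (nmol/site) and a response in %MPE
#' (percent of maximum possible effect; may be negative — hyperalgesia — or
#' exceed 100).
#'
#' @param dose positive numeric vector, nmol/site.
#' @param response finite numeric vector of %MPE values, same length.
#' @param regimen single label for the drug/route regimen.
#' @param unit dose unit of the *input* `dose` vector; `"pmol/site"` values
#'   are converted to nmol/site on construction.
#' @param subject_id optional per-animal identifiers.
#' @return A `dose_effect_table` (data.frame) whose doses are in nmol/site.
#' @examples
#' det <- dose_effect_table(rep(c(0.1, 1, 10), each = 2),
#'                          c(5, 10, 20, 30, 55, 60), regimen = "demo")
#' nlevels(factor(det$dose))
#' @export
dose_effect_table <- function(dose, response, regimen = "unknown",
                              unit = "nmol/site", subject_id = NULL) {
  if (length(dose) != length(response))
    stop("`dose` and `response` must have the same length", call. = FALSE)
  dose <- convert_dose(as.numeric(dose), from = unit, to = "nmol/site")
  response <- as.numeric(response)
  out <- data.frame(regimen = as.character(regimen)[1L],
                    dose = dose,
                    unit = "nmol/site",
                    response = response,
                    stringsAsFactors = FALSE)
  if (!is.null(subject_id)) out$subject_id <- as.character(subject_id)
  class(out) <- c("dose_effect_table", "data.frame")
  validate_dose_effect(out)
}

#' Validate a dose-effect table
#'
#' Checks the container invariants: all doses positive and finite, all
#' responses finite, at least 4 records and at least 2 distinct dose levels
#' (the minimum for a slope test on N-2 df to be meaningful).
#'
#' @param x a `dose_effect_table` (or coercible data.frame with `dose` and
#'   `response` columns).
#' @return `x`, invisibly classed, or an error naming the offending row.
#' @export
validate_dose_effect <- function(x) {
  if (!all(c("dose", "response") %in% names(x)))
    stop("table must have `dose` and `response` columns", call. = FALSE)
  bad <- which(!is.finite(x$dose) | x$dose <= 0)
  if (length(bad))
    stop(sprintf("non-positive or non-numeric dose at row %d", bad[1L]), call. = FALSE)
  bad <- which(!is.finite(x$response))
  if (length(bad))
    stop(sprintf("non-finite response at row %d", bad[1L]), call. = FALSE)
  if (nrow(x) < 4L)
    stop(sprintf("need at least 4 records, got %d", nrow(x)), call. = FALSE)
  if (length(unique(x$dose)) < 2L)
    stop("need at least 2 distinct dose levels", call. = FALSE)
  if (!inherits(x, "dose_effect_table"))
    class(x) <- c("dose_effect_table", class(x))
  invisible(x)
}

#' Percent maximum possible effect from raw nociception times
#'
#' Computes `%MPE = 100 * (A - B) / A` for each treated animal, where `A` is
#' the mean nociceptive time of the vehicle group and `B` the animal's own
#' nociceptive time.  100 means complete suppression (B = 0), 0 means no
#' effect (B = A), and negative values (hyperalgesia, B > A) are allowed.
#' Times must lie in the 300-s observation window.
#'
#' @param vehicle_times numeric vector of vehicle-group times, seconds.
#' @param treated_times numeric vector of treated-group times, seconds.
#' @param t_max maximum recordable time, seconds (observation window).
#' @return Numeric vector of %MPE values, one per treated animal.
#' @examples
#' compute_mpe(c(120, 80), c(50, 150))  # 50, -50
#' @export
compute_mpe <- function(vehicle_times, treated_times, t_max = 300) {
  if (length(vehicle_times) == 0L)
    stop("vehicle group is empty", call. = FALSE)
  for (nm in c("vehicle_times", "treated_times")) {
    v <- get(nm)
    bad <- which(!is.finite(v) | v < 0 | v > t_max)
    if (length(bad))
      stop(sprintf("%s[%d] outside [0, %g] s", nm, bad[1L], t_max), call. = FALSE)
  }
  a <- mean(vehicle_times)
  if (a <= 0) stop("vehicle mean must be strictly positive", call. = FALSE)
  100 * (a - treated_times) / a
}

#' Read a dose-effect table from delimited text
#'
#' Expects a comma-separated file with a header containing at least `dose`
#' and `response` columns (the shipped dialect is
#' `regimen,dose,unit,response`); lines starting with `#` are comments.
#' Doses declared in pmol/site are converted to nmol/site.
#'
#' @param path file path.
#' @param unit fallback dose unit when the file has no `unit` column.
#' @return A [dose_effect_table()].
#' @export
read_dose_effect <- function(path, unit = "nmol/site") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = NA),
    error = function(e) stop(sprintf("cannot parse %s: %s", path, conditionMessage(e)),
                             call. = FALSE))
  if (nrow(raw) == 0L) stop(sprintf("no records in %s", path), call. = FALSE)
  if (!all(c("dose", "response") %in% names(raw)))
    stop(sprintf("%s lacks dose/response columns", path), call. = FALSE)
  for (col in c("dose", "response")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric %s at data row %d of %s", col, bad[1L], path),
           call. = FALSE)
    raw[[col]] <- v
  }
  file_unit <- if ("unit" %in% names(raw)) raw$unit[1L] else unit
  dose_effect_table(raw$dose, raw$response,
                    regimen = if ("regimen" %in% names(raw)) raw$regimen[1L] else "unknown",
                    unit = file_unit,
                    subject_id = if ("subject_id" %in% names(raw)) raw$subject_id else NULL)
}

#' Write a dose-effect table as delimited text
#'
#' Inverse of [read_dose_effect()]: `write_dose_effect()` then
#' `read_dose_effect()` round-trips doses and responses exactly.
#'
#' @param x a `dose_effect_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dose_effect <- function(x, path) {
  validate_dose_effect(x)
  cols <- intersect(c("regimen", "dose", "unit", "response", "subject_id"), names(x))
  df <- as.data.frame(x)[, cols]
  # full-precision decimal text so the round trip is bit-exact
  df$dose <- vapply(df$dose, function(v) format(v, digits = 17, scientific = FALSE,
                                                trim = TRUE), character(1))
  df$response <- vapply(df$response, function(v) format(v, digits = 17,
                                                        scientific = FALSE,
                                                        trim = TRUE), character(1))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load one of the packaged dose-effect fixtures
#'
#' The five curated per-animal tables from the mouse capsaicin-test
#' experiment shipped with the package:
#' \describe{
#'   \item{`sb_ipl`}{SB366791 intraplantar, N = 60, 5 dose levels.}
#'   \item{`pha_ipl`}{Phalpha1beta intraplantar, N = 47.}
#'   \item{`pha_it`}{Phalpha1beta intrathecal, N = 72 (one dose/log typo in
#'     the source curated to 0.003 nmol/site; see the fixture file comment).}
#'   \item{`combo_ipl_ipl`}{fixed-ratio mixture, both intraplantar, N = 82;
#'     dose is the composed pair total.}
#'   \item{`combo_ipl_it`}{fixed-ratio mixture, intraplantar + intrathecal,
#'     N = 81.}
#' }
#'
#' @param name one of the five fixture names above.
#' @return A [dose_effect_table()] in nmol/site.
#' @examples
#' nrow(load_fixture("pha_ipl"))  # 47
#' @export
load_fixture <- function(name) {
  name <- match.arg(name, FIXTURE_NAMES)
  path <- system.file("extdata", paste0(name, ".csv"), package = "isobolr",
                      mustWork = TRUE)
  read_dose_effect(path)
}

#' @export
print.dose_effect_table <- function(x, ...) {
  lv <- sort(unique(x$dose))
  cat(sprintf("Dose-effect table: %s (%d animals, %d dose levels, %s)\n",
              x$regimen[1L], nrow(x), length(lv), x$unit[1L]))
  cat("doses:", paste(signif(lv, 4), collapse = ", "), "\n")
  cat(sprintf("response (%%MPE): %.2f .. %.2f, mean %.2f\n",
              min(x$response), max(x$response), mean(x$response)))
  invisible(x)
}
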