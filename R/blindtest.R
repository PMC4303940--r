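# Blind-test harness: apply a frozen stage table or regression fit to
# held-out individuals of known age and score interval coverage.
#
# Verdicts per record are exhaustive and mutually exclusive:
#   within     known age inside the inclusive integer interval
#   under_aged the method's interval lies entirely below the known age
#   over_aged  the interval lies entirely above the known age

new_blind_test <- function(ledger, method, n_excluded, rmse = NA_real_) {
  n <- nrow(ledger)
  within <- sum(ledger$verdict == "within")
  structure(list(
    ledger = ledger, method = method, n = n,
    within = within,
    under_aged = sum(ledger$verdict == "under_aged"),
    over_aged = sum(ledger$verdict == "over_aged"),
    pct_within = round_half_up(100 * within / n, 1),
    rmse = rmse, n_excluded = n_excluded
  ), class = "blind_test")
}

verdict_for <- function(age, lower, upper) {
  ifelse(upper < age, "under_aged",
         ifelse(lower > age, "over_aged", "within"))
}

drop_unknown_sex <- function(records) {
  sex <- normalize_sex(records$sex, allow_unknown = TRUE)
  excl <- sex == "unknown"
  if (any(excl)) {
    warning(sum(excl), " record(s) of unknown sex excluded from the blind test")
  }
  out <- records[!excl, , drop = FALSE]
  attr(out, "n_excluded") <- sum(excl)
  out
}

#' Blind test of the composite-score staging method
#'
#' Assigns each held-out individual to a degeneration stage using the per-sex
#' stage tables, and checks whether the known age falls inside the stage's
#' 95% age interval (inclusive integer bounds).
#'
#' @param records held-out records with known `age`, `sex` and valid trait
#'   grades.  Unknown-sex records are excluded with a warning (stage tables
#'   are sex-specific).
#' @param tables named list with elements `male` and `female`, each a
#'   [stage_table] (e.g. [reference_stage_table()]).
#' @return A `blind_test` object: per-record ledger plus counts, the percent
#'   within (one decimal) and the over/under-aging split.
#' @export
blind_test_composite <- function(records,
                                 tables = list(
                                   male = reference_stage_table("male"),
                                   female = reference_stage_table("female"))) {
  check_records(records)
  stopifnot(all(c("male", "female") %in% names(tables)))
  records <- drop_unknown_sex(records)
  n_excl <- attr(records, "n_excluded") %||% 0L
  comp <- record_composite(records)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    tab <- tables[[as.character(records$sex[i])]]
    stage <- assign_stage(comp[i], tab)
    r <- tab[tab$stage == stage, ]
    data.frame(id = if (!is.null(records$id)) records$id[i] else i,
               sex = as.character(records$sex[i]), age = records$age[i],
               composite = comp[i], stage = stage,
               lower = r$lower, upper = r$upper)
  })
  ledger <- do.call(rbind, rows)
  ledger$verdict <- verdict_for(ledger$age, ledger$lower, ledger$upper)
  new_blind_test(ledger, "composite-score stages", n_excl)
}

#' Blind test of the regression aging equation
#'
#' Predicts each held-out individual's age from the fitted truncated-normal
#' regression, forms the interval `prediction +/- 1.96 sigma_sex` and checks
#' the known age against it; also reports the RMSE of the point predictions.
#'
#' @param records held-out records with known `age` and the fit's covariates.
#' @param fit a [trunc_lm()] fit.
#' @param level interval coverage (default 0.95).
#' @return A `blind_test` object (see [blind_test_composite()]) with `rmse`.
#' @export
blind_test_regression <- function(records, fit, level = 0.95) {
  check_records(records)
  records <- if (fit$sex_sigma) drop_unknown_sex(records) else records
  pr <- predict(fit, records, interval = "prediction", level = level)
  ledger <- data.frame(
    id = if (!is.null(records$id)) records$id else seq_len(nrow(records)),
    sex = as.character(records$sex), age = records$age,
    estimate = pr$fit, lower = pr$lwr, upper = pr$upr)
  ledger$verdict <- verdict_for(ledger$age, ledger$lower, ledger$upper)
  new_blind_test(ledger, "regression equation", 0L,
                 rmse = sqrt(mean((pr$fit - records$age)^2)))
}

#' @export
print.blind_test <- function(x, ...) {
  cat("Blind test of the", x$method, "\n")
  cat(sprintf("  n = %d   within interval: %d (%.1f%%)\n",
              x$n, x$within, x$pct_within))
  cat(sprintf("  under-aged: %d   over-aged: %d\n", x$under_aged, x$over_aged))
  if (!is.na(x$rmse)) cat(sprintf("  RMSE: %.2f years\n", x$rmse))
  if (x$n_excluded > 0) cat("  excluded (unknown sex):", x$n_excluded, "\n")
  invisible(x)
}

#' @export
summary.blind_test <- function(object, ...) {
  c(n = object$n, within = object$within, under_aged = object$under_aged,
    over_aged = object$over_aged, pct_within = object$pct_within,
    rmse = object$rmse)
}
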