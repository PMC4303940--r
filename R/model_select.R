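# AIC comparison of candidate covariate sets for the age regression.
# Classical F-tests are unavailable under the truncated-normal likelihood,
# so candidate models are ranked by AIC = 2k - 2 logLik, k counting every
# free parameter (intercept, covariate weights, collection dummies and each
# residual-scale parameter).

#' Specify a candidate age-regression model
#'
#' Builds a covariate specification for [trunc_lm()] / [compare_models()] from
#' inclusion flags.  At least one covariate must be included.
#'
#' @param topography,porosity,osteophytes include the trait score as a linear
#'   covariate.
#' @param sex include a sex main effect (dummy male = 1).
#' @param collection include collection fixed effects (dummy-coded against
#'   `collection_ref`).
#' @param sex_sigma sex-dependent residual scale.
#' @param collection_ref reference level for collection dummies.
#' @return A `model_spec` object (list with `formula` and flags).
#' @export
model_spec <- function(topography = TRUE, porosity = TRUE, osteophytes = FALSE,
                       sex = TRUE, collection = FALSE, sex_sigma = TRUE,
                       collection_ref = NULL) {
  terms <- c("topography"[topography], "porosity"[porosity],
             "osteophytes"[osteophytes], "sex"[sex], "collection"[collection])
  if (!length(terms)) stop("at least one covariate must be included",
                           call. = FALSE)
  f <- stats::reformulate(terms, response = "age")
  structure(list(formula = f, topography = topography, porosity = porosity,
                 osteophytes = osteophytes, sex = sex, collection = collection,
                 sex_sigma = sex_sigma, collection_ref = collection_ref),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Age-regression spec: ", deparse(x$formula),
      if (x$sex_sigma) " | sex-dependent sigma" else " | single sigma", "\n",
      sep = "")
  invisible(x)
}

#' Default candidate set for covariate selection
#'
#' Six candidate specifications spanning the usual questions: does dropping
#' the osteophyte score help, does each trait carry independent signal, and is
#' a sex-dependent residual scale warranted.
#'
#' @return List of [model_spec()] objects.
#' @export
default_model_set <- function() {
  list(
    model_spec(TRUE, TRUE, FALSE, TRUE, sex_sigma = TRUE),
    model_spec(TRUE, TRUE, TRUE, TRUE, sex_sigma = TRUE),
    model_spec(TRUE, TRUE, FALSE, TRUE, sex_sigma = FALSE),
    model_spec(TRUE, TRUE, FALSE, FALSE, sex_sigma = FALSE),
    model_spec(TRUE, FALSE, FALSE, TRUE, sex_sigma = TRUE),
    model_spec(FALSE, TRUE, FALSE, TRUE, sex_sigma = TRUE)
  )
}

#' Fit and rank candidate age-regression models by AIC
#'
#' Fits each specification by maximum likelihood and reports the AIC, the
#' estimated residual scales and (when a test set is supplied) the blind-test
#' RMSE, sorted ascending by AIC.  The minimum-AIC row is flagged as
#' recommended.  A specification that fails to fit gets an `error` note
#' instead of aborting the comparison.
#'
#' @param records training records (both sexes, known ages >= `lower`).
#' @param specs list of [model_spec()] objects (default [default_model_set()]).
#' @param test optional held-out records for RMSE.
#' @param lower truncation bound passed to [trunc_lm()].
#' @return A `model_comparison` data frame with one row per spec, sorted by
#'   AIC; fitted objects are attached as attribute `"fits"` (in input order).
#' @export
compare_models <- function(records, specs = default_model_set(), test = NULL,
                           lower = 40) {
  if (length(specs) < 2) stop("need at least two specs to compare",
                              call. = FALSE)
  if (inherits(specs, "model_spec")) specs <- list(specs)
  records <- as.data.frame(records)
  if (any(vapply(specs, function(s) isTRUE(s$collection), logical(1)))) {
    if (is.null(records$collection)) {
      stop("a spec includes collection effects but records has no collection",
           call. = FALSE)
    }
  }
  fits <- vector("list", length(specs))
  rows <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    dat <- records
    if (isTRUE(s$collection)) {
      ref <- s$collection_ref %||% sort(unique(dat$collection))[1]
      dat$collection <- stats::relevel(factor(dat$collection), ref = ref)
    }
    fit <- tryCatch(trunc_lm(s$formula, dat, sex_sigma = s$sex_sigma,
                             lower = lower),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      return(data.frame(topography = s$topography, porosity = s$porosity,
                        osteophytes = s$osteophytes, sex = s$sex,
                        collection = s$collection, sex_sigma = s$sex_sigma,
                        k = NA, loglik = NA, aic = NA, sigma_male = NA,
                        sigma_female = NA, rmse = NA,
                        error = conditionMessage(fit)))
    }
    fits[[i]] <<- fit
    sig <- fit$sigma
    data.frame(
      topography = s$topography, porosity = s$porosity,
      osteophytes = s$osteophytes, sex = s$sex, collection = s$collection,
      sex_sigma = s$sex_sigma, k = fit$k, loglik = fit$loglik, aic = fit$aic,
      sigma_male = unname(if (s$sex_sigma) sig["male"] else sig["pooled"]),
      sigma_female = unname(if (s$sex_sigma) sig["female"] else sig["pooled"]),
      rmse = if (is.null(test)) NA_real_ else rmse_on_test(fit, test),
      error = NA_character_
    )
  })
  out <- do.call(rbind, rows)
  out$spec <- seq_along(specs)
  out <- out[order(out$aic), ]
  out$delta_aic <- out$aic - min(out$aic, na.rm = TRUE)
  # exactly one recommendation even under AIC ties (first after sorting)
  out$recommended <- seq_len(nrow(out)) == which.min(out$aic)
  rownames(out) <- NULL
  structure(out, fits = fits, specs = specs,
            class = c("model_comparison", "data.frame"))
}

#' @export
print.model_comparison <- function(x, digits = 2, ...) {
  cat("Candidate age-regression models, ordered by AIC (lower is better)\n")
  df <- as.data.frame(x)
  flag <- function(v) ifelse(v, "yes", "no")
  show <- data.frame(
    topo = flag(df$topography), poro = flag(df$porosity),
    osteo = flag(df$osteophytes), sex = flag(df$sex),
    `sex sd` = flag(df$sex_sigma), k = df$k,
    AIC = round(df$aic, 1), dAIC = round(df$delta_aic, 1),
    `sd M` = round(df$sigma_male, digits),
    `sd F` = round(df$sigma_female, digits),
    RMSE = round(df$rmse, digits),
    check.names = FALSE
  )
  show$" " <- ifelse(df$recommended, "<- recommended", "")
  print(show, row.names = FALSE)
  invisible(x)
}
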