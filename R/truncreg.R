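# Truncated-normal regression of age on degeneration traits.
#
# The training samples contain only individuals of known age >= 40, so an
# ordinary normal residual would put probability mass on impossible ages.
# The model keeps the linear predictor mu = X beta but restricts the residual
# so that age >= `lower` (40 years): the residual is a normal with location
# zero truncated, per record, to epsilon > lower - mu.  The residual scale may
# differ by sex (female age is harder to estimate from this joint surface).

# log-density helpers --------------------------------------------------------

#' Log-likelihood of ages under the lower-truncated normal regression
#'
#' For each record, the contribution is
#' `log phi((y - mu)/sigma) - log sigma - log(1 - Phi((lower - mu)/sigma))`;
#' the last term renormalizes the density to the ages actually observable
#' (`y >= lower`).  With `lower = -Inf` this reduces to the ordinary normal
#' log-likelihood.
#'
#' @param y observed ages (all `>= lower`).
#' @param mean linear-predictor values, recycled against `y`.
#' @param sd residual scale(s), strictly positive, recycled against `y`.
#' @param lower truncation bound in years (default 40).
#' @return The summed log-likelihood (a single number).
#' @export
truncnorm_loglik <- function(y, mean, sd, lower = 40) {
  if (any(sd <= 0)) stop("sd must be strictly positive", call. = FALSE)
  if (any(y < lower)) stop("all ages must be >= the truncation bound", call. = FALSE)
  sum(stats::dnorm(y, mean, sd, log = TRUE) -
        stats::pnorm(lower, mean, sd, lower.tail = FALSE, log.p = TRUE))
}

# draws from a lower-truncated normal (inverse-CDF; adequate for the mild
# truncation this application sees)
rtnorm <- function(n, mean, sd, lower) {
  plo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, plo, 1)
  q <- stats::qnorm(u, mean, sd)
  pmax(q, lower)  # guard against u == plo rounding
}

# mean of a lower-truncated normal: mu + sd * phi(a)/(1 - Phi(a)), a = (L-mu)/sd
etnorm <- function(mean, sd, lower) {
  a <- (lower - mean) / sd
  # hazard of the standard normal, computed on the log scale for stability
  lambda <- exp(stats::dnorm(a, log = TRUE) -
                  stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
  mean + sd * lambda
}

# fitting ---------------------------------------------------------------------

#' Fit a truncated-normal regression of age on degeneration traits
#'
#' Maximum-likelihood fit of `age = X beta + epsilon` where `epsilon` is
#' normal with location zero, truncated so that age >= `lower` (40 years by
#' default, the lower bound of the training samples).  The residual standard
#' deviation is sex-specific by default.  Optimization is deterministic:
#' starting values come from the ordinary least-squares fit and scales are
#' optimized on the log scale.
#'
#' @param formula model formula, e.g.
#'   `age ~ topography + porosity + sex`.  The sex covariate is dummy-coded
#'   male = 1, female = 0.
#' @param data data frame containing the model variables; must also contain a
#'   `sex` column when `sex_sigma = TRUE`.
#' @param sex_sigma logical; estimate separate residual scales for males and
#'   females (default `TRUE`).
#' @param lower truncation bound in years (default 40).  `-Inf` gives an
#'   ordinary normal regression.
#' @param control list passed to [stats::optim()] (`method = "BFGS"`).
#' @return An object of class `"trunc_lm"` with components `coefficients`,
#'   `sigma` (named vector, `male`/`female` or `pooled`), `loglik`, `k`
#'   (free-parameter count), `aic`, `se` (delta-method standard errors for all
#'   parameters including the scales), `vcov` (on the internal scale), and
#'   bookkeeping needed by the methods.
#' @seealso [predict.trunc_lm()], [compare_models()], [blind_test_regression()]
#' @examples
#' cohort <- simulate_regression_cohort(seed = 1)
#' fit <- trunc_lm(age ~ topography + porosity + sex, cohort)
#' summary(fit)
#' @export
trunc_lm <- function(formula, data, sex_sigma = TRUE, lower = 40,
                     control = list(maxit = 500, reltol = 1e-12)) {
  cl <- match.call()
  data <- as.data.frame(data)
  uses_sex <- "sex" %in% all.vars(formula) || sex_sigma
  if (uses_sex) {
    if (is.null(data$sex)) stop("data must contain a sex column", call. = FALSE)
    data$sex <- normalize_sex(data$sex, allow_unknown = FALSE)
  }
  mf <- stats::model.frame(formula, data)
  mt <- attr(mf, "terms")
  y <- stats::model.response(mf)
  X <- stats::model.matrix(mt, mf)
  if (any(y < lower)) {
    stop("all training ages must be >= the truncation bound (", lower, ")",
         call. = FALSE)
  }
  p <- ncol(X)
  male <- if (sex_sigma) {
    data$sex[match(rownames(mf), rownames(data))] == "male"
  } else NULL
  if (sex_sigma && (!any(male) || all(male))) {
    stop("sex_sigma = TRUE requires both sexes in the training data",
         call. = FALSE)
  }

  # OLS starting values
  ols <- stats::lm.fit(X, y)
  beta0 <- ols$coefficients
  beta0[is.na(beta0)] <- 0
  r <- y - drop(X %*% beta0)
  logsig0 <- if (sex_sigma) {
    log(c(max(stats::sd(r[male]), 1e-3), max(stats::sd(r[!male]), 1e-3)))
  } else {
    log(max(stats::sd(r), 1e-3))
  }
  par0 <- c(beta0, logsig0)
  n_sig <- length(logsig0)

  negll <- function(par) {
    mu <- drop(X %*% par[seq_len(p)])
    sig <- if (sex_sigma) {
      ifelse(male, exp(par[p + 1L]), exp(par[p + 2L]))
    } else {
      exp(par[p + 1L])
    }
    ll <- sum(stats::dnorm(y, mu, sig, log = TRUE) -
                stats::pnorm(lower, mu, sig, lower.tail = FALSE, log.p = TRUE))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  opt <- stats::optim(par0, negll, method = "BFGS", control = control)
  if (opt$convergence != 0) {
    stop("trunc_lm did not converge (optim code ", opt$convergence,
         if (nzchar(opt$message %||% "")) paste0(": ", opt$message), ")",
         call. = FALSE)
  }
  hess <- stats::optimHess(opt$par, negll)
  vc <- tryCatch(solve(hess), error = function(e) matrix(NA_real_, length(par0),
                                                         length(par0)))
  par_names <- c(colnames(X),
                 if (sex_sigma) c("log_sigma_male", "log_sigma_female")
                 else "log_sigma")
  dimnames(vc) <- list(par_names, par_names)
  se <- sqrt(pmax(diag(vc), 0))

  beta <- opt$par[seq_len(p)]
  names(beta) <- colnames(X)
  sigma <- if (sex_sigma) {
    c(male = exp(opt$par[p + 1L]), female = exp(opt$par[p + 2L]))
  } else {
    c(pooled = exp(opt$par[p + 1L]))
  }
  # delta method: se(sigma) = sigma * se(log sigma)
  sigma_se <- sigma * se[p + seq_len(n_sig)]
  loglik <- -opt$value
  k <- p + n_sig

  structure(list(
    coefficients = beta,
    sigma = sigma,
    sigma_se = sigma_se,
    loglik = loglik,
    k = k,
    aic = 2 * k - 2 * loglik,
    se = stats::setNames(se, par_names),
    vcov = vc,
    lower = lower,
    sex_sigma = sex_sigma,
    nobs = length(y),
    terms = mt,
    xlevels = stats::.getXlevels(mt, mf),
    model = mf,
    data_sex = if (sex_sigma) factor(ifelse(male, "male", "female"),
                                     levels = .sex_levels) else NULL,
    formula = formula,
    call = cl,
    optim = opt[c("counts", "convergence")]
  ), class = "trunc_lm")
}

# methods ---------------------------------------------------------------------

#' @export
print.trunc_lm <- function(x, digits = 4, ...) {
  cat("Truncated-normal age regression (age >=", x$lower, "years)\n")
  cat("Call: ", deparse(x$call), "\n\n")
  cat("Coefficients (years per unit):\n")
  print(round(x$coefficients, digits))
  cat("\nResidual SD (years): ",
      paste(names(x$sigma), round(x$sigma, digits + 1), sep = " = ",
            collapse = ", "), "\n")
  cat("logLik ", format(x$loglik, digits = 7), "  k ", x$k,
      "  AIC ", format(x$aic, digits = 7), "  n ", x$nobs, "\n", sep = "")
  invisible(x)
}

#' @export
summary.trunc_lm <- function(object, ...) {
  p <- length(object$coefficients)
  est <- object$coefficients
  se <- object$se[seq_len(p)]
  z <- est / se
  coef_table <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
                      `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  sig_table <- cbind(Estimate = object$sigma, `Std. Error` = object$sigma_se)
  structure(list(call = object$call, coefficients = coef_table,
                 sigma = sig_table, loglik = object$loglik, k = object$k,
                 aic = object$aic, nobs = object$nobs, lower = object$lower),
            class = "summary.trunc_lm")
}

#' @export
print.summary.trunc_lm <- function(x, ...) {
  cat("Truncated-normal age regression (age >=", x$lower, "years)\n")
  cat("Call: ", deparse(x$call), "\n\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nResidual SD (years):\n")
  print(round(x$sigma, 4))
  cat("\nlogLik ", format(x$loglik, digits = 7), "  k ", x$k,
      "  AIC ", format(x$aic, digits = 7), "  n ", x$nobs, "\n", sep = "")
  invisible(x)
}

#' @export
coef.trunc_lm <- function(object, ...) object$coefficients

#' @export
vcov.trunc_lm <- function(object, ...) object$vcov

#' @export
nobs.trunc_lm <- function(object, ...) object$nobs

#' @export
logLik.trunc_lm <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$nobs,
            class = "logLik")
}

# per-record residual scale for new data
sigma_for <- function(object, sex) {
  if (!object$sex_sigma) {
    return(rep(unname(object$sigma["pooled"]), length(sex)))
  }
  if (is.null(sex)) {
    stop("newdata must contain a sex column for a sex-dependent-scale fit",
         call. = FALSE)
  }
  sex <- normalize_sex(sex, allow_unknown = TRUE)
  if (any(sex == "unknown", na.rm = TRUE)) {
    stop("sex is unknown but the fit uses sex-dependent residual scales; ",
         "refit with sex_sigma = FALSE (and without a sex covariate)",
         call. = FALSE)
  }
  unname(object$sigma[ifelse(sex == "male", "male", "female")])
}

#' Predict age from a fitted truncated-normal regression
#'
#' @param object a [trunc_lm()] fit.
#' @param newdata data frame with the model covariates (and `sex` when the
#'   fit has sex-dependent scales).  Omitted: the training data are used.
#' @param interval `"none"` for point estimates or `"prediction"` to add the
#'   normal-approximation interval `fit +/- z * sigma_sex` (unrounded years).
#' @param level interval coverage (default 0.95, i.e. z = 1.96).
#' @param type `"link"` (default) returns the linear predictor, the form of
#'   the published aging equations; `"conditional"` returns the mean of the
#'   truncated residual distribution, `E[age | age >= lower]`, which differs
#'   appreciably only when the linear predictor sits near the bound.
#' @param ... unused.
#' @return A numeric vector, or with `interval = "prediction"` a data frame
#'   with columns `fit`, `lwr`, `upr`.
#' @export
predict.trunc_lm <- function(object, newdata = NULL,
                             interval = c("none", "prediction"),
                             level = 0.95,
                             type = c("link", "conditional"), ...) {
  interval <- match.arg(interval)
  type <- match.arg(type)
  if (is.null(newdata)) {
    mf <- object$model
    sex <- object$data_sex
  } else {
    newdata <- as.data.frame(newdata)
    if ("sex" %in% names(newdata)) {
      newdata$sex <- normalize_sex(newdata$sex,
                                   allow_unknown = !object$sex_sigma)
      if (!object$sex_sigma) {
        # sex-free fit: drop unknowns to the factor used at fit time if the
        # covariate was not in the model
        if ("sex" %in% all.vars(object$formula) &&
            any(newdata$sex == "unknown")) {
          stop("sex is unknown but the fit includes a sex covariate",
               call. = FALSE)
        }
      }
    }
    mf <- stats::model.frame(stats::delete.response(object$terms), newdata,
                             xlev = object$xlevels)
    sex <- if (!is.null(newdata$sex)) newdata$sex else NULL
  }
  X <- stats::model.matrix(stats::delete.response(object$terms), mf,
                           xlev = object$xlevels)
  mu <- drop(X %*% object$coefficients)
  sig <- if (object$sex_sigma) sigma_for(object, sex) else
    rep(unname(object$sigma["pooled"]), length(mu))
  est <- if (type == "conditional") etnorm(mu, sig, object$lower) else mu
  if (interval == "none") return(est)
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(fit = est, lwr = est - z * sig, upr = est + z * sig)
}

#' Point and interval age estimate for a single set of trait scores
#'
#' Convenience wrapper around [predict.trunc_lm()] taking the three grades
#' directly.
#'
#' @inheritParams composite_score
#' @param fit a [trunc_lm()] fit.
#' @param sex `"male"`, `"female"`, or `"unknown"` (the latter only for
#'   sex-free fits).
#' @param level interval coverage (default 0.95).
#' @return One-row data frame with columns `fit`, `lwr`, `upr` (years,
#'   unrounded).
#' @export
predict_age <- function(fit, topography, porosity, osteophytes,
                        sex = "unknown", level = 0.95) {
  check_grades(topography, porosity, osteophytes)
  nd <- data.frame(topography = topography, porosity = porosity,
                   osteophytes = osteophytes, sex = sex)
  predict(fit, nd, interval = "prediction", level = level)
}

#' @export
residuals.trunc_lm <- function(object, type = c("response", "quantile"), ...) {
  type <- match.arg(type)
  y <- stats::model.response(object$model)
  X <- stats::model.matrix(object$terms, object$model)
  mu <- drop(X %*% object$coefficients)
  if (type == "response") return(y - mu)
  # randomized-free quantile residuals: Phi^-1 of the truncated CDF at y
  sig <- if (object$sex_sigma) sigma_for(object, object$data_sex) else
    rep(unname(object$sigma["pooled"]), length(mu))
  plo <- stats::pnorm(object$lower, mu, sig)
  u <- (stats::pnorm(y, mu, sig) - plo) / (1 - plo)
  stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
}

#' @export
fitted.trunc_lm <- function(object, ...) {
  predict(object)
}

#' Simulate ages from a fitted truncated-normal regression
#'
#' Draws ages from the fitted truncated normal, conditional on the covariates
#' (training covariates by default).
#'
#' @param object a [trunc_lm()] fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param newdata optional covariate data frame.
#' @param ... unused.
#' @return Data frame with `nsim` columns (`sim_1`, ...).
#' @export
simulate.trunc_lm <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                              ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object, newdata = newdata)
  sig <- if (is.null(newdata)) {
    if (object$sex_sigma) sigma_for(object, object$data_sex) else
      rep(unname(object$sigma["pooled"]), length(mu))
  } else {
    if (object$sex_sigma) sigma_for(object, newdata$sex) else
      rep(unname(object$sigma["pooled"]), length(mu))
  }
  out <- as.data.frame(replicate(nsim, rtnorm(length(mu), mu, sig,
                                              object$lower)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.trunc_lm <- function(x, ...) {
  y <- stats::model.response(x$model)
  mu <- predict(x)
  rq <- residuals(x, type = "quantile")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(mu, y, xlab = "Predicted age (years)",
                 ylab = "Known age (years)",
                 main = "Known vs predicted age", ...)
  graphics::abline(0, 1, lty = 2)
  stats::qqnorm(rq, main = "Quantile residuals")
  stats::qqline(rq, lty = 2)
  invisible(x)
}

#' Root-mean-squared prediction error on a test set
#'
#' @param fit a [trunc_lm()] fit.
#' @param records test records with known `age` and the fit's covariates.
#' @return RMSE in years.
#' @export
rmse_on_test <- function(fit, records) {
  if (!nrow(records)) stop("test set is empty", call. = FALSE)
  check_records(records, cols = "age")
  pred <- predict(fit, records)
  sqrt(mean((pred - records$age)^2))
}
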