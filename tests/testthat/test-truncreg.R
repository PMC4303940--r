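test_that("truncated log-likelihood matches closed forms and quadrature", {
  # single record at its own mean, unit scale, far from the bound:
  # log phi(0) = -log sqrt(2 pi)
  expect_equal(truncnorm_loglik(60, 60, 1, lower = 40), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  # removing the bound recovers the ordinary normal log-likelihood
  y <- c(45, 52, 60, 71, 88)
  mu <- c(48, 50, 63, 70, 90)
  expect_equal(truncnorm_loglik(y, mu, 10, lower = -Inf),
               sum(dnorm(y, mu, 10, log = TRUE)), tolerance = 1e-12)
  # five hand-made records against the quadrature oracle
  expect_equal(truncnorm_loglik(y, mu, 10, lower = 40),
               oracle_trunc_loglik(y, mu, 10, 40), tolerance = 1e-8)
  # truncation close to the data: the term matters and still matches
  mu2 <- c(41, 43, 40.5, 47, 44)
  expect_equal(truncnorm_loglik(y, mu2, 6, lower = 40),
               oracle_trunc_loglik(y, mu2, 6, 40), tolerance = 1e-8)
  # renormalizing to y >= bound can only raise the log-density of observed y
  expect_gte(truncnorm_loglik(y, mu2, 6, lower = 40),
             sum(dnorm(y, mu2, 6, log = TRUE)))
  expect_error(truncnorm_loglik(c(39, 50), c(50, 50), 5), "truncation bound")
  expect_error(truncnorm_loglik(50, 50, 0), "positive")
})

test_that("fit agrees with OLS when truncation is irrelevant", {
  dat <- withr::with_seed(301, {
    n <- 400
    d <- data.frame(topography = sample(1:6, n, TRUE),
                    porosity = sample(1:6, n, TRUE),
                    sex = sample(c("male", "female"), n, TRUE))
    d$age <- 200 + 4 * d$topography + 2 * d$porosity + rnorm(n, 0, 5)
    d
  })
  fit <- trunc_lm(age ~ topography + porosity, dat, sex_sigma = FALSE,
                  lower = 40)
  ols <- lm(age ~ topography + porosity, dat)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-3)
  # ML variance is the 1/n variant; compare against its square root
  sd_ml <- sqrt(mean(residuals(ols)^2))
  expect_equal(unname(fit$sigma["pooled"]), sd_ml, tolerance = 1e-3)
})

test_that("likelihood is additive: duplicating the data doubles logLik", {
  co <- simulate_regression_cohort(seed = 302)
  fit1 <- trunc_lm(age ~ topography + porosity + sex, co)
  fit2 <- trunc_lm(age ~ topography + porosity + sex, rbind(co, co))
  expect_equal(unname(coef(fit2)), unname(coef(fit1)), tolerance = 1e-4)
  expect_equal(fit2$loglik, 2 * fit1$loglik, tolerance = 1e-5)
})

test_that("AIC bookkeeping counts every free parameter", {
  co <- simulate_regression_cohort(seed = 303)
  fit <- trunc_lm(age ~ topography + porosity + sex, co)  # 4 betas + 2 sigmas
  expect_identical(fit$k, 6L + 0L)
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$loglik)
  expect_equal(AIC(fit), fit$aic)
  pooled <- trunc_lm(age ~ topography + porosity + sex, co, sex_sigma = FALSE)
  expect_identical(pooled$k, 5L + 0L)
  # the larger model can only improve the likelihood
  bigger <- trunc_lm(age ~ topography + porosity + osteophytes + sex, co)
  expect_gte(bigger$loglik, fit$loglik - 1e-6)
})

test_that("fitting is deterministic", {
  co <- simulate_regression_cohort(seed = 304)
  f1 <- trunc_lm(age ~ topography + porosity + sex, co)
  f2 <- trunc_lm(age ~ topography + porosity + sex, co)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$sigma, f2$sigma)
})

test_that("predictions follow the linear predictor and sex-specific interval", {
  co <- simulate_regression_cohort(seed = 305)
  fit <- trunc_lm(age ~ topography + porosity + sex, co)
  b <- coef(fit)
  nd <- data.frame(topography = 4, porosity = 3,
                   sex = c("male", "female"))
  pr <- predict(fit, nd, interval = "prediction")
  mu_m <- b["(Intercept)"] + 4 * b["topography"] + 3 * b["porosity"] +
    b["sexmale"]
  expect_equal(pr$fit[1], unname(mu_m), tolerance = 1e-10)
  # male and female estimates differ by exactly the sex coefficient
  expect_equal(pr$fit[1] - pr$fit[2], unname(b["sexmale"]), tolerance = 1e-10)
  expect_equal(pr$upr[1] - pr$fit[1], 1.96 * unname(fit$sigma["male"]),
               tolerance = 1e-3)
  expect_equal(pr$upr[2] - pr$fit[2], 1.96 * unname(fit$sigma["female"]),
               tolerance = 1e-3)
  # predict_age wrapper agrees
  pa <- predict_age(fit, 4, 3, 2, sex = "male")
  expect_equal(pa$fit, pr$fit[1])
})

test_that("sex unknown is rejected by sex-dependent fits and served by sex-free fits", {
  co <- simulate_regression_cohort(seed = 306)
  fit_sex <- trunc_lm(age ~ topography + porosity + sex, co)
  nd <- data.frame(topography = 4, porosity = 3, osteophytes = 2,
                   sex = "unknown")
  expect_error(predict(fit_sex, nd), "unknown")
  fit_free <- trunc_lm(age ~ topography + porosity, co, sex_sigma = FALSE)
  expect_silent(pr <- predict(fit_free, nd, interval = "prediction"))
  expect_true(pr$lwr < pr$fit && pr$fit < pr$upr)
})

test_that("linear predictor and truncated conditional mean agree away from the bound", {
  # mu = 75, sigma = 10: E[Y | Y >= 40] exceeds mu by sigma * hazard(-3.5)
  lam <- dnorm(-3.5) / (1 - pnorm(-3.5))
  expect_lt(10 * lam, 0.01)
  co <- simulate_regression_cohort(seed = 307)
  fit <- trunc_lm(age ~ topography + porosity + sex, co)
  nd <- data.frame(topography = 5, porosity = 5, sex = "male")
  link <- predict(fit, nd)
  cond <- predict(fit, nd, type = "conditional")
  mu <- unname(link); sig <- unname(fit$sigma["male"])
  a <- (40 - mu) / sig
  expect_equal(unname(cond - link), sig * dnorm(a) / (1 - pnorm(a)),
               tolerance = 1e-8)
})

test_that("simulated ages respect the bound and the fitted scales", {
  co <- simulate_regression_cohort(seed = 308)
  fit <- trunc_lm(age ~ topography + porosity + sex, co)
  sims <- simulate(fit, nsim = 3, seed = 99)
  expect_true(all(sims >= fit$lower))
  expect_identical(dim(sims), c(fit$nobs, 3L))
})

test_that("RMSE reduces to the expected closed forms", {
  co <- simulate_regression_cohort(seed = 309)
  fit <- trunc_lm(age ~ topography + porosity + sex, co)
  perfect <- co
  perfect$age <- predict(fit, co)
  expect_equal(rmse_on_test(fit, perfect), 0, tolerance = 1e-12)
  shifted <- perfect
  shifted$age <- shifted$age + 5
  expect_equal(rmse_on_test(fit, shifted), 5, tolerance = 1e-12)
  expect_error(rmse_on_test(fit, co[0, ]), "empty")
})

test_that("quantile residuals of a well-specified fit look standard normal", {
  co <- simulate_regression_cohort(seed = 310)
  fit <- trunc_lm(age ~ topography + porosity + sex, co)
  rq <- residuals(fit, type = "quantile")
  expect_equal(mean(rq), 0, tolerance = 0.15)
  expect_equal(sd(rq), 1, tolerance = 0.15)
  expect_gt(shapiro.test(rq)$p.value, 0.001)
})

test_that("model comparison ranks by AIC and reports per-spec errors", {
  co <- simulate_regression_cohort(seed = 311)
  specs <- list(model_spec(TRUE, TRUE, FALSE, TRUE),
                model_spec(TRUE, TRUE, FALSE, TRUE),
                model_spec(FALSE, TRUE, FALSE, TRUE))
  cmp <- compare_models(co, specs)
  df <- as.data.frame(cmp)
  expect_true(!is.unsorted(df$aic))
  # identical specs produce identical rows
  dup <- df[df$topography & df$porosity, ]
  expect_equal(dup$aic[1], dup$aic[2], tolerance = 1e-8)
  expect_identical(sum(df$recommended), 1L)
  expect_error(compare_models(co, specs[1]), "at least two")
})

test_that("sex-free and sex-dependent fits coincide when sex truly plays no role", {
  cfg <- synthetic_config(sex_age_offset = 0, sigma_male = 9, sigma_female = 9)
  co <- simulate_regression_cohort(cfg, coef = c(`(Intercept)` = 38,
                                                 topography = 4,
                                                 porosity = 2.5,
                                                 sexmale = 0),
                                   seed = 312)
  fit_free <- trunc_lm(age ~ topography + porosity, co, sex_sigma = FALSE)
  fit_sex <- trunc_lm(age ~ topography + porosity + sex, co)
  expect_equal(coef(fit_sex)[c("topography", "porosity")],
               coef(fit_free)[c("topography", "porosity")], tolerance = 0.05)
  expect_lt(abs(coef(fit_sex)["sexmale"]), 3 * fit_sex$se["sexmale"])
})
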