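# Synthetic skeletal-collection generator.
#
# Emulates the statistical structure the analyses assume, not anatomy: ages
# drawn per decade bin at configured counts; a shared latent degeneration
# level rising with age (females reaching the same morphology a few years
# later); per-trait loadings and noise so topography tracks the latent level
# most tightly; ordinal grades via fixed cut-points; bilateral correlation
# with an optional per-collection left-right bias; left-side missingness.
# Grade 0 ("element not present") is modelled by dropping rows, never by
# generating zeros.

#' Configuration of a synthetic skeletal-collection cohort
#'
#' Defaults mirror the documented reference collections: the per-collection,
#' per-sex decade-bin counts of [reference_age_composition()] (318 male / 246
#' female right clavicles), ages 40--96, a 3.7-year female offset (a female
#' reaches the same degeneration about 3.7 years later than a male), residual
#' age scales 8.56 (male) / 10.38 (female) years for the model-based
#' generator, and a small left-right bias confined to the CC collection to
#' emulate its documented asymmetry.
#'
#' @param counts data frame `collection`, `sex`, `bin`, `n` (bins
#'   `"40-49"`, ..., `"80+"`).
#' @param age_max cap of the open 80+ bin (years).
#' @param sex_age_offset years by which a female is older than a male at
#'   equal trait expression.
#' @param sigma_male,sigma_female residual age scales (years) used by
#'   [simulate_regression_cohort()].
#' @param shared_sd SD (years) of the shared latent degeneration noise.
#' @param trait_sd named numeric: per-trait latent noise SDs (years); smaller
#'   means the trait tracks age more tightly.  The default gives topography
#'   the strongest age correlation.
#' @param loadings named numeric: per-trait multipliers on the shared latent
#'   level.
#' @param cutpoints named list of strictly increasing cut-points (latent
#'   years-since-40 scale) mapping the latent level to ordinal grades
#'   (5 cut-points for the 6-grade traits, 3 for osteophytes).
#' @param bilateral_correlation probability a left grade equals the right
#'   grade exactly (otherwise it is perturbed by one grade).
#' @param asymmetry_shift named numeric per collection: probability of an
#'   extra +1 grade on the left side (emulates side asymmetry).
#' @param missing_left_rate probability the left element is absent.
#' @param seed optional integer seed stored in the config.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(counts = reference_age_composition(),
                             age_max = 96,
                             sex_age_offset = 3.7,
                             sigma_male = 8.56,
                             sigma_female = 10.38,
                             shared_sd = 9,
                             trait_sd = c(topography = 10, porosity = 16,
                                          osteophytes = 18),
                             loadings = c(topography = 1, porosity = 1,
                                          osteophytes = 1),
                             cutpoints = list(
                               topography = c(5, 15, 27, 41, 58),
                               porosity = c(9, 20, 33, 47, 60),
                               osteophytes = c(11, 33, 55)),
                             bilateral_correlation = 0.9,
                             asymmetry_shift = c(HT = 0, PBC = 0, SB = 0,
                                                 CC = 0.1),
                             missing_left_rate = 0.032,
                             seed = NULL) {
  stopifnot(all(counts$n >= 0), age_max > 40,
            sigma_male > 0, sigma_female > 0, shared_sd >= 0,
            all(trait_sd >= 0),
            bilateral_correlation >= 0, bilateral_correlation <= 1,
            missing_left_rate >= 0, missing_left_rate <= 1)
  stopifnot(identical(sort(names(cutpoints)), sort(.trait_cols)))
  for (nm in .trait_cols) {
    cp <- cutpoints[[nm]]
    if (is.unsorted(cp, strictly = TRUE)) {
      stop("cut-points must be strictly increasing for ", nm, call. = FALSE)
    }
    if (length(cp) != .grade_max[[nm]] - 1L) {
      stop(sprintf("%s needs %d cut-points for grades 1..%d", nm,
                   .grade_max[[nm]] - 1L, .grade_max[[nm]]), call. = FALSE)
    }
  }
  structure(list(counts = counts, age_max = age_max,
                 sex_age_offset = sex_age_offset, sigma_male = sigma_male,
                 sigma_female = sigma_female, shared_sd = shared_sd,
                 trait_sd = trait_sd, loadings = loadings,
                 cutpoints = cutpoints,
                 bilateral_correlation = bilateral_correlation,
                 asymmetry_shift = asymmetry_shift,
                 missing_left_rate = missing_left_rate, seed = seed),
            class = "synthetic_config")
}

bin_bounds <- function(bin, age_max) {
  if (bin == "80+") return(c(80L, as.integer(age_max)))
  b <- as.integer(strsplit(bin, "-", fixed = TRUE)[[1]])
  c(b[1], b[2])
}

grade_from_latent <- function(z, cutpoints) {
  findInterval(z, cutpoints) + 1L
}

clip_grade <- function(g, trait) {
  pmin(pmax(g, 1L), .grade_max[[trait]])
}

#' Simulate a documented-collection-style cohort
#'
#' Draws individuals per collection/sex/decade-bin at the configured counts
#' (integer ages uniform within each bin), generates right-side trait grades
#' through the latent degeneration mechanism, and adds correlated left-side
#' rows subject to the configured asymmetry bias and missingness.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed (defaults to `config$seed`); `NULL` leaves the
#'   RNG state alone.
#' @return Data frame with columns `id`, `collection`, `sex`, `side`, `age`,
#'   `topography`, `porosity`, `osteophytes`; the generating config is
#'   attached as attribute `"config"`.
#' @export
simulate_cohort <- function(config = synthetic_config(), seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  counts <- config$counts
  rows <- list()
  serial <- 0L
  for (i in seq_len(nrow(counts))) {
    n <- counts$n[i]
    if (n == 0) next
    b <- bin_bounds(counts$bin[i], config$age_max)
    ages <- b[1] + sample.int(b[2] - b[1] + 1L, n, replace = TRUE) - 1L
    ids <- sprintf("%s-%s-%04d", counts$collection[i],
                   toupper(substr(counts$sex[i], 1, 1)), serial + seq_len(n))
    serial <- serial + n
    rows[[i]] <- data.frame(id = ids, collection = counts$collection[i],
                            sex = counts$sex[i], age = ages)
  }
  ind <- do.call(rbind, rows)
  n <- nrow(ind)

  # shared latent degeneration level (years-since-40 scale); females reach the
  # same level sex_age_offset years later
  eff_age <- ind$age - ifelse(ind$sex == "female", config$sex_age_offset, 0)
  latent <- (eff_age - 40) + stats::rnorm(n, 0, config$shared_sd)

  right <- ind
  right$side <- "right"
  for (trait in .trait_cols) {
    z <- config$loadings[[trait]] * latent +
      stats::rnorm(n, 0, config$trait_sd[[trait]])
    right[[trait]] <- clip_grade(grade_from_latent(z, config$cutpoints[[trait]]),
                                 trait)
  }

  left <- right
  left$side <- "left"
  shift_p <- config$asymmetry_shift[as.character(ind$collection)]
  shift_p[is.na(shift_p)] <- 0
  for (trait in .trait_cols) {
    keep <- stats::runif(n) < config$bilateral_correlation
    perturb <- ifelse(keep, 0L, sample(c(-1L, 1L), n, replace = TRUE))
    bias <- as.integer(stats::runif(n) < shift_p)
    left[[trait]] <- clip_grade(right[[trait]] + perturb + bias, trait)
  }
  left <- left[stats::runif(n) >= config$missing_left_rate, , drop = FALSE]

  out <- rbind(right, left)
  out <- out[, c("id", "collection", "sex", "side", "age", .trait_cols)]
  rownames(out) <- NULL
  attr(out, "config") <- config
  out
}

#' Simulate a cohort whose ages follow the truncated-normal regression
#'
#' Generates a realistic trait/sex design via [simulate_cohort()] (right
#' sides only), then redraws each age from the truncated-normal regression
#' model given its covariates: `age ~ TN(mu, sigma_sex; age >= lower)` with
#' `mu = b0 + b_t * topography + b_p * porosity + b_o * osteophytes +
#' b_s * male`.  This is the parameter-recovery harness: the coefficients
#' and scales attached as attribute `"truth"` are, by construction, the true
#' generating values.
#'
#' @param config a [synthetic_config()]; supplies the design, the residual
#'   scales (`sigma_male`, `sigma_female`) and the sex offset (the default
#'   male coefficient is `-sex_age_offset`).
#' @param coef named coefficients of the linear predictor; names from
#'   `(Intercept)`, `topography`, `porosity`, `osteophytes`, `sexmale`.
#' @param lower truncation bound (years).
#' @param seed integer seed.
#' @return Right-side records data frame with attribute `"truth"` (list of
#'   `coef`, `sigma_male`, `sigma_female`, `lower`).
#' @export
simulate_regression_cohort <- function(config = synthetic_config(),
                                       coef = c(`(Intercept)` = 36,
                                                topography = 4.5,
                                                porosity = 2.5,
                                                osteophytes = 0,
                                                sexmale = -config$sex_age_offset),
                                       lower = 40, seed = config$seed) {
  cohort <- simulate_cohort(config, seed = seed)
  rights <- cohort[cohort$side == "right", , drop = FALSE]
  full <- c(`(Intercept)` = 0, topography = 0, porosity = 0, osteophytes = 0,
            sexmale = 0)
  full[names(coef)] <- coef
  mu <- unname(full["(Intercept)"]) +
    unname(full["topography"]) * rights$topography +
    unname(full["porosity"]) * rights$porosity +
    unname(full["osteophytes"]) * rights$osteophytes +
    unname(full["sexmale"]) * (rights$sex == "male")
  sig <- ifelse(rights$sex == "male", config$sigma_male, config$sigma_female)
  rights$age <- rtnorm(nrow(rights), mu, sig, lower)
  rownames(rights) <- NULL
  attr(rights, "truth") <- list(coef = full, sigma_male = config$sigma_male,
                                sigma_female = config$sigma_female,
                                lower = lower)
  attr(rights, "config") <- config
  rights
}

#' Simulate a multi-rater scoring panel
#'
#' Emulates an inter-observer study: true ordinal grades are drawn per
#' specimen and each rater reports the truth perturbed by a discretized
#' normal error with the given spread, clipped to the grade range.
#'
#' @param n_specimens,n_raters panel dimensions (each >= 2).
#' @param reliability_spread SD (grade units) of each rater's error;
#'   0 gives perfect agreement.  The default 0.5 is calibrated to the
#'   strong-agreement regime typical of the topography trait.
#' @param trait which trait's grade range to use.
#' @param seed optional integer seed.
#' @return Specimens x raters integer matrix with attributes `"trait"`,
#'   `"grades"` and `"truth"`.
#' @export
simulate_rater_panel <- function(n_specimens = 10, n_raters = 10,
                                 reliability_spread = 0.5,
                                 trait = c("topography", "porosity",
                                           "osteophytes"),
                                 seed = NULL) {
  trait <- match.arg(trait)
  stopifnot(n_specimens >= 2, n_raters >= 2, reliability_spread >= 0)
  if (!is.null(seed)) set.seed(seed)
  gmax <- .grade_max[[trait]]
  truth <- sample.int(gmax, n_specimens, replace = TRUE)
  panel <- vapply(seq_len(n_raters), function(r) {
    err <- round(stats::rnorm(n_specimens, 0, reliability_spread))
    clip_grade(truth + as.integer(err), trait)
  }, integer(n_specimens))
  dimnames(panel) <- list(paste0("specimen_", seq_len(n_specimens)),
                          paste0("rater_", seq_len(n_raters)))
  attr(panel, "trait") <- trait
  attr(panel, "grades") <- seq_len(gmax)
  attr(panel, "truth") <- truth
  panel
}
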