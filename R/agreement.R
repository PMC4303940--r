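# Observer agreement, bilateral symmetry, sex-difference and correlation
# statistics supporting validation of the scoring system.

agreement_result <- function(statistic, se = NA_real_, p = NA_real_,
                             df = NA_real_, method = "", note = NULL) {
  structure(list(statistic = unname(statistic), se = unname(se),
                 p = unname(p), df = unname(df), method = method,
                 note = note),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, digits = 4, ...) {
  cat(x$method, "\n  statistic = ", round(x$statistic, digits), sep = "")
  if (!is.na(x$se)) cat("  SE =", round(x$se, digits))
  if (!is.na(x$df)) cat("  df =", round(x$df, 2))
  if (!is.na(x$p)) cat("  p =", format.pval(x$p, digits = digits))
  cat("\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

kappa_weights <- function(grades, weighting) {
  d <- abs(outer(grades, grades, "-"))
  if (weighting == "quadratic") d^2 else d
}

#' Weighted Cohen's kappa for two raters of an ordinal trait
#'
#' Chance-corrected agreement between two raters scoring the same specimens
#' on an ordinal grade scale, using disagreement weights
#' `kappa = 1 - sum(w * O) / sum(w * E)` with `w` the linear (`|i - j|`) or
#' quadratic (`(i - j)^2`) weight over the full grade range, `O` the observed
#' and `E` the chance-expected joint proportions.
#'
#' @param rater_a,rater_b equal-length integer grade vectors (>= 2 specimens).
#' @param weighting `"linear"` (default) or `"quadratic"`.
#' @param grades the full ordinal grade set; defaults to the integer range
#'   spanned by the data, but should be the trait's full scale (e.g. `1:6`)
#'   so that chance agreement is computed over all possible grades.
#' @return An `agreement_result` (fields `statistic`, `se`, `p`, `df`,
#'   `note`).  Degenerate tables (no expected disagreement) give `NA` with an
#'   explanatory note rather than `NaN`.
#' @export
weighted_kappa <- function(rater_a, rater_b,
                           weighting = c("linear", "quadratic"),
                           grades = NULL) {
  weighting <- match.arg(weighting)
  if (length(rater_a) != length(rater_b) || length(rater_a) < 2) {
    stop("need two equal-length grade vectors with >= 2 specimens",
         call. = FALSE)
  }
  if (is.null(grades)) {
    grades <- seq(min(rater_a, rater_b), max(rater_a, rater_b))
  }
  fa <- factor(rater_a, levels = grades)
  fb <- factor(rater_b, levels = grades)
  if (anyNA(fa) || anyNA(fb)) stop("grades outside the declared grade set",
                                   call. = FALSE)
  n <- length(rater_a)
  O <- table(fa, fb) / n
  E <- outer(rowSums(O), colSums(O))
  w <- kappa_weights(grades, weighting)
  ew <- sum(w * E)
  if (ew == 0) {
    return(agreement_result(NA_real_, method = "Weighted Cohen's kappa",
                            note = "degenerate: no expected disagreement (single category)"))
  }
  agreement_result(1 - sum(w * O) / ew,
                   method = sprintf("Weighted Cohen's kappa (%s weights)",
                                    weighting))
}

#' Light's kappa: multi-rater agreement for an ordinal trait
#'
#' Extends weighted Cohen's kappa to more than two raters by averaging the
#' pairwise kappas over all rater pairs.  Pairs with degenerate tables are
#' dropped from the mean with a warning.
#'
#' @param panel specimens x raters matrix (or data frame) of ordinal grades,
#'   e.g. from [simulate_rater_panel()].
#' @inheritParams weighted_kappa
#' @return An `agreement_result`; `note` records dropped pairs, attribute
#'   `"pairwise"` holds the pairwise kappas.
#' @export
lights_kappa <- function(panel, weighting = c("linear", "quadratic"),
                         grades = NULL) {
  weighting <- match.arg(weighting)
  panel <- as.matrix(panel)
  if (ncol(panel) < 2) stop("need >= 2 raters", call. = FALSE)
  if (is.null(grades)) grades <- attr(panel, "grades") %||%
      seq(min(panel), max(panel))
  pairs <- utils::combn(ncol(panel), 2)
  ks <- apply(pairs, 2, function(idx) {
    weighted_kappa(panel[, idx[1]], panel[, idx[2]], weighting, grades)$statistic
  })
  dropped <- sum(is.na(ks))
  if (dropped > 0) {
    warning(dropped, " degenerate rater pair(s) dropped from Light's kappa")
  }
  res <- agreement_result(mean(ks, na.rm = TRUE),
                          method = sprintf("Light's kappa (%s weights, %d raters)",
                                           weighting, ncol(panel)),
                          note = if (dropped > 0)
                            paste(dropped, "degenerate pair(s) dropped"))
  attr(res, "pairwise") <- ks
  res
}

#' Bootstrap standard error of Light's kappa
#'
#' Resamples specimens (panel rows) with replacement and reports the standard
#' deviation of Light's kappa across replicates.
#'
#' @inheritParams lights_kappa
#' @param B number of bootstrap replicates (>= 100).
#' @param seed optional integer seed for reproducibility.
#' @return The bootstrap standard error (single number).
#' @export
bootstrap_kappa_se <- function(panel, weighting = c("linear", "quadratic"),
                               B = 1000, seed = NULL, grades = NULL) {
  weighting <- match.arg(weighting)
  panel <- as.matrix(panel)
  if (nrow(panel) < 2) stop("need >= 2 specimens to bootstrap", call. = FALSE)
  if (B < 100) stop("B must be >= 100", call. = FALSE)
  if (is.null(grades)) grades <- attr(panel, "grades") %||%
      seq(min(panel), max(panel))
  if (!is.null(seed)) set.seed(seed)
  reps <- vapply(seq_len(B), function(b) {
    idx <- sample.int(nrow(panel), replace = TRUE)
    suppressWarnings(lights_kappa(panel[idx, , drop = FALSE], weighting,
                                  grades)$statistic)
  }, numeric(1))
  stats::sd(reps, na.rm = TRUE)
}

#' Paired t-test for repeat scorings or left/right composite scores
#'
#' Classical paired t-test on within-pair differences, used both for
#' intra-observer repeatability (first vs second scoring of the same bones)
#' and for bilateral symmetry of composite scores.  A zero-variance nonzero
#' difference (every pair shifted by the same amount) is flagged degenerate
#' rather than reported as an infinite t.
#'
#' @param values_a,values_b equal-length numeric vectors; incomplete pairs
#'   (NA in either member) are dropped.
#' @return An `agreement_result` with `statistic` (t), `df` and `p`.
#' @export
paired_t_test <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  ok <- stats::complete.cases(values_a, values_b)
  d <- values_a[ok] - values_b[ok]
  if (length(d) < 2) stop("need >= 2 complete pairs", call. = FALSE)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(agreement_result(0, p = 1, df = length(d) - 1,
                              method = "Paired t-test",
                              note = "no within-pair variation"))
    }
    return(agreement_result(NA_real_, df = length(d) - 1,
                            method = "Paired t-test",
                            note = "degenerate: constant nonzero difference"))
  }
  tt <- stats::t.test(d)
  agreement_result(tt$statistic, p = tt$p.value, df = tt$parameter,
                   method = "Paired t-test")
}

#' Bonferroni correction for a family of m tests
#'
#' @param p uncorrected p-values.
#' @param m family size; defaults to the number of tests actually performed
#'   (`length(p)`).
#' @return `pmin(1, m * p)`.
#' @export
bonferroni_correct <- function(p, m = length(p)) pmin(1, m * p)

#' Female-male age differences per composite score
#'
#' For each composite score with at least `min_per_sex` individuals of each
#' sex, performs a Welch two-sample t-test of age between females and males
#' and reports the mean difference (female minus male), its 95% CI and the
#' two-tailed p-value before and after Bonferroni correction.  The correction
#' multiplies by the number of tests actually performed, not by the number of
#' possible composite values; untestable scores are reported as omitted.
#'
#' @param records data frame with `sex`, `age` and trait columns (one side).
#' @param min_per_sex minimum group size per sex to test a score (default 2).
#' @return Data frame with columns `composite`, `n`, `diff` (F - M years),
#'   `ci_lower`, `ci_upper`, `p`, `p_bonferroni`; attribute `"omitted"` lists
#'   untested scores and `"m"` the family size.
#' @export
sex_difference_by_score <- function(records, min_per_sex = 2) {
  check_records(records)
  sex <- normalize_sex(records$sex, allow_unknown = TRUE)
  comp <- record_composite(records)
  rows <- list(); omitted <- integer(0)
  for (s in 3:16) {
    af <- records$age[comp == s & sex == "female"]
    am <- records$age[comp == s & sex == "male"]
    if (length(af) < min_per_sex || length(am) < min_per_sex) {
      if (length(af) + length(am) > 0) omitted <- c(omitted, s)
      next
    }
    tt <- stats::t.test(af, am)
    rows[[length(rows) + 1L]] <- data.frame(
      composite = s, n = length(af) + length(am),
      diff = unname(diff(rev(tt$estimate))),  # mean(af) - mean(am)
      ci_lower = tt$conf.int[1], ci_upper = tt$conf.int[2],
      p = tt$p.value)
  }
  if (!length(rows)) stop("no composite score has both sexes represented",
                          call. = FALSE)
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni_correct(out$p)
  attr(out, "omitted") <- omitted
  attr(out, "m") <- nrow(out)
  out
}

# pooled-variance two-proportion z test
two_proportion_z <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  agreement_result(z, p = 2 * stats::pnorm(-abs(z)),
                   method = "Two-proportion z-test (pooled variance)")
}

#' Sex difference in bilateral trait asymmetry
#'
#' For each trait, classifies every individual with both sides scored as
#' having differing or equal grades on the two sides, then tests whether the
#' proportion with differences is the same for males and females using a
#' pooled-variance two-proportion z statistic (two-sided normal p-value).
#'
#' @param records data frame with `id`, `sex`, `side`, and trait columns;
#'   only individuals contributing a left and a right row are used.
#' @return Named list (one `agreement_result` per trait) with the z statistic
#'   and p-value; attributes record the per-sex proportions.
#' @export
side_asymmetry_test <- function(records) {
  check_records(records, cols = c("id", "sex", "side", .trait_cols))
  sexv <- normalize_sex(records$sex, allow_unknown = TRUE)
  out <- list()
  for (trait in .trait_cols) {
    wide <- stats::reshape(
      records[, c("id", "sex", "side", trait)],
      idvar = c("id", "sex"), timevar = "side", direction = "wide")
    l <- wide[[paste0(trait, ".left")]]
    r <- wide[[paste0(trait, ".right")]]
    ok <- !is.na(l) & !is.na(r) & l > 0 & r > 0
    wide <- wide[ok, ]; l <- l[ok]; r <- r[ok]
    differs <- l != r
    male <- wide$sex == "male"; female <- wide$sex == "female"
    if (!any(male) || !any(female)) {
      stop("both sexes need bilateral individuals for the asymmetry test",
           call. = FALSE)
    }
    res <- two_proportion_z(sum(differs[male]), sum(male),
                            sum(differs[female]), sum(female))
    attr(res, "proportions") <- c(male = mean(differs[male]),
                                  female = mean(differs[female]))
    out[[trait]] <- res
  }
  out
}

#' Spearman rank correlation between age and trait expression
#'
#' Rank correlation (midranks for ties) between known age and one trait grade
#' or the composite score, with a two-tailed p-value from the t
#' approximation.
#'
#' @param records data frame with `age` and trait columns.
#' @param feature `"topography"`, `"porosity"`, `"osteophytes"` or
#'   `"composite"`.
#' @return An `agreement_result` with `statistic` = r_s and `df` = n - 2.
#' @export
spearman_age_correlation <- function(records,
                                     feature = c("composite", "topography",
                                                 "porosity", "osteophytes")) {
  feature <- match.arg(feature)
  check_records(records)
  if (nrow(records) < 3) stop("need >= 3 records", call. = FALSE)
  x <- if (feature == "composite") record_composite(records)
       else records[[feature]]
  if (length(unique(x)) == 1) {
    return(agreement_result(NA_real_, method = "Spearman rank correlation",
                            note = "degenerate: feature is constant"))
  }
  ct <- suppressWarnings(
    stats::cor.test(records$age, x, method = "spearman", exact = FALSE))
  agreement_result(ct$estimate, p = ct$p.value, df = nrow(records) - 2,
                   method = sprintf("Spearman rank correlation (age vs %s)",
                                    feature))
}
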