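# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive statistics from first principles (explicit
# loops, direct formulas, quadrature) so they share no code with the package
# implementations they check.

# direct Welch two-sample t statistic / df / two-tailed p
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# weighted kappa by explicit enumeration of the contingency table
oracle_weighted_kappa <- function(a, b, grades, quadratic = FALSE) {
  n <- length(a)
  obs <- exp_ <- 0
  for (gi in grades) {
    for (gj in grades) {
      w <- if (quadratic) (gi - gj)^2 else abs(gi - gj)
      o <- sum(a == gi & b == gj) / n
      e <- (sum(a == gi) / n) * (sum(b == gj) / n)
      obs <- obs + w * o
      exp_ <- exp_ + w * e
    }
  }
  1 - obs / exp_
}

# truncated-normal log-likelihood with the normalizing constant obtained by
# numerical quadrature of the untruncated density (independent of pnorm-based
# implementation path)
oracle_trunc_loglik <- function(y, mu, sigma, lower) {
  sum(mapply(function(yi, mi, si) {
    z <- integrate(function(t) dnorm(t, mi, si), lower, Inf,
                   rel.tol = 1e-12)$value
    dnorm(yi, mi, si, log = TRUE) - log(z)
  }, y, mu, sigma))
}

# Spearman's rho via midranks and the product-moment formula on ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# records frame with given ages and composite-controlling grades; grades are
# chosen so that composite == target score
records_at_scores <- function(scores, ages, sex = "male", side = "right") {
  stopifnot(length(scores) == length(ages))
  grade_for <- function(s) {
    # decompose s in [3, 16] into valid grades (topo 1-6, poro 1-6, osteo 1-4)
    topo <- min(6L, s - 2L)
    rem <- s - topo
    poro <- min(6L, rem - 1L)
    osteo <- rem - poro
    c(topo, poro, osteo)
  }
  g <- t(vapply(as.integer(scores), grade_for, integer(3)))
  data.frame(id = sprintf("id%03d", seq_along(ages)), collection = "SYN",
             sex = sex, side = side, age = ages,
             topography = g[, 1], porosity = g[, 2], osteophytes = g[, 3])
}

# cohort of clearly separated age strata mapped onto blocks of composite
# scores, for stage-recovery tests
strata_cohort <- function(seed, strata_scores, strata_means, n_per_score = 20,
                          sd = 4) {
  withr::with_seed(seed, {
    rows <- lapply(seq_along(strata_scores), function(i) {
      scores <- rep(strata_scores[[i]], each = n_per_score)
      ages <- pmax(40, rnorm(length(scores), strata_means[i], sd))
      records_at_scores(scores, ages)
    })
    do.call(rbind, rows)
  })
}
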