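test_that("weighted kappa matches hand computation on a small grid", {
  a <- c(1, 2, 2, 4)
  b <- c(1, 3, 2, 3)
  for (w in c("linear", "quadratic")) {
    got <- weighted_kappa(a, b, w, grades = 1:4)$statistic
    want <- oracle_weighted_kappa(a, b, 1:4, quadratic = (w == "quadratic"))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("weighted kappa hits its reference points", {
  g <- c(1, 3, 2, 5, 6, 4, 2, 1)
  expect_equal(weighted_kappa(g, g, grades = 1:6)$statistic, 1)
  # independent ratings: near zero agreement beyond chance
  ab <- withr::with_seed(401, list(a = sample(1:6, 4000, TRUE),
                                   b = sample(1:6, 4000, TRUE)))
  k <- weighted_kappa(ab$a, ab$b, grades = 1:6)$statistic
  expect_lt(abs(k), 0.05)
  # degenerate table: flagged NA, not NaN
  res <- weighted_kappa(rep(2, 5), rep(2, 5), grades = 2)
  expect_true(is.na(res$statistic))
  expect_match(res$note, "degenerate")
})

test_that("Light's kappa is exactly the mean of pairwise kappas", {
  panel <- simulate_rater_panel(12, 3, 0.8, seed = 402)
  k12 <- weighted_kappa(panel[, 1], panel[, 2], grades = 1:6)$statistic
  k13 <- weighted_kappa(panel[, 1], panel[, 3], grades = 1:6)$statistic
  k23 <- weighted_kappa(panel[, 2], panel[, 3], grades = 1:6)$statistic
  expect_equal(lights_kappa(panel, grades = 1:6)$statistic,
               mean(c(k12, k13, k23)), tolerance = 1e-12)

  big <- simulate_rater_panel(10, 10, 0.5, seed = 403)
  pairs <- combn(10, 2)
  oracle <- mean(apply(pairs, 2, function(ix) {
    oracle_weighted_kappa(big[, ix[1]], big[, ix[2]], 1:6)
  }))
  expect_equal(lights_kappa(big, grades = 1:6)$statistic, oracle,
               tolerance = 1e-12)
  # all raters identical
  same <- matrix(rep(c(1, 3, 5, 2, 6), 4), ncol = 4)
  expect_equal(lights_kappa(same, grades = 1:6)$statistic, 1)
})

test_that("bootstrap SE of Light's kappa is seeded, stable and zero when exact", {
  panel <- simulate_rater_panel(10, 10, 0.5, seed = 404)
  se1 <- bootstrap_kappa_se(panel, B = 300, seed = 5)
  se2 <- bootstrap_kappa_se(panel, B = 300, seed = 5)
  expect_identical(se1, se2)
  se_big <- bootstrap_kappa_se(panel, B = 600, seed = 5)
  expect_lt(abs(se_big - se1) / se_big, 0.2)
  # all raters identical on every resample -> SE exactly 0
  same <- matrix(rep(c(1, 3, 5, 2, 6), 4), ncol = 4)
  expect_equal(bootstrap_kappa_se(same, B = 100, seed = 1, grades = 1:6), 0)
  expect_error(bootstrap_kappa_se(panel[1, , drop = FALSE], B = 100, seed = 1),
               ">= 2 specimens")
  expect_error(bootstrap_kappa_se(panel, B = 50, seed = 1), "B must be")
})

test_that("paired t-test handles agreement, shift and noise correctly", {
  x <- c(2, 4, 3, 5, 1, 6)
  same <- paired_t_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  shifted <- paired_t_test(x + 1, x)
  expect_true(is.na(shifted$statistic))
  expect_match(shifted$note, "degenerate")
  ab <- withr::with_seed(405, list(a = rnorm(40, 10), b = rnorm(40, 10)))
  got <- paired_t_test(ab$a, ab$b)
  d <- ab$a - ab$b
  t_direct <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(got$statistic, t_direct, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(t_direct), length(d) - 1), tolerance = 1e-12)
})

test_that("Bonferroni correction floors at the uncorrected p and caps at 1", {
  p <- c(0.001, 0.3820, 0.9820, 0.004)
  corr <- bonferroni_correct(p, m = 11)
  expect_true(all(corr >= p))
  expect_true(all(corr <= 1))
  expect_equal(corr[2], 1)
  expect_equal(corr[3], 1)
  expect_equal(corr[1], 0.011)
})

test_that("per-score sex differences use the tests actually performed as the family", {
  co <- simulate_cohort(seed = 406)
  rights <- co[co$side == "right", ]
  tab <- sex_difference_by_score(rights)
  m <- attr(tab, "m")
  expect_identical(m, nrow(tab))
  expect_equal(tab$p_bonferroni, pmin(1, m * tab$p))
  # difference direction: synthetic females are older at equal scores
  expect_gt(mean(tab$diff), 0)
  # a score carried by one sex only is omitted, not guessed at
  solo <- rights
  comp <- composite_score(solo$topography, solo$porosity, solo$osteophytes)
  solo <- solo[!(comp == 5 & solo$sex == "female"), ]
  tab2 <- sex_difference_by_score(solo)
  expect_false(5 %in% tab2$composite)
  expect_true(5 %in% attr(tab2, "omitted"))
})

test_that("side asymmetry test reduces to z = 0 for equal proportions", {
  # 20 of 100 differ for each sex -> identical proportions
  make <- function(sex, n, ndiff) {
    id <- sprintf("%s%03d", sex, seq_len(n))
    r <- data.frame(id = id, sex = sex, side = "right", age = 60,
                    topography = 3, porosity = 3, osteophytes = 2)
    l <- r; l$side <- "left"
    l$topography[seq_len(ndiff)] <- 4
    l$porosity[seq_len(ndiff)] <- 4
    l$osteophytes[seq_len(ndiff)] <- 3
    rbind(r, l)
  }
  rec <- rbind(make("male", 100, 20), make("female", 100, 20))
  res <- side_asymmetry_test(rec)
  for (trait in names(res)) {
    expect_equal(res[[trait]]$statistic, 0)
    expect_equal(res[[trait]]$p, 1)
  }
})

test_that("pooled z-statistic squares to the uncorrected chi-square", {
  rec <- withr::with_seed(407, {
    co <- simulate_cohort(seed = 407)
    co
  })
  res <- side_asymmetry_test(rec)
  # rebuild the 2x2 counts independently and compare with prop.test
  for (trait in c("topography", "porosity", "osteophytes")) {
    wide <- reshape(rec[, c("id", "sex", "side", trait)],
                    idvar = c("id", "sex"), timevar = "side",
                    direction = "wide")
    l <- wide[[paste0(trait, ".left")]]
    r <- wide[[paste0(trait, ".right")]]
    ok <- !is.na(l) & !is.na(r)
    differs <- l[ok] != r[ok]
    male <- wide$sex[ok] == "male"
    pt <- prop.test(c(sum(differs[male]), sum(differs[!male])),
                    c(sum(male), sum(!male)), correct = FALSE)
    expect_equal(res[[trait]]$statistic^2, unname(pt$statistic),
                 tolerance = 1e-10)
    expect_equal(res[[trait]]$p, pt$p.value, tolerance = 1e-10)
  }
})

test_that("Spearman correlation uses midranks and the t approximation", {
  rec <- records_at_scores(c(4, 5, 7, 9, 11, 13), c(45, 50, 55, 60, 70, 80))
  res <- spearman_age_correlation(rec, "composite")
  expect_equal(res$statistic, 1)
  # hand grid with ties
  tied <- records_at_scores(c(5, 5, 7, 7, 9, 9), c(44, 48, 48, 60, 60, 72))
  got <- spearman_age_correlation(tied, "composite")$statistic
  comp <- composite_score(tied$topography, tied$porosity, tied$osteophytes)
  expect_equal(got, oracle_spearman(tied$age, comp), tolerance = 1e-12)
  # constant feature flagged
  flat <- records_at_scores(rep(6, 5), c(41, 50, 60, 70, 80))
  expect_true(is.na(spearman_age_correlation(flat, "composite")$statistic))
  # independence: near-zero at large n
  big <- withr::with_seed(408, records_at_scores(
    sample(3:16, 2000, TRUE), runif(2000, 40, 96)))
  expect_lt(abs(spearman_age_correlation(big, "composite")$statistic), 0.06)
})

test_that("null calibration: type-I error near nominal for the suite's tests", {
  alpha <- 0.05
  n_sim <- 2000
  rej <- withr::with_seed(409, {
    paired <- welch <- prop <- spear <- logical(n_sim)
    for (i in seq_len(n_sim)) {
      a <- rnorm(15); b <- rnorm(15)
      paired[i] <- paired_t_test(a, b)$p < alpha
      welch[i] <- clavage:::welch_p(rnorm(20, 50, 8), rnorm(25, 50, 12)) < alpha
      x1 <- rbinom(1, 60, 0.3); x2 <- rbinom(1, 80, 0.3)
      pz <- clavage:::two_proportion_z(x1, 60, x2, 80)
      prop[i] <- pz$p < alpha
      rec <- data.frame(sex = "male", age = rnorm(20, 60, 10),
                        topography = sample(1:6, 20, TRUE),
                        porosity = 1, osteophytes = 1)
      spear[i] <- spearman_age_correlation(rec, "topography")$p < alpha
    }
    c(paired = mean(paired), welch = mean(welch), prop = mean(prop),
      spear = mean(spear))
  })
  # binomial 99.9% band around 0.05 at 2000 sims is about +/- 0.016
  expect_true(all(abs(rej - alpha) < 0.02),
              info = paste(names(rej), round(rej, 3), collapse = ", "))
})
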