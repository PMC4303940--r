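# Published reference tables for the pooled four-collection European training
# sample (318 male / 246 female right clavicles, known ages 40-96 years).
# These are the tables a practitioner applies to a new skeleton when no local
# training data are available.

# per-composite-score age descriptives, pooled sample, right clavicles
.ref_desc_male <- data.frame(
  composite  = 3:16,
  n          = c(1L, 4L, 25L, 30L, 32L, 31L, 53L, 37L, 67L, 21L, 10L, 4L, 3L, 0L),
  mean_age   = c(41.0, 47.0, 49.4, 54.9, 55.4, 62.8, 67.3, 72.5, 75.2, 78.1,
                 82.9, 83.0, 84.0, NA),
  sd_age     = c(NA, 6.7, 6.3, 5.9, 11.5, 10.1, 9.0, 9.3, 8.0, 7.1, 7.9, 7.5,
                 3.5, NA),
  median_age = c(41, 46, 48, 55, 55, 63, 68, 75, 75, 80, 85, 80, 86, NA),
  min_age    = c(41, 41, 41, 44, 40, 45, 47, 53, 54, 64, 71, 77, 80, NA),
  max_age    = c(41, 55, 69, 67, 85, 86, 83, 87, 96, 87, 92, 94, 86, NA)
)

.ref_desc_female <- data.frame(
  composite  = 3:16,
  n          = c(0L, 13L, 23L, 18L, 30L, 28L, 53L, 33L, 35L, 9L, 3L, 1L, 0L, 0L),
  mean_age   = c(NA, 47.3, 50.4, 66.8, 62.8, 64.9, 71.9, 72.1, 79.2, 79.8,
                 87.3, 86.0, NA, NA),
  sd_age     = c(NA, 3.6, 8.4, 11.4, 12.2, 12.0, 9.8, 10.1, 8.5, 8.5, 0.6,
                 NA, NA, NA),
  median_age = c(NA, 48, 50, 64, 62, 65, 72, 70, 80, 80, 87, 86, NA, NA),
  min_age    = c(NA, 42, 40, 43, 43, 45, 46, 46, 46, 63, 87, 86, NA, NA),
  max_age    = c(NA, 53, 78, 84, 90, 89, 93, 89, 94, 95, 88, 86, NA, NA)
)

# five-stage partitions of the composite score with per-stage age descriptives
# and published 95% intervals (years)
.ref_stages_male <- data.frame(
  stage     = c("I", "II", "III", "IV", "V"),
  score_min = c(3L, 6L, 8L, 10L, 13L),
  score_max = c(5L, 7L, 9L, 12L, 16L),
  n         = c(30L, 62L, 84L, 125L, 17L),
  mean_age  = c(48.8, 55.2, 65.7, 74.9, 83.1),
  sd_age    = c(6.3, 9.1, 9.6, 8.4, 6.9),
  lower     = c(36L, 37L, 47L, 58L, 70L),
  upper     = c(61L, 73L, 85L, 91L, 97L)
)

.ref_stages_female <- data.frame(
  stage     = c("I", "II", "III", "IV", "V"),
  score_min = c(3L, 6L, 9L, 11L, 13L),
  score_max = c(5L, 8L, 10L, 12L, 16L),
  n         = c(36L, 76L, 86L, 44L, 4L),
  mean_age  = c(49.3, 64.5, 72.0, 79.3, 87.0),
  sd_age    = c(7.1, 11.9, 9.9, 8.4, 0.8),
  lower     = c(35L, 41L, 53L, 63L, 85L),
  upper     = c(63L, 88L, 91L, 96L, 89L)
)

# age composition of the four reference collections (counts of right
# clavicles by decade bin); HT = Hamann-Todd, PBC = Pretoria, SB = St Bride's,
# CC = Coimbra
.ref_age_bins <- c("40-49", "50-59", "60-69", "70-79", "80+")

.ref_counts <- local({
  male <- rbind(HT = c(10, 18, 19, 24, 23), PBC = c(4, 13, 22, 32, 24),
                SB = c(6, 9, 9, 10, 4), CC = c(20, 22, 21, 21, 7))
  female <- rbind(HT = c(10, 12, 15, 14, 14), PBC = c(1, 4, 16, 24, 20),
                  SB = c(5, 7, 11, 7, 6), CC = c(14, 16, 17, 16, 17))
  colnames(male) <- colnames(female) <- .ref_age_bins
  long <- function(m, sex) {
    data.frame(
      collection = rep(rownames(m), each = ncol(m)),
      sex = sex,
      bin = rep(colnames(m), times = nrow(m)),
      n = as.integer(t(m))
    )
  }
  rbind(long(male, "male"), long(female, "female"))
})

#' Reference degeneration stage table
#'
#' The published five-stage partition of the composite score for the pooled
#' European reference sample, with per-stage sample sizes, mean ages, SDs and
#' 95% age intervals.  Apply with [assign_stage()] / [blind_test_composite()].
#'
#' @param sex `"male"` or `"female"` (the staging is sex-specific).
#' @return A [stage_table] object (data frame with columns `stage`,
#'   `score_min`, `score_max`, `n`, `mean_age`, `sd_age`, `lower`, `upper`).
#' @export
reference_stage_table <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  df <- if (sex == "male") .ref_stages_male else .ref_stages_female
  new_stage_table(df, sex = sex, alpha = 0.05)
}

#' Reference per-composite-score age descriptives
#'
#' Published descriptive statistics of known age for each composite score in
#' the pooled reference sample (right clavicles; 318 males, 246 females).
#'
#' @inheritParams reference_stage_table
#' @return Data frame with columns `composite`, `n`, `mean_age`, `sd_age`,
#'   `median_age`, `min_age`, `max_age`.
#' @export
reference_score_descriptives <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (sex == "male") .ref_desc_male else .ref_desc_female
}

#' Age composition of the reference collections
#'
#' Counts of right clavicles per decade age bin in the four documented
#' reference collections, by sex.  These counts are the default sampling frame
#' of [synthetic_config()].
#'
#' @return Data frame with columns `collection`, `sex`, `bin`, `n`.
#' @export
reference_age_composition <- function() .ref_counts
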