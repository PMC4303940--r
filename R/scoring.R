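#' Composite degeneration score of the sternal clavicular surface
#'
#' Sums the three ordinal trait grades recorded on the sternal end of the
#' clavicle -- surface topography (1--6), porosity (1--6) and osteophyte
#' formation (1--4) -- into a single composite score ranging from 3 (pristine
#' surface) to 16 (complete breakdown).  Grade 0 codes "element not present";
#' such records cannot be composite-scored and must be excluded, never imputed.
#'
#' @param topography integer vector of surface-topography grades (1--6).
#' @param porosity integer vector of porosity grades (1--6).
#' @param osteophytes integer vector of osteophyte-formation grades (1--4).
#'
#' @return An integer vector of composite scores in 3--16.
#' @seealso [descriptives_by_score()], [assign_stage()]
#' @examples
#' composite_score(6, 6, 4)  # maximal degeneration -> 16
#' composite_score(1, 1, 1)  # pristine surface -> 3
#' @export
composite_score <- function(topography, porosity, osteophytes) {
  n <- length(topography)
  if (length(porosity) != n || length(osteophytes) != n) {
    stop("trait grade vectors must have equal length", call. = FALSE)
  }
  check_grades(topography, porosity, osteophytes, allow_zero = TRUE)
  if (any(topography == 0 | porosity == 0 | osteophytes == 0)) {
    stop("element absent: grade 0 means the element is not present; ",
         "exclude the record rather than imputing a grade", call. = FALSE)
  }
  as.integer(topography + porosity + osteophytes)
}

#' Drop records whose element is absent (any trait grade 0)
#'
#' @param records data frame with columns `topography`, `porosity`,
#'   `osteophytes`.
#' @param quiet suppress the message reporting how many rows were dropped.
#' @return `records` without grade-0 rows.
#' @export
drop_absent <- function(records, quiet = FALSE) {
  check_records(records, cols = .trait_cols)
  absent <- records$topography == 0 | records$porosity == 0 |
    records$osteophytes == 0
  if (any(absent) && !quiet) {
    message(sum(absent), " record(s) excluded: element not present (grade 0)")
  }
  records[!absent, , drop = FALSE]
}

#' Age descriptive statistics per composite score
#'
#' Tabulates, for every composite score 3--16, the number of individuals and
#' the mean, standard deviation, median and observed range of their known
#' ages-at-death.  Scores with no observations are kept in the table with
#' `n = 0` and undefined statistics, so the table always has 14 rows.
#'
#' @param records data frame with columns `age`, `topography`, `porosity`,
#'   `osteophytes` (or a precomputed `composite` column).  Typically one sex
#'   and one side.
#' @return A data frame with columns `composite`, `n`, `mean_age`, `sd_age`,
#'   `median_age`, `min_age`, `max_age`.
#' @export
descriptives_by_score <- function(records) {
  if (!nrow(records)) stop("records must be non-empty", call. = FALSE)
  comp <- record_composite(records)
  out <- data.frame(composite = 3:16)
  stats_at <- function(s) {
    a <- records$age[comp == s]
    if (!length(a)) {
      return(c(n = 0, mean_age = NA, sd_age = NA, median_age = NA,
               min_age = NA, max_age = NA))
    }
    c(n = length(a), mean_age = mean(a),
      sd_age = if (length(a) > 1) stats::sd(a) else NA,
      median_age = stats::median(a), min_age = min(a), max_age = max(a))
  }
  m <- t(vapply(out$composite, stats_at, numeric(6)))
  cbind(out, as.data.frame(m))
}

# composite scores of a records frame (uses `composite` column if present)
record_composite <- function(records) {
  if (!is.null(records$composite)) {
    return(as.integer(records$composite))
  }
  check_records(records, cols = c("age", .trait_cols))
  composite_score(records$topography, records$porosity, records$osteophytes)
}

#' 95% age interval for a degeneration stage
#'
#' Computes the normal-approximation 95% interval `mean +/- 1.96 * sd`,
#' rounded half-up to whole years.  Although usually labelled a "confidence
#' interval" in the aging literature, this is a prediction-style interval for
#' an individual's age given its stage, not an interval for the stage mean.
#'
#' @param mean_age stage mean age in years.
#' @param sd_age stage standard deviation of age in years (>= 0).
#' @return A data frame with integer columns `lower` and `upper` (years).
#' @examples
#' stage_interval(48.8, 6.3)  # -> 36--61
#' @export
stage_interval <- function(mean_age, sd_age) {
  if (length(mean_age) != length(sd_age)) {
    stop("mean_age and sd_age must have equal length", call. = FALSE)
  }
  if (any(sd_age < 0, na.rm = TRUE)) {
    stop("sd_age must be non-negative", call. = FALSE)
  }
  data.frame(
    lower = as.integer(round_half_up(mean_age - 1.96 * sd_age)),
    upper = as.integer(round_half_up(mean_age + 1.96 * sd_age))
  )
}

#' Assign a composite score to its degeneration stage
#'
#' @param composite integer composite score(s) in 3--16.
#' @param table a [stage_table] (e.g. from [build_stage_table()] or
#'   [reference_stage_table()]).
#' @return Character vector of stage labels (`"I"`, `"II"`, ...).
#' @export
assign_stage <- function(composite, table) {
  stopifnot(inherits(table, "stage_table"))
  if (!all(is_whole(composite)) || any(composite < 3 | composite > 16)) {
    stop("composite scores must be integers in 3..16", call. = FALSE)
  }
  idx <- vapply(composite, function(s) {
    which(table$score_min <= s & s <= table$score_max)[1]
  }, integer(1))
  table$stage[idx]
}
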