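# Data-driven grouping of consecutive composite scores into age stages.
#
# The grouping rule: scan composite scores 3..16 in ascending order; the
# current group absorbs the next non-empty score while a Welch two-sample
# t-test between the group's pooled ages and that score's ages gives P >
# alpha; a significant difference closes the stage and starts a new one.
# Empty scores attach to the preceding group (leading empties to the first
# group, trailing empties to the last stage); singleton scores, which cannot
# be t-tested, are absorbed into the adjacent group with the closer mean.

new_stage_table <- function(df, sex, alpha) {
  stopifnot(all(c("stage", "score_min", "score_max", "n",
                  "mean_age", "sd_age", "lower", "upper") %in% names(df)))
  structure(df, sex = sex, alpha = alpha,
            class = c("stage_table", "data.frame"))
}

#' Group consecutive composite scores into statistically distinct age stages
#'
#' Builds a per-sex stage table by merging consecutive composite scores whose
#' age distributions are statistically indistinguishable (Welch t-test,
#' `P > alpha`), in a single ascending greedy scan.  The resulting score
#' ranges always partition 3--16.  Stage intervals come from
#' [stage_interval()] (`mean +/- 1.96 SD`, whole years).
#'
#' @param records data frame of scored clavicles for **one sex** (and one
#'   side), with columns `age`, `topography`, `porosity`, `osteophytes`.
#' @param sex label stored on the resulting table (`"male"`, `"female"`);
#'   if `records` has a `sex` column the records are filtered to this sex.
#' @param alpha significance level for the merge test (default 0.05).
#' @return A `stage_table`: data frame with columns `stage`, `score_min`,
#'   `score_max`, `n`, `mean_age`, `sd_age`, `lower`, `upper`, with the sex
#'   and alpha stored as attributes.
#' @seealso [stage_separation_tests()] to verify adjacent stages differ.
#' @export
build_stage_table <- function(records, sex = NULL, alpha = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  if (!is.null(sex) && !is.null(records$sex)) {
    records <- records[records$sex == sex, , drop = FALSE]
  }
  if (!nrow(records)) stop("no records for this sex", call. = FALSE)
  comp <- record_composite(records)
  ages <- lapply(3:16, function(s) records$age[comp == s])
  names(ages) <- 3:16
  if (sum(lengths(ages) > 0) < 2) {
    stop("need at least two non-empty composite scores to build stages",
         call. = FALSE)
  }

  groups <- list()
  cur <- NULL
  pending <- integer(0)  # leading empty scores, attach to the first group
  scores <- 3:16
  for (i in seq_along(scores)) {
    s <- scores[i]
    a <- ages[[as.character(s)]]
    if (!length(a)) {
      if (is.null(cur)) pending <- c(pending, s)
      else cur$scores <- c(cur$scores, s)
      next
    }
    if (is.null(cur)) {
      cur <- list(scores = c(pending, s), ages = a)
      pending <- integer(0)
      next
    }
    merge <- if (length(a) == 1) {
      # singleton: attach to the adjacent group with the closer mean
      nxt <- unlist(ages[as.character(scores[scores > s])], use.names = FALSE)
      length(nxt) == 0 ||
        abs(a - mean(cur$ages)) <= abs(a - mean(nxt))
    } else if (length(cur$ages) < 2) {
      TRUE  # current group untestable; absorb
    } else {
      welch_p(cur$ages, a) > alpha
    }
    if (merge) {
      cur$scores <- c(cur$scores, s)
      cur$ages <- c(cur$ages, a)
    } else {
      groups[[length(groups) + 1L]] <- cur
      cur <- list(scores = s, ages = a)
    }
  }
  groups[[length(groups) + 1L]] <- cur

  df <- do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    m <- mean(g$ages)
    sdev <- if (length(g$ages) > 1) stats::sd(g$ages) else NA_real_
    ci <- if (is.na(sdev)) data.frame(lower = NA_integer_, upper = NA_integer_)
          else stage_interval(m, sdev)
    data.frame(stage = NA_character_, score_min = min(g$scores),
               score_max = max(g$scores), n = length(g$ages),
               mean_age = m, sd_age = sdev, lower = ci$lower, upper = ci$upper)
  }))
  df$stage <- roman_labels(nrow(df))
  new_stage_table(df, sex = sex %||% attr(records, "sex"), alpha = alpha)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Welch t-tests between adjacent age stages
#'
#' Verifies that each pair of adjacent stages in a stage table has
#' significantly different age distributions, reporting the Welch t statistic,
#' approximate degrees of freedom and two-tailed P per pair.
#'
#' @param table a [stage_table] built from `records`.
#' @param records the records the table was built from (one sex).
#' @param alpha significance level used for the `distinct` flag.
#' @return Data frame with columns `pair`, `t`, `df`, `p`, `distinct`,
#'   `testable` (a stage with fewer than 2 individuals makes its pairs
#'   untestable).
#' @export
stage_separation_tests <- function(table, records, alpha = attr(table, "alpha")) {
  stopifnot(inherits(table, "stage_table"))
  comp <- record_composite(records)
  stage_of <- assign_stage(comp, table)
  out <- lapply(seq_len(nrow(table) - 1L), function(i) {
    a <- records$age[stage_of == table$stage[i]]
    b <- records$age[stage_of == table$stage[i + 1L]]
    pair <- paste(table$stage[i], "vs", table$stage[i + 1L])
    if (length(a) < 2 || length(b) < 2) {
      return(data.frame(pair = pair, t = NA_real_, df = NA_real_,
                        p = NA_real_, distinct = NA, testable = FALSE))
    }
    tt <- stats::t.test(a, b)
    data.frame(pair = pair, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               distinct = tt$p.value < alpha, testable = TRUE)
  })
  do.call(rbind, out)
}

#' @export
print.stage_table <- function(x, ...) {
  sex <- attr(x, "sex")
  cat("Clavicular degeneration stage table",
      if (!is.null(sex)) paste0("(", sex, ")"), "\n")
  df <- as.data.frame(x)
  df$scores <- ifelse(df$score_min == df$score_max, df$score_min,
                      paste0(df$score_min, "-", df$score_max))
  df$interval <- ifelse(is.na(df$lower), "-",
                        paste0(df$lower, "-", df$upper, " yr"))
  print(df[, c("stage", "scores", "n", "mean_age", "sd_age", "interval")],
        row.names = FALSE, digits = 4)
  invisible(x)
}
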