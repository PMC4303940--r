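# internal helpers shared across the package

# half-up rounding (round() is banker's rounding; stage intervals need 0.5 -> up)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

roman_labels <- function(k) as.character(utils::as.roman(seq_len(k)))

# grade bounds per trait; grade 0 encodes "element not present"
.grade_max <- c(topography = 6L, porosity = 6L, osteophytes = 4L)

.trait_cols <- c("topography", "porosity", "osteophytes")

.sex_levels <- c("female", "male")

is_whole <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

check_grades <- function(topography, porosity, osteophytes, allow_zero = FALSE) {
  g <- list(topography = topography, porosity = porosity, osteophytes = osteophytes)
  for (nm in names(g)) {
    v <- g[[nm]]
    if (!all(is_whole(v))) {
      stop(sprintf("%s grades must be whole numbers", nm), call. = FALSE)
    }
    lo <- if (allow_zero) 0L else 1L
    if (any(v < lo | v > .grade_max[[nm]])) {
      stop(sprintf("%s grades must lie in %d..%d", nm, lo, .grade_max[[nm]]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# columns a records data frame must carry for the pipeline
check_records <- function(records,
                          cols = c("sex", "age", .trait_cols),
                          require_age_bound = FALSE,
                          lower = 40) {
  if (!is.data.frame(records)) stop("records must be a data frame", call. = FALSE)
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols)) {
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if ("age" %in% cols) {
    if (!is.numeric(records$age) || any(!is.finite(records$age))) {
      stop("age must be finite numeric", call. = FALSE)
    }
    if (require_age_bound && any(records$age < lower)) {
      stop(sprintf("all ages must be >= %s (the method's truncation bound)", lower),
           call. = FALSE)
    }
  }
  invisible(records)
}

# normalize the sex column to a factor female < male (so the model-matrix dummy
# is `sexmale`, i.e. male = 1, female = 0); "unknown" only where permitted
normalize_sex <- function(sex, allow_unknown = FALSE) {
  sex <- as.character(sex)
  ok <- c(.sex_levels, if (allow_unknown) "unknown")
  bad <- setdiff(unique(sex), ok)
  if (length(bad)) {
    stop("invalid sex codes: ", paste(bad, collapse = ", "),
         "; expected ", paste(ok, collapse = "/"), call. = FALSE)
  }
  factor(sex, levels = ok)
}

# Welch two-sample p-value that tolerates zero-variance groups
welch_p <- function(x, y, tol = 1e-12) {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  se2 <- stats::var(x) / length(x) + stats::var(y) / length(y)
  if (se2 < tol) {
    return(if (abs(mean(x) - mean(y)) < tol) 1 else 0)
  }
  stats::t.test(x, y)$p.value
}
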