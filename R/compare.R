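#' Percent difference between two values
#'
#' Two conventions: `"rel_first"` is signed relative to the first value,
#' \eqn{(a-b)/a \times 100}; `"rel_mean"` is the unsigned difference
#' relative to the mean, \eqn{|a-b| / ((a+b)/2) \times 100}. A zero
#' denominator yields `NA` (an undefined-result marker), not an error, so
#' organ tables with 0.000 entries still render.
#'
#' @param a,b Numeric values (vectorised).
#' @param convention `"rel_first"` or `"rel_mean"`.
#' @return Percent difference(s); `NA` where the denominator is zero.
#' @examples
#' percent_difference(22.47, 21.47)            # 4.45
#' percent_difference(3, 5, "rel_mean")        # 50
#' @export
percent_difference <- function(a, b, convention = c("rel_first", "rel_mean")) {
  convention <- match.arg(convention)
  switch(convention,
    rel_first = ifelse(a == 0, NA_real_, (a - b) / a * 100),
    rel_mean = ifelse(a + b == 0, NA_real_, abs(a - b) / ((a + b) / 2) * 100)
  )
}

#' Compare two dosimetry pipelines organ by organ
#'
#' Inputs are long-format per-subject tables (columns `subject`, `sex`,
#' `organ`, `value`) holding the same quantity — residence times or doses —
#' from two methods. Percent differences are computed per subject per organ
#' first, then averaged within sex and overall; raw values are summarised
#' as mean and sample SD (n-1 denominator) per method per sex. Averaging
#' per-subject differences (rather than differencing averaged tables) keeps
#' the comparison paired.
#'
#' @param method_a,method_b Data.frames with columns `subject`, `sex`,
#'   `organ`, `value`; must cover identical (subject, organ) sets.
#' @param convention Passed to [percent_difference()]; `method_a` is the
#'   reference for `"rel_first"`.
#' @return An object of class `comparison_report`: list with
#'   `per_subject` (long table of per-subject percent differences),
#'   `by_organ` (organ x sex summary: mean/SD per method, mean and mean
#'   absolute percent difference, n), and `convention`.
#' @export
compare_tables <- function(method_a, method_b,
                           convention = c("rel_first", "rel_mean")) {
  convention <- match.arg(convention)
  req <- c("subject", "sex", "organ", "value")
  stopifnot(all(req %in% names(method_a)), all(req %in% names(method_b)))
  key_a <- paste(method_a$subject, method_a$organ, sep = "\r")
  key_b <- paste(method_b$subject, method_b$organ, sep = "\r")
  only_a <- setdiff(key_a, key_b)
  only_b <- setdiff(key_b, key_a)
  if (length(only_a) || length(only_b)) {
    stop(sprintf(
      "subject/organ keys differ between methods; only in A: {%s}; only in B: {%s}",
      paste(gsub("\r", ":", only_a), collapse = ", "),
      paste(gsub("\r", ":", only_b), collapse = ", ")))
  }
  if (anyDuplicated(key_a) || anyDuplicated(key_b)) {
    stop("duplicate subject/organ rows in input tables")
  }
  b_val <- method_b$value[match(key_a, key_b)]
  per_subject <- data.frame(
    subject = method_a$subject,
    sex = method_a$sex,
    organ = method_a$organ,
    value_a = method_a$value,
    value_b = b_val,
    pct_diff = percent_difference(method_a$value, b_val, convention),
    stringsAsFactors = FALSE
  )

  summarise_stratum <- function(df, sex_label) {
    stats_by <- function(v) c(mean = mean(v), sd = stats::sd(v))
    organs <- unique(df$organ)
    do.call(rbind, lapply(organs, function(og) {
      d <- df[df$organ == og, ]
      data.frame(
        organ = og, sex = sex_label, n = nrow(d),
        mean_a = mean(d$value_a), sd_a = stats::sd(d$value_a),
        mean_b = mean(d$value_b), sd_b = stats::sd(d$value_b),
        mean_pct_diff = mean(d$pct_diff),      # NA propagates from 0/0 organs
        mean_abs_pct_diff = mean(abs(d$pct_diff)),
        stringsAsFactors = FALSE
      )
    }))
  }
  strata <- lapply(unique(per_subject$sex), function(sx) {
    summarise_stratum(per_subject[per_subject$sex == sx, ], sx)
  })
  by_organ <- rbind(do.call(rbind, strata),
                    summarise_stratum(per_subject, "all"))
  rownames(by_organ) <- NULL
  structure(list(per_subject = per_subject, by_organ = by_organ,
                 convention = convention),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> convention = %s, %d subjects, %d organs\n",
              x$convention, length(unique(x$per_subject$subject)),
              length(unique(x$per_subject$organ))))
  all_rows <- x$by_organ[x$by_organ$sex == "all", ]
  print(all_rows[order(-abs(all_rows$mean_pct_diff)),
                 c("organ", "mean_a", "mean_b", "mean_pct_diff", "n")],
        row.names = FALSE, digits = 4)
  invisible(x)
}
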