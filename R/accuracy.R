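#' Build a 2x2 contingency table from calls and truth
#'
#' Cross-tabulates predicted class against true condition with
#' beta-thalassaemia trait as the positive group by default. Subjects whose
#' call is `not_evaluable` (or `NA`) are excluded from the table but counted
#' in the exclusion report — silent dropping is forbidden.
#'
#' @param calls Predicted class per subject.
#' @param truth True condition per subject, aligned with `calls`.
#' @param positive_class Label counted as condition-present / test-positive.
#' @return A `thal_contingency`: counts `tp`, `fp`, `fn`, `tn`, plus
#'   `n_excluded` and the positive class.
#' @export
build_contingency <- function(calls, truth, positive_class = "beta_trait") {
  if (length(calls) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(calls) == length(truth))
  evaluable <- !is.na(calls) & calls != "not_evaluable" & !is.na(truth)
  n_excl <- sum(!evaluable)
  calls <- calls[evaluable]; truth <- truth[evaluable]
  if (length(calls) == 0) stop("no evaluable subjects", call. = FALSE)
  cp <- calls == positive_class
  tp <- truth == positive_class
  contingency_table(tp = sum(cp & tp), fp = sum(cp & !tp),
                    fn = sum(!cp & tp), tn = sum(!cp & !tp),
                    positive_class = positive_class, n_excluded = n_excl)
}

#' Construct a contingency table from counts
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts (true/false
#'   positives/negatives).
#' @param positive_class Condition counted as positive.
#' @param n_excluded Subjects excluded as not evaluable before counting.
#' @return A `thal_contingency` object.
#' @export
contingency_table <- function(tp, fp, fn, tn, positive_class = "beta_trait",
                              n_excluded = 0L) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  if (sum(counts) == 0) stop("contingency table is empty", call. = FALSE)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 positive_class = positive_class,
                 n_excluded = as.integer(n_excluded)),
            class = "thal_contingency")
}

#' @export
print.thal_contingency <- function(x, ...) {
  m <- matrix(c(x$fp, x$tp, x$tp + x$fp,
                x$tn, x$fn, x$tn + x$fn,
                x$fp + x$tn, x$tp + x$fn, x$tp + x$fp + x$fn + x$tn),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("Positive", "Negative", "Total"),
                              c("Absent", "Present", "Total")))
  cat("<thal_contingency> positive class:", x$positive_class, "\n")
  print(m)
  if (x$n_excluded > 0) cat("excluded (not evaluable):", x$n_excluded, "\n")
  invisible(x)
}

#' Binomial proportion confidence interval
#'
#' Wilson score (default), exact Clopper-Pearson (beta quantiles), or Wald.
#' Wilson and exact intervals always lie inside `[0, 1]`; the Wald interval
#' is clipped.
#'
#' @param k Number of successes.
#' @param n Number of trials (> 0).
#' @param method `"wilson"`, `"exact"`, or `"wald"`.
#' @param level Confidence level.
#' @return Numeric `c(low, high)`.
#' @export
binom_ci <- function(k, n, method = c("wilson", "exact", "wald"), level = 0.95) {
  method <- match.arg(method)
  stopifnot(n > 0, k >= 0, k <= n)
  alpha <- 1 - level
  p <- k / n
  z <- stats::qnorm(1 - alpha / 2)
  ci <- switch(method,
    wilson = {
      centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
      c(centre - half, centre + half)
    },
    exact = c(if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1),
              if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)),
    wald = p + c(-1, 1) * z * sqrt(p * (1 - p) / n)
  )
  pmin(pmax(ci, 0), 1)
}

#' Diagnostic accuracy statistics from a 2x2 table
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp) and NPV
#' tn/(tn+fn) as exact ratios, each with a binomial confidence interval, and
#' a display percentage rounded half-up to 2 decimals. A statistic with a
#' zero denominator is returned as `NA` and noted; the others are computed.
#'
#' @param table A `thal_contingency`.
#' @param ci_method CI method passed to [binom_ci()]; default Wilson score.
#' @param level Confidence level.
#' @return Data frame, one row per statistic: `statistic`, `numerator`,
#'   `denominator`, `estimate` (proportion), `percent` (2-dp display),
#'   `ci_low`, `ci_high`, `ci_method`, `level`, `note`.
#' @export
accuracy_stats <- function(table, ci_method = c("wilson", "exact", "wald"),
                           level = 0.95) {
  stopifnot(inherits(table, "thal_contingency"))
  ci_method <- match.arg(ci_method)
  defs <- list(
    sensitivity = c(table$tp, table$tp + table$fn),
    specificity = c(table$tn, table$tn + table$fp),
    ppv         = c(table$tp, table$tp + table$fp),
    npv         = c(table$tn, table$tn + table$fn)
  )
  rows <- lapply(names(defs), function(s) {
    k <- defs[[s]][1]; n <- defs[[s]][2]
    if (n == 0) {
      return(data.frame(statistic = s, numerator = k, denominator = n,
                        estimate = NA_real_, percent = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        ci_method = ci_method, level = level,
                        note = "undefined: zero denominator",
                        stringsAsFactors = FALSE))
    }
    ci <- binom_ci(k, n, ci_method, level)
    data.frame(statistic = s, numerator = k, denominator = n,
               estimate = k / n, percent = round_half_up(100 * k / n, 2),
               ci_low = ci[1], ci_high = ci[2],
               ci_method = ci_method, level = level, note = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
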