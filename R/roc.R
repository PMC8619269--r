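#' Empirical ROC curve
#'
#' Builds the empirical ROC of a numeric marker against a binary class
#' labelling. Candidate thresholds are the midpoints between consecutive
#' distinct sorted marker values plus infinite sentinels, so every achievable
#' operating point appears exactly once. The AUC is the Mann-Whitney
#' statistic (probability a random positive exceeds a random negative, ties
#' half-credited), computed from ranks. If the raw AUC falls below 0.5 the
#' orientation is flipped (positives called below the threshold) and the flip
#' recorded, so the reported AUC is always >= 0.5.
#'
#' @param scores Numeric marker values, one per subject.
#' @param labels Class label per subject.
#' @param positive_class Which label is the positive class (default
#'   `"beta_trait"`).
#' @param parameter_name Marker name carried into reports.
#' @return A `thal_roc` object: operating `points` (threshold, sensitivity,
#'   specificity), `auc`, `direction` (`">"` = positive above threshold),
#'   `flipped`, `n_pos`, `n_neg`, and the class score vectors.
#' @export
empirical_roc <- function(scores, labels, positive_class = "beta_trait",
                          parameter_name = deparse(substitute(scores))) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  pos <- scores[labels == positive_class]
  neg <- scores[labels != positive_class]
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0)
    stop("both classes must be present (", m, " positive, ", n, " negative)", call. = FALSE)

  auc_raw <- mann_whitney_auc(pos, neg)
  degenerate <- length(unique(scores)) == 1L
  if (degenerate) warning("all scores identical: degenerate ROC curve, AUC = 0.5")

  flipped <- !degenerate && auc_raw < 0.5
  direction <- if (flipped) "<" else ">"
  auc <- if (flipped) 1 - auc_raw else auc_raw

  u <- sort(unique(scores))
  thr <- if (length(u) > 1) c(-Inf, (u[-length(u)] + u[-1]) / 2, Inf) else c(-Inf, Inf)
  sp <- sort(pos); sn <- sort(neg)
  # counts strictly above each threshold (midpoint thresholds never tie)
  pos_above <- m - findInterval(thr, sp)
  neg_above <- n - findInterval(thr, sn)
  if (direction == ">") {
    sens <- pos_above / m
    spec <- 1 - neg_above / n
  } else {
    sens <- 1 - pos_above / m
    spec <- neg_above / n
  }
  points <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)

  structure(list(parameter_name = parameter_name, points = points, auc = auc,
                 direction = direction, flipped = flipped, degenerate = degenerate,
                 n_pos = m, n_neg = n, pos = pos, neg = neg,
                 positive_class = positive_class),
            class = "thal_roc")
}

# Mann-Whitney AUC via midranks; ties half-credited
mann_whitney_auc <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Trapezoidal area under an empirical ROC polygon
#'
#' Integrates sensitivity against false-positive rate over the curve's
#' operating points. Equals the Mann-Whitney AUC exactly (tie segments are
#' diagonal chords, which the trapezoid rule bisects just as half-credit
#' does).
#'
#' @param roc A `thal_roc`.
#' @return The trapezoidal area.
#' @export
trapezoid_auc <- function(roc) {
  stopifnot(inherits(roc, "thal_roc"))
  x <- 1 - roc$points$specificity
  y <- roc$points$sensitivity
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Confidence interval for the AUC
#'
#' DeLong's placement-based variance (deterministic) or a within-class
#' percentile bootstrap (seeded). Intervals are clipped to `[0, 1]`. A
#' perfectly separating marker has zero DeLong variance; the degenerate
#' zero-width interval is returned with a warning.
#'
#' @param roc A `thal_roc` with at least 2 subjects per class.
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param level Confidence level, default 0.95.
#' @param B Bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap stream.
#' @return Numeric `c(low, high)` with attributes `auc`, `method`, `level`.
#' @export
auc_ci <- function(roc, method = c("delong", "bootstrap"), level = 0.95,
                   B = 2000, seed = NULL) {
  stopifnot(inherits(roc, "thal_roc"))
  method <- match.arg(method)
  m <- roc$n_pos; n <- roc$n_neg
  if (m < 2 || n < 2)
    stop("auc_ci needs at least 2 subjects per class (have ", m, "/", n, ")", call. = FALSE)
  # work on the oriented scale so the interval brackets the reported AUC
  pos <- if (roc$flipped) -roc$pos else roc$pos
  neg <- if (roc$flipped) -roc$neg else roc$neg

  if (method == "delong") {
    v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), numeric(1))
    v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), numeric(1))
    se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
    if (se == 0) warning("zero DeLong variance: degenerate zero-width interval")
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- roc$auc + c(-1, 1) * z * se
  } else {
    ci <- with_local_seed(seed, {
      reps <- vapply(seq_len(B), function(b) {
        mann_whitney_auc(sample(pos, m, replace = TRUE),
                         sample(neg, n, replace = TRUE))
      }, numeric(1))
      stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                      names = FALSE, type = 7)
    })
  }
  ci <- pmin(pmax(ci, 0), 1)
  structure(ci, auc = roc$auc, method = method, level = level)
}

#' Select an operating cutoff from a ROC curve
#'
#' `"youden"` maximises sensitivity + specificity - 1; `"closest_topleft"`
#' minimises (1-sens)^2 + (1-spec)^2. Ties are broken toward the operating
#' point with higher specificity, then toward the lower threshold value, so
#' the choice is deterministic. On a degenerate curve (all scores identical)
#' the median score is returned with a warning.
#'
#' @param roc A `thal_roc`.
#' @param rule `"youden"` or `"closest_topleft"`.
#' @return List: `threshold`, `sensitivity`, `specificity`, `rule`,
#'   `direction`.
#' @export
select_cutoff <- function(roc, rule = c("youden", "closest_topleft")) {
  stopifnot(inherits(roc, "thal_roc"))
  rule <- match.arg(rule)
  pts <- roc$points
  if (isTRUE(roc$degenerate)) {
    warning("degenerate ROC curve: returning the median score as threshold")
    med <- stats::median(c(roc$pos, roc$neg))
    return(list(threshold = med, sensitivity = NA_real_, specificity = NA_real_,
                rule = rule, direction = roc$direction))
  }
  inner <- is.finite(pts$threshold)
  cand <- pts[inner, , drop = FALSE]
  obj <- if (rule == "youden") cand$sensitivity + cand$specificity - 1
         else -((1 - cand$sensitivity)^2 + (1 - cand$specificity)^2)
  best <- which(obj >= max(obj) - 1e-12)  # tolerance so fp noise cannot mask ties
  if (length(best) > 1) {
    best <- best[cand$specificity[best] >= max(cand$specificity[best]) - 1e-12]
    best <- best[which.min(cand$threshold[best])]
  }
  list(threshold = cand$threshold[best],
       sensitivity = cand$sensitivity[best],
       specificity = cand$specificity[best],
       rule = rule, direction = roc$direction)
}

#' Shortlist candidate discriminator parameters
#'
#' For each candidate column, compares the two classes with a two-sided
#' Welch t-test and computes the Mann-Whitney AUC; a parameter is kept when
#' p < `alpha_level` and AUC > `auc_min`. No multiple-testing correction is
#' applied (a documented limitation). The report is sorted by AUC descending.
#'
#' @param cohort A labelled `thal_cohort` containing both classes.
#' @param parameters Character vector of column names to assess.
#' @param alpha_level Significance threshold for the class difference.
#' @param auc_min Minimum AUC to keep.
#' @param positive_class,negative_class Labels defining the contrast.
#' @return Data frame: parameter, auc, orientation flip, p_value, kept,
#'   n_pos, n_neg, note. Absent or unusable columns get `kept = NA` and note
#'   `"not_evaluable"`.
#' @export
shortlist_parameters <- function(cohort, parameters, alpha_level = 0.05,
                                 auc_min = 0.8,
                                 positive_class = "beta_trait",
                                 negative_class = "alpha_trait") {
  stopifnot(inherits(cohort, "thal_cohort"), "label" %in% names(cohort))
  df <- as.data.frame(cohort)
  df <- df[!is.na(df$label) & df$label %in% c(positive_class, negative_class), ]
  if (!any(df$label == positive_class) || !any(df$label == negative_class))
    stop("cohort must contain both ", positive_class, " and ", negative_class, call. = FALSE)

  rows <- lapply(parameters, function(p) {
    out <- data.frame(parameter = p, auc = NA_real_, flipped = NA,
                      p_value = NA_real_, kept = NA, n_pos = NA_integer_,
                      n_neg = NA_integer_, note = "", stringsAsFactors = FALSE)
    if (!p %in% names(df) || !is.numeric(df[[p]])) {
      out$note <- "not_evaluable"; return(out)
    }
    x <- df[[p]][df$label == positive_class]
    y <- df[[p]][df$label == negative_class]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) { out$note <- "not_evaluable"; return(out) }
    roc <- suppressWarnings(
      empirical_roc(df[[p]], df$label, positive_class, parameter_name = p))
    pv <- tryCatch(stats::t.test(x, y, var.equal = FALSE)$p.value,
                   error = function(e) NA_real_)  # e.g. both classes constant
    if (is.na(pv)) { out$auc <- roc$auc; out$note <- "constant data: no p-value"; return(out) }
    out$auc <- roc$auc; out$flipped <- roc$flipped
    out$p_value <- pv
    out$kept <- (pv < alpha_level) && (roc$auc > auc_min)
    out$n_pos <- length(x); out$n_neg <- length(y)
    out
  })
  rep <- do.call(rbind, rows)
  rep[order(-rep$auc, rep$parameter, na.last = TRUE), , drop = FALSE]
}

#' @export
print.thal_roc <- function(x, ...) {
  cat(sprintf("<thal_roc> %s: AUC %.4f (%d pos / %d neg, direction %s%s)\n",
              x$parameter_name, x$auc, x$n_pos, x$n_neg, x$direction,
              if (x$flipped) ", orientation flipped" else ""))
  invisible(x)
}
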