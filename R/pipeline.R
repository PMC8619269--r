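default_candidate_parameters <- function() {
  c("mn_lmals_ret", "rdw", "mch", "mcv", "maf",
    "mn_v_ret", "mn_v_nret", "mn_mals_ret", "mn_lmals_nret")
}

#' Develop the composite discriminant on a labelled cohort
#'
#' Reproduces the algorithm-development procedure on a cohort containing
#' alpha- and beta-trait records: shortlist candidate parameters by Welch
#' p-value and AUC, build the empirical ROC of the fixed composite score
#' (its form — light-scatter channel times RDW minus MCH — is fixed; only
#' the cutoff and its performance are re-derived), attach an AUC confidence
#' interval, and select an operating cutoff.
#'
#' @param cohort A labelled `thal_cohort` with alpha- and beta-trait records.
#' @param config A [screening_config()].
#' @param parameters Candidate columns for shortlisting.
#' @param rule Cutoff-selection rule, see [select_cutoff()].
#' @param ci_method AUC CI method, see [auc_ci()].
#' @param level Confidence level.
#' @param seed Seed (used by the bootstrap CI only).
#' @param out_dir If given, writes `shortlist.csv`, `roc_points.csv` and
#'   `develop_summary.csv` (with metadata sidecars) there.
#' @return A `thal_develop_report`: `shortlist`, `roc`, `auc_ci`, `cutoff`,
#'   `n_pos`, `n_neg`, `exclusions`.
#' @export
run_develop <- function(cohort, config = screening_config(),
                        parameters = default_candidate_parameters(),
                        rule = "youden", ci_method = "delong", level = 0.95,
                        seed = NULL, out_dir = NULL) {
  stopifnot(inherits(cohort, "thal_cohort"), "label" %in% names(cohort))
  ab <- cohort_subset(cohort, c("alpha_trait", "beta_trait"))
  if (nrow(ab) == 0) stop("cohort has no alpha/beta-trait records", call. = FALSE)
  scored <- score_cohort(ab, config, include_classical = FALSE)
  usable <- scored$call != "not_evaluable"
  n_excl <- sum(!usable)
  labs <- ab$label[usable]
  if (min(table(factor(labs, c("alpha_trait", "beta_trait")))) < 10)
    warning("fewer than 10 evaluable subjects in a class: estimates will be unstable")

  shortlist <- shortlist_parameters(ab, intersect(parameters, names(ab)))
  roc <- empirical_roc(scored$score[usable], labs, positive_class = "beta_trait",
                       parameter_name = "ab_score")
  ci <- auc_ci(roc, method = ci_method, level = level, seed = seed)
  cut <- select_cutoff(roc, rule = rule)

  report <- structure(list(shortlist = shortlist, roc = roc, auc_ci = ci,
                           cutoff = cut, n_pos = roc$n_pos, n_neg = roc$n_neg,
                           exclusions = n_excl, config = config),
                      class = "thal_develop_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(shortlist, file.path(out_dir, "shortlist.csv"),
                  seed = seed, config = unclass(config))
    write_results(roc$points, file.path(out_dir, "roc_points.csv"),
                  seed = seed, config = unclass(config))
    summary_df <- data.frame(auc = roc$auc, ci_low = ci[1], ci_high = ci[2],
                             flipped = roc$flipped,
                             threshold = cut$threshold,
                             sensitivity = cut$sensitivity,
                             specificity = cut$specificity,
                             rule = cut$rule, n_pos = roc$n_pos,
                             n_neg = roc$n_neg, n_excluded = n_excl)
    write_results(summary_df, file.path(out_dir, "develop_summary.csv"),
                  seed = seed, config = unclass(config))
  }
  report
}

#' Validate the discriminant on a labelled cohort
#'
#' Scores every subject, summarises the score distribution per disorder
#' group with an interquartile overlap report, and — for the alpha- vs
#' beta-trait contrast — builds the 2x2 contingency table at the configured
#' cutoff and computes diagnostic accuracy with confidence intervals.
#' Not-evaluable subjects are excluded from the table but reported; every
#' subject appears exactly once across scored and excluded sets.
#'
#' @param cohort A labelled `thal_cohort`.
#' @param config A [screening_config()].
#' @param ci_method Binomial CI method, see [accuracy_stats()].
#' @param level Confidence level.
#' @param seed Recorded into output metadata (validation itself is
#'   deterministic).
#' @param out_dir If given, writes `scores.csv`, `group_summary.csv`,
#'   `overlap.csv`, `contingency.csv` and `accuracy.csv` there.
#' @return A `thal_validate_report`: `scores`, `group_summary`, `overlap`,
#'   `contingency`, `accuracy` (the latter two `NULL` when a class is
#'   absent), `exclusions`.
#' @export
run_validate <- function(cohort, config = screening_config(),
                         ci_method = "wilson", level = 0.95, seed = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(cohort, "thal_cohort"), "label" %in% names(cohort))
  scored <- score_cohort(cohort, config, include_classical = FALSE)
  summary_df <- summarize_scores(cohort, config = config)
  overlap <- if (nrow(summary_df) >= 2) overlap_report(summary_df) else NULL

  ab <- scored[!is.na(scored$label) &
                 scored$label %in% c("alpha_trait", "beta_trait"), ]
  contingency <- NULL; accuracy <- NULL
  if (any(ab$label == "beta_trait") && any(ab$label == "alpha_trait")) {
    contingency <- build_contingency(ab$call, ab$label,
                                     positive_class = "beta_trait")
    accuracy <- accuracy_stats(contingency, ci_method = ci_method, level = level)
  } else {
    message("alpha/beta accuracy undefined: a trait class is absent; summaries still emitted")
  }
  report <- structure(list(scores = scored, group_summary = summary_df,
                           overlap = overlap, contingency = contingency,
                           accuracy = accuracy,
                           exclusions = sum(scored$call == "not_evaluable"),
                           config = config),
                      class = "thal_validate_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg <- unclass(config)
    write_results(scored, file.path(out_dir, "scores.csv"), seed = seed, config = cfg)
    write_results(summary_df, file.path(out_dir, "group_summary.csv"),
                  seed = seed, config = cfg)
    if (!is.null(overlap))
      write_results(overlap, file.path(out_dir, "overlap.csv"), seed = seed, config = cfg)
    if (!is.null(contingency)) {
      ct <- data.frame(tp = contingency$tp, fp = contingency$fp,
                       fn = contingency$fn, tn = contingency$tn,
                       n_excluded = contingency$n_excluded,
                       positive_class = contingency$positive_class)
      write_results(ct, file.path(out_dir, "contingency.csv"), seed = seed, config = cfg)
      write_results(accuracy, file.path(out_dir, "accuracy.csv"), seed = seed, config = cfg)
    }
  }
  report
}

#' @export
print.thal_develop_report <- function(x, ...) {
  cat("<thal_develop_report>\n")
  cat(sprintf("  composite AUC %.4f (%.0f%% CI %.4f-%.4f), %d beta / %d alpha\n",
              x$roc$auc, 100 * attr(x$auc_ci, "level"), x$auc_ci[1], x$auc_ci[2],
              x$n_pos, x$n_neg))
  cat(sprintf("  selected cutoff (%s): %.4f (sens %.3f, spec %.3f)\n",
              x$cutoff$rule, x$cutoff$threshold, x$cutoff$sensitivity,
              x$cutoff$specificity))
  cat(sprintf("  shortlisted parameters: %s\n",
              paste(x$shortlist$parameter[isTRUE(x$shortlist$kept) | x$shortlist$kept %in% TRUE],
                    collapse = ", ")))
  invisible(x)
}

#' @export
print.thal_validate_report <- function(x, ...) {
  cat("<thal_validate_report>\n")
  cat(sprintf("  %d subjects scored, %d not evaluable\n",
              nrow(x$scores), x$exclusions))
  if (!is.null(x$accuracy)) {
    for (i in seq_len(nrow(x$accuracy)))
      cat(sprintf("  %-12s %6.2f%% (%.0f%% CI %.4f-%.4f)\n",
                  x$accuracy$statistic[i], x$accuracy$percent[i],
                  100 * x$accuracy$level[i], x$accuracy$ci_low[i],
                  x$accuracy$ci_high[i]))
  }
  invisible(x)
}
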