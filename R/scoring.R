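#' Screening configuration
#'
#' Holds the decision cutoff for the composite alpha-beta score and the
#' red-cell-index thresholds of the initial microcytosis pre-screen
#' (MCH < 27 pg, MCV < 80 fL, RDW > 14%).
#'
#' @param cutoff Score decision threshold. Scores strictly above call
#'   beta-thalassaemia trait; at or below, alpha-thalassaemia trait.
#' @param mch_max Pre-screen MCH threshold, pg.
#' @param mcv_max Pre-screen MCV threshold, fL.
#' @param rdw_min Pre-screen RDW threshold, %.
#' @param screen_combination `"any"` (a subject screens in when any criterion
#'   fires; the conservative reading, fewer missed carriers) or `"all"`.
#' @return A `screening_config` list.
#' @export
screening_config <- function(cutoff = 1742.5, mch_max = 27, mcv_max = 80,
                             rdw_min = 14, screen_combination = c("any", "all")) {
  assert_scalar_number(cutoff, "cutoff")
  for (v in c(mch_max = mch_max, mcv_max = mcv_max, rdw_min = rdw_min))
    if (!is.finite(v) || v <= 0) stop("pre-screen thresholds must be positive", call. = FALSE)
  structure(list(cutoff = cutoff, mch_max = mch_max, mcv_max = mcv_max,
                 rdw_min = rdw_min,
                 screen_combination = match.arg(screen_combination)),
            class = "screening_config")
}

#' Composite alpha-beta score
#'
#' `mn_lmals_ret * rdw - mch`: the product of the two quantities elevated in
#' beta-trait relative to alpha-trait (reticulocyte lower-median-angle light
#' scatter and RDW) minus the one depressed (MCH). Vectorised; returns `NA`
#' where any input is missing.
#'
#' @param mn_lmals_ret Median lower-median-angle light scatter of
#'   reticulocytes, analyzer channel units.
#' @param rdw Red-cell distribution width, %.
#' @param mch Mean corpuscular haemoglobin, pg.
#' @return Numeric score(s), full floating precision.
#' @export
#' @examples
#' ab_score(109.5, 15.85, 22.3)  # 1713.275
ab_score <- function(mn_lmals_ret, rdw, mch) {
  mn_lmals_ret * rdw - mch
}

#' Classify a score at the cutoff
#'
#' Scores strictly above the cutoff call `beta_trait`; scores at or below
#' (including an exact tie) call `alpha_trait` — beta-trait is assigned only
#' to scores strictly above the decision threshold, so the tie goes to the
#' negative class. `NA` scores yield `NA`.
#'
#' @param score Numeric score(s).
#' @param config A [screening_config()], or a single numeric cutoff.
#' @return Character vector in `{"alpha_trait", "beta_trait"}`.
#' @export
classify_score <- function(score, config = screening_config()) {
  cutoff <- if (inherits(config, "screening_config")) config$cutoff else config
  assert_scalar_number(cutoff, "cutoff")
  if (any(!is.na(score) & !is.finite(score)))
    stop("scores must be finite", call. = FALSE)
  ifelse(is.na(score), NA_character_,
         ifelse(score > cutoff, "beta_trait", "alpha_trait"))
}

#' Red-cell-index pre-screen
#'
#' Flags subjects whose routine indices suggest a microcytic/hypochromic
#' picture worth scoring: MCH below `mch_max`, MCV below `mcv_max`, RDW above
#' `rdw_min`, combined by OR (`"any"`, default) or AND (`"all"`).
#'
#' @param mch,mcv,rdw Numeric vectors of the three indices.
#' @param config A [screening_config()].
#' @return Logical vector; `NA` where any required index is missing.
#' @export
prescreen <- function(mch, mcv, rdw, config = screening_config()) {
  crit <- cbind(mch < config$mch_max, mcv < config$mcv_max, rdw > config$rdw_min)
  if (config$screen_combination == "any") apply(crit, 1, function(r) any(r))
  else apply(crit, 1, function(r) all(r))
}

#' Classical red-cell discriminant indices
#'
#' The literature indices long used to separate thalassaemia trait from iron
#' deficiency, computed for comparison output only (their cutoffs are never
#' applied to make calls here): Mentzer (MCV/RBC), Shine & Lal
#' (MCV^2 x MCH / 100), England & Fraser (MCV - RBC - 5 Hb - 3.4), Ehsani
#' (MCV - 10 RBC), Srivastava (MCH/RBC), Green & King (MCV^2 x RDW / (100 Hb))
#' and the RDW Index (MCV x RDW / RBC). Formulas follow the original reports.
#'
#' @param hb Haemoglobin, g/dL.
#' @param rbc Red-cell count, 10^6/uL.
#' @param mcv Mean corpuscular volume, fL.
#' @param mch Mean corpuscular haemoglobin, pg.
#' @param rdw Red-cell distribution width, %.
#' @return Data frame with one column per index; an index whose denominator
#'   is zero is `NA` for that row (with a warning), the others are returned.
#' @export
classical_indices <- function(hb, rbc, mcv, mch, rdw) {
  n <- max(length(hb), length(rbc), length(mcv), length(mch), length(rdw))
  hb <- rep_len(hb, n); rbc <- rep_len(rbc, n); mcv <- rep_len(mcv, n)
  mch <- rep_len(mch, n); rdw <- rep_len(rdw, n)
  rbc0 <- !is.na(rbc) & rbc == 0
  hb0 <- !is.na(hb) & hb == 0
  if (any(rbc0)) warning("rbc = 0: Mentzer, Ehsani, Srivastava and RDW Index undefined for affected rows")
  if (any(hb0)) warning("hb = 0: Green & King undefined for affected rows")
  safe <- function(x, bad) ifelse(bad, NA_real_, x)
  data.frame(
    mentzer        = safe(mcv / rbc, rbc0),
    shine_lal      = mcv^2 * mch / 100,
    england_fraser = mcv - rbc - 5 * hb - 3.4,
    ehsani         = mcv - 10 * rbc,
    srivastava     = safe(mch / rbc, rbc0),
    green_king     = safe(mcv^2 * rdw / (100 * hb), hb0),
    rdw_index      = safe(mcv * rdw / rbc, rbc0)
  )
}

#' Score a cohort
#'
#' Computes the alpha-beta score, the pre-screen flag and the cutoff call for
#' every subject. Subjects with missing or flagged required inputs
#' (mn_lmals_ret, rdw, mch) receive call `not_evaluable`; flagged rows are
#' excluded from scoring by default but always accounted for.
#'
#' @param cohort A `thal_cohort`.
#' @param config A [screening_config()].
#' @param include_classical Append the [classical_indices()] columns when the
#'   needed inputs exist.
#' @param exclude_flagged Treat rows flagged at parse time as not evaluable.
#' @return Data frame: `subject_id`, `screened_in`, `score`, `call`
#'   (`alpha_trait` / `beta_trait` / `not_evaluable`), plus classical index
#'   columns when requested; `label` is carried through if present.
#' @export
score_cohort <- function(cohort, config = screening_config(),
                         include_classical = TRUE, exclude_flagged = TRUE) {
  stopifnot(inherits(cohort, "thal_cohort"))
  df <- as.data.frame(cohort)
  need <- c("mn_lmals_ret", "rdw", "mch")
  for (col in need) if (!col %in% names(df)) df[[col]] <- NA_real_

  usable <- !(exclude_flagged & df$.flagged)
  score <- ifelse(usable, ab_score(df$mn_lmals_ret, df$rdw, df$mch), NA_real_)
  call <- classify_score(score, config)
  call[is.na(call)] <- "not_evaluable"

  screened <- if (all(c("mcv") %in% names(df)))
    prescreen(df$mch, df$mcv, df$rdw, config) else NA

  out <- data.frame(subject_id = df$subject_id,
                    screened_in = screened,
                    score = score,
                    call = call,
                    stringsAsFactors = FALSE)
  if ("label" %in% names(df)) out$label <- df$label
  if (include_classical && all(c("hb", "rbc", "mcv") %in% names(df))) {
    out <- cbind(out, classical_indices(df$hb, df$rbc, df$mcv, df$mch, df$rdw))
  }
  out
}
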