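# Independent oracles used across the suite. Each is a deliberately naive
# implementation kept separate from the code paths it checks.

# AUC by exhaustive pair enumeration (wins + half-ties over all pos x neg pairs)
brute_pair_auc <- function(pos, neg) {
  wins <- 0; ties <- 0
  for (x in pos) for (y in neg) {
    if (x > y) wins <- wins + 1 else if (x == y) ties <- ties + 1
  }
  (wins + 0.5 * ties) / (length(pos) * length(neg))
}

# Youden-optimal operating point by exhaustive sweep over midpoint thresholds
# (direction ">": positive when score strictly above threshold), with the
# package's tie rule re-derived independently: highest J, then highest
# specificity, then lowest threshold.
brute_youden <- function(pos, neg) {
  u <- sort(unique(c(pos, neg)))
  thr <- (u[-length(u)] + u[-1]) / 2
  best <- NULL
  for (t in thr) {
    sens <- mean(pos > t); spec <- mean(neg <= t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-15 ||
        (abs(j - best$j) <= 1e-15 &&
         (spec > best$spec + 1e-15 ||
          (abs(spec - best$spec) <= 1e-15 && t < best$t)))) {
      best <- list(t = t, sens = sens, spec = spec, j = j)
    }
  }
  best
}

# Wilson interval by brute-force inversion of the score test: the interval is
# the set of p with |p_hat - p| <= z * sqrt(p (1 - p) / n). The acceptance
# region is a single interval, so a coarse grid brackets each boundary and a
# 1e-6 fine grid pins it down; pure grid search, no closed form.
invert_score_test <- function(k, n, level = 0.95, fine = 1e-6) {
  z <- qnorm(1 - (1 - level) / 2)
  accept <- function(p) abs(k / n - p) <= z * sqrt(p * (1 - p) / n)
  coarse <- seq(0, 1, by = 1e-3)
  acc <- accept(coarse)
  lo_i <- which(acc)[1]; hi_i <- rev(which(acc))[1]
  refine <- function(from, to, first) {
    g <- seq(max(0, from), min(1, to), by = fine)
    a <- accept(g)
    if (first) g[which(a)[1]] else g[rev(which(a))[1]]
  }
  c(refine(coarse[max(1, lo_i - 1)], coarse[lo_i], first = TRUE),
    refine(coarse[hi_i], coarse[min(length(coarse), hi_i + 1)], first = FALSE))
}

# P(X > Y) for X ~ N(mp, sp), Y ~ N(mn, sn) by numeric integration,
# independent of the closed form under test
integrate_binormal_auc <- function(mn, sn, mp, sp) {
  lo <- min(mn, mp) - 12 * max(sn, sp)
  hi <- max(mn, mp) + 12 * max(sn, sp)
  stats::integrate(function(x) dnorm(x, mp, sp) * pnorm(x, mn, sn),
                   lo, hi, rel.tol = 1e-10)$value
}

# score marginals from the in-house validation summaries with infinite
# bounds: the binormal oracle applies to the untruncated parameters
untruncated_ab_spec <- function(n_alpha, n_beta) {
  simulation_spec("untruncated_ab", groups = list(
    alpha_trait = list(n = n_alpha, params = list(
      score = c(1667.82, 148.21, -Inf, Inf),
      rdw = c(15.43, 1.45, 12.90, 21.40), mch = c(24.57, 2.18, 19.20, 32.80))),
    beta_trait = list(n = n_beta, params = list(
      score = c(1960.19, 248.65, -Inf, Inf),
      rdw = c(17.31, 2.01, 14.80, 24.30), mch = c(21.57, 2.17, 18.30, 26.30)))))
}

# small labelled cohort with exact control over scores: with rdw = 1 and
# mch = 20 (inside the sanity bounds), mn_lmals_ret = score + 20 makes
# ab_score return `scores` unchanged
cohort_from_scores <- function(scores, labels) {
  as_cohort(data.frame(subject_id = paste0("s", seq_along(scores)),
                       mn_lmals_ret = scores + 20, rdw = 1, mch = 20,
                       label = labels))
}
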