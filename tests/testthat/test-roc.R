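roc_of <- function(pos, neg) {
  empirical_roc(c(pos, neg),
                rep(c("beta_trait", "alpha_trait"), c(length(pos), length(neg))),
                parameter_name = "x")
}

test_that("perfectly separated classes give AUC 1 and a gap-midpoint cutoff", {
  roc <- roc_of(pos = c(10, 11, 12), neg = c(1, 2, 3))
  expect_equal(roc$auc, 1.0)
  cut <- select_cutoff(roc, "youden")
  expect_equal(cut$threshold, (3 + 10) / 2)
  expect_equal(cut$sensitivity, 1)
  expect_equal(cut$specificity, 1)
})

test_that("half-credit ties reproduce the exhaustive pair count on the toy instance", {
  roc <- roc_of(pos = c(2, 3, 4), neg = c(1, 2, 3))
  expect_equal(roc$auc, 7 / 9)  # 6 wins + 2 half-ties over 9 pairs
  expect_equal(roc$auc, brute_pair_auc(c(2, 3, 4), c(1, 2, 3)))
})

test_that("rank AUC equals the exhaustive pair oracle on random tied instances", {
  set.seed(501)
  for (i in 1:300) {
    m <- sample(1:30, 1); n <- sample(1:30, 1)
    # heavy rounding induces ties across and within classes
    pos <- round(rnorm(m, 0.5, 1), sample(0:1, 1))
    neg <- round(rnorm(n), sample(0:1, 1))
    roc <- suppressWarnings(roc_of(pos, neg))
    raw <- if (roc$flipped) 1 - roc$auc else roc$auc
    expect_equal(raw, brute_pair_auc(pos, neg), tolerance = 1e-12)
  }
})

test_that("the Mann-Whitney AUC equals the trapezoidal area under the ROC polygon", {
  set.seed(502)
  for (i in 1:50) {
    pos <- round(rnorm(sample(2:25, 1), 0.8), 1)
    neg <- round(rnorm(sample(2:25, 1)), 1)
    roc <- roc_of(pos, neg)
    expect_equal(trapezoid_auc(roc), roc$auc, tolerance = 1e-12)
  }
})

test_that("orientation flip complements the AUC and leaves the reported AUC >= 0.5", {
  set.seed(503)
  pos <- rnorm(40, -1); neg <- rnorm(60)  # positives lower: must flip
  roc <- roc_of(pos, neg)
  expect_true(roc$flipped)
  expect_equal(roc$direction, "<")
  expect_gte(roc$auc, 0.5)
  expect_equal(roc$auc, 1 - brute_pair_auc(pos, neg), tolerance = 1e-12)
})

test_that("operating points are monotone and invariant to a common score shift", {
  set.seed(504)
  pos <- rnorm(30, 1); neg <- rnorm(30)
  roc <- roc_of(pos, neg)
  expect_true(all(diff(roc$points$sensitivity) * diff(1 - roc$points$specificity) >= 0))
  o <- order(1 - roc$points$specificity, roc$points$sensitivity)
  expect_true(all(diff(roc$points$sensitivity[o]) >= -1e-12))
  shifted <- roc_of(pos + 100, neg + 100)
  expect_equal(shifted$points$sensitivity, roc$points$sensitivity)
  expect_equal(shifted$points$specificity, roc$points$specificity)
})

test_that("null scores give AUC near one half and all-identical scores degenerate to it", {
  set.seed(505)
  roc <- roc_of(rnorm(500), rnorm(500))
  expect_lt(abs(roc$auc - 0.5), 0.06)
  expect_warning(deg <- roc_of(rep(1, 5), rep(1, 7)), "degenerate")
  expect_equal(deg$auc, 0.5)
  expect_warning(cut <- select_cutoff(deg), "degenerate")
  expect_equal(cut$threshold, 1)
})

test_that("single-class input is an error", {
  expect_error(empirical_roc(1:5, rep("beta_trait", 5)), "both classes")
})

test_that("Youden cutoff selection matches the exhaustive sweep oracle", {
  set.seed(506)
  for (i in 1:100) {
    pos <- round(rnorm(sample(3:20, 1), 1), 1)
    neg <- round(rnorm(sample(3:20, 1)), 1)
    roc <- roc_of(pos, neg)
    if (roc$flipped) next  # oracle covers the un-flipped direction
    got <- select_cutoff(roc, "youden")
    want <- brute_youden(pos, neg)
    expect_equal(got$threshold, want$t)
    expect_equal(got$sensitivity, want$sens)
    expect_equal(got$specificity, want$spec)
  }
})

test_that("cutoff sens/spec are invariant under a positive monotone score transform", {
  set.seed(507)
  pos <- rnorm(25, 1.2); neg <- rnorm(25)
  a <- select_cutoff(roc_of(pos, neg))
  b <- select_cutoff(roc_of(10 * pos, 10 * neg))
  expect_equal(b$sensitivity, a$sensitivity)
  expect_equal(b$specificity, a$specificity)
  expect_equal(b$threshold, 10 * a$threshold)
})

test_that("DeLong CI matches an established independent implementation", {
  set.seed(508)
  pos <- rnorm(60, 0.9); neg <- rnorm(80)
  roc <- roc_of(pos, neg)
  ci <- auc_ci(roc, "delong")
  ref <- suppressMessages(pROC::ci.auc(
    pROC::roc(response = rep(c(1, 0), c(60, 80)), predictor = c(pos, neg),
              direction = "<", quiet = TRUE), method = "delong"))
  expect_equal(roc$auc, as.numeric(ref[2]), tolerance = 1e-12)
  expect_equal(ci[1], as.numeric(ref[1]), tolerance = 1e-9)
  expect_equal(ci[2], as.numeric(ref[3]), tolerance = 1e-9)
})

test_that("a perfect separator yields the degenerate zero-width DeLong interval", {
  roc <- roc_of(pos = 11:14, neg = 1:4)
  expect_warning(ci <- auc_ci(roc, "delong"), "zero DeLong variance")
  expect_equal(as.numeric(ci), c(1, 1))
})

test_that("bootstrap CI is seed-reproducible and small classes are rejected", {
  set.seed(509)
  pos <- rnorm(30, 1); neg <- rnorm(30)
  roc <- roc_of(pos, neg)
  ci1 <- auc_ci(roc, "bootstrap", seed = 99, B = 400)
  ci2 <- auc_ci(roc, "bootstrap", seed = 99, B = 400)
  expect_identical(as.numeric(ci1), as.numeric(ci2))
  expect_error(auc_ci(roc_of(1:2, c(0.5)), "delong"), "at least 2")
})

test_that("DeLong and bootstrap intervals both cover the binormal truth in repeated draws", {
  truth <- binormal_auc(0, 1, 1, 1)
  hits_d <- 0; hits_b <- 0; reps <- 60
  for (s in 1:reps) {
    set.seed(510 + s)
    pos <- rnorm(100, 1); neg <- rnorm(100)
    roc <- roc_of(pos, neg)
    d <- auc_ci(roc, "delong")
    b <- auc_ci(roc, "bootstrap", seed = s, B = 300)
    hits_d <- hits_d + (truth >= d[1] && truth <= d[2])
    hits_b <- hits_b + (truth >= b[1] && truth <= b[2])
    expect_lt(max(d[1], b[1]), min(d[2], b[2]))  # intervals overlap
  }
  expect_gte(hits_d / reps, 0.9)
  expect_gte(hits_b / reps, 0.9)
})

test_that("shortlisting keeps strong discriminators and drops pure noise", {
  set.seed(511)
  n <- 100
  co <- as_cohort(data.frame(
    subject_id = paste0("s", 1:(2 * n)),
    label = rep(c("alpha_trait", "beta_trait"), each = n),
    signal = c(rnorm(n), rnorm(n, 3)),       # 3 SD apart
    noise = rnorm(2 * n),                     # same distribution
    rdw = c(rnorm(n, 15.43, 1.45), rnorm(n, 17.31, 2.01))))
  rep <- shortlist_parameters(co, c("signal", "noise", "rdw", "absent_column"))
  expect_true(rep$kept[rep$parameter == "signal"])
  expect_false(rep$kept[rep$parameter == "noise"])
  expect_equal(rep$note[rep$parameter == "absent_column"], "not_evaluable")
  # sorted by AUC descending with not-evaluable rows last
  expect_equal(rep$parameter[1], "signal")
  expect_false(is.unsorted(rev(rep$auc[!is.na(rep$auc)])))
})
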