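test_that("built-in presets carry the published group summaries", {
  specs <- builtin_specs()
  vb <- specs$validation_cohort$groups$beta_trait
  expect_equal(vb$n, 48)
  expect_equal(unname(vb$params$score), c(1960.19, 248.65, 1604.30, 2819.50))
  va <- specs$validation_cohort$groups$alpha_trait
  expect_equal(va$n, 119)
  expect_equal(unname(va$params$score[1:2]), c(1667.82, 148.21))
  pa <- specs$primary_cohort$groups$alpha_trait
  expect_equal(unname(pa$params$rdw[1:2]), c(15.43, 1.45))
  expect_equal(specs$primary_cohort$groups$healthy$n, 1394)
  # presets survive serialization unchanged
  expect_identical(unserialize(serialize(specs, NULL)), specs)
})

test_that("simulation is byte-identical under a fixed seed and leaves the RNG alone", {
  spec <- builtin_specs()$validation_cohort
  set.seed(123); before <- rnorm(1)
  a <- simulate_cohort(spec, seed = 7, mode = "score")
  b <- simulate_cohort(spec, seed = 7, mode = "score")
  expect_identical(as.data.frame(a), as.data.frame(b))
  set.seed(123)
  expect_identical(rnorm(1), before)  # ambient stream untouched
  c2 <- simulate_cohort(spec, seed = 8, mode = "score")
  expect_false(identical(a$mn_lmals_ret, c2$mn_lmals_ret))
})

test_that("score-mode back-fill reproduces the drawn score through the composite", {
  co <- simulate_cohort(builtin_specs()$validation_cohort, seed = 11, mode = "score")
  sc <- score_cohort(co, include_classical = FALSE)
  expect_lt(max(abs(sc$score - co$drawn_score)), 1e-9)
})

test_that("simulated group moments track the specification", {
  spec <- builtin_specs()$validation_cohort
  co <- simulate_cohort(spec, n_per_group = 1000, seed = 21, mode = "score")
  for (g in names(spec$groups)) {
    m <- spec$groups[[g]]$params$score
    x <- co$drawn_score[co$label == g]
    expect_lt(abs(mean(x) - m[1]), 3 * m[2] / sqrt(1000))
  }
})

test_that("truncated draws respect their bounds and the sd = 0 edge case", {
  set.seed(701)
  x <- rtrunc_norm(5000, 10, 4, 8, 11)
  expect_true(all(x >= 8 & x <= 11))
  expect_equal(rtrunc_norm(3, 5, 0), rep(5, 3))
  # closed-form truncated moments agree with simulation
  mom <- truncnorm_moments(10, 4, 8, 11)
  expect_lt(abs(mean(x) - mom[1]), 4 * mom[2] / sqrt(5000))
  expect_lt(abs(sd(x) / mom[2] - 1), 0.05)
})

test_that("moment matching recovers printed summaries despite truncation", {
  # a marginal whose printed sd is near the uniform limit of its range
  set.seed(702)
  x <- thalscreen:::draw_marginal(20000, c(68.00, 6.24, 61.50, 82.10))
  expect_lt(abs(mean(x) - 68.00), 4 * 6.24 / sqrt(20000))
  expect_lt(abs(sd(x) / 6.24 - 1), 0.04)
})

test_that("the closed-form binormal AUC matches numeric integration", {
  expect_equal(binormal_auc(5, 1, 5, 2), 0.5)              # equal means
  expect_equal(binormal_auc(0, 1, 1e6, 1), 1.0)            # separation limit
  # in-house validation alpha vs beta parameters
  got <- binormal_auc(1667.82, 148.21, 1960.19, 248.65)
  expect_equal(got, integrate_binormal_auc(1667.82, 148.21, 1960.19, 248.65),
               tolerance = 1e-8)
  expect_equal(got, 0.8438, tolerance = 1e-4)
  expect_error(binormal_auc(0, 0, 1, 1), "positive")
})

test_that("group summaries expose the full statistic set with edge handling", {
  s <- summarize_values(c(3, 1, 2, 4, 10))
  expect_equal(s$n, 5)
  expect_equal(s$median, 3)
  expect_equal(s$range, 9)
  expect_equal(s$variance, s$sd^2, tolerance = 1e-9)
  expect_equal(s$q1, unname(quantile(c(3, 1, 2, 4, 10), 0.25)))

  one <- summarize_values(42)
  expect_true(is.na(one$sd))
  expect_match(one$note, "sd undefined")
  expect_equal(one$min, one$max)

  const <- summarize_values(rep(7, 10))
  expect_equal(const$sd, 0)
  expect_equal(const$range, 0)
})

test_that("interquartile overlap is exact interval arithmetic", {
  s <- data.frame(group = c("a", "b", "c"),
                  q1 = c(0, 0, 10), q3 = c(4, 4, 12))
  rep <- overlap_report(s)
  ab <- rep[rep$group1 == "a" & rep$group2 == "b", ]
  expect_equal(ab$overlap, 4)  # identical intervals: full overlap
  ac <- rep[rep$group1 == "a" & rep$group2 == "c", ]
  expect_equal(ac$overlap, 0)
  expect_true(ac$disjoint)

  # simulated alpha/beta groups: cross-check against direct empirical quartiles
  co <- simulate_cohort(builtin_specs()$validation_cohort,
                        n_per_group = 500, seed = 31, mode = "score")
  sm <- summarize_scores(co)
  ov <- overlap_report(sm)
  a <- quantile(co$drawn_score[co$label == "alpha_trait"], c(0.25, 0.75))
  b <- quantile(co$drawn_score[co$label == "beta_trait"], c(0.25, 0.75))
  want <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  got <- ov$overlap[(ov$group1 == "alpha_trait" & ov$group2 == "beta_trait") |
                    (ov$group1 == "beta_trait" & ov$group2 == "alpha_trait")]
  expect_equal(got, want)
})

test_that("component mode draws every marginal and leaves scores emergent", {
  co <- simulate_cohort(builtin_specs()$primary_cohort, n_per_group = 50,
                        seed = 41, mode = "component")
  expect_true(all(c("hb", "rbc", "mcv", "mch", "rdw", "mn_lmals_ret", "maf")
                  %in% names(co)))
  expect_false("drawn_score" %in% names(co))
  expect_equal(sum(co$label == "healthy"), 50)
  sc <- score_cohort(co, include_classical = FALSE)
  expect_true(all(is.finite(sc$score)))
})
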