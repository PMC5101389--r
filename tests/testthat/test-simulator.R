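test_that("the shipped ground truth reproduces the critical anchors", {
  # A/B coelute at 70% ACN / pH 2.8, independent of buffer level
  expect_lt(attr(outcome_at(70, 2.8, 20), "Rs_AB"), 0.05)
  expect_lt(attr(outcome_at(70, 2.8, 60), "Rs_AB"), 0.05)
  # C/D coelute at 75% / pH 4.68 / 40 mM while A/B resolve at 10.91
  crit <- outcome_at(75, 4.68, 40)
  expect_lt(attr(crit, "Rs_CD"), 0.05)
  expect_equal(attr(crit, "Rs_AB"), 10.91, tolerance = 0.2 / 10.91)
  # optimized conditions: baseline separation within 12 minutes
  opt <- outcome_at(80, 2.8, 40)
  expect_gte(attr(opt, "Rs_AB"), 2)
  expect_gte(attr(opt, "Rs_CD"), 2)
  expect_lte(attr(opt, "last_peak_time"), 12)
})

test_that("retention grows with acetonitrile and pH drives impurity A", {
  acns <- seq(70, 80, 1)
  ks <- sapply(acns, function(a) {
    o <- outcome_at(a, 2.8, 40)
    stats::setNames(o$k, o$compound)
  })
  for (cm in c("moxonidine", "impB", "impC", "impD"))
    expect_true(all(diff(ks[cm, ]) > 0), label = paste("monotone", cm))
  # pH is the dominant (negative) driver of impurity A at the center
  B <- default_truth$coefficients
  expect_lt(B["impA", "ph"], 0)
  expect_gt(abs(B["impA", "ph"]), abs(B["impA", "acn"]))
})

test_that("retention, width and dead time stay physical over the region", {
  a <- (2^3)^(1/4)
  g <- seq(-a, a, length.out = 11)
  pts <- as.matrix(expand.grid(g, g, g))
  pts <- pts[sqrt(rowSums(pts^2)) <= a, ]
  act <- to_actual(pts, hilic_factors())
  for (i in seq_len(nrow(act))) {
    o <- outcome_at(act[i, 1], act[i, 2], act[i, 3])
    expect_true(all(o$k > 0) && all(o$width > 0) &&
                  all(o$tr >= default_truth$t0))
  }
})

test_that("retention noise is seeded and reproducible", {
  o1 <- outcome_at(80, 2.8, 40, noise = TRUE, seed = 5)
  o2 <- outcome_at(80, 2.8, 40, noise = TRUE, seed = 5)
  o3 <- outcome_at(80, 2.8, 40, noise = TRUE, seed = 6)
  expect_identical(o1$k, o2$k)
  expect_false(identical(o1$k, o3$k))
  # marginal log10 k noise SD equals the configured 0.01
  tr <- default_truth
  expect_equal(sqrt(tr$sigma_logk_run^2 + tr$sigma_logk_compound^2), 0.01,
               tolerance = 1e-12)
})

test_that("resolution and retention-factor formulas match hand computations", {
  expect_equal(resolution(5, 5, 0.4, 0.4), 0)
  expect_equal(resolution(5.0, 6.0, 0.4, 0.6), 2.0)
  expect_equal(resolution(6.0, 5.0, 0.6, 0.4), resolution(5.0, 6.0, 0.4, 0.6))
  expect_error(resolution(5, 6, 0, 0.5), "positive")
  expect_equal(retention_factor(2.05, 2.05), 0)
  expect_equal(retention_factor(4.10, 2.05), 1)
  expect_equal(retention_factor(6.15, 2.05), 2.0)
  expect_error(retention_factor(1, 2.05), "t0")
})

test_that("inadmissible conditions are rejected", {
  expect_error(method_conditions(acn = 95), "admissible")
  expect_error(method_conditions(ph = 1.5), "admissible")
  expect_error(method_conditions(flow = 3), "admissible")
})

test_that("the in-silico study assembles one row per design run", {
  expect_equal(nrow(noiseless_study), 20)
  expect_named(noiseless_study, c("run_id", "k_M", "k_A", "k_B", "k_C",
                                  "k_D", "Rs_AB", "Rs_CD"))
  expect_true(all(as.matrix(noiseless_study[-1]) >= 0))
  s1 <- generate_study(default_truth, default_design, seed = 9)
  s2 <- generate_study(default_truth, default_design, seed = 9)
  expect_identical(s1, s2)
})

test_that("a noiseless study refit recovers the truth coefficients", {
  # log10 k responses are inside the quadratic model class
  X <- default_terms
  for (i in seq_len(ncol(noiseless_logk))) {
    cm <- rownames(default_truth$coefficients)[i]
    fit <- fit_pls(X, noiseless_logk[, i], ncomp = 9)
    expect_equal(unname(coef(fit)),
                 unname(default_truth$coefficients[cm, ]),
                 tolerance = 1e-6)
  }
})

test_that("study-level Q2 stays high at the default noise level", {
  # sigma_logk = 0.01: all seven responses keep Q2 > 0.7 in >= 90% of
  # 25 seeded replicate studies
  set.seed(515)
  ok <- replicate(25, {
    st <- generate_study(default_truth, default_design, noise = TRUE)
    models <- fit_study_models(default_design, st, ncomp = 9)
    all(vapply(models, `[[`, numeric(1), "Q2") > 0.7)
  })
  expect_gte(mean(ok), 0.9)
})

test_that("fitted coefficient signs match the reported factor effects", {
  models <- fit_study_models(default_design, noiseless_study, ncomp = 9)
  # acetonitrile in positive correlation with k_M, k_B, k_C, k_D
  for (r in c("k_M", "k_B", "k_C", "k_D")) {
    ct <- coefficient_table(models[[r]])
    expect_gt(ct$coefficient[ct$term == "acn"], 0)
  }
  # pH in negative correlation with k_A, and dominant over acetonitrile
  ctA <- coefficient_table(models[["k_A"]])
  expect_lt(ctA$coefficient[ctA$term == "ph"], 0)
  expect_gt(abs(ctA$coefficient[ctA$term == "ph"]),
            abs(ctA$coefficient[ctA$term == "acn"]))
})
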