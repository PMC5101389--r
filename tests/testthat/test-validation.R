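test_that("Student critical values match the tabulated ones", {
  expect_equal(t_critical(0.05, 7), 2.365, tolerance = 5e-4)
  expect_equal(t_critical(0.05, 9), 2.262, tolerance = 5e-4)
  expect_equal(t_critical(0.05, 1e6), 1.960, tolerance = 0.01)
  expect_error(t_critical(0.05, 0), "df")
})

test_that("a perfect line through the origin passes linearity", {
  s <- list(compound = "x", levels = 1:9,
            responses = matrix(rep(3 * (1:9), 2), ncol = 2))
  fit <- fit_linearity(s)
  expect_equal(fit$r, 1)
  expect_equal(fit$t, 0, tolerance = 1e-7)
  expect_true(fit$pass)
  expect_error(fit_linearity(list(levels = c(1, 2),
                                  responses = cbind(c(1, 2)))),
               "insufficient")
})

test_that("a real intercept is flagged by the t test", {
  # intercept engineered at 4x its standard error: two-sided t power at
  # df = 7 is ~0.93, so detection in >= 80% of replicates
  set.seed(606)
  hits <- replicate(200, {
    lv <- calibration_levels("impA")
    sig <- 0.05
    se_int <- sig * sqrt(1 / 9 + mean(lv)^2 / (8 * var(lv)))
    y <- 24 * lv + 4 * se_int + rnorm(9, sd = sig)
    f <- fit_linearity(list(levels = lv, responses = cbind(y)))
    !f$pass_intercept
  })
  expect_gte(mean(hits), 0.8)
})

test_that("linearity respects the configurable df", {
  s <- simulate_calibration("moxonidine", 29142, seed = 2)
  f1 <- fit_linearity(s)              # 6 level means -> df 4
  f2 <- fit_linearity(s, df = 7)
  expect_equal(f1$df, 4)
  expect_equal(f2$t_crit, t_critical(0.05, 7))
})

test_that("LOD/LOQ arithmetic reproduces the reported limits", {
  expect_equal(loq_from_lod(0.012), 0.04)
  expect_equal(loq_from_lod(0.024), 0.08)
  expect_equal(loq_from_lod(0.3), 1.0)
  expect_error(loq_from_lod(0), "positive")
  expect_equal(relative_percent(0.04, 100), 0.04)
  expect_equal(relative_percent(0, 100), 0)
  expect_equal(relative_percent(100, 100), 100)
  expect_error(relative_percent(1, 0), "positive")
})

test_that("trace-based LOD estimation recovers an engineered S/N", {
  # engineered S/N ~ 30 at 0.12 ug/mL -> LOD ~ 0.012 ug/mL
  lods <- sapply(1:50, function(s) {
    h <- 30 / 2 * (6 * 0.05) # height giving 2H/h = 30 for p2p noise ~6 sigma
    peak <- data.frame(compound = "impA", k = 1, tr = 5, width = 0.4,
                       area = 1, height = h)
    tr <- simulate_chromatogram(peak, baseline_sigma = 0.05,
                                sampling_rate = 10, duration = 8, seed = s)
    r <- lod_loq_from_trace(tr, c(4.5, 5.5), c(0.5, 2.5), conc = 0.12)
    expect_equal(r$loq_conc / r$lod_conc, 10 / 3, tolerance = 1e-12)
    r$lod_conc
  })
  expect_equal(median(lods), 0.012, tolerance = 0.15)
  # doubling the analyte concentration doubles S/N on a fixed noise floor
  peak <- data.frame(compound = "x", k = 1, tr = 5, width = 0.4, area = 1,
                     height = 4)
  tr1 <- simulate_chromatogram(peak, baseline_sigma = 0, sampling_rate = 10,
                               duration = 8)
  base_noise <- sin(seq_len(nrow(tr1))) * 0.05
  tr1$signal <- tr1$signal + base_noise
  tr2 <- tr1; tr2$signal <- 2 * (tr1$signal - base_noise) + base_noise
  s1 <- measure_snr(tr1, c(4.5, 5.5), c(0.5, 2.5))
  s2 <- measure_snr(tr2, c(4.5, 5.5), c(0.5, 2.5))
  expect_equal(s2 / s1, 2, tolerance = 0.01)
})

test_that("the benchmark recovery table is classified pass throughout", {
  bench <- recovery_benchmark()
  acc <- assess_accuracy(bench)
  expect_true(all(acc$pass_accuracy))
  prec <- assess_precision(bench)
  expect_true(all(prec$pass_precision))
  expect_equal(nrow(bench), 15)
  imp <- bench[bench$role == "impurity", ]
  expect_equal(min(imp$recovery), 93.66)
  expect_equal(max(imp$recovery), 114.08)
})

test_that("accuracy windows depend on role and impurity level", {
  rec <- data.frame(
    compound = c("moxonidine", "moxonidine", "impC", "impA"),
    role = c("API", "API", "impurity", "impurity"),
    level_percent = c(100, 100, 1.0, 0.04),
    recovery = c(101.15, 97.0, 114.08, 95.89))
  out <- assess_accuracy(rec)
  expect_equal(out$pass_accuracy, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(out$window_low, c(98, 98, 80, 70))
})

test_that("precision thresholds depend on the compound class", {
  rec <- data.frame(compound = c("moxonidine", "impA", "moxonidine",
                                 "impC"),
                    rsd = c(1.85, 3.79, 2.5, 10.5))
  out <- assess_precision(rec)
  expect_equal(out$pass_precision, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$rsd_limit, c(2, 15, 2, 10))
})

test_that("the OFAT robustness study passes at the published deltas", {
  rob <- robustness_ofat(default_truth)
  expect_equal(nrow(rob), 8)
  expect_true(all(rob$pass))
  expect_true(all(rob$max_tr_change < 3))
  expect_true(all(rob$max_rs_change < 3))
  expect_true(all(rob$max_area_change < 5))
  # zero deltas change nothing
  z <- robustness_ofat(default_truth,
                       plan = data.frame(factor = "acn", delta = 0))
  expect_equal(z$max_tr_change, 0)
  expect_true(z$pass)
  # an exaggerated acetonitrile shift breaks the thresholds
  big <- robustness_ofat(default_truth,
                         plan = data.frame(factor = "acn", delta = 5))
  expect_false(big$pass)
})

test_that("the robustness pass rule is the conjunction of the three limits", {
  mk <- function(area, tr, rs)
    area < 5 && tr < 3 && rs < 3
  expect_true(mk(4.99, 2.99, 2.99))
  expect_false(mk(5.01, 2.99, 2.99))
  expect_false(mk(4.99, 3.01, 2.99))
  expect_false(mk(4.99, 2.99, 3.01))
  # and the implementation applies it with strict inequalities
  rob <- robustness_ofat(default_truth,
                         limits = c(area = 1e-9, tr = 1e-9, rs = 1e-9),
                         plan = data.frame(factor = "acn", delta = 0.5))
  expect_false(rob$pass)
})

test_that("selectivity flags an interferent inside an analyte window", {
  flat <- simulate_chromatogram(NULL, baseline_sigma = 0.01, duration = 10,
                                seed = 2)
  expect_true(assess_selectivity(flat, list(c(4, 5)), 10)$pass)
  spiked <- flat
  spiked$signal[spiked$time_min > 4.4 & spiked$time_min < 4.6] <- 8
  expect_false(assess_selectivity(spiked, list(c(4, 5)), 10)$pass)
  expect_true(assess_selectivity(spiked, list(c(4, 5)), 10,
                                 threshold = Inf)$pass)
})

test_that("the tablet assay recovers the simulated contents", {
  cal <- lapply(stats::setNames(nm = moxonidine_compounds()$compound),
                function(nm) fit_linearity(simulate_calibration(
                  nm, default_truth$response_factors[[nm]], sigma0 = 0,
                  sigma_rel = 0)))
  noise_rsd <- 0.005
  sample <- simulate_tablet_sample(default_truth, noise_rsd = noise_rsd,
                                   seed = 77)
  res <- assay_tablet(sample$responses, cal,
                      loq = c(impA = 0.04, impB = 0.04, impC = 0.08,
                              impD = 0.08))
  truth_pct <- sample$content
  for (nm in c("moxonidine", "impC", "impD")) {
    row <- res[res$compound == nm, ]
    expect_false(row$below_loq)
    expect_equal(row$content_percent, truth_pct[[nm]],
                 tolerance = 2 * noise_rsd)
  }
  expect_true(all(res$below_loq[res$compound %in% c("impA", "impB")]))
  # zero responses fall below the detection limit
  zero <- stats::setNames(rep(0, 5), names(sample$responses))
  rz <- assay_tablet(zero, cal, loq = c(impA = 0.04), lod = c(impA = 0.012))
  expect_true(rz$below_lod[rz$compound == "impA"])
  # content is invariant under a dilution round-trip
  half <- assay_tablet(sample$responses / 2, cal)
  expect_equal(half$conc * 2, assay_tablet(sample$responses, cal)$conc,
               tolerance = 1e-10)
})

test_that("specification checks honour limits and below-LOQ flags", {
  contents <- data.frame(
    compound = c("impA", "impB", "impC", "impD"),
    content_percent = c(NA, NA, 0.68, 0.87),
    below_loq = c(TRUE, TRUE, FALSE, FALSE))
  expect_true(check_specification(contents)$pass)
  contents$content_percent[3] <- 1.2
  contents$below_loq[3] <- FALSE
  expect_false(check_specification(contents)$pass)
  expect_true(check_specification(contents, limits = numeric(0))$pass)
})
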