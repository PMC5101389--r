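test_that("full-component PLS reproduces the least-squares fit", {
  # 50 random full-rank problems against the normal-equations oracle
  set.seed(101)
  for (r in 1:50) {
    n <- sample(15:30, 1); p <- sample(3:8, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% rnorm(p)) + rnorm(n, sd = 0.3) + 2
    fit <- fit_pls(X, y, ncomp = p)
    expect_equal(unname(coef(fit)), unname(ls_oracle(X, y)),
                 tolerance = 1e-8)
  }
})

test_that("a single-column fit equals the simple regression slope", {
  set.seed(7)
  x <- matrix(rnorm(20), ncol = 1)
  y <- 3 * x[, 1] + rnorm(20, sd = 0.1)
  fit <- fit_pls(x, y, ncomp = 1)
  ls <- ls_oracle(x, y)
  expect_equal(unname(coef(fit)[2]), unname(ls[2]), tolerance = 1e-10)
})

test_that("noiseless responses on the screening design are recovered exactly", {
  beta <- c(0.4, 0.15, -0.26, 0.02, 0.01, -0.02, 0, -0.03, 0, -0.02)
  y <- drop(cbind(1, default_terms) %*% beta)
  fit <- fit_pls(default_terms, y, ncomp = 9)
  expect_equal(unname(coef(fit)), beta, tolerance = 1e-6)
  expect_equal(fit$R2, 1, tolerance = 1e-10)
  # prediction at a training point reproduces the training value
  expect_equal(unname(predict(fit, default_terms[16, , drop = FALSE])),
               y[[16]], tolerance = 1e-6)
  # prediction at the center equals the center response
  expect_equal(unname(predict(fit, c(0, 0, 0))), y[[1]], tolerance = 1e-6)
  # agreement with the least-squares surface at random interior points
  set.seed(3)
  pts <- matrix(runif(30, -1, 1), ncol = 3)
  ls <- ls_oracle(default_terms, y)
  Xp <- expand_terms(pts)
  expect_equal(unname(predict(fit, Xp)),
               unname(drop(cbind(1, Xp) %*% ls)), tolerance = 1e-6)
})

test_that("identical inputs give identical models (determinism)", {
  y <- noiseless_study$k_C
  f1 <- fit_pls(default_terms, y)
  f2 <- fit_pls(default_terms, y)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$ncomp, f2$ncomp)
})

test_that("leave-one-out Q2 behaves as a cross-validation statistic", {
  # model class contains the truth -> Q2 = 1, PRESS = 0
  beta <- c(1, 0.5, -0.2, 0.1, 0.05, 0, 0, 0.02, 0, 0)
  y <- drop(cbind(1, default_terms) %*% beta)
  q <- q2_loo(default_terms, y, ncomp = 9)
  expect_equal(q$Q2, 1, tolerance = 1e-6)
  expect_equal(q$PRESS, 0, tolerance = 1e-6)

  # structureless responses: Q2 <= 0 in the majority of seeded replicates
  set.seed(202)
  neg <- replicate(200, q2_loo(default_terms, rnorm(20), ncomp = 3)$Q2 <= 0)
  expect_gt(mean(neg), 0.5)

  # degenerate response errors
  expect_error(q2_loo(default_terms, rep(1, 20), 2), "degenerate")
})

test_that("Q2 never exceeds R2 on the simulated study responses", {
  models <- fit_study_models(default_design, noiseless_study)
  for (m in models) expect_lte(m$Q2, m$R2 + 1e-8)
})

test_that("ncomp exceeding the rank is truncated with a warning", {
  X <- default_terms[, 1:3]
  y <- drop(X %*% c(1, 2, 3)) + rnorm(20, sd = 0.01)
  expect_warning(fit <- fit_pls(X, y, ncomp = 7), "rank")
  expect_lte(fit$ncomp, 3)
  expect_error(fit_pls(default_terms, rep(2, 20)), "degenerate")
})

test_that("jackknife intervals flag true zero terms and detect strong effects", {
  # exactly-zero coefficient on ph:buffer -> insignificant
  beta <- c(1, 0.5, -0.3, 0.1, 0.05, -0.02, 0.01, 0.03, 0.02, 0)
  y <- drop(cbind(1, default_terms) %*% beta)
  ci <- coefficient_ci(fit_pls(default_terms, y, ncomp = 9))
  expect_false(ci$significant[ci$term == "ph:buffer"])

  # large acn effect at small noise: significant and positive almost always
  set.seed(303)
  hits <- replicate(200, {
    yn <- drop(cbind(1, default_terms) %*% beta) + rnorm(20, sd = 0.05)
    ci <- coefficient_ci(fit_pls(default_terms, yn, ncomp = 9))
    row <- ci[ci$term == "acn", ]
    row$significant && row$coefficient > 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("interval width shrinks as the noise level drops", {
  beta <- c(1, 0.5, -0.3, 0.1, 0.05, -0.02, 0.01, 0.03, 0.02, 0.01)
  widths <- sapply(c(0.4, 0.1, 0.025), function(s) {
    set.seed(404)
    mean(replicate(30, {
      y <- drop(cbind(1, default_terms) %*% beta) + rnorm(20, sd = s)
      ci <- coefficient_ci(fit_pls(default_terms, y, ncomp = 9))
      mean(ci$ci_high - ci$ci_low)
    }))
  })
  expect_true(all(diff(widths) < 0))
})

test_that("the coefficient table has the fixed 9-term layout", {
  fit <- fit_pls(default_terms, noiseless_study$k_A, ncomp = 9)
  ct <- coefficient_table(fit)
  expect_equal(nrow(ct), 9)
  expect_equal(ct$term, colnames(default_terms))
  expect_named(ct, c("term", "coefficient", "ci_low", "ci_high",
                     "significant"))
})

test_that("predicting far outside the design region warns", {
  fit <- fit_pls(default_terms, noiseless_study$k_C, ncomp = 9)
  expect_warning(predict(fit, c(3, 3, 3)), "outside")
  expect_silent(predict(fit, c(1, -1, 0)))
})
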