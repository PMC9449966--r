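test_that("coefficients of variation follow their definitions", {
  vc <- variance_components(4 * 4 + 0.25, ms_error = 0.25, r = 4)
  expect_equal(vc$sigma2_g, 4)
  cv <- coefficients_of_variation(vc, grand_mean = 20)
  expect_equal(cv$gcv, 10)
  expect_equal(cv$pcv, 100 * sqrt(4.25) / 20, tolerance = 1e-12)
  expect_equal(cv$ecv, 100 * sqrt(0.25) / 20, tolerance = 1e-12)
  expect_true(cv$gcv <= cv$pcv)
  expect_error(coefficients_of_variation(vc, 0), "non-positive")

  # zero error variance: pcv == gcv
  vc2 <- variance_components(8, ms_error = 0, r = 4)
  cv2 <- coefficients_of_variation(vc2, 10)
  expect_equal(cv2$pcv, cv2$gcv)
})

test_that("broad-sense heritability is the genotypic variance share", {
  vc <- variance_components(2, ms_error = 2, r = 4)  # sigma2_g = 0
  expect_equal(broad_sense_heritability(vc), 0)
  vc2 <- variance_components(10, ms_error = 2, r = 4)
  expect_equal(broad_sense_heritability(vc2), 0.5)
  vc0 <- variance_components(0, ms_error = 0, r = 4)
  expect_warning(h <- broad_sense_heritability(vc0), "undefined")
  expect_true(is.na(h))
})

test_that("heritability implied by printed CVs matches the reference rows", {
  # plant height: PCV 6.08, GCV 5.83 -> 91.94 -> 92
  expect_equal(round(100 * h2_from_cv(5.83, 6.08)), 92)
  # fruit aspect ratio: PCV 6.86, GCV 3.80 -> 30.68 -> 31
  expect_equal(round(100 * h2_from_cv(3.80, 6.86)), 31)
  expect_equal(100 * h2_from_cv(3.80, 6.86), 30.68, tolerance = 0.005)
})

test_that("genetic advance reproduces the k*h2*pcv chain", {
  vc <- variance_components(10, ms_error = 2, r = 4)
  h2 <- broad_sense_heritability(vc)
  ga0 <- genetic_advance(vc, 0, k = 2.06, grand_mean = 10)
  expect_equal(ga0$ga, 0)
  ga <- genetic_advance(vc, h2, k = 2.06, grand_mean = 10)
  expect_equal(ga$ga, 2.06 * 0.5 * 2, tolerance = 1e-12)
  expect_equal(ga$ga_percent_mean, 100 * ga$ga / 10, tolerance = 1e-12)
  # reference rows via the printed-CV route: GA% = k * GCV^2 / PCV
  expect_equal(2.06 * 21.10^2 / 21.22, 43.22, tolerance = 0.005)
  expect_equal(2.06 * 16.39^2 / 16.49, 33.56, tolerance = 0.005)
  expect_error(genetic_advance(vc, h2, k = 0, grand_mean = 10), "positive")
})

test_that("qualitative bands use left-closed conventional cutoffs", {
  expect_identical(classify_cv(c(9.99, 10, 16.49, 20, 20.01)),
                   c("low", "moderate", "moderate", "moderate", "high"))
  expect_identical(classify_h2(c(29.9, 30, 60, 92)),
                   c("low", "moderate", "moderate", "high"))
  expect_identical(classify_h2(0.92, percent = FALSE), "high")
  expect_identical(classify_ga(c(9.99, 10.0, 43.22)),
                   c("low", "moderate", "high"))
})

test_that("the fitted parameter table satisfies its internal identities", {
  sim <- simulate_trial(demo_trial_spec(seed = 9))
  fit <- rbd_genetics(sim$dataset, year = "2020-2021",
                      correlations = FALSE)
  p <- fit$params
  expect_identical(nrow(p), 22L)
  expect_true(all(p$gcv <= p$pcv + 1e-12))
  expect_true(all(p$h2 >= 0 & p$h2 <= 1))
  # ga% = k * h2 * pcv and h2 = (gcv/pcv)^2, exactly
  expect_equal(p$ga_percent_mean, fit$k * p$h2 * p$pcv, tolerance = 1e-9)
  expect_equal(p$h2, (p$gcv / p$pcv)^2, tolerance = 1e-12)
  expect_equal(p$sigma2_p, p$sigma2_g + p$sigma2_e, tolerance = 1e-12)

  cm <- coef(fit)
  expect_identical(rownames(cm), p$trait)
  expect_identical(colnames(cm), c("sigma2_g", "sigma2_e", "sigma2_p", "h2"))
  expect_output(print(fit), "Clonal-trial genetic parameters")
  expect_output(print(summary(fit)), "Qualitative bands")
})

test_that("RBD residuals sum to zero within clones and blocks", {
  sim <- simulate_trial(demo_trial_spec(seed = 13))
  fit <- rbd_genetics(sim$dataset, year = "2020-2021",
                      traits = c("seed_yield", "plant_height"),
                      correlations = FALSE)
  res <- rbd_residuals(sim$dataset, fit)
  for (tr in unique(res$trait)) {
    sub <- res[res$trait == tr, ]
    expect_equal(max(abs(tapply(sub$residual, sub$clone, sum))), 0,
                 tolerance = 1e-9)
    expect_equal(max(abs(tapply(sub$residual, sub$replication, sum))), 0,
                 tolerance = 1e-9)
  }
})
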