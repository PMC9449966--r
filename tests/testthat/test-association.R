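test_that("perfect linear dependence gives correlation -1 across levels", {
  set.seed(71)
  # clear clone effects so the genotypic variance estimate is positive
  m <- outer(seq(0, 10, 2), rep(1, 4)) + matrix(rnorm(24, 10, 0.5), 6, 4)
  ds <- grid_trial2(m, -m)
  cs <- correlation_matrices(ds, year = "y1")
  expect_equal(unname(diag(cs$r_g)), rep(1, 2))
  expect_equal(cs$r_p["x", "y"], -1, tolerance = 1e-9)
  expect_equal(cs$r_g["x", "y"], -1, tolerance = 1e-9)
  expect_equal(cs$r_e["x", "y"], -1, tolerance = 1e-9)
})

test_that("zero-variance traits yield undefined correlation cells", {
  m <- matrix(rnorm(24, 10), 6, 4)
  ds <- grid_trial2(m, matrix(5, 6, 4))
  cs <- suppressWarnings(correlation_matrices(ds, year = "y1"))
  expect_true(is.na(cs$r_g["x", "y"]))
  expect_true(is.na(cs$r_p["x", "y"]))
})

test_that("correlation significance uses the t test on n - 2 df", {
  expect_false(cor_significance(0, 10)$significant)
  expect_true(cor_significance(0.845, 6)$significant)
  expect_false(cor_significance(0.50, 6)$significant)
  # critical |r| at n = 6, alpha = 0.05 is about 0.811
  expect_equal(critical_r(6), 0.8114, tolerance = 5e-4)
  expect_true(cor_significance(critical_r(6) + 1e-6, 6)$significant)
  expect_false(cor_significance(critical_r(6) - 1e-6, 6)$significant)
  deg <- cor_significance(1.02, 6)
  expect_true(deg$significant)
  expect_match(deg$note, "degenerate")
  expect_error(cor_significance(0.5, 2), "n >= 3")
})

test_that("out-of-range genotypic correlations are flagged, never clamped", {
  # low-heritability noise regularly pushes |r_g| past 1 at small g
  found <- FALSE
  for (s in 1:60) {
    spec <- trial_sim_spec(g = 4, r = 2, mu = c(x = 10, y = 10),
                           Sigma_g = matrix(c(1, 0.95, 0.95, 1), 2),
                           Sigma_e = c(3, 3), seed = s)
    cs <- correlation_matrices(simulate_trial(spec)$dataset, year = "year1")
    if (!is.na(cs$r_g["x", "y"]) && abs(cs$r_g["x", "y"]) > 1) {
      found <- TRUE
      expect_true(cs$out_of_range["x", "y"])
      expect_gt(abs(cs$r_g["x", "y"]), 1)  # value kept raw
      expect_error(path_analysis(cs, target = "y"), "outside \\[-1, 1\\]")
      break
    }
  }
  expect_true(found)
})

test_that("null genotypic correlations are centred with calibrated flags", {
  n_sim <- 1000
  hits <- logical(n_sim)
  est <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    spec <- trial_sim_spec(g = 20, r = 4, mu = c(x = 10, y = 10),
                           Sigma_g = c(0.95, 0.95),
                           Sigma_e = c(0.05, 0.05),
                           block_sd = 0.1, seed = s)
    cs <- correlation_matrices(simulate_trial(spec)$dataset, year = "year1")
    est[s] <- cs$r_g["x", "y"]
    hits[s] <- isTRUE(cs$sig_g["x", "y"])
  }
  expect_lt(abs(mean(est, na.rm = TRUE)), 0.03)
  mc_sd <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(mean(hits) - 0.05), 2 * mc_sd)
})

test_that("path analysis solves the correlation normal equations", {
  # orthogonal predictors: direct effects are the target correlations
  ry <- c(a = 0.3, b = -0.5, c = 0.2)
  R <- diag(3); dimnames(R) <- list(names(ry), names(ry))
  pr <- path_analysis(R, ry)
  expect_equal(pr$direct, ry)
  expect_equal(unname(pr$indirect[upper.tri(pr$indirect)]), rep(0, 3))
  expect_equal(pr$residual_squared, 1 - sum(ry^2), tolerance = 1e-12)

  # 2-predictor worked system vs the hand-rolled elimination oracle
  R2 <- matrix(c(1, 0.5, 0.5, 1), 2,
               dimnames = list(c("p1", "p2"), c("p1", "p2")))
  ry2 <- c(p1 = 0.8, p2 = 0.7)
  pr2 <- path_analysis(R2, ry2)
  expect_equal(unname(pr2$direct), brute_solve(R2, ry2), tolerance = 1e-12)
  expect_equal(pr2$reconstruction, ry2, tolerance = 1e-12)
  expect_equal(pr2$residual_squared, 1 - sum(pr2$direct * ry2),
               tolerance = 1e-12)
})

test_that("singular or out-of-range predictor matrices are refused", {
  R <- matrix(c(1, 1, 1, 1), 2)
  expect_error(path_analysis(R, c(0.5, 0.5)), "ill-conditioned|singular")
  R2 <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_error(path_analysis(R2, c(0.5, 0.5)), "exceeds 1")
  # out-of-range target correlations can be truncated on request
  R3 <- matrix(c(1, 0.5, 0.5, 1), 2)
  pr <- path_analysis(R3, c(1.2, 0.5), clamp = TRUE)
  expect_equal(unname(pr$target_corr), c(1, 0.5))
  expect_error(path_analysis(matrix(c(1, 0.2, 0.3, 1), 2), c(0.1, 0.1)),
               "symmetric")
})

test_that("simulated genotypic correlation is recovered on average", {
  # moderate version of the recovery experiment (full run in acceptance)
  n_sim <- 40
  est <- numeric(n_sim)
  Sg <- matrix(c(0.8, 0.6 * 0.8, 0.6 * 0.8, 0.8), 2)
  for (s in seq_len(n_sim)) {
    spec <- trial_sim_spec(g = 50, r = 4, mu = c(x = 20, y = 20),
                           Sigma_g = Sg, Sigma_e = c(0.2, 0.2),
                           block_sd = 0.1, seed = 5000 + s)
    cs <- correlation_matrices(simulate_trial(spec)$dataset, year = "year1")
    est[s] <- cs$r_g["x", "y"]
  }
  expect_lt(abs(mean(est) - 0.6), 0.05)
})
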