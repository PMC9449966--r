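test_that("degenerate all-equal input yields zero SS and undefined F", {
  ds <- grid_trial(matrix(7, 4, 3))
  an <- rbd_anova(ds, "y", "y1")
  expect_equal(an$table$sum_sq[1:3], rep(0, 3))
  expect_true(is.na(an$table$F[1]))
})

test_that("RBD decomposition matches the definitional oracle and aov", {
  m <- matrix(c(10, 14, 18, 12, 16, 20), 3, 2)  # clones x reps
  ds <- grid_trial(m)
  an <- rbd_anova(ds, "y", "y1")
  oracle <- brute_rbd_ss(m)
  expect_equal(an$table$sum_sq[an$table$source == "Genotype"],
               oracle$ss_genotype, tolerance = 1e-12)
  expect_equal(an$table$sum_sq[an$table$source == "Replication"],
               oracle$ss_replication, tolerance = 1e-12)
  expect_equal(an$table$sum_sq[an$table$source == "Error"],
               oracle$ss_error, tolerance = 1e-12)
  expect_identical(an$table$df[1:3], c(2L, 1L, 2L) * 1)

  # cross-check against stats::aov on a noisy grid
  set.seed(21)
  m2 <- matrix(rnorm(24, 50, 4), 6, 4)
  ds2 <- grid_trial(m2)
  an2 <- rbd_anova(ds2, "y", "y1")
  df <- data.frame(y = as.vector(m2),
                   clone = factor(rep(1:6, 4)),
                   block = factor(rep(1:4, each = 6)))
  ref <- summary(aov(y ~ block + clone, data = df))[[1]]
  expect_equal(an2$table$sum_sq[an2$table$source == "Genotype"],
               ref["clone", "Sum Sq"], tolerance = 1e-9)
  expect_equal(an2$table$sum_sq[an2$table$source == "Error"],
               ref["Residuals", "Sum Sq"], tolerance = 1e-9)
  expect_equal(an2$table$F[1], ref["clone", "F value"], tolerance = 1e-9)
  expect_equal(an2$table$p[1], ref["clone", "Pr(>F)"], tolerance = 1e-9)
})

test_that("SS partition is exact on random balanced layouts", {
  set.seed(31)
  for (i in 1:10) {
    g <- sample(3:8, 1); r <- sample(2:6, 1)
    m <- matrix(rnorm(g * r, 100, 10), g, r)
    an <- rbd_anova(grid_trial(m), "y", "y1")
    ss <- an$table$sum_sq
    expect_equal(ss[4], sum(ss[1:3]), tolerance = 1e-9 * max(1, ss[4]))
  }
})

test_that("one-way mode pools the replication stratum into error", {
  set.seed(41)
  m <- matrix(rnorm(24, 10), 6, 4)
  ds <- grid_trial(m)
  rbd <- rbd_anova(ds, "y", "y1")
  ow <- rbd_anova(ds, "y", "y1", method = "oneway")
  expect_identical(ow$table$df[ow$table$source == "Error"], 18L * 1)
  expect_equal(ow$table$sum_sq[ow$table$source == "Error"],
               sum(rbd$table$sum_sq[rbd$table$source %in%
                                      c("Replication", "Error")]),
               tolerance = 1e-12)
})

test_that("unbalanced layouts are refused, not approximated", {
  d <- expand.grid(clone = c("A", "B", "C"), replication = 1:3,
                   year = "y1", trait = "t", stringsAsFactors = FALSE)
  d$value <- rnorm(9)
  ds <- suppressWarnings(clonal_trial(d[-2, ]))
  expect_error(rbd_anova(ds, "t", "y1"), "unbalanced")
})

test_that("variance components follow the expected-mean-squares rules", {
  vc <- variance_components(10, ms_error = 2, r = 4)
  expect_equal(vc$sigma2_g, 2)
  expect_equal(vc$sigma2_e, 2)
  expect_equal(vc$sigma2_p, 4)
  expect_false(vc$truncated)

  vc0 <- variance_components(2, ms_error = 2, r = 4)
  expect_equal(vc0$sigma2_g, 0)
  expect_false(vc0$truncated)

  vc_neg <- variance_components(1, ms_error = 2, r = 4)
  expect_equal(vc_neg$sigma2_g, 0)
  expect_true(vc_neg$truncated)
  expect_equal(vc_neg$sigma2_p, vc_neg$sigma2_e)

  expect_error(variance_components(3, ms_error = 1, r = 1), "r >= 2")

  # monotone in MS_genotype at fixed MS_error
  s2g <- vapply(seq(0.5, 10, by = 0.5),
                function(msg) variance_components(msg, 2, 4)$sigma2_g,
                numeric(1))
  expect_true(all(diff(s2g) >= 0))
})

test_that("mean products reduce to mean squares on the self-pair", {
  set.seed(51)
  m <- matrix(rnorm(20, 30, 3), 5, 4)
  ds <- grid_trial(m)
  an <- rbd_anova(ds, "y", "y1")
  mp <- mean_products(ds, "y", "y", "y1")
  expect_equal(mp$mp_genotype, an$table$mean_sq[1], tolerance = 1e-12)
  expect_equal(mp$mp_replication, an$table$mean_sq[2], tolerance = 1e-12)
  expect_equal(mp$mp_error, an$table$mean_sq[3], tolerance = 1e-12)
})

test_that("mean products are linear: cov terms of (X, 2X) double those of X", {
  set.seed(61)
  m <- matrix(rnorm(18, 8), 3, 6)
  ds <- grid_trial2(m, 2 * m)
  mp <- mean_products(ds, "x", "y", "y1")
  vc <- variance_components(rbd_anova(ds, "x", "y1"))
  raw_g <- (rbd_anova(ds, "x", "y1")$ms_genotype -
              rbd_anova(ds, "x", "y1")$ms_error) / 6
  expect_equal(mp$cov_g, 2 * raw_g, tolerance = 1e-10)
  expect_equal(mp$cov_e, 2 * vc$sigma2_e, tolerance = 1e-10)
})

test_that("cross-products match the definitional oracle and manova", {
  mx <- matrix(c(3, 7, 11, 5, 9, 13), 3, 2)
  my <- matrix(c(20, 14, 9, 22, 12, 11), 3, 2)
  ds <- grid_trial2(mx, my)
  mp <- mean_products(ds, "x", "y", "y1")
  oracle <- brute_rbd_sp(mx, my)
  expect_equal(mp$mp_genotype, oracle$sp_genotype / 2, tolerance = 1e-12)
  expect_equal(mp$mp_replication, oracle$sp_replication / 1,
               tolerance = 1e-12)
  expect_equal(mp$mp_error, oracle$sp_error / 2, tolerance = 1e-12)

  # independent route: SSP matrices from stats::manova on a larger grid
  set.seed(71)
  mx2 <- matrix(rnorm(20, 30, 4), 5, 4)
  my2 <- 0.5 * mx2 + matrix(rnorm(20, 0, 2), 5, 4)
  ds2 <- grid_trial2(mx2, my2)
  mp2 <- mean_products(ds2, "x", "y", "y1")
  df <- data.frame(x = as.vector(mx2), y = as.vector(my2),
                   clone = factor(rep(1:5, 4)),
                   block = factor(rep(1:4, each = 5)))
  fit <- summary(manova(cbind(x, y) ~ block + clone, data = df))
  expect_equal(mp2$mp_genotype, fit$SS$clone["x", "y"] / 4,
               tolerance = 1e-9)
  expect_equal(mp2$mp_error, fit$SS$Residuals["x", "y"] / 12,
               tolerance = 1e-9)
})
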