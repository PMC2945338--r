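test_that("stratum weights are area proportions and sum to one", {
  em <- table1_matrix()
  W <- stratum_weights(em)
  expect_equal(sum(W), 1)
  expect_equal(round(unname(W), c(4, 3, 3)), c(0.0032, 0.397, 0.600))

  eq3 <- error_matrix(matrix(c(3, 1, 1, 1, 3, 1, 1, 1, 3), 3),
                      mapped_area_ha = rep(7e5, 3))
  expect_equal(unname(stratum_weights(eq3)), rep(1 / 3, 3))

  one <- error_matrix(matrix(5), mapped_area_ha = 123)
  expect_equal(unname(stratum_weights(one)), 1)
})

test_that("class proportions weight per-stratum reference shares by area", {
  em <- table1_matrix()
  phi <- class_proportion(em)
  expect_equal(sum(phi), 1)
  expect_equal(round(class_proportion(em, "change"), 4), 0.0033,
               ignore_attr = TRUE)
  expect_equal(round(class_proportion(em, "stable_forest"), 2), 0.41,
               ignore_attr = TRUE)

  # perfect map: phi equals the area weight, no confusion to correct for
  dm <- error_matrix(diag(c(10, 20, 30)), mapped_area_ha = c(1e4, 5e4, 2e5))
  expect_equal(class_proportion(dm), stratum_weights(dm))
  expect_error(class_proportion(em, "regrowth"), "unknown class")
})

test_that("adjusted areas match the published Table-1 block", {
  em <- table1_matrix()
  adj <- adjusted_area(em)
  expect_equal(sum(adj), em$A_tot)
  expect_lte(abs(round(adj[["change"]]) - 22370), 1)
  expect_lte(abs(round(adj[["stable_forest"]]) - 2795765), 1)
  expect_lte(abs(round(adj[["stable_nonforest"]]) - 3970273), 1)
})

test_that("variance, SE and CI reproduce the published uncertainty", {
  em <- table1_matrix()
  se <- proportion_variance_se(em, "change")
  expect_true(se$se_area_ha > 9519 - 1 && se$se_area_ha < 9520 + 1)
  expect_lte(abs(round(proportion_variance_se(em, "stable_forest")$se_area_ha) -
                   47690), 1)

  ci <- confidence_interval(em, "change")
  expect_lte(abs(round(ci[["lower_ha"]]) - 3331), 1)
  expect_lte(abs(round(ci[["upper_ha"]]) - 41408), 1)
  ci2 <- confidence_interval(em, "stable_forest")
  expect_lte(abs(round(ci2[["lower_ha"]]) - 2700384), 1)
  expect_lte(abs(round(ci2[["upper_ha"]]) - 2891146), 1)
  expect_error(confidence_interval(em, "change", multiplier = 0), "positive")
})

test_that("a diagonal matrix is a fixed point with zero variance", {
  dm <- error_matrix(diag(c(4, 9, 16)), mapped_area_ha = c(100, 200, 700))
  expect_equal(adjusted_area(dm), dm$A_h)
  v <- proportion_variance_se(dm)
  expect_equal(v$variance_phi, rep(0, 3))
  expect_equal(v$se_area_ha, rep(0, 3))
  ci <- confidence_interval(dm)
  expect_equal(unname(ci[, "lower_ha"]), unname(ci[, "upper_ha"]))
  acc <- accuracy_summary(dm)
  expect_equal(unname(acc$users_pct), rep(100, 3))
  expect_equal(unname(acc$producers_pct), rep(100, 3))
  expect_equal(acc$overall_pct, 100)
  expect_equal(acc$area_weighted_pct, 100)
})

test_that("accuracy summaries match the published values", {
  acc <- accuracy_summary(table1_matrix())
  expect_equal(round(acc$overall_pct), 92)
  expect_equal(round(acc$area_weighted_pct), 96)
  expect_equal(round(acc$users_pct[["change"]]), 59)
  expect_equal(round(acc$producers_pct[["change"]]), 98)
  expect_equal(round(acc$users_pct[["stable_forest"]]), 97)
  expect_equal(round(acc$producers_pct[["stable_forest"]]), 91)

  # empty reference column: producer's accuracy is missing, not zero
  em0 <- error_matrix(rbind(c(2, 0), c(3, 0)), mapped_area_ha = c(10, 20))
  expect_true(is.na(accuracy_summary(em0)$producers_pct[[2]]))
})

test_that("completeness holds for arbitrary valid matrices", {
  for (s in 1:20) {
    em <- random_error_matrix(k = sample(2:5, 1), seed = s)
    expect_equal(sum(class_proportion(em)), 1, tolerance = 1e-9)
    expect_equal(sum(adjusted_area(em)), em$A_tot, tolerance = 1e-9)
    expect_true(all(proportion_variance_se(em)$variance_phi >= 0))
  }
})

test_that("the variance estimator is unbiased for the sampling variance", {
  # independent oracle: empirical variance of phi-hat under per-stratum
  # multinomial sampling at known truth, small strata (n_h <= 10)
  set.seed(42)
  n_h <- c(5, 8, 10)
  probs <- rbind(c(0.6, 0.3, 0.1), c(0.1, 0.8, 0.1), c(0.2, 0.2, 0.6))
  A_h <- c(500, 3000, 6500)
  W <- A_h / sum(A_h)
  R <- 5000
  phi_hat <- vhat <- numeric(R)
  for (r in seq_len(R)) {
    counts <- t(vapply(1:3, function(h) rmultinom(1, n_h[h], probs[h, ])[, 1],
                       numeric(3)))
    em <- error_matrix(counts, A_h)
    phi_hat[r] <- class_proportion(em, 1)
    vhat[r] <- proportion_variance_se(em, 1)$variance_phi
  }
  dev2 <- (phi_hat - mean(phi_hat))^2
  diff <- mean(vhat) - var(phi_hat)
  mc_se <- sd(vhat - dev2) / sqrt(R)
  expect_lt(abs(diff), 3 * mc_se)
  # and phi-hat itself is unbiased
  true_phi <- sum(W * probs[, 1])
  expect_lt(abs(mean(phi_hat) - true_phi), 3 * sd(phi_hat) / sqrt(R))
})

test_that("invalid matrices are rejected with informative errors", {
  expect_error(error_matrix(rbind(c(1, 0), c(0, 5)), c(10, 20)),
               "at least 2 samples")
  expect_error(error_matrix(rbind(c(2, 1), c(1, 5)), c(0, 20)), "positive")
  expect_error(error_matrix(rbind(c(-1, 3), c(1, 5)), c(10, 20)),
               "non-negative")
  expect_error(error_matrix(matrix(1:6, 2), c(10, 20)), "square")
})
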