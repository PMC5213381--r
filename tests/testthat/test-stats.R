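test_that("exact McNemar matches hand values, symmetry and enumeration", {
  expect_equal(mcnemar_exact(7, 0)$p.value, 0.015625)
  expect_equal(mcnemar_exact(6, 0)$p.value, 0.03125)
  expect_warning(p00 <- mcnemar_exact(0, 0)$p.value)
  expect_equal(p00, 1)

  # symmetric in the two discordant counts
  for (bc in list(c(3, 1), c(5, 0), c(4, 4), c(9, 2))) {
    expect_equal(mcnemar_exact(bc[1], bc[2])$p.value,
                 mcnemar_exact(bc[2], bc[1])$p.value)
  }

  # equals brute-force enumeration over all 2^(b+c) assignments
  for (bc in list(c(1, 0), c(2, 1), c(4, 0), c(3, 3), c(7, 0), c(8, 4))) {
    expect_equal(mcnemar_exact(bc[1], bc[2])$p.value,
                 mcnemar_brute(bc[1], bc[2]), tolerance = 1e-15)
  }

  expect_error(mcnemar_exact(-1, 2), class = "paddleire_input_error")
  expect_error(mcnemar_exact(1.5, 2), class = "paddleire_input_error")
})

test_that("nested discordance reconstruction gives the published pairs", {
  expect_equal(nested_discordance(5, 12, 12), c(ab = 7, ba = 0))
  expect_equal(nested_discordance(5, 11, 12), c(ab = 6, ba = 0))
  d <- nested_discordance(5, 12, 12)
  expect_equal(mcnemar_exact(d[["ab"]], d[["ba"]])$p.value, 0.015625)
  expect_error(nested_discordance(13, 5, 12), class = "paddleire_input_error")
})

test_that("repeated-measures ANOVA reproduces explicit sums of squares", {
  y <- matrix(c(1, 2, 3, 2, 3, 4.5), nrow = 3)  # 3 pigs x 2 conditions
  fit <- rm_anova(long_from_matrix(y), y, pig, cond)
  oracle <- rm_anova_brute(y)
  expect_equal(fit$statistic, oracle$f, tolerance = 1e-12)
  expect_equal(unname(fit$ss["conditions"]), oracle$ss_cond, tolerance = 1e-12)
  expect_equal(unname(fit$ss["error"]), oracle$ss_err, tolerance = 1e-12)
  expect_equal(fit$p.value, oracle$p, tolerance = 1e-12)

  # random matrices: SS identity and agreement with the oracle and with aov()
  set.seed(7)
  for (rep in 1:5) {
    y <- matrix(rnorm(12 * 3, mean = 4), nrow = 12)
    fit <- rm_anova(long_from_matrix(y), y, pig, cond)
    oracle <- rm_anova_brute(y)
    expect_equal(fit$statistic, oracle$f, tolerance = 1e-12)
    ss <- fit$ss
    expect_equal(unname(ss["total"]),
                 unname(ss["conditions"] + ss["subjects"] + ss["error"]),
                 tolerance = 1e-10)
    d <- long_from_matrix(y)
    d$pig <- factor(d$pig); d$cond <- factor(d$cond)
    aov_fit <- summary(stats::aov(y ~ cond + Error(pig / cond), data = d))
    ftab <- aov_fit[["Error: pig:cond"]][[1]]
    expect_equal(fit$statistic, ftab[["F value"]][1], tolerance = 1e-10)
    expect_equal(fit$p.value, ftab[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("ANOVA edge cases: null effect, degenerate designs, sphericity option", {
  # equal condition means with residual noise: F = 0, p = 1
  y0 <- matrix(c(1, 3, 2, 2, 2, 2), nrow = 3)
  fit0 <- rm_anova(long_from_matrix(y0), y, pig, cond)
  expect_equal(fit0$statistic, 0)
  expect_equal(fit0$p.value, 1)

  # perfectly additive pig + condition effects leave no error variance
  y_add <- outer(1:4, c(0, 2, 5), "+")
  expect_error(rm_anova(long_from_matrix(y_add), y, pig, cond),
               class = "paddleire_numerical_error")
  # the classic ladder matrix [[1,2],[2,3],[3,4]] is additive too
  expect_error(rm_anova(long_from_matrix(matrix(c(1, 2, 3, 2, 3, 4), 3)),
                        y, pig, cond),
               class = "paddleire_numerical_error")

  # incomplete layout
  d <- long_from_matrix(matrix(rnorm(9), 3))[-1, ]
  expect_error(rm_anova(d, y, pig, cond), class = "paddleire_input_error")

  # Greenhouse-Geisser epsilon within [1/(k-1), 1] and correction shrinks df
  set.seed(11)
  y <- matrix(rnorm(36, 4), nrow = 12)
  f1 <- rm_anova(long_from_matrix(y), y, pig, cond)
  f2 <- rm_anova(long_from_matrix(y), y, pig, cond, gg_correction = TRUE)
  expect_gte(f1$gg_epsilon, 0.5)
  expect_lte(f1$gg_epsilon, 1)
  expect_lte(f2$df[1], f1$df[1])
  expect_equal(f1$statistic, f2$statistic)
})

test_that("tidy and glance expose the ANOVA decomposition", {
  y <- matrix(rnorm(36, 4), nrow = 12)
  fit <- rm_anova(long_from_matrix(y), y, pig, cond)
  td <- tidy(fit)
  expect_equal(td$term, c("conditions", "subjects", "error"))
  expect_equal(sum(td$sumsq), unname(fit$ss["total"]), tolerance = 1e-10)
  expect_equal(td$df, c(2, 11, 22))
  gl <- glance(fit)
  expect_equal(gl$p.value, fit$p.value)
  expect_equal(gl$df.residual, 22)
})

test_that("threshold separation at study scale is detectable by the within-pig design", {
  # cohorts at the three group threshold means with study-scale dispersion:
  # the F test should reject far more often than half the time
  set.seed(31)
  means <- c(4.3, 5.1, 3.4)
  rej <- vapply(1:500, function(i) {
    pig <- rnorm(12, 0, 0.25)
    y <- sapply(means, function(m) m + pig + rnorm(12, 0, 0.5))
    glance(rm_anova(long_from_matrix(y), y, pig, cond))$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.5)
})

test_that("paired contrast matches the t reference and flags degeneracy", {
  expect_warning(same <- paired_contrast(c(4, 5, 6), c(4, 5, 6)))
  expect_equal(same$estimate, 0)
  expect_equal(same$p.value, 1)

  expect_warning(toy <- paired_contrast(c(5, 6, 7), c(4, 5, 6)))
  expect_equal(toy$estimate, 1)
  expect_equal(c(toy$conf.low, toy$conf.high), c(1, 1))
  expect_true(toy$degenerate)

  set.seed(13)
  x <- rnorm(12, 4.7, 0.8); y <- rnorm(12, 3.4, 0.5)
  got <- paired_contrast(x, y)
  ref <- stats::t.test(x, y, paired = TRUE)
  expect_equal(got$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(c(got$conf.low, got$conf.high), as.numeric(ref$conf.int),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  expect_error(paired_contrast(1:3, 1:4), class = "paddleire_input_error")
})

test_that("single-to-serial threshold ratio is scale invariant", {
  expect_equal(round(threshold_ratio(c(4.3, 5.1), 3.4), 1), 1.4)
  expect_equal(threshold_ratio(c(3, 3), 3), 1)
  expect_equal(threshold_ratio(c(4.3, 5.1), 3.4),
               threshold_ratio(2 * c(4.3, 5.1), 2 * 3.4), tolerance = 1e-15)
  expect_error(threshold_ratio(c(4, 5), 0), class = "paddleire_domain_error")
})
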