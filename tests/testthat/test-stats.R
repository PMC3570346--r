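test_that("t_test_auto matches the hand-computed Welch formulas", {
  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8)
  res <- t_test_auto(a, b)
  # hand calculation: se^2 = 5/12 + 20/12, t = -2.5/sqrt(25/12),
  # Welch-Satterthwaite df = (625/144) / (425/432) = 1875/425
  expect_equal(res$p_welch,
               2 * pt(-2.5 / sqrt(25 / 12), 1875 / 425))
  welch <- t.test(a, b) # reference for the reported Welch branch numbers
  expect_equal(t_test_auto(a, b)$p_welch, welch$p.value)
  # identical samples: t = 0, p = 1
  same <- t_test_auto(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("variance check selects the Student or Welch branch", {
  a <- c(1, 2, 3, 4, 5)
  same_var <- t_test_auto(a, a + 10)
  expect_identical(same_var$variant, "student")
  # ~60-fold variance ratio clears the two-sided F critical value
  blown <- t_test_auto(a, c(0, 10, -10, 15, -15))
  expect_identical(blown$variant, "welch")
  # Welch df never exceeds the pooled df
  expect_lte(blown$df, length(a) + 5 - 2)
  # equal variances and sizes: Welch p equals Student p
  expect_equal(same_var$p_welch, same_var$p_student, tolerance = 1e-12)
})

test_that("zero-variance degenerate groups are defined", {
  res <- t_test_auto(c(2, 2), c(2, 2))
  expect_equal(res$p_value, 1)
  res2 <- t_test_auto(c(2, 2), c(3, 3))
  expect_equal(res2$p_value, 0)
})

test_that("ANOVA omnibus F matches a hand sum-of-squares decomposition", {
  g1 <- c(6, 8, 4, 5, 3, 4)
  g2 <- c(8, 12, 9, 11, 6, 8)
  g3 <- c(13, 9, 11, 8, 7, 12)
  d <- tibble::tibble(value = c(g1, g2, g3),
                      group = rep(c("control", "minor", "medium"), each = 6))
  res <- anova_tukey(d)
  # independent arithmetic from the raw definition
  grand <- mean(d$value)
  ss_b <- 6 * sum((c(mean(g1), mean(g2), mean(g3)) - grand)^2)
  ss_w <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2) + sum((g3 - mean(g3))^2)
  f_hand <- (ss_b / 2) / (ss_w / 15)
  expect_equal(res$omnibus$f_statistic, f_hand)
  expect_equal(res$omnibus$p_value, pf(f_hand, 2, 15, lower.tail = FALSE))
  # Tukey adjusted p from the studentized-range distribution, by hand
  mse <- ss_w / 15
  q_obs <- abs(mean(g2) - mean(g1)) / sqrt(mse / 6)
  p_hand <- ptukey(q_obs, nmeans = 3, df = 15, lower.tail = FALSE)
  row <- res$pairwise[grepl("minor", res$pairwise$comparison) &
                        grepl("control", res$pairwise$comparison), ]
  expect_equal(row$p_adj, p_hand, tolerance = 1e-8)
})

test_that("Tukey-adjusted p values are never smaller than unadjusted pairwise p", {
  withr::with_seed(17, {
    d <- tibble::tibble(
      value = c(rnorm(5, 0), rnorm(5, 1), rnorm(5, 0.5)),
      group = rep(c("a", "b", "c"), each = 5)
    )
  })
  res <- anova_tukey(d)
  mse <- sum(unlist(tapply(d$value, d$group, function(v) (v - mean(v))^2))) / 12
  for (cmp in res$pairwise$comparison) {
    gs <- strsplit(cmp, "-")[[1]]
    dm <- mean(d$value[d$group == gs[1]]) - mean(d$value[d$group == gs[2]])
    p_raw <- 2 * pt(-abs(dm) / sqrt(mse * (1 / 5 + 1 / 5)), df = 12)
    p_adj <- res$pairwise$p_adj[res$pairwise$comparison == cmp]
    expect_gte(p_adj, p_raw - 1e-10)
  }
  # identical groups: F ~ 0, all adjusted p = 1
  same <- tibble::tibble(value = rep(c(1, 2, 3), 3),
                         group = rep(c("a", "b", "c"), each = 3))
  res0 <- anova_tukey(same)
  expect_equal(res0$omnibus$f_statistic, 0)
  expect_equal(res0$pairwise$p_adj, rep(1, 3))
})

test_that("Pearson correlation handles exact and simulated relationships", {
  x <- c(1, 3, 4, 6, 8)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  # closed-form p from the t transform with n - 2 df
  withr::with_seed(5, y <- x + rnorm(5))
  res <- pearson_r(x, y)
  tstat <- res$r * sqrt((5 - 2) / (1 - res$r^2))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), 3))
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(c(1, 2), c(1, 2)), "3 complete pairs")
})

test_that("estimated correlation is close to the generating correlation", {
  withr::with_seed(31, {
    rho <- 0.9
    rhat <- replicate(300, {
      x <- rnorm(8)
      y <- rho * x + sqrt(1 - rho^2) * rnorm(8)
      pearson_r(x, y)$r
    })
  })
  expect_equal(mean(rhat), rho, tolerance = 0.05)
})

test_that("percent difference reproduces the worked group-mean values", {
  expect_equal(percent_difference(5.3, 20.6), 288.679, tolerance = 1e-5)
  expect_equal(percent_difference(6.1, 23.4), 283.607, tolerance = 1e-5)
  expect_equal(percent_difference(4, 4), 0)
  expect_error(percent_difference(0, 5), "positive")
  # antisymmetry under the exchange transform pd(a,b) = -pd(b,a) * a/b
  a <- 5.3; b <- 20.6
  expect_equal(percent_difference(a, b),
               -percent_difference(b, a) * b / a)
})
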