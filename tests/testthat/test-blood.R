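test_that("decay correction doubles per half-life and refuses double application", {
  s <- tibble::tibble(time_min = c(0, 109.77, 219.54),
                      activity_kBq = c(7, 5, 8))
  out <- decay_correct(s, reference_min = 0, half_life_min = 109.77)
  expect_equal(out$activity_kBq, c(7, 10, 32)) # 0, 1 and 2 half-lives
  expect_error(decay_correct(out), "already decay-corrected")
})

test_that("decay correction and weight normalization commute", {
  s <- tibble::tibble(time_min = c(1, 5, 30), activity_kBq = c(2, 3, 1),
                      weight_g = c(0.1, 0.11, 0.09))
  a <- decay_correct(s)
  a$conc <- normalize_sample(a$activity_kBq, a$weight_g)
  b <- s
  b$conc <- normalize_sample(b$activity_kBq, b$weight_g)
  b <- decay_correct(b, value_col = "conc")
  expect_equal(a$conc, b$conc)
})

test_that("weight normalization matches hand arithmetic", {
  expect_equal(normalize_sample(2, 0.1, density_g_ml = 1), 20)
  expect_equal(normalize_sample(0, 0.1), 0)
  # 3.3 kBq in 0.11 g at 1.03 g/ml -> 3.3 / (0.11 / 1.03)
  expect_equal(normalize_sample(3.3, 0.11, 1.03), 3.3 * 1.03 / 0.11)
  expect_error(normalize_sample(1, 0), "positive")
})

test_that("two-exponential parent-fraction fit recovers generating parameters", {
  t <- c(2, 5, 10, 20, 30, 60)
  f <- 55 * exp(-0.25 * t) + 45 * exp(-0.012 * t)
  fit <- fit_parent_fraction(t, f)
  expect_equal(fit$A1, 55, tolerance = 1e-3)
  expect_equal(fit$lambda1, 0.25, tolerance = 1e-3)
  expect_equal(fit$A2, 45, tolerance = 1e-3)
  expect_equal(fit$lambda2, 0.012, tolerance = 1e-3)
  expect_gt(fit$r_squared, 0.999999)
  expect_equal(fit$half_life_fast, log(2) / fit$lambda1)
  # f(0) = 100 constraint satisfied
  expect_equal(fit$A1 + fit$A2 + fit$plateau, 100)
  expect_equal(nrow(tidy(fit)), 4)
  expect_true(all(c("r.squared", "half_life_fast_min") %in% names(glance(fit))))
})

test_that("parent fit is scale-equivariant in time units", {
  t <- c(2, 5, 10, 15, 20, 30, 45, 60)
  f <- 60 * exp(-0.3 * t) + 40 * exp(-0.015 * t)
  fit_min <- fit_parent_fraction(t, f)
  fit_sec <- fit_parent_fraction(t * 60, f)
  expect_equal(fit_min$lambda1 / fit_sec$lambda1, 60, tolerance = 1e-4)
  expect_equal(fit_min$lambda2 / fit_sec$lambda2, 60, tolerance = 1e-4)
})

test_that("plateau-only data and nested single-exponential data are handled", {
  t <- c(1, 5, 10, 20, 40, 60)
  fit <- fit_parent_fraction(t, rep(100, 6), plateau = TRUE)
  # constant 100% data: exponential terms contribute nothing
  expect_equal(predict(fit, t), rep(100, 6), tolerance = 1e-6)
  # single-exponential truth: two-exponential fit can only do better
  f1 <- 100 * exp(-0.1 * t)
  fit2 <- fit_parent_fraction(t, f1, constrain_f0 = FALSE)
  rss1 <- {
    g <- lm(log(f1) ~ t)
    sum((f1 - exp(fitted(g)))^2)
  }
  expect_lte(fit2$rss, rss1 + 1e-10)
})

test_that("comparison of fits prefers shared curve for identical groups and separates distinct ones", {
  t <- c(2, 5, 10, 20, 30, 60)
  f <- 55 * exp(-0.25 * t) + 45 * exp(-0.012 * t)
  same <- dplyr::bind_rows(
    tibble::tibble(time_min = t, parent_pct = f, group = "control"),
    tibble::tibble(time_min = t, parent_pct = f, group = "kase")
  )
  res <- compare_parent_fits(same)
  expect_lt(res$f_statistic, 1e-3)
  expect_identical(res$preferred, "shared")

  # 3-fold different rates, low noise: separate curves win
  withr::with_seed(42, {
    tt <- rep(c(2, 5, 10, 20, 30, 45, 60), each = 2)
    fa <- 55 * exp(-0.25 * tt) + 45 * exp(-0.012 * tt) + rnorm(length(tt), 0, 0.5)
    fb <- 55 * exp(-0.75 * tt) + 45 * exp(-0.036 * tt) + rnorm(length(tt), 0, 0.5)
    diff <- dplyr::bind_rows(
      tibble::tibble(time_min = tt, parent_pct = pmin(pmax(fa, 1), 100), group = "control"),
      tibble::tibble(time_min = tt, parent_pct = pmin(pmax(fb, 1), 100), group = "kase")
    )
    res2 <- compare_parent_fits(diff)
    expect_identical(res2$preferred, "separate")
    expect_lt(res2$p_value, 0.05)
  })
})

test_that("metabolite correction scales plasma by the parent fraction", {
  pl <- tibble::tibble(time_min = c(5, 20, 50), plasma_kBq_ml = c(10, 4, 1))
  all_parent <- parent_curve(100, 0, 0, 0) # f = 100% everywhere
  expect_equal(apply_metabolite_correction(pl, all_parent)$plasma_corr_kBq_ml,
               pl$plasma_kBq_ml)
  half <- parent_curve(0, 1, 0, 0, plateau = 50) # f = 50% everywhere
  expect_equal(apply_metabolite_correction(pl, half)$plasma_corr_kBq_ml,
               pl$plasma_kBq_ml / 2)
  # closed-form check at t = 20
  crv <- parent_curve(55, 0.25, 45, 0.012)
  f20 <- 55 * exp(-0.25 * 20) + 45 * exp(-0.012 * 20)
  expect_equal(apply_metabolite_correction(pl, crv)$plasma_corr_kBq_ml[2],
               4 * f20 / 100)
})

test_that("interpolated input is exact at samples and linear on the rise", {
  bl <- tibble::tibble(
    time_min = c(0.5, 1, 2, 5, 10),
    whole_blood_kBq_ml = c(5, 10, 8, 4, 2),
    plasma_corr_kBq_ml = c(4, 8, 6, 3, 1.5)
  )
  inp <- interpolate_input(bl)
  expect_equal(inp$cp(bl$time_min), bl$plasma_corr_kBq_ml)
  expect_equal(inp$cwb(bl$time_min), bl$whole_blood_kBq_ml)
  # linear between (0,0) anchor and first sample, and on the rise
  expect_equal(inp$cp(0.25), 2)
  expect_equal(inp$cp(0.75), 6)
  # log-linear after the peak
  expect_equal(inp$cp(3.5), exp(mean(log(c(6, 3)))))
})

test_that("interpolation error against a bi-exponential truth is small and tail extrapolation decays", {
  sim <- simulate_plasma_input(fixture_plasma(), sample_times = default_sample_times())
  inp <- interpolate_input(sim$samples)
  tt <- seq(0.25, 50, by = 0.05)
  truth <- sim$input$cp(tt)
  rel <- abs(inp$cp(tt) - truth) / pmax(truth, 1e-6)
  expect_lt(stats::median(rel), 0.02)
  # exponential tail extrapolation keeps decaying beyond the last sample
  expect_lt(inp$cp(60), inp$cp(50))
  inp_const <- interpolate_input(sim$samples, extrapolate = "constant")
  expect_equal(inp_const$cp(60), inp_const$cp(50))
})

test_that("fitted input function tracks the true curve closely on sparse sampling", {
  sim <- simulate_plasma_input(fixture_plasma(), sample_times = default_sample_times())
  inp <- fit_input(sim$samples)
  tt <- seq(0, 60, by = 0.05)
  truth <- sim$input$cp(tt)
  # integral (what the kinetic model sees) agrees to well under 1%
  expect_lt(abs(sum(inp$cp(tt)) - sum(truth)) / sum(truth), 0.005)
})

test_that("comparison of fits holds its nominal type-I error under identical truth", {
  tt <- c(2, 5, 10, 20, 30, 45, 60)
  f_true <- 55 * exp(-0.25 * tt) + 45 * exp(-0.012 * tt)
  rej <- withr::with_seed(77, {
    mean(replicate(100, {
      noisy <- function() pmin(pmax(f_true + rnorm(length(tt), 0, 1.5), 1), 100)
      d <- dplyr::bind_rows(
        tibble::tibble(time_min = tt, parent_pct = noisy(), group = "a"),
        tibble::tibble(time_min = tt, parent_pct = noisy(), group = "b")
      )
      compare_parent_fits(d)$p_value < 0.05
    }))
  })
  # 100 replicates: wide binomial band around the nominal 5%
  expect_lt(rej, 0.12)
})
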