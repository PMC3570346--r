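test_that("plasma simulation: identity ratio, infusion peak, closed-form value", {
  pm <- plasma_model(c(50, 10), c(0.5, 0.02), plasma_to_blood = 1)
  sim <- simulate_plasma_input(pm, sample_times = c(0.5, 1, 2, 10, 30))
  # ratio 1 -> plasma equals whole blood everywhere
  expect_equal(sim$samples$plasma_kBq_ml, sim$samples$whole_blood_kBq_ml)
  # zero at t = 0, peak at end of the 1-min infusion
  expect_equal(sim$input$cwb(0), 0)
  tt <- seq(0, 5, by = 0.01)
  expect_equal(tt[which.max(sim$input$cwb(tt))], 1)
  # closed form at t = 10: sum A_i exp(-lambda_i * (10 - 1))
  expect_equal(sim$input$cwb(10), 50 * exp(-0.5 * 9) + 10 * exp(-0.02 * 9))
  # continuity at end of infusion
  expect_equal(sim$input$cwb(1 - 1e-9), sim$input$cwb(1 + 1e-9),
               tolerance = 1e-6)
})

test_that("plasma simulation validates inputs", {
  expect_error(simulate_plasma_input(sample_times = c(2, 1)), "increasing")
  expect_error(simulate_plasma_input(sample_times = c(10, 70)), "\\[0, 60\\]")
  expect_error(plasma_model(c(-1, 2), c(0.1, 0.2)), "non-negative")
})

test_that("simulated TACs equal the forward model at zero noise", {
  inp <- exp_input()
  sched <- default_frame_schedule()
  sim <- simulate_tac(0.3, 0.06, 0.05, inp, sched, noise_model(0))
  mod <- model_tac(0.3, 0.06, 0.05, inp, sched)
  expect_identical(sim$activity_kBq_ml, mod$activity_kBq_ml)
  # K1 = 0, Vb = 0 -> all frames zero
  zero <- simulate_tac(0, 0.1, 0, inp, sched)
  expect_equal(zero$activity_kBq_ml, rep(0, nrow(sched)))
})

test_that("frame noise is duration-dependent and seed-reproducible", {
  inp <- exp_input()
  sched <- default_frame_schedule()
  a <- simulate_tac(0.3, 0.06, 0.05, inp, sched, noise_model(0.5, seed = 7))
  b <- simulate_tac(0.3, 0.06, 0.05, inp, sched, noise_model(0.5, seed = 7))
  expect_identical(a, b)
  # residual spread shrinks with frame duration (pooled over replicates)
  mod <- model_tac(0.3, 0.06, 0.05, inp, sched)
  resid <- withr::with_seed(11, {
    replicate(200, simulate_tac(0.3, 0.06, 0.05, inp, sched,
                                noise_model(0.5))$activity_kBq_ml -
                mod$activity_kBq_ml)
  })
  sds <- apply(resid, 1, sd)
  short <- sched$dur_s == 15 & mod$activity_kBq_ml > 1
  long <- sched$dur_s == 500
  expect_gt(mean(sds[short]), mean(sds[long]))
})

test_that("cohort simulation is deterministic and hits configured truth", {
  cfg <- small_config()
  a <- simulate_cohort(cfg, seed = 5)
  b <- simulate_cohort(cfg, seed = 5)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$tacs, b$tacs)
  expect_identical(a$blood, b$blood)
  # SD 0 -> every animal's truth equals the configured group mean
  gt <- a$ground_truth
  left_ctrl <- gt$vt[gt$group == "control" & gt$hemisphere == "left"]
  left_kase <- gt$vt[gt$group == "KASE" & gt$hemisphere == "left"]
  expect_equal(left_ctrl, rep(5.3, 4))
  expect_equal(left_kase, rep(20.6, 4))
  expect_equal(gt$vt, gt$K1 / gt$k2)
})

test_that("cohort files written twice from the same seed are byte-identical", {
  cfg <- small_config()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg, seed = 3), d1)
  write_cohort(simulate_cohort(cfg, seed = 3), d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("invalid cohort configs are rejected", {
  expect_error(cohort_config(group_sizes = c(control = 0, KASE = 4)), "positive")
  expect_error(cohort_config(regions = tibble::tibble(region = "x")), "columns")
})

test_that("autoradiogram plates invert the configured film response", {
  # identity response, no noise: OD equals activity
  plate <- simulate_autorad_plate(c(1, 2, 3, 4), c(r1 = 1.5, r2 = 2.5),
                                  od_response = c(0, 1, 0, 0),
                                  od_range = c(0, 5))
  expect_equal(plate$standards$od, c(1, 2, 3, 4))
  expect_equal(plate$rois$od, c(1.5, 2.5))

  # 4 standards determine the cubic exactly: zero calibration residual
  plate4 <- simulate_autorad_plate(c(0.5, 1, 2, 4), c(a = 1.2),
                                   od_response = c(0.1, 1.5, 0.2, 0.3))
  cal <- fit_calibration(plate4$standards$od, plate4$standards$kBq_per_mg)
  expect_lt(max(abs(cal$residuals)), 1e-9)

  # non-monotone response is refused
  expect_error(
    simulate_autorad_plate(c(1, 2, 3, 4), 2, od_response = c(0, 1, 0, -1)),
    "monotone"
  )
})
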