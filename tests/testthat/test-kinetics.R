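test_that("forward model matches the analytic exponential-input convolution", {
  sched <- default_frame_schedule()
  A <- 100; beta <- 0.3; K1 <- 0.3; k2 <- 0.06
  tac <- model_tac(K1, k2, Vb = 0, input = exp_input(A, beta),
                   schedule = sched, dt_s = 0.05)
  truth <- exp_input_tac_truth(A, beta, K1, k2, sched)
  expect_equal(tac$activity_kBq_ml, truth, tolerance = 1e-8)
})

test_that("forward model limits: zero influx and steady state", {
  sched <- default_frame_schedule()
  zero <- model_tac(0, 0.1, 0, exp_input(), sched)
  expect_equal(zero$activity_kBq_ml, rep(0, nrow(sched)))
  # constant input, late frames approach c * ((1-Vb) K1/k2 + Vb)
  cc <- 10; K1 <- 0.4; k2 <- 0.4; Vb <- 0.05
  long <- frame_schedule(rep(600, 12))
  tac <- model_tac(K1, k2, Vb, const_input(cc), long)
  expect_equal(tail(tac$activity_kBq_ml, 1),
               cc * ((1 - Vb) * K1 / k2 + Vb), tolerance = 1e-4)
})

test_that("forward model agrees with an independent ODE integration", {
  sched <- default_frame_schedule()
  sim <- simulate_plasma_input(fixture_plasma())
  for (K1 in c(0.1, 0.3)) {
    for (k2 in c(0.02, 0.1)) {
      mod <- model_tac(K1, k2, 0.05, sim$input, sched, dt_s = 0.05)
      oracle <- ode_oracle_tac(K1, k2, 0.05, sim$input, sched)
      expect_lt(max(abs(mod$activity_kBq_ml - oracle) / oracle), 1e-6)
    }
  }
})

test_that("noiseless fits recover K1, k2 and Vt to high accuracy", {
  sched <- default_frame_schedule()
  sim <- simulate_plasma_input(fixture_plasma())
  tac <- model_tac(0.3, 0.06, 0.05, sim$input, sched)
  fit <- fit_1tc(tac, sim$input)
  expect_equal(fit$K1, 0.3, tolerance = 5e-3)
  expect_equal(fit$k2, 0.06, tolerance = 5e-3)
  expect_equal(fit$vt, 5, tolerance = 5e-3)
  # Vt identity holds exactly at the solution
  expect_identical(fit$vt, fit$K1 / fit$k2)
  # refitting the fitted curve reproduces the same solution
  tac2 <- tac
  tac2$activity_kBq_ml <- fit$fitted
  fit2 <- fit_1tc(tac2, sim$input)
  expect_equal(fit2$vt, fit$vt, tolerance = 1e-6)
  expect_equal(nrow(tidy(fit)), 3)
  expect_identical(glance(fit)$converged, TRUE)
})

test_that("fits are scale-equivariant and Vt is invariant to global rescaling", {
  sched <- default_frame_schedule()
  sim <- simulate_plasma_input(fixture_plasma())
  tac <- model_tac(0.25, 0.05, 0.05, sim$input, sched)
  fit <- fit_1tc(tac, sim$input)
  cc <- 3.7
  scaled_input <- input_function(
    cp = function(t) cc * sim$input$cp(t),
    cwb = function(t) cc * sim$input$cwb(t),
    support = sim$input$support
  )
  tac_scaled <- tac
  tac_scaled$activity_kBq_ml <- cc * tac$activity_kBq_ml
  fit_scaled <- fit_1tc(tac_scaled, scaled_input)
  expect_equal(fit_scaled$K1, fit$K1, tolerance = 1e-6)
  expect_equal(fit_scaled$vt, fit$vt, tolerance = 1e-6)
})

test_that("identical left and right TACs give identical Vt", {
  sched <- default_frame_schedule()
  sim <- simulate_plasma_input(fixture_plasma())
  left <- model_tac(0.3, 0.06, 0.05, sim$input, sched,
                    region = "amygdala", hemisphere = "left")
  right <- left
  right$hemisphere <- "right"
  expect_identical(fit_1tc(left, sim$input)$vt, fit_1tc(right, sim$input)$vt)
})

test_that("Logan graphical slope cross-checks the compartmental Vt", {
  sched <- frame_schedule(c(rep(60, 10), rep(300, 16))) # long equilibration
  sim <- simulate_plasma_input(plasma_model(c(50, 10), c(0.5, 0.005),
                                            plasma_to_blood = 1))
  tac <- model_tac(0.3, 0.06, 0, sim$input, sched)
  fit <- fit_1tc(tac, sim$input, Vb = 0)
  expect_equal(logan_slope(tac, sim$input, n_late = 10), fit$vt,
               tolerance = 0.02)
})

test_that("degenerate TACs are rejected", {
  sched <- default_frame_schedule()
  sim <- simulate_plasma_input(fixture_plasma())
  tac <- model_tac(0.3, 0.06, 0.05, sim$input, sched)
  zero <- tac; zero$activity_kBq_ml <- 0
  expect_error(fit_1tc(zero, sim$input), "all-zero")
  expect_error(fit_1tc(tac[1:4, ], sim$input), "6 frames")
})

test_that("VOI extraction averages labelled voxels per frame", {
  sched <- frame_schedule(rep(30, 4))
  img <- array(0, c(4, 4, 2, 4))
  lab <- array(0L, c(4, 4, 2))
  lab[1:2, 1, 1] <- 1L
  lab[4, 4, 2] <- 2L
  for (fr in 1:4) {
    img[1, 1, 1, fr] <- fr      # label 1, voxel A
    img[2, 1, 1, fr] <- fr + 2  # label 1, voxel B
    img[4, 4, 2, fr] <- 10 * fr # label 2 (single voxel)
  }
  tacs <- extract_voi_tacs(img, lab, sched,
                           label_names = c("1" = "hippocampus"))
  hc <- tacs[tacs$region == "hippocampus", ]
  expect_equal(hc$activity_kBq_ml, (1:4) + 1) # mean of fr and fr+2
  single <- tacs[tacs$region == "label_2", ]
  expect_equal(single$activity_kBq_ml, 10 * (1:4))
  # calibration factor scales everything
  tacs2 <- extract_voi_tacs(img, lab, sched, calibration = 2)
  expect_equal(tacs2$activity_kBq_ml[tacs2$region == "label_2"], 20 * (1:4))
  expect_error(extract_voi_tacs(img, lab[1:3, , ], sched), "grids")
  expect_error(extract_voi_tacs(img[, , , 1:3], lab, sched), "frame count")
})

test_that("VOI extraction round-trips through NIfTI files", {
  sched <- frame_schedule(rep(30, 3))
  img <- array(runif(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  lab <- array(0L, c(4, 4, 2)); lab[2:3, 2:3, 1] <- 1L
  tf_img <- tempfile(fileext = ".nii.gz")
  tf_lab <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(img), tf_img)
  RNifti::writeNifti(RNifti::asNifti(lab), tf_lab)
  from_file <- extract_voi_tacs(tf_img, tf_lab, sched)
  from_mem <- extract_voi_tacs(img, lab, sched)
  expect_equal(from_file$activity_kBq_ml, from_mem$activity_kBq_ml,
               tolerance = 1e-6)
  unlink(c(tf_img, tf_lab))
})

test_that("%ID/ml conversion and its inverse", {
  tac <- model_tac(0.3, 0.06, 0.05, exp_input(), default_frame_schedule())
  out <- to_percent_id_per_ml(tac, injected_dose_MBq = 20)
  # 20 kBq/ml at 20 MBq -> 0.1 %ID/ml
  expect_equal(out$pct_id_ml, tac$activity_kBq_ml / (20 * 1000) * 100)
  back <- to_kbq_per_ml(out, 20)
  expect_equal(back$activity_kBq_ml, tac$activity_kBq_ml)
  expect_error(to_percent_id_per_ml(tac, 0), "positive")
})
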