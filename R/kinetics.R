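#' @section One-tissue compartment model:
#' Tissue activity follows `dCt/dt = K1 Cp(t) - k2 Ct(t)`, so
#' `Ct(t) = K1 * exp(-k2 t) (*) Cp(t)` (convolution). What the scanner sees
#' in a VOI also contains blood in the vascular fraction `Vb`:
#' `C(t) = (1 - Vb) Ct(t) + Vb Cwb(t)`. The volume of distribution is
#' `Vt = K1 / k2`.
#' @name onetcm
#' @keywords internal
NULL

# uniform time grid (minutes) covering [0, end of schedule]; the step is
# adjusted so the grid lands exactly on the scan end
model_grid <- function(schedule, dt_s = 0.25) {
  end_s <- max(schedule$end_s)
  n <- max(2L, ceiling(end_s / dt_s))
  seq(0, end_s, length.out = n + 1) / 60
}

# exact solution of dB/dt = Cp - k2 B on a uniform grid with Cp
# piecewise-linear between grid points; evaluated with a fast recursive
# filter. Returns B(t) = int_0^t exp(-k2 (t-s)) Cp(s) ds at the grid points.
conv_exp_plinear <- function(cp, k2, dt) {
  n <- length(cp)
  if (k2 * dt > 1e-10) {
    a <- exp(-k2 * dt)
    I0 <- (1 - a) / k2          # int_0^dt exp(-k2 (dt - s)) ds
    I1 <- (dt - I0) / k2        # int_0^dt exp(-k2 (dt - s)) s ds
  } else {                      # series limit for k2 -> 0
    a <- exp(-k2 * dt)
    I0 <- dt * (1 - k2 * dt / 2)
    I1 <- dt^2 * (1 / 2 - k2 * dt / 3)
  }
  u <- cp[-n] * (I0 - I1 / dt) + cp[-1] * (I1 / dt)
  c(0, as.numeric(stats::filter(u, a, method = "recursive")))
}

# duration-weighted frame means of a piecewise-linear curve y on grid t_min,
# via interpolated cumulative trapezoid integrals at the frame boundaries
frame_average <- function(t_min, y, schedule) {
  dt <- diff(t_min)
  ctz <- c(0, cumsum((y[-1] + y[-length(y)]) / 2 * dt))
  Fcum <- stats::approxfun(t_min, ctz, rule = 2)
  (Fcum(schedule$end_s / 60) - Fcum(schedule$start_s / 60)) /
    (schedule$dur_s / 60)
}

#' Forward one-tissue-compartment model of a time-activity curve
#'
#' Predicts the frame-averaged VOI activity for given kinetic parameters,
#' convolving the metabolite-corrected plasma curve with the tissue impulse
#' response and adding the whole-blood signal of the vascular fraction:
#' \deqn{C(t) = (1 - V_b)\, K_1 \int_0^t e^{-k_2 (t - s)} C_p(s)\, ds +
#'   V_b\, C_{wb}(t).}
#' The convolution is evaluated exactly for a piecewise-linear plasma curve
#' on a fine uniform grid (default 0.25 s step) and each reported value is
#' the average of `C(t)` over its frame.
#'
#' @param K1 Plasma-to-tissue influx rate, ml plasma / (ml tissue x min).
#' @param k2 Tissue efflux rate constant, 1/min.
#' @param Vb Vascular (blood volume) fraction in the VOI; default 0.05.
#' @param input An [input_function()] whose support covers the schedule.
#' @param schedule A [frame_schedule()].
#' @param dt_s Convolution grid step in seconds (<= 1 s).
#' @param region,hemisphere Labels attached to the returned TAC.
#'
#' @return A TAC tibble (class `pet_tac`): the schedule columns plus
#'   `region`, `hemisphere` and `activity_kBq_ml`.
#' @examples
#' input <- simulate_plasma_input(sample_times = default_sample_times())$input
#' tac <- model_tac(K1 = 0.3, k2 = 0.06, input = input,
#'                  schedule = default_frame_schedule())
#' @export
model_tac <- function(K1, k2, Vb = 0.05, input, schedule, dt_s = 0.25,
                      region = "model", hemisphere = "whole") {
  assert_schedule(schedule)
  if (K1 < 0 || k2 < 0) abort("K1 and k2 must be non-negative")
  if (Vb < 0 || Vb >= 1) abort("Vb must lie in [0, 1)")
  if (dt_s <= 0 || dt_s > 1) abort("`dt_s` must be in (0, 1] seconds")
  assert_input_support(input, c(0, schedule_end_min(schedule)),
                       "frame schedule")
  t_min <- model_grid(schedule, dt_s)
  cp <- input$cp(t_min)
  cwb <- input$cwb(t_min)
  B <- conv_exp_plinear(cp, k2, t_min[2] - t_min[1])
  curve <- (1 - Vb) * K1 * B + Vb * cwb
  out <- as_tibble(schedule)
  out$region <- region
  out$hemisphere <- hemisphere
  out$activity_kBq_ml <- frame_average(t_min, curve, schedule)
  class(out) <- c("pet_tac", class(out))
  out
}

#' Estimate Vt with the one-tissue compartment model
#'
#' Weighted nonlinear least-squares fit of the forward model in
#' [model_tac()] to a measured TAC, with the vascular fraction fixed. The
#' model is linear in `K1` given `k2`, so `K1` is profiled out by weighted
#' linear regression and the search runs over `k2` alone: the residual sum
#' of squares is scanned over a log-spaced `k2` multi-start grid, then
#' polished by bounded 1-D optimisation. The fit is deterministic.
#'
#' @param tac A TAC tibble with schedule columns and `activity_kBq_ml`
#'   (>= 6 frames).
#' @param input The [input_function()] used as model input.
#' @param Vb Fixed vascular fraction (default 0.05).
#' @param weighting `"duration"` (weights proportional to frame duration,
#'   default) or `"uniform"`.
#' @param k2_bounds Search bounds for `k2` in 1/min.
#' @param K1_max Upper clamp for the profiled `K1`.
#' @param dt_s Convolution grid step in seconds.
#'
#' @return An object of class `kinetic_fit` with elements `K1`, `k2`, `Vb`,
#'   `vt` (= K1/k2), standard errors, `rss`, `converged`, `fitted` and the
#'   input data. Use [tidy()] / [glance()] to get tibbles.
#' @export
fit_1tc <- function(tac, input, Vb = 0.05, weighting = c("duration", "uniform"),
                    k2_bounds = c(1e-4, 10), K1_max = 10, dt_s = 0.25) {
  weighting <- match.arg(weighting)
  need <- c("start_s", "dur_s", "end_s", "activity_kBq_ml")
  if (!all(need %in% names(tac))) {
    abort("`tac` must have columns start_s, dur_s, end_s, activity_kBq_ml")
  }
  if (nrow(tac) < 6) abort("need at least 6 frames to fit the model")
  y <- tac$activity_kBq_ml
  if (all(y == 0)) abort("all-zero TAC: nothing to fit")
  sched <- frame_schedule(tac$dur_s, start_s = tac$start_s[1])
  assert_input_support(input, c(0, schedule_end_min(sched)), "frame schedule")
  w <- if (weighting == "duration") tac$dur_s / mean(tac$dur_s) else rep(1, nrow(tac))

  t_min <- model_grid(sched, dt_s)
  dt <- t_min[2] - t_min[1]
  cp <- input$cp(t_min)
  cwb <- input$cwb(t_min)
  vb_frames <- Vb * frame_average(t_min, cwb, sched)
  y_adj <- y - vb_frames

  profile_k1 <- function(k2) {
    Bf <- (1 - Vb) * frame_average(t_min, conv_exp_plinear(cp, k2, dt), sched)
    denom <- sum(w * Bf^2)
    K1 <- if (denom > 0) sum(w * Bf * y_adj) / denom else 0
    K1 <- min(max(K1, 1e-8), K1_max)
    list(K1 = K1, rss = sum(w * (y_adj - K1 * Bf)^2), Bf = Bf)
  }
  rss_of <- function(logk2) profile_k1(exp(logk2))$rss

  k2_grid <- exp(seq(log(k2_bounds[1]), log(k2_bounds[2]), length.out = 17))
  rss_grid <- vapply(log(k2_grid), rss_of, numeric(1))
  i <- which.min(rss_grid)
  lo <- log(k2_grid[max(1, i - 1)]); hi <- log(k2_grid[min(length(k2_grid), i + 1)])
  opt <- optimize(rss_of, lower = lo, upper = hi, tol = 1e-10)
  k2 <- exp(opt$minimum)
  sol <- profile_k1(k2)
  K1 <- sol$K1

  # parameter covariance from the local Jacobian (delta method for Vt)
  model_frames <- function(K1, k2) {
    K1 * (1 - Vb) * frame_average(t_min, conv_exp_plinear(cp, k2, dt), sched) +
      vb_frames
  }
  f0 <- model_frames(K1, k2)
  hK <- 1e-6 * max(1, K1); hk <- 1e-6 * max(1, k2)
  J <- cbind((model_frames(K1 + hK, k2) - f0) / hK,
             (model_frames(K1, k2 + hk) - f0) / hk)
  dof <- length(y) - 2
  sigma2 <- sum(w * (y - f0)^2) / dof
  JtWJ <- crossprod(J * sqrt(w))
  vc <- tryCatch(sigma2 * solve(JtWJ), error = function(e) matrix(NA_real_, 2, 2))
  g <- c(1 / k2, -K1 / k2^2) # grad of Vt = K1/k2
  se_vt <- sqrt(max(0, drop(t(g) %*% vc %*% g)))

  structure(
    list(K1 = K1, k2 = k2, Vb = Vb, vt = K1 / k2,
         se_K1 = sqrt(vc[1, 1]), se_k2 = sqrt(vc[2, 2]), se_vt = se_vt,
         rss = sol$rss, sigma = sqrt(sigma2), n_frames = length(y),
         weighting = weighting, converged = TRUE,
         region = tac$region[1] %||% "region",
         hemisphere = tac$hemisphere[1] %||% "whole",
         fitted = f0, data = tac, input_provenance = input$provenance),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit>  one-tissue compartment, fixed Vb\n")
  cat(sprintf("  region: %s (%s)\n", x$region, x$hemisphere))
  cat(sprintf("  K1 = %.4g ml/ml/min (SE %.2g), k2 = %.4g /min (SE %.2g)\n",
              x$K1, x$se_K1, x$k2, x$se_k2))
  cat(sprintf("  Vt = K1/k2 = %.4g (SE %.2g), Vb = %.3g, RSS = %.4g\n",
              x$vt, x$se_vt, x$Vb, x$rss))
  invisible(x)
}

#' Extract per-VOI time-activity curves from a dynamic image
#'
#' Computes the unweighted mean activity over each labelled region for every
#' frame of a 4D activity image, optionally applying a scanner
#' cross-calibration factor to express values in kBq/ml.
#'
#' @param image_4d 4D numeric array (x, y, z, frame) or a path to a NIfTI
#'   file (read with the RNifti package).
#' @param labels 3D integer array (same spatial grid) or NIfTI path; voxels
#'   with label 0 are background.
#' @param schedule A [frame_schedule()] with one frame per volume.
#' @param calibration Multiplicative cross-calibration factor to kBq/ml.
#' @param label_names Optional named character vector mapping label integers
#'   to region names, e.g. `c("1" = "hippocampus")`.
#'
#' @return A long TAC tibble: schedule columns plus `region`, `hemisphere`
#'   (`"whole"`), `activity_kBq_ml`.
#' @export
extract_voi_tacs <- function(image_4d, labels, schedule, calibration = 1,
                             label_names = NULL) {
  assert_schedule(schedule)
  if (is.character(image_4d)) image_4d <- as.array(RNifti::readNifti(image_4d))
  if (is.character(labels)) labels <- as.array(RNifti::readNifti(labels))
  di <- dim(image_4d); dl <- dim(labels)
  if (length(di) != 4) abort("`image_4d` must be a 4D array")
  if (!identical(as.integer(di[1:3]), as.integer(dl))) {
    abort("image and label volumes are on different voxel grids")
  }
  if (di[4] != nrow(schedule)) abort("frame count does not match the schedule")
  lab <- as.integer(round(as.vector(labels)))
  keep <- lab > 0
  if (!any(keep)) abort("label image contains no labelled voxels")
  lab <- lab[keep]
  nvox <- prod(di[1:3])
  mat <- matrix(image_4d, nrow = nvox)[keep, , drop = FALSE]
  means <- rowsum(mat, lab) / as.vector(table(lab))
  ids <- sort(unique(lab))
  out <- purrr::map(seq_along(ids), function(j) {
    nm <- as.character(ids[j])
    region <- if (!is.null(label_names) && nm %in% names(label_names)) {
      label_names[[nm]]
    } else {
      paste0("label_", nm)
    }
    tac <- as_tibble(schedule)
    tac$region <- region
    tac$hemisphere <- "whole"
    tac$activity_kBq_ml <- as.numeric(means[j, ]) * calibration
    tac
  }) |> list_rbind()
  class(out) <- c("pet_tac", class(out))
  out
}

#' Convert a TAC between kBq/ml and percent injected dose per ml
#'
#' `%ID/ml = activity(kBq/ml) / (dose_MBq * 1000) * 100`. The two functions
#' are exact inverses.
#'
#' @param tac TAC tibble with `activity_kBq_ml` (or `pct_id_ml`).
#' @param injected_dose_MBq Injected dose in MBq, > 0.
#' @return The TAC with a `pct_id_ml` (resp. `activity_kBq_ml`) column.
#' @export
to_percent_id_per_ml <- function(tac, injected_dose_MBq) {
  if (injected_dose_MBq <= 0) abort("injected dose must be positive")
  if (!"activity_kBq_ml" %in% names(tac)) abort("`tac` lacks activity_kBq_ml")
  tac$pct_id_ml <- tac$activity_kBq_ml / (injected_dose_MBq * 1000) * 100
  tac
}

#' @rdname to_percent_id_per_ml
#' @export
to_kbq_per_ml <- function(tac, injected_dose_MBq) {
  if (injected_dose_MBq <= 0) abort("injected dose must be positive")
  if (!"pct_id_ml" %in% names(tac)) abort("`tac` lacks pct_id_ml")
  tac$activity_kBq_ml <- tac$pct_id_ml / 100 * injected_dose_MBq * 1000
  tac
}

#' @method autoplot pet_tac
#' @export
autoplot.pet_tac <- function(object, unit = c("kBq_ml", "pct_id"), ...) {
  unit <- match.arg(unit)
  ycol <- if (unit == "kBq_ml") "activity_kBq_ml" else "pct_id_ml"
  ggplot(object, aes(.data$mid_min, .data[[ycol]], colour = .data$region)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "time (min)",
         y = if (unit == "kBq_ml") "activity (kBq/ml)" else "%ID/ml",
         colour = NULL) +
    theme_minimal()
}
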