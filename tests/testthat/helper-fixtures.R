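# shared fixtures, built in code at test time

# bi-exponential whole-blood model used across modules
fixture_plasma <- function() plasma_model(amplitudes = c(50, 10),
                                          rates = c(0.5, 0.02),
                                          plasma_to_blood = 1)

# analytic input function with a single-exponential plasma curve (no
# infusion ramp): convenient because the tissue convolution has a closed form
exp_input <- function(A = 100, beta = 0.3) {
  input_function(
    cp = function(t) A * exp(-beta * t),
    cwb = function(t) A * exp(-beta * t),
    support = c(0, Inf), provenance = "analytic"
  )
}

# closed-form frame-averaged 1TC TAC for Cp = A exp(-beta t), Vb = 0
exp_input_tac_truth <- function(A, beta, K1, k2, schedule) {
  Fint <- function(t) {
    K1 * A / (beta - k2) * ((1 - exp(-k2 * t)) / k2 - (1 - exp(-beta * t)) / beta)
  }
  (Fint(schedule$end_s / 60) - Fint(schedule$start_s / 60)) / (schedule$dur_s / 60)
}

# constant-activity input
const_input <- function(c = 10) {
  input_function(cp = function(t) rep(c, length(t)),
                 cwb = function(t) rep(c, length(t)),
                 support = c(0, Inf), provenance = "constant")
}

# small cohort config: amygdala only, deterministic truth unless asked
small_config <- function(noise_scale = 0, sd_zero = TRUE, ...) {
  regions <- dplyr::filter(kase_region_table(), region == "amygdala")
  if (sd_zero) {
    regions$vt_sd_control <- 0
    regions$vt_sd_kase <- 0
  }
  default_cohort_config(regions = regions, noise_scale = noise_scale, ...)
}

# independent ODE oracle: integrate dCt/dt = K1 Cp - k2 Ct with deSolve on
# the continuous input, then frame-average on a fine reporting grid
ode_oracle_tac <- function(K1, k2, Vb, input, schedule, dt_report_s = 0.05) {
  end_min <- max(schedule$end_s) / 60
  times <- seq(0, end_min, by = dt_report_s / 60)
  sol <- deSolve::ode(
    y = c(Ct = 0), times = times,
    func = function(t, y, parms) list(K1 * input$cp(t) - k2 * y[1]),
    method = "lsoda", rtol = 1e-10, atol = 1e-12
  )
  ct <- (1 - Vb) * sol[, "Ct"] + Vb * input$cwb(times)
  # trapezoid frame means on the reporting grid (boundaries are grid points)
  vapply(seq_len(nrow(schedule)), function(i) {
    sel <- times >= schedule$start_s[i] / 60 - 1e-12 &
      times <= schedule$end_s[i] / 60 + 1e-12
    tt <- times[sel]; yy <- ct[sel]
    sum(diff(tt) * (head(yy, -1) + tail(yy, -1)) / 2) / (tt[length(tt)] - tt[1])
  }, numeric(1))
}

# Logan graphical analysis (test oracle only): slope of
# int_0^T Ct / Ct(T) vs int_0^T Cp / Ct(T) over late frames estimates Vt
logan_slope <- function(tac, input, n_late = 8) {
  t_mid <- tac$mid_min
  ct <- tac$activity_kBq_ml
  grid <- seq(0, max(tac$end_s) / 60, by = 0.002)
  cp <- input$cp(grid)
  int_cp <- stats::approx(grid, cumsum(c(0, diff(grid) * (head(cp, -1) + tail(cp, -1)) / 2)),
                          t_mid)$y
  int_ct <- vapply(seq_along(t_mid), function(i) {
    sel <- grid <= t_mid[i]
    g <- grid[sel]; y <- stats::approx(t_mid, ct, g, rule = 2)$y
    sum(diff(g) * (head(y, -1) + tail(y, -1)) / 2)
  }, numeric(1))
  idx <- tail(seq_along(t_mid), n_late)
  x <- int_cp[idx] / ct[idx]; y <- int_ct[idx] / ct[idx]
  unname(coef(lm(y ~ x))[2])
}
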