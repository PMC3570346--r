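#' Decay-correct a timed sample series
#'
#' Corrects gamma-counter measurements back to a common reference time using
#' the physical half-life of the radionuclide:
#' `corrected = measured * 2^((t - reference) / half_life)`.
#' Correction is tracked on the returned tibble and applying it twice is an
#' error (the operation is not idempotent on the numbers).
#'
#' @param series Tibble with a `time_min` column and the activity column
#'   named by `value_col`.
#' @param reference_min Reference time in minutes (same clock as `time_min`);
#'   default 0, i.e. injection start.
#' @param half_life_min Physical half-life in minutes; defaults to F-18
#'   ([F18_HALF_LIFE_MIN]).
#' @param value_col Name of the activity column to correct.
#'
#' @return The tibble with `value_col` corrected, a `decay_factor` column
#'   appended, and attribute `decay_corrected = TRUE`.
#' @examples
#' s <- tibble::tibble(time_min = c(0, 109.77), activity_kBq = c(5, 5))
#' decay_correct(s)$activity_kBq # 5, 10
#' @export
decay_correct <- function(series, reference_min = 0,
                          half_life_min = F18_HALF_LIFE_MIN,
                          value_col = "activity_kBq") {
  if (half_life_min <= 0) abort("`half_life_min` must be positive")
  if (!"time_min" %in% names(series)) abort("`series` must have a `time_min` column")
  if (!value_col %in% names(series)) {
    abort(sprintf("column `%s` not found in `series`", value_col))
  }
  if (anyNA(series$time_min)) abort("`time_min` contains missing values")
  if (isTRUE(attr(series, "decay_corrected"))) {
    abort("series is already decay-corrected; refusing to correct twice")
  }
  factor <- 2^((series$time_min - reference_min) / half_life_min)
  series[[value_col]] <- series[[value_col]] * factor
  series$decay_factor <- factor
  attr(series, "decay_corrected") <- TRUE
  series
}

#' Convert a weighed sample's activity to a concentration
#'
#' Blood and plasma aliquots are pipetted then weighed; the measured
#' activity is divided by the sample volume `weight / density`.
#'
#' @param activity_kBq Measured activity in kBq (vectorised).
#' @param weight_g Sample weight in grams; must be positive.
#' @param density_g_ml Fluid density in g/ml; default 1.03 (plasma).
#' @return Activity concentration in kBq/ml.
#' @examples
#' normalize_sample(2, 0.1, density_g_ml = 1) # 20 kBq/ml
#' @export
normalize_sample <- function(activity_kBq, weight_g, density_g_ml = 1.03) {
  if (any(weight_g <= 0)) abort("sample weights must be positive")
  if (density_g_ml <= 0) abort("`density_g_ml` must be positive")
  activity_kBq / (weight_g / density_g_ml)
}

# ---- parent-fraction fitting -------------------------------------------------

# Given rates (l1, l2), profile the amplitudes by linear least squares.
# With the f(0) = 100 constraint the amplitudes satisfy A1 = 100 - A2 - c,
# so the model is linear in the remaining amplitude parameters either way.
profile_parent_amplitudes <- function(t, f, l1, l2, constrain_f0, plateau) {
  E1 <- exp(-l1 * t); E2 <- exp(-l2 * t)
  if (constrain_f0) {
    y <- f - 100 * E1
    X <- cbind(E2 - E1, if (plateau) 1 - E1)
  } else {
    y <- f
    X <- cbind(E1, E2, if (plateau) rep(1, length(t)))
  }
  beta <- tryCatch(qr.coef(qr(X), y), error = function(e) rep(NA_real_, ncol(X)))
  if (anyNA(beta)) beta[is.na(beta)] <- 0
  if (constrain_f0) {
    A2 <- beta[1]; cc <- if (plateau) beta[2] else 0
    A1 <- 100 - A2 - cc
  } else {
    A1 <- beta[1]; A2 <- beta[2]; cc <- if (plateau) beta[3] else 0
  }
  pred <- A1 * E1 + A2 * E2 + cc
  list(A1 = A1, A2 = A2, plateau = cc, pred = pred, rss = sum((f - pred)^2))
}

#' Fit a two-exponential parent-fraction (metabolite) standard curve
#'
#' Fits \deqn{f(t) = A_1 e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t} + c} to
#' measured percent-parent data by unweighted nonlinear least squares. The
#' amplitudes enter linearly and are profiled out, so the search runs over
#' the two rate constants only, from a decade-spaced multi-start grid;
#' ties are broken by lowest residual then lowest \eqn{\lambda_1}. By default
#' the curve is constrained through 100% at t = 0 (a just-injected tracer is
#' fully unmetabolised).
#'
#' @param time_min Sampling times in minutes (>= 5 distinct values).
#' @param parent_pct Measured percent parent compound, in (0, 100].
#' @param constrain_f0 Constrain f(0) = 100% (default TRUE).
#' @param plateau Include a constant plateau term (default FALSE).
#'
#' @return Object of classes `parent_fit` and `parent_curve`: fitted
#'   parameters, biological half-lives `log(2)/lambda`, `r_squared`, residual
#'   sum of squares `rss`, parameter covariance `cov` (rows/cols for the free
#'   parameters), `fitted`, `data` and a `converged` flag. Evaluate with
#'   [predict.parent_curve()]; summarise with [tidy()] / [glance()].
#' @examples
#' t <- c(2, 5, 10, 20, 30, 60)
#' f <- 55 * exp(-0.25 * t) + 45 * exp(-0.012 * t)
#' fit <- fit_parent_fraction(t, f)
#' glance(fit)
#' @export
fit_parent_fraction <- function(time_min, parent_pct, constrain_f0 = TRUE,
                                plateau = FALSE) {
  t <- as.numeric(time_min); f <- as.numeric(parent_pct)
  if (length(t) != length(f)) abort("times and fractions must have equal length")
  n_par <- 4 + plateau - constrain_f0
  if (length(unique(t)) < max(5, n_par + 1)) {
    abort("need at least 5 distinct time points to fit a two-exponential curve")
  }
  if (any(f <= 0 | f > 100 + 1e-6)) {
    abort("parent fractions must lie in (0, 100] percent")
  }

  grid <- expand.grid(l1 = 10^seq(-1.5, 0.5, by = 0.5),
                      l2 = 10^seq(-3, -1, by = 0.5))
  grid <- grid[grid$l1 > grid$l2, ]

  objective <- function(par) { # par = log rates
    l <- sort(exp(par), decreasing = TRUE)
    profile_parent_amplitudes(t, f, l[1], l[2], constrain_f0, plateau)$rss
  }
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    res <- stats::optim(log(c(grid$l1[i], grid$l2[i])), objective,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 2000))
    l <- sort(exp(res$par), decreasing = TRUE)
    cand <- list(l1 = l[1], l2 = l[2], rss = res$value,
                 converged = res$convergence == 0)
    if (is.null(best) || cand$rss < best$rss - 1e-12 ||
        (abs(cand$rss - best$rss) <= 1e-12 && cand$l1 < best$l1)) {
      best <- cand
    }
  }
  prof <- profile_parent_amplitudes(t, f, best$l1, best$l2, constrain_f0, plateau)

  # covariance of the free parameters from the Jacobian at the solution
  free <- c(if (!constrain_f0) "A1", "A2", if (plateau) "plateau",
            "lambda1", "lambda2")
  theta <- c(if (!constrain_f0) prof$A1, prof$A2, if (plateau) prof$plateau,
             best$l1, best$l2)
  model_fun <- function(th) {
    k <- 1
    if (!constrain_f0) { A1 <- th[k]; k <- k + 1 }
    A2 <- th[k]; k <- k + 1
    cc <- if (plateau) { v <- th[k]; k <- k + 1; v } else 0
    l1 <- th[k]; l2 <- th[k + 1]
    if (constrain_f0) A1 <- 100 - A2 - cc
    A1 * exp(-l1 * t) + A2 * exp(-l2 * t) + cc
  }
  J <- numDeriv_jacobian(model_fun, theta)
  dof <- length(t) - length(theta)
  sigma2 <- if (dof > 0) prof$rss / dof else NA_real_
  cov <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) {
    matrix(NA_real_, length(theta), length(theta))
  })
  dimnames(cov) <- list(free, free)

  sst <- sum((f - mean(f))^2)
  out <- parent_curve(prof$A1, best$l1, prof$A2, best$l2, prof$plateau)
  out$r_squared <- if (sst > 0) 1 - prof$rss / sst else NA_real_
  out$rss <- prof$rss
  out$cov <- cov
  out$fitted <- prof$pred
  out$data <- tibble(time_min = t, parent_pct = f)
  out$constrain_f0 <- constrain_f0
  out$has_plateau <- plateau
  out$converged <- best$converged
  out$n <- length(t)
  class(out) <- c("parent_fit", class(out))
  out
}

# forward-difference jacobian; adequate for covariance reporting
numDeriv_jacobian <- function(fn, theta, eps = 1e-6) {
  f0 <- fn(theta)
  J <- matrix(0, length(f0), length(theta))
  for (j in seq_along(theta)) {
    h <- eps * max(1, abs(theta[j]))
    th <- theta; th[j] <- th[j] + h
    J[, j] <- (fn(th) - f0) / h
  }
  J
}

#' Compare parent-fraction curves between two groups
#'
#' Extra-sum-of-squares F test of a single shared two-exponential curve
#' against separate per-group curves, the standard "comparison of fits" for
#' deciding whether tracer metabolism differs between treatment groups.
#'
#' @param data Tibble with columns `time_min`, `parent_pct` and `group`
#'   (exactly two levels).
#' @inheritParams fit_parent_fraction
#'
#' @return One-row tibble: `f_statistic`, `df1`, `df2`, `p_value`,
#'   `preferred` (`"shared"` unless p < alpha), `rss_shared`, `rss_separate`,
#'   `alpha`.
#' @param alpha Significance level for preferring the separate-curves model.
#' @export
compare_parent_fits <- function(data, constrain_f0 = TRUE, plateau = FALSE,
                                alpha = 0.05) {
  need <- c("time_min", "parent_pct", "group")
  if (!all(need %in% names(data))) {
    abort("`data` must have columns time_min, parent_pct, group")
  }
  groups <- split(data, data$group)
  if (length(groups) != 2) abort("`group` must have exactly two levels")

  n_par <- 4 + plateau - constrain_f0
  fit_shared <- fit_parent_fraction(data$time_min, data$parent_pct,
                                    constrain_f0, plateau)
  fits_sep <- map(groups, ~ fit_parent_fraction(.x$time_min, .x$parent_pct,
                                                constrain_f0, plateau))
  rss_sh <- fit_shared$rss
  rss_sep <- sum(map_dbl(fits_sep, "rss"))
  df1 <- n_par
  df2 <- nrow(data) - 2 * n_par
  if (df2 <= 0) abort("too few points for the separate-curves model")
  f_stat <- max(0, ((rss_sh - rss_sep) / df1) / (rss_sep / df2))
  p <- pf(f_stat, df1, df2, lower.tail = FALSE)
  tibble(
    f_statistic = f_stat, df1 = df1, df2 = df2, p_value = p,
    preferred = ifelse(p < alpha, "separate", "shared"),
    rss_shared = rss_sh, rss_separate = rss_sep, alpha = alpha
  )
}

#' Apply metabolite correction to total plasma activity
#'
#' Multiplies total plasma activity by the predicted parent fraction,
#' leaving only the activity attributable to intact tracer:
#' `corrected(t) = plasma(t) * f(t) / 100`.
#'
#' @param plasma Tibble with `time_min` and the column named by `value_col`.
#' @param curve A [parent_curve()] or [fit_parent_fraction()] result.
#' @param value_col Column holding total plasma activity (kBq/ml).
#'
#' @return The tibble with columns `parent_fraction_pct` and
#'   `plasma_corr_kBq_ml` appended.
#' @export
apply_metabolite_correction <- function(plasma, curve,
                                        value_col = "plasma_kBq_ml") {
  if (!inherits(curve, "parent_curve")) abort("`curve` must be a parent_curve")
  if (!value_col %in% names(plasma)) {
    abort(sprintf("column `%s` not found in `plasma`", value_col))
  }
  if (any(plasma$time_min < 0)) abort("plasma times precede injection (t < 0)")
  f <- predict(curve, plasma$time_min)
  plasma$parent_fraction_pct <- f
  plasma$plasma_corr_kBq_ml <- plasma[[value_col]] * f / 100
  plasma
}

# ---- input-function construction --------------------------------------------

# piecewise interpolator: linear up to the peak sample, log-linear after
# (positivity-preserving for exponential-like decays), anchored at (0, 0)
# when the first sample is after t = 0. Beyond the last sample the tail is
# either continued exponentially with the washout rate of the last log-linear
# segment, or held constant.
make_series_interpolator <- function(t, v, extrapolate = "exponential") {
  if (is.unsorted(t, strictly = TRUE)) abort("sample times must be strictly increasing")
  if (t[1] > 0) { t <- c(0, t); v <- c(0, v) }
  peak <- which.max(v)
  n <- length(t)
  uselog <- rep(FALSE, max(n - 1, 1))
  if (peak < n) {
    seg <- peak:(n - 1)
    uselog[seg] <- v[seg] > 0 & v[seg + 1] > 0
  }
  # washout rate for tail extrapolation; fall back to constant when the
  # last segment is not a positive decay
  tail_rate <- 0
  if (extrapolate == "exponential" && n >= 2 && uselog[n - 1] &&
      v[n] < v[n - 1]) {
    tail_rate <- log(v[n - 1] / v[n]) / (t[n] - t[n - 1])
  }
  force(t); force(v); force(uselog)
  function(q) {
    i <- findInterval(q, t, rightmost.closed = TRUE)
    out <- numeric(length(q))
    out[i <= 0] <- v[1]
    past <- i >= n
    out[past] <- v[n] * exp(-tail_rate * (q[past] - t[n]))
    inside <- i >= 1 & i < n
    ii <- i[inside]; qq <- q[inside]
    w <- (qq - t[ii]) / (t[ii + 1] - t[ii])
    lin <- v[ii] * (1 - w) + v[ii + 1] * w
    lg <- uselog[ii]
    lin[lg] <- exp(log(v[ii][lg]) * (1 - w[lg]) + log(v[ii + 1][lg]) * w[lg])
    out[inside] <- lin
    out
  }
}

# profile-amplitude sum-of-exponentials least squares on (t - t0)
fit_exp_series <- function(t, v, n_exp = 3) {
  t0 <- t[1]
  rss_of <- function(log_rates) {
    X <- exp(outer(t - t0, -exp(log_rates)))
    b <- tryCatch(qr.coef(qr(X), v), error = function(e) rep(0, ncol(X)))
    b[is.na(b)] <- 0
    sum((v - X %*% b)^2)
  }
  starts <- list(c(2, 0.3, 0.03), c(0.5, 0.1, 0.01))
  starts <- lapply(starts, function(s) log(s[seq_len(n_exp)]))
  fits <- lapply(starts, function(s) {
    stats::optim(s, rss_of, method = "Nelder-Mead",
                 control = list(reltol = 1e-13, maxit = 3000))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  rates <- exp(best$par)
  X <- exp(outer(t - t0, -rates))
  amps <- qr.coef(qr(X), v)
  amps[is.na(amps)] <- 0
  list(t0 = t0, rates = rates, amplitudes = as.numeric(amps),
       rss = best$value)
}

#' Fit a smooth input function to blood samples
#'
#' Alternative to [interpolate_input()] for sparse late sampling: the
#' post-peak portion of each curve is fitted with a sum of `n_exp`
#' exponentials (amplitudes profiled by linear least squares, rates by
#' multi-start optimisation) while the rise is interpolated linearly through
#' the early samples from zero at t = 0. The fitted tail extrapolates
#' naturally beyond the last sample. Values are floored at zero.
#'
#' @inheritParams interpolate_input
#' @param n_exp Number of exponential terms in the post-peak fit.
#' @return An [input_function()].
#' @export
fit_input <- function(blood, wb_col = "whole_blood_kBq_ml",
                      plasma_col = "plasma_corr_kBq_ml", n_exp = 3) {
  for (col in c("time_min", wb_col, plasma_col)) {
    if (!col %in% names(blood)) abort(sprintf("column `%s` not found", col))
  }
  if (nrow(blood) < n_exp * 2 + 2) abort("too few blood samples for the exponential fit")
  blood <- arrange(blood, .data$time_min)
  make_fitted <- function(v) {
    t <- blood$time_min
    peak <- which.max(v)
    fit <- fit_exp_series(t[peak:length(t)], v[peak:length(t)], n_exp)
    rise_t <- c(0, t[1:peak]); rise_v <- c(0, v[1:peak])
    function(q) {
      out <- numeric(length(q))
      pre <- q <= fit$t0
      out[pre] <- stats::approx(rise_t, rise_v, q[pre], rule = 2)$y
      out[!pre] <- exp(outer(q[!pre] - fit$t0, -fit$rates)) %*% fit$amplitudes
      pmax(out, 0)
    }
  }
  input_function(
    cp = make_fitted(blood[[plasma_col]]),
    cwb = make_fitted(blood[[wb_col]]),
    support = c(0, Inf),
    provenance = sprintf("fitted (%d-exponential post-peak, linear rise)", n_exp)
  )
}

#' Build a continuous input function from blood samples
#'
#' Interpolates discrete whole-blood and metabolite-corrected plasma samples
#' into the continuous curves the kinetic model convolves: piecewise-linear
#' up to the peak sample, log-linear afterwards (positive and faithful to
#' exponential washout), and anchored at zero activity at t = 0. Beyond the
#' last sample the curve is continued exponentially with the washout rate of
#' the final inter-sample segment (default — a scan typically outlasts the
#' last blood draw), or held constant with `extrapolate = "constant"`; the
#' choice is recorded in the provenance.
#'
#' @param blood Tibble with columns `time_min`, the whole-blood column named
#'   by `wb_col` and the corrected-plasma column named by `plasma_col`
#'   (>= 3 samples).
#' @param wb_col,plasma_col Column names.
#' @param extrapolate Tail behaviour beyond the last sample.
#'
#' @return An [input_function()]; evaluation reproduces the samples exactly
#'   at the sample times.
#' @export
interpolate_input <- function(blood, wb_col = "whole_blood_kBq_ml",
                              plasma_col = "plasma_corr_kBq_ml",
                              extrapolate = c("exponential", "constant")) {
  extrapolate <- match.arg(extrapolate)
  for (col in c("time_min", wb_col, plasma_col)) {
    if (!col %in% names(blood)) abort(sprintf("column `%s` not found", col))
  }
  if (nrow(blood) < 3) abort("need at least 3 blood samples")
  blood <- arrange(blood, .data$time_min)
  cp <- make_series_interpolator(blood$time_min, blood[[plasma_col]], extrapolate)
  cwb <- make_series_interpolator(blood$time_min, blood[[wb_col]], extrapolate)
  input_function(
    cp = cp, cwb = cwb, support = c(0, Inf),
    provenance = sprintf(
      "interpolated (linear rise / log-linear tail); %s extrapolation beyond %.3g min",
      extrapolate, max(blood$time_min))
  )
}
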