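#' Tidy a fitted parent-fraction curve
#'
#' @param x A [fit_parent_fraction()] result.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`,
#'   `std.error` (NA for parameters fixed by the f(0) = 100 constraint).
#' @method tidy parent_fit
#' @export
tidy.parent_fit <- function(x, ...) {
  terms <- c("A1", "lambda1", "A2", "lambda2", "plateau")
  est <- c(x$A1, x$lambda1, x$A2, x$lambda2, x$plateau)
  se <- rep(NA_real_, 5)
  free <- rownames(x$cov)
  for (i in seq_along(terms)) {
    if (terms[i] %in% free) se[i] <- sqrt(x$cov[terms[i], terms[i]])
  }
  out <- tibble(term = terms, estimate = est, std.error = se)
  if (!x$has_plateau) out <- out[out$term != "plateau", ]
  out
}

#' @rdname tidy.parent_fit
#' @method glance parent_fit
#' @export
glance.parent_fit <- function(x, ...) {
  tibble(
    r.squared = x$r_squared, rss = x$rss, n = x$n,
    half_life_fast_min = x$half_life_fast,
    half_life_slow_min = x$half_life_slow,
    constrain_f0 = x$constrain_f0, converged = x$converged
  )
}

#' Tidy a one-tissue-compartment fit
#'
#' @param x A [fit_1tc()] result.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (K1, k2, vt) with standard
#'   errors; `glance()`: a one-row model summary.
#' @method tidy kinetic_fit
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble(
    term = c("K1", "k2", "vt"),
    estimate = c(x$K1, x$k2, x$vt),
    std.error = c(x$se_K1, x$se_k2, x$se_vt)
  )
}

#' @rdname tidy.kinetic_fit
#' @method glance kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble(
    region = x$region, hemisphere = x$hemisphere,
    K1 = x$K1, k2 = x$k2, vt = x$vt, Vb = x$Vb,
    rss = x$rss, sigma = x$sigma, n_frames = x$n_frames,
    weighting = x$weighting, converged = x$converged
  )
}

#' @method autoplot parent_fit
#' @export
autoplot.parent_fit <- function(object, n = 200, ...) {
  rng <- range(object$data$time_min)
  grid <- tibble(time_min = seq(0, rng[2], length.out = n))
  grid$parent_pct <- predict(object, grid$time_min)
  ggplot(object$data, aes(.data$time_min, .data$parent_pct)) +
    geom_line(data = grid, colour = "grey40") +
    geom_point() +
    labs(x = "time (min)", y = "parent compound (%)") +
    theme_minimal()
}

#' @method autoplot kinetic_fit
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- object$fitted
  ggplot(d, aes(.data$mid_min, .data$activity_kBq_ml)) +
    geom_point() +
    geom_line(aes(y = .data$fitted), colour = "grey40") +
    labs(x = "time (min)", y = "activity (kBq/ml)",
         title = sprintf("%s (%s): Vt = %.2f", object$region,
                         object$hemisphere, object$vt)) +
    theme_minimal()
}
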