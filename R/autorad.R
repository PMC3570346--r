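#' Calibrate film optical density against co-exposed standards
#'
#' Least-squares cubic fit of standard activity (kBq/mg) on optical density,
#' `activity = c0 + c1 OD + c2 OD^2 + c3 OD^3`, the usual densitometric
#' calibration for autoradiographic film exposed together with polymer
#' activity standards. The fit must be strictly monotone increasing over the
#' standards' OD range (the film's pseudolinear response range); otherwise
#' the calibration is rejected with diagnostics.
#'
#' @param standard_od Optical densities of the standards (>= 4 distinct).
#' @param standard_activity Their known activities in kBq/mg, non-negative.
#'
#' @return Object of class `autorad_cal`: `coefficients` (c0..c3),
#'   `od_range`, `residuals`, `fitted`, `rss`, `data`. Evaluate with
#'   [predict.autorad_cal()] or [quantify_roi()].
#' @export
fit_calibration <- function(standard_od, standard_activity) {
  od <- as.numeric(standard_od); act <- as.numeric(standard_activity)
  if (length(od) != length(act)) abort("standards: lengths differ")
  if (length(unique(od)) < 4) abort("need at least 4 distinct standards")
  if (any(act < 0)) abort("standard activities must be non-negative")
  fit <- lm(act ~ od + I(od^2) + I(od^3))
  coefs <- unname(coef(fit))
  coefs[is.na(coefs)] <- 0
  rng <- range(od)
  grid <- seq(rng[1], rng[2], length.out = 201)
  deriv <- coefs[2] + 2 * coefs[3] * grid + 3 * coefs[4] * grid^2
  if (any(deriv <= 0)) {
    abort(sprintf(
      "calibration cubic is not monotone increasing over OD range [%.3g, %.3g] (min slope %.3g at OD %.3g)",
      rng[1], rng[2], min(deriv), grid[which.min(deriv)]))
  }
  structure(
    list(coefficients = setNames(coefs, c("c0", "c1", "c2", "c3")),
         od_range = rng, residuals = stats::residuals(fit),
         fitted = stats::fitted(fit), rss = sum(stats::residuals(fit)^2),
         data = tibble(od = od, kBq_per_mg = act)),
    class = "autorad_cal"
  )
}

#' Evaluate an autoradiographic calibration curve
#'
#' @param object An [fit_calibration()] result.
#' @param od Optical densities; must lie within the calibrated OD range.
#' @param ... Unused.
#' @return Activities in kBq/mg.
#' @export
predict.autorad_cal <- function(object, od, ...) {
  rng <- object$od_range
  if (any(od < rng[1] - 1e-9 | od > rng[2] + 1e-9)) {
    abort(sprintf(
      "OD outside the pseudolinear response range [%.3g, %.3g] of the calibration",
      rng[1], rng[2]))
  }
  unname(cubic_eval(unname(object$coefficients), od))
}

#' @export
print.autorad_cal <- function(x, ...) {
  cat("<autorad_cal>  activity = c0 + c1*OD + c2*OD^2 + c3*OD^3 (kBq/mg)\n")
  cat(sprintf("  coefficients: %s\n",
              paste(sprintf("%s=%.4g", names(x$coefficients), x$coefficients),
                    collapse = ", ")))
  cat(sprintf("  OD range: [%.3g, %.3g], RSS = %.3g (n = %d standards)\n",
              x$od_range[1], x$od_range[2], x$rss, nrow(x$data)))
  invisible(x)
}

#' Quantify ROI optical densities in kBq/mg
#'
#' Converts ROI optical densities through a calibration curve and averages
#' replicate sections (calibrate first, then average — triplicate sections
#' are the norm).
#'
#' @param data Tibble with an `od` column plus any identifying columns
#'   (e.g. `region`, `condition`, `section`), or a bare numeric vector of
#'   ODs (returns its calibrated mean).
#' @param curve An [fit_calibration()] result.
#' @param by Columns to average within; defaults to every column except
#'   `od` and `section`.
#'
#' @return Tibble of per-group means `kBq_per_mg` with replicate counts, or
#'   a single number for vector input.
#' @export
quantify_roi <- function(data, curve, by = NULL) {
  if (is.numeric(data)) return(mean(predict(curve, data)))
  if (!"od" %in% names(data)) abort("`data` must have an `od` column")
  data$kBq_per_mg <- predict(curve, data$od)
  by <- by %||% setdiff(names(data), c("od", "section", "kBq_per_mg"))
  if (length(by) == 0) {
    return(tibble(kBq_per_mg = mean(data$kBq_per_mg), n_sections = nrow(data)))
  }
  data |>
    group_by(across(dplyr::all_of(by))) |>
    summarise(kBq_per_mg = mean(.data$kBq_per_mg), n_sections = n(),
              .groups = "drop")
}

#' Specific binding from total and non-specific sections
#'
#' `specific = total - nonspecific`, where non-specific binding comes from
#' adjacent sections co-incubated with an excess of unlabelled competitor
#' (10 uM PK11195) and both are quantified with the same calibration.
#' Negative values are reported as-is with a warning unless a floor is set.
#'
#' @param total,nonspecific Activities in kBq/mg (vectorised, equal length).
#' @param floor Optional lower bound applied to the difference.
#' @return Specific binding in kBq/mg.
#' @examples
#' specific_binding(1.2, 0.2) # 1.0
#' @export
specific_binding <- function(total, nonspecific, floor = NULL) {
  if (length(total) != length(nonspecific)) {
    abort("`total` and `nonspecific` must have equal length")
  }
  out <- total - nonspecific
  if (is.null(floor)) {
    if (any(out < 0)) {
      warn(sprintf("%d specific-binding value(s) are negative; reported as-is",
                   sum(out < 0)))
    }
  } else {
    out <- pmax(out, floor)
  }
  out
}
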