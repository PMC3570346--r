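#' Simplified tissue/plasma ratio at 50 min (r50')
#'
#' Computes the late-time VOI-to-plasma activity ratio proposed as a
#' non-invasive surrogate for the volume of distribution in longitudinal
#' studies: the duration-weighted mean VOI activity over the frames
#' overlapping a late window (default 49–54 min) divided by the
#' metabolite-corrected plasma activity at 50 min. Frames are combined with
#' weights equal to their overlap with the window.
#'
#' The plasma denominator can come from the terminal blood sample's own
#' metabolite analysis (r50', `denominator = "sample"`) or from a continuous
#' input function built with the fitted standard curve (r50'(SC),
#' `denominator = "interp"` with an [input_function()]).
#'
#' @param tac A `pet_tac` tibble; may contain several regions (and an
#'   `animal` column) — the ratio is computed per region/hemisphere/animal.
#' @param plasma Either a blood-sample tibble with `time_min` and
#'   `plasma_corr_kBq_ml` (a sample must exist at `at_min`), or an
#'   [input_function()] evaluated at `at_min`.
#' @param window Length-2 numeric, the tissue window in minutes.
#' @param at_min Time of the plasma denominator (default 50 min).
#'
#' @return Tibble with one row per TAC: grouping columns, `r50`,
#'   `tissue_kBq_ml`, `plasma_kBq_ml`, `window_lo`, `window_hi`, `source`.
#' @export
compute_r50 <- function(tac, plasma, window = c(49, 54), at_min = 50) {
  if (length(window) != 2 || window[1] >= window[2]) {
    abort("`window` must be an increasing length-2 interval in minutes")
  }
  if (!all(c("start_s", "end_s", "activity_kBq_ml") %in% names(tac))) {
    abort("`tac` must have schedule columns and activity_kBq_ml")
  }
  if (window[2] * 60 > max(tac$end_s) + 1e-9 || window[1] * 60 < min(tac$start_s) - 1e-9) {
    abort("ratio window extends outside the scan")
  }

  if (inherits(plasma, "input_function")) {
    denom <- eval_cp(plasma, at_min)
    source <- "standard-curve"
  } else {
    if (!all(c("time_min", "plasma_corr_kBq_ml") %in% names(plasma))) {
      abort("`plasma` must be an input_function or have time_min + plasma_corr_kBq_ml")
    }
    hit <- which(abs(plasma$time_min - at_min) < 1e-6)
    if (length(hit) == 0) {
      abort(sprintf("no plasma sample at %g min; use an input_function for interpolation",
                    at_min))
    }
    denom <- plasma$plasma_corr_kBq_ml[hit[1]]
    source <- "per-sample"
  }
  if (denom <= 0) abort("plasma denominator must be positive")

  keys <- intersect(c("animal", "region", "hemisphere"), names(tac))
  grouped <- if (length(keys)) dplyr::group_by(tac, across(dplyr::all_of(keys))) else tac
  out <- dplyr::summarise(
    grouped,
    tissue_kBq_ml = {
      ov <- pmin(.data$end_s / 60, window[2]) - pmax(.data$start_s / 60, window[1])
      ov <- pmax(ov, 0)
      if (sum(ov) <= 0) abort("no frames overlap the ratio window")
      sum(ov * .data$activity_kBq_ml) / sum(ov)
    },
    .groups = "drop"
  )
  out$plasma_kBq_ml <- denom
  out$r50 <- out$tissue_kBq_ml / denom
  out$window_lo <- window[1]
  out$window_hi <- window[2]
  out$source <- source
  out
}

#' Correlate quantitative endpoints across animals, per region
#'
#' Pearson correlations between matched per-animal endpoints (e.g. Vt, r50'
#' and autoradiographic specific binding) for each region, honouring an
#' animal exclusion list (as when a tracer-negative animal is omitted).
#'
#' @param data Wide tibble with columns `animal`, `region` and two or more
#'   numeric endpoint columns.
#' @param endpoints Character vector of endpoint column names to correlate
#'   pairwise; default all numeric columns except identifiers.
#' @param exclude Animal ids to drop before correlating.
#'
#' @return Tibble with one row per region x endpoint pair: `region`,
#'   `endpoint_x`, `endpoint_y`, `n`, `r`, `p_value`, `significant`, `trend`.
#' @export
correlate_endpoints <- function(data, endpoints = NULL, exclude = NULL) {
  if (!all(c("animal", "region") %in% names(data))) {
    abort("`data` must have `animal` and `region` columns")
  }
  if (!is.null(exclude)) data <- filter(data, !.data$animal %in% exclude)
  if (is.null(endpoints)) {
    endpoints <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                         c("animal", "region"))
  }
  if (length(endpoints) < 2) abort("need at least two endpoint columns")
  pairs <- utils::combn(endpoints, 2, simplify = FALSE)
  out <- list()
  for (reg in unique(data$region)) {
    d <- data[data$region == reg, ]
    for (pr in pairs) {
      ok <- complete.cases(d[, pr])
      if (sum(ok) < 3) {
        abort(sprintf("fewer than 3 matched pairs for %s ~ %s in region %s",
                      pr[1], pr[2], reg))
      }
      ct <- pearson_r(d[[pr[1]]][ok], d[[pr[2]]][ok])
      out[[length(out) + 1]] <- tibble(
        region = reg, endpoint_x = pr[1], endpoint_y = pr[2],
        n = ct$n, r = ct$r, p_value = ct$p_value,
        significant = ct$significant, trend = ct$trend
      )
    }
  }
  list_rbind(out)
}
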