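#' Construct a continuous-time input function
#'
#' Pairs a metabolite-corrected plasma activity curve `Cp(t)` with a
#' whole-blood activity curve `Cwb(t)` on a common support. The plasma curve
#' drives the tissue compartment; the whole-blood curve models the signal of
#' the vascular fraction inside a tissue volume of interest.
#'
#' Most users will not call this directly: [interpolate_input()] builds one
#' from measured samples and [simulate_plasma_input()] returns the
#' ground-truth one attached to simulated data.
#'
#' @param cp Function of time (minutes) returning metabolite-corrected plasma
#'   activity in kBq/ml.
#' @param cwb Function of time (minutes) returning whole-blood activity in
#'   kBq/ml.
#' @param support Length-2 numeric, the time interval (minutes) on which the
#'   evaluators are defined.
#' @param provenance Character scalar describing how the curves were obtained
#'   (e.g. `"simulated-truth"`, `"interpolated(per-sample correction)"`).
#'
#' @return An object of class `input_function`.
#' @export
input_function <- function(cp, cwb, support, provenance = "unspecified") {
  stopifnot(is.function(cp), is.function(cwb),
            length(support) == 2, support[1] < support[2])
  structure(
    list(cp = cp, cwb = cwb, support = as.numeric(support),
         provenance = provenance),
    class = "input_function"
  )
}

#' Evaluate the plasma or whole-blood curve of an input function
#'
#' @param input An [input_function()] object.
#' @param t_min Times in minutes; must lie within the support.
#' @return Activity in kBq/ml at `t_min`.
#' @export
eval_cp <- function(input, t_min) {
  assert_input_support(input, t_min)
  input$cp(t_min)
}

#' @rdname eval_cp
#' @export
eval_cwb <- function(input, t_min) {
  assert_input_support(input, t_min)
  input$cwb(t_min)
}

assert_input_support <- function(input, t_min, what = "evaluation times") {
  if (!inherits(input, "input_function")) {
    abort("`input` must be an input_function object")
  }
  tol <- 1e-9
  if (any(t_min < input$support[1] - tol | t_min > input$support[2] + tol)) {
    abort(sprintf(
      "%s outside input-function support [%.3g, %.3g] min",
      what, input$support[1], input$support[2]
    ))
  }
  invisible(input)
}

#' @export
print.input_function <- function(x, ...) {
  cat("<input_function>\n")
  cat(sprintf("  support: [%.3g, %.3g] min\n", x$support[1], x$support[2]))
  cat(sprintf("  provenance: %s\n", x$provenance))
  invisible(x)
}

#' @method autoplot input_function
#' @export
autoplot.input_function <- function(object, n = 400, ...) {
  t <- seq(object$support[1], object$support[2], length.out = n)
  df <- tibble(
    time_min = rep(t, 2),
    activity_kBq_ml = c(object$cp(t), object$cwb(t)),
    curve = rep(c("metabolite-corrected plasma", "whole blood"), each = n)
  )
  ggplot(df, aes(.data$time_min, .data$activity_kBq_ml, colour = .data$curve)) +
    geom_line() +
    labs(x = "time (min)", y = "activity (kBq/ml)", colour = NULL) +
    theme_minimal()
}
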