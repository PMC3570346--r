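#' Remove animals from a simulated or assembled cohort
#'
#' Drops the given animal ids from every table of a cohort (ground truth,
#' blood, metabolite, TACs, autoradiograms and input functions) so that all
#' downstream tables are recomputed without them — the computational
#' counterpart of omitting a tracer-negative animal from a group comparison.
#'
#' @param cohort A `sim_cohort` (see [simulate_cohort()]).
#' @param ids Character vector of animal ids; all must exist. An empty
#'   vector returns the cohort unchanged.
#' @return The cohort without those animals; the exclusion is recorded in
#'   the `excluded` attribute.
#' @export
exclude_animals <- function(cohort, ids) {
  if (!inherits(cohort, "sim_cohort")) abort("`cohort` must be a sim_cohort")
  if (length(ids) == 0) return(cohort)
  known <- unique(cohort$ground_truth$animal)
  bad <- setdiff(ids, known)
  if (length(bad)) {
    abort(paste("unknown animal id(s):", paste(bad, collapse = ", ")))
  }
  drop_rows <- function(df) {
    if (is.null(df) || !"animal" %in% names(df)) return(df)
    df[!df$animal %in% ids, , drop = FALSE]
  }
  cohort$ground_truth <- drop_rows(cohort$ground_truth)
  cohort$blood <- drop_rows(cohort$blood)
  cohort$metabolite <- drop_rows(cohort$metabolite)
  cohort$tacs <- drop_rows(cohort$tacs)
  cohort$autorad_truth <- drop_rows(cohort$autorad_truth)
  if (!is.null(cohort$autorad)) {
    cohort$autorad$sections <- drop_rows(cohort$autorad$sections)
  }
  cohort$inputs <- cohort$inputs[setdiff(names(cohort$inputs), ids)]
  attr(cohort, "excluded") <- union(attr(cohort, "excluded"), ids)
  cohort
}

#' Run the full quantification study
#'
#' Replays the whole analysis on a cohort: fits the parent-fraction standard
#' curve from the metabolite-study tables, builds a metabolite-corrected
#' input function per animal, estimates Vt for every VOI with the
#' one-tissue compartment model (fixed vascular fraction), computes the
#' simplified ratios r50' and r50'(SC), calibrates and quantifies the
#' autoradiograms, and runs the group statistics — producing the summary
#' tables (group means +/- SEM, percent increase, significance flags) and
#' the per-region endpoint correlations.
#'
#' @param cohort A [cohort_config()] (simulated with `seed`) or an existing
#'   `sim_cohort`.
#' @param seed Integer seed used when `cohort` is a config.
#' @param exclude Animal ids omitted from the group comparison and the
#'   correlations (e.g. a tracer-negative animal).
#' @param Vb Fixed vascular fraction used in the kinetic fits.
#' @param r50_window Tissue window (min) of the simplified ratio.
#' @param alpha,trend_alpha Significance and trend thresholds.
#' @param constrain_f0 Constrain the standard curve through 100% at t = 0.
#' @param input_method How the continuous input function is built from the
#'   corrected samples: `"fit"` (sum-of-exponentials tail, [fit_input()];
#'   default, robust to sparse late sampling) or `"interpolate"`
#'   ([interpolate_input()]).
#' @param correlate_regions Regions entered into the endpoint correlations.
#'
#' @return A list of class `study_report` with elements `parent_fit`,
#'   `inputs`, `vt_fits`, `vt_summary`, `r50_table`, `autorad_table`,
#'   `correlations`, `excluded`, `seed`, `config_hash` and `log` (one line
#'   per decision taken).
#' @export
run_study <- function(cohort = default_cohort_config(), seed = 1,
                      exclude = character(), Vb = 0.05,
                      r50_window = c(49, 54), alpha = 0.05,
                      trend_alpha = 0.1, constrain_f0 = TRUE,
                      input_method = c("fit", "interpolate"),
                      correlate_regions = c("hippocampus", "thalamus",
                                            "amygdala")) {
  input_method <- match.arg(input_method)
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))

  if (inherits(cohort, "cohort_config")) {
    config_hash <- rlang::hash(cohort)
    cohort <- simulate_cohort(cohort, seed)
    say("simulated cohort from config (seed %d)", seed)
  } else if (inherits(cohort, "sim_cohort")) {
    config_hash <- rlang::hash(cohort$config)
  } else {
    abort("`cohort` must be a cohort_config or sim_cohort")
  }
  config <- cohort$config

  if (length(exclude)) {
    cohort <- exclude_animals(cohort, exclude)
    say("excluded animal(s): %s", paste(exclude, collapse = ", "))
  }

  # 1. parent-fraction standard curve, pooled across the metabolite study
  pf <- fit_parent_fraction(cohort$metabolite$time_min,
                            cohort$metabolite$parent_pct,
                            constrain_f0 = constrain_f0)
  say("standard metabolite curve: R^2 = %.4f, half-lives %.2f / %.1f min",
      pf$r_squared, pf$half_life_fast, pf$half_life_slow)

  animals <- unique(cohort$ground_truth$animal)
  groups <- cohort$ground_truth |>
    dplyr::distinct(.data$animal, .data$group)

  # 2. metabolite-corrected input function per animal (standard-curve route)
  inputs <- map(setNames(animals, animals), function(an) {
    bl <- cohort$blood[cohort$blood$animal == an, ]
    bl <- apply_metabolite_correction(bl, pf, value_col = "plasma_kBq_ml")
    if (input_method == "fit") fit_input(bl) else interpolate_input(bl)
  })
  say("input functions: %s", inputs[[1]]$provenance)

  # 3. kinetic fits
  vt_fits <- map(animals, function(an) {
    tacs <- cohort$tacs[cohort$tacs$animal == an, ]
    split(tacs, paste(tacs$region, tacs$hemisphere)) |>
      map(function(tac) {
        fit <- fit_1tc(tac, inputs[[an]], Vb = Vb)
        tibble(animal = an, region = tac$region[1],
               hemisphere = tac$hemisphere[1], K1 = fit$K1, k2 = fit$k2,
               vt = fit$vt, se_vt = fit$se_vt, rss = fit$rss,
               converged = fit$converged)
      }) |> list_rbind()
  }) |> list_rbind() |> left_join(groups, by = "animal")
  if (any(!vt_fits$converged)) {
    say("WARNING: %d kinetic fit(s) flagged non-converged",
        sum(!vt_fits$converged))
  }

  # 4. simplified ratios: r50' (terminal sample's own metabolite analysis)
  #    and r50'(SC) (fitted standard curve)
  r50_table <- map(animals, function(an) {
    tacs <- cohort$tacs[cohort$tacs$animal == an, ]
    bl <- cohort$blood[cohort$blood$animal == an, ]
    bl_sample <- mutate(bl, plasma_corr_kBq_ml =
                          .data$plasma_kBq_ml * .data$parent_fraction_pct / 100)
    r_sample <- compute_r50(tacs, bl_sample, window = r50_window)
    r_sc <- compute_r50(tacs, inputs[[an]], window = r50_window)
    left_join(
      select(r_sample, dplyr::all_of(c("animal", "region", "hemisphere")),
             r50 = "r50"),
      select(r_sc, dplyr::all_of(c("animal", "region", "hemisphere")),
             r50_sc = "r50"),
      by = c("animal", "region", "hemisphere")
    )
  }) |> list_rbind() |> left_join(groups, by = "animal")

  # 5. autoradiography: calibrate against the co-exposed standards, quantify
  #    triplicate sections, subtract non-specific binding
  autorad_table <- NULL
  if (!is.null(cohort$autorad)) {
    cal <- fit_calibration(cohort$autorad$standards$od,
                           cohort$autorad$standards$kBq_per_mg)
    quant <- quantify_roi(cohort$autorad$sections, cal,
                          by = c("animal", "region", "condition"))
    autorad_table <- quant |>
      tidyr::pivot_wider(names_from = "condition",
                         values_from = c("kBq_per_mg", "n_sections")) |>
      mutate(
        total = .data$kBq_per_mg_total,
        nonspecific = .data$kBq_per_mg_nonspecific,
        specific = specific_binding(.data$total, .data$nonspecific)
      ) |>
      select(dplyr::all_of(c("animal", "region", "total", "nonspecific",
                             "specific"))) |>
      left_join(groups, by = "animal")
    if (any(autorad_table$specific < 0)) {
      say("WARNING: negative specific binding retained in autoradiography table")
    }
  }

  # 6. Vt group comparison per region/hemisphere
  ctrl_name <- grep("control", unique(groups$group), ignore.case = TRUE,
                    value = TRUE)[1]
  if (is.na(ctrl_name)) ctrl_name <- unique(groups$group)[1]
  vt_summary <- vt_fits |>
    group_by(.data$region, .data$hemisphere) |>
    dplyr::group_modify(function(d, key) {
      a <- d$vt[d$group == ctrl_name]
      b <- d$vt[d$group != ctrl_name]
      tt <- t_test_auto(a, b, alpha = alpha, trend_alpha = trend_alpha)
      tibble(
        mean_control = mean(a), sem_control = stats::sd(a) / sqrt(length(a)),
        n_control = length(a),
        mean_kase = mean(b), sem_kase = stats::sd(b) / sqrt(length(b)),
        n_kase = length(b),
        pct_increase = percent_difference(mean(a), mean(b)),
        p_value = tt$p_value, variant = tt$variant,
        flag = significance_flag(tt$p_value)
      )
    }) |> ungroup()

  # 7. endpoint correlations (hemispheres averaged to match the per-region
  #    autoradiography values)
  correlations <- NULL
  corr_regions <- intersect(correlate_regions, unique(vt_fits$region))
  if (length(corr_regions)) {
    vt_reg <- vt_fits |>
      filter(.data$region %in% corr_regions) |>
      group_by(.data$animal, .data$region) |>
      summarise(vt = mean(.data$vt), .groups = "drop")
    r50_reg <- r50_table |>
      filter(.data$region %in% corr_regions) |>
      group_by(.data$animal, .data$region) |>
      summarise(r50 = mean(.data$r50), r50_sc = mean(.data$r50_sc),
                .groups = "drop")
    wide <- left_join(vt_reg, r50_reg, by = c("animal", "region"))
    if (!is.null(autorad_table)) {
      wide <- left_join(wide,
                        select(autorad_table,
                               dplyr::all_of(c("animal", "region")),
                               autorad = "specific"),
                        by = c("animal", "region"))
    }
    correlations <- correlate_endpoints(wide)
  }

  structure(
    list(parent_fit = pf, inputs = inputs, vt_fits = vt_fits,
         vt_summary = vt_summary, r50_table = r50_table,
         autorad_table = autorad_table, correlations = correlations,
         excluded = attr(cohort, "excluded") %||% character(),
         seed = seed, config_hash = config_hash, config = config, log = log),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  seed %s, config hash %s\n", x$seed, x$config_hash))
  if (length(x$excluded)) {
    cat(sprintf("  excluded: %s\n", paste(x$excluded, collapse = ", ")))
  }
  cat("\nVt group summary (mean +/- SEM; % increase over control):\n")
  disp <- x$vt_summary
  disp$display <- sprintf(
    "%s %s: %.1f +/- %.1f vs %.1f +/- %.1f  (%+d%%)%s",
    disp$region, disp$hemisphere, disp$mean_control, disp$sem_control,
    disp$mean_kase, disp$sem_kase, round(disp$pct_increase), disp$flag
  )
  cat(paste0("  ", disp$display, collapse = "\n"), "\n")
  if (!is.null(x$correlations)) {
    cat("\nEndpoint correlations:\n")
    print(x$correlations)
  }
  invisible(x)
}

#' @method autoplot study_report
#' @export
autoplot.study_report <- function(object, ...) {
  d <- object$vt_summary |>
    tidyr::pivot_longer(
      cols = c("mean_control", "mean_kase"),
      names_to = "group", values_to = "mean_vt"
    ) |>
    mutate(
      sem = ifelse(.data$group == "mean_control", .data$sem_control,
                   .data$sem_kase),
      group = ifelse(.data$group == "mean_control", "control", "KASE"),
      label = paste(.data$region, .data$hemisphere)
    )
  ggplot(d, aes(.data$label, .data$mean_vt, colour = .data$group)) +
    geom_pointrange(aes(ymin = .data$mean_vt - .data$sem,
                        ymax = .data$mean_vt + .data$sem),
                    position = ggplot2::position_dodge(width = 0.5)) +
    labs(x = NULL, y = expression(V[t]), colour = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
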