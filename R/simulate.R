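#' Measurement-noise model for simulated PET frames
#'
#' Zero-mean Gaussian noise whose variance follows the usual PET count-noise
#' surrogate: proportional to the frame activity divided by the frame
#' duration, so short early frames are noisier than long late frames.
#' `scale = 0` makes every simulator output exactly equal to its forward
#' model.
#'
#' @param scale Non-negative noise scale factor (roughly the fractional
#'   standard deviation of a 1-min frame at unit activity).
#' @param seed Optional integer seed applied when the noise is drawn.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(scale = 0, seed = NULL) {
  if (scale < 0) abort("noise `scale` must be non-negative")
  structure(list(scale = scale, seed = seed), class = "noise_model")
}

add_frame_noise <- function(values, dur_min, noise) {
  if (noise$scale == 0) return(values)
  sd <- noise$scale * sqrt(pmax(values, 0) / dur_min)
  draw <- function() values + rnorm(length(values), 0, sd)
  if (!is.null(noise$seed)) withr::with_seed(noise$seed, draw()) else draw()
}

#' Simulate arterial blood sampling of a tracer infusion
#'
#' Draws timed whole-blood and plasma samples from a ground-truth plasma
#' model: a 1-min constant infusion followed by multi-exponential clearance,
#' a constant plasma-to-whole-blood ratio and a two-exponential parent
#' fraction. Total (parent + metabolite) plasma activity is reported with
#' the parent fraction attached, as a gamma counter would see it; the
#' metabolite-corrected truth is available from the returned continuous
#' curves.
#'
#' @param plasma A [plasma_model()]; default [default_plasma_model()].
#' @param parent A [parent_curve()]; default [default_parent_curve()].
#' @param sample_times Strictly increasing sampling times in minutes within
#'   \[0, 60\]; default [default_sample_times()].
#' @param noise A [noise_model()] applied to the sampled activities with
#'   `sd = scale * sqrt(activity)`.
#'
#' @return A list with
#'   * `samples`: tibble `time_min`, `whole_blood_kBq_ml`, `plasma_kBq_ml`
#'     (total), `parent_fraction_pct`, `plasma_corr_kBq_ml` (parent only);
#'   * `input`: the ground-truth [input_function()] (metabolite-corrected
#'     plasma + whole blood);
#'   * `plasma_model`, `parent_curve`.
#' @export
simulate_plasma_input <- function(plasma = default_plasma_model(),
                                  parent = default_parent_curve(),
                                  sample_times = default_sample_times(),
                                  noise = noise_model(0)) {
  if (is.unsorted(sample_times, strictly = TRUE)) {
    abort("`sample_times` must be strictly increasing")
  }
  if (any(sample_times < 0 | sample_times > 60)) {
    abort("`sample_times` must lie within [0, 60] minutes")
  }
  cwb_fun <- function(t) whole_blood_curve(plasma, t)
  cp_fun <- function(t) {
    whole_blood_curve(plasma, t) * plasma$plasma_to_blood *
      predict(parent, t) / 100
  }
  wb <- cwb_fun(sample_times)
  pl <- wb * plasma$plasma_to_blood
  wb <- add_sample_noise(wb, noise)
  pl <- add_sample_noise(pl, noise)
  f <- predict(parent, sample_times)
  samples <- tibble(
    time_min = sample_times,
    whole_blood_kBq_ml = wb,
    plasma_kBq_ml = pl,
    parent_fraction_pct = f,
    plasma_corr_kBq_ml = pl * f / 100
  )
  list(
    samples = samples,
    input = input_function(cp_fun, cwb_fun, support = c(0, Inf),
                           provenance = "simulated-truth"),
    plasma_model = plasma,
    parent_curve = parent
  )
}

add_sample_noise <- function(values, noise) {
  if (noise$scale == 0) return(values)
  draw <- function() values + rnorm(length(values), 0,
                                    noise$scale * sqrt(pmax(values, 0)))
  if (!is.null(noise$seed)) withr::with_seed(noise$seed, draw()) else draw()
}

#' Simulate a noisy time-activity curve from known kinetics
#'
#' Forward-models a VOI TAC with [model_tac()] (one-tissue compartment plus
#' vascular fraction) and adds frame-duration-dependent Gaussian noise from
#' a [noise_model()]. With `scale = 0` the output equals [model_tac()]
#' bit-for-bit.
#'
#' @inheritParams model_tac
#' @param noise A [noise_model()].
#' @return A `pet_tac` tibble.
#' @export
simulate_tac <- function(K1, k2, Vb = 0.05, input, schedule,
                         noise = noise_model(0), region = "sim",
                         hemisphere = "whole", dt_s = 0.25) {
  tac <- model_tac(K1, k2, Vb, input, schedule, dt_s = dt_s,
                   region = region, hemisphere = hemisphere)
  tac$activity_kBq_ml <- add_frame_noise(tac$activity_kBq_ml,
                                         tac$dur_s / 60, noise)
  tac
}

#' Cohort simulation configuration
#'
#' Bundles everything the cohort generator needs: group sizes, the
#' per-region true Vt distribution for each group, the shared blood/parent
#' models, the acquisition schedule and the noise scales.
#'
#' @param group_sizes Named integer vector, e.g. `c(control = 4, KASE = 4)`.
#' @param regions Tibble with columns `region`, `hemisphere`, `vt_mean_control`,
#'   `vt_sd_control`, `vt_mean_kase`, `vt_sd_kase` (Vt is unitless; SDs are
#'   between-animal standard deviations).
#' @param K1_mean,K1_sd Mean/SD of the true influx rate K1
#'   (ml/ml/min) across animals; per-animal k2 is derived as `K1 / Vt`.
#' @param Vb True vascular fraction.
#' @param noise_scale TAC noise scale (see [noise_model()]).
#' @param blood_noise_scale Noise scale for blood samples.
#' @param parent_noise_pct SD (percentage points) of noise on measured
#'   parent fractions in the metabolite study tables.
#' @param plasma,parent,schedule,sample_times Shared ground-truth models.
#' @param metabolite_times Sampling times (min) of the metabolite study.
#' @param injected_dose_MBq Range from which per-animal injected doses are
#'   drawn uniformly.
#' @param autorad_regions Regions quantified on the autoradiograms (those
#'   with high TSPO binding plus a low-binding reference region, where
#'   present in `regions`).
#' @param autorad_scale kBq/mg of specific binding per unit of true Vt (the
#'   shared inflammation signal linking the in vivo and in vitro endpoints).
#' @param autorad_nonspecific True non-specific binding in kBq/mg.
#' @param autorad_od_noise SD of optical-density noise on simulated plates.
#' @param autorad_standards Calibration-standard activities in kBq/mg.
#' @param autorad_response Cubic OD-to-activity coefficients (see
#'   [simulate_autorad_plate()]).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(control = 4, KASE = 4),
                          regions = kase_region_table(),
                          K1_mean = 0.3, K1_sd = 0, Vb = 0.05,
                          noise_scale = 0, blood_noise_scale = 0,
                          parent_noise_pct = 0,
                          plasma = default_plasma_model(),
                          parent = default_parent_curve(),
                          schedule = default_frame_schedule(),
                          sample_times = default_sample_times(),
                          metabolite_times = c(2, 5, 10, 20, 30, 45, 60),
                          injected_dose_MBq = c(12.5, 29),
                          autorad_regions = c("hippocampus", "thalamus",
                                              "amygdala", "colliculi"),
                          autorad_scale = 0.08,
                          autorad_nonspecific = 0.2,
                          autorad_od_noise = 0,
                          autorad_standards = c(0.15, 0.3, 0.6, 1.2, 2.5, 5, 9, 15),
                          autorad_response = c(0, 1.2, 0, 0.8)) {
  if (length(group_sizes) < 1 || any(group_sizes < 1)) {
    abort("all group sizes must be positive")
  }
  need <- c("region", "hemisphere", "vt_mean_control", "vt_sd_control",
            "vt_mean_kase", "vt_sd_kase")
  if (!all(need %in% names(regions))) {
    abort(paste("`regions` must have columns:", paste(need, collapse = ", ")))
  }
  structure(
    list(group_sizes = group_sizes, regions = regions, K1_mean = K1_mean,
         K1_sd = K1_sd, Vb = Vb, noise_scale = noise_scale,
         blood_noise_scale = blood_noise_scale,
         parent_noise_pct = parent_noise_pct, plasma = plasma,
         parent = parent, schedule = schedule, sample_times = sample_times,
         metabolite_times = metabolite_times,
         injected_dose_MBq = injected_dose_MBq,
         autorad_regions = autorad_regions, autorad_scale = autorad_scale,
         autorad_nonspecific = autorad_nonspecific,
         autorad_od_noise = autorad_od_noise,
         autorad_standards = autorad_standards,
         autorad_response = autorad_response),
    class = "cohort_config"
  )
}

#' Region-wise true Vt group means for the default cohort
#'
#' Group means of the tracer volume of distribution for control and
#' kainic-acid status-epilepticus (KASE) animals across the analysed brain
#' VOIs (per hemisphere where applicable). Between-animal SDs are derived
#' from the reported SEMs with n = 4 per group.
#'
#' @return A tibble usable as the `regions` argument of [cohort_config()].
#' @export
kase_region_table <- function() {
  tb <- tibble::tribble(
    ~region,           ~hemisphere, ~vt_mean_control, ~sem_control, ~vt_mean_kase, ~sem_kase,
    "frontal_cortex",  "left",      5.4, 1.0, 11.3, 2.4,
    "frontal_cortex",  "right",     5.7, 1.2, 11.2, 2.4,
    "striatum",        "left",      2.8, 0.6,  8.0, 1.2,
    "striatum",        "right",     3.0, 0.5,  7.8, 1.1,
    "parietal_cortex", "left",      4.5, 0.6,  9.5, 1.1,
    "parietal_cortex", "right",     4.9, 0.8, 11.6, 2.0,
    "hippocampus",     "left",      3.6, 0.5,  9.1, 1.1,
    "hippocampus",     "right",     3.6, 0.4,  9.4, 1.6,
    "thalamus",        "left",      2.6, 0.5,  7.0, 1.8,
    "thalamus",        "right",     2.8, 0.5,  7.1, 1.4,
    "hypothalamus",    "whole",     4.0, 0.7,  8.2, 1.4,
    "amygdala",        "left",      5.3, 0.8, 20.6, 2.8,
    "amygdala",        "right",     6.1, 0.7, 23.4, 4.8,
    "occipital_cortex","left",      9.8, 3.4, 15.1, 3.5,
    "occipital_cortex","right",     9.3, 1.4, 15.0, 1.4,
    "colliculi",       "left",      4.0, 1.0,  5.8, 1.1,
    "colliculi",       "right",     4.1, 1.1,  6.9, 1.8,
    "brainstem",       "whole",     4.7, 0.8,  6.7, 1.0,
    "pons",            "whole",     4.2, 0.9,  7.5, 1.8,
    "cerebellum",      "whole",     7.5, 0.8, 10.6, 1.3
  )
  n <- 4
  tibble(
    region = tb$region, hemisphere = tb$hemisphere,
    vt_mean_control = tb$vt_mean_control,
    vt_sd_control = tb$sem_control * sqrt(n),
    vt_mean_kase = tb$vt_mean_kase,
    vt_sd_kase = tb$sem_kase * sqrt(n)
  )
}

#' Default cohort configuration
#'
#' Control and KASE groups of 4 animals each, region-wise true Vt means and
#' SDs from [kase_region_table()], the 28-frame acquisition schedule and the
#' standard blood-sampling design.
#'
#' @param ... Overrides passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
default_cohort_config <- function(...) cohort_config(...)

#' Simulate a full synthetic study cohort
#'
#' Generates, per animal: a ground-truth kinetic parameter set for every
#' region (true Vt drawn from the group/region distribution, `k2 = K1/Vt`),
#' a sampled blood table, a metabolite-study parent-fraction table, the
#' ground-truth input function, and noisy TACs on the configured schedule.
#' Deterministic given `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A list of class `sim_cohort`:
#'   `ground_truth` (animal, group, region, hemisphere, K1, k2, Vb, vt,
#'   injected_dose_MBq), `blood`, `metabolite`, `tacs` (long tibbles keyed
#'   by `animal`), `inputs` (named list of ground-truth input functions) and
#'   `config`.
#' @export
simulate_cohort <- function(config = default_cohort_config(), seed = 1) {
  if (!inherits(config, "cohort_config")) abort("`config` must be a cohort_config")
  withr::with_seed(seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  groups <- rep(names(config$group_sizes), config$group_sizes)
  animals <- sprintf("%s_%02d", groups, unlist(lapply(config$group_sizes, seq_len)))
  doses <- stats::runif(length(animals), config$injected_dose_MBq[1],
                        config$injected_dose_MBq[2])

  truth <- imap(animals, function(an, i) {
    grp <- groups[i]
    kase <- !identical(tolower(grp), "control")
    mu <- if (kase) config$regions$vt_mean_kase else config$regions$vt_mean_control
    sd <- if (kase) config$regions$vt_sd_kase else config$regions$vt_sd_control
    vt <- pmax(stats::rnorm(nrow(config$regions), mu, sd), 0.2)
    K1 <- pmax(stats::rnorm(nrow(config$regions), config$K1_mean, config$K1_sd), 0.02)
    tibble(
      animal = an, group = grp,
      region = config$regions$region, hemisphere = config$regions$hemisphere,
      K1 = K1, k2 = K1 / vt, Vb = config$Vb, vt = vt,
      injected_dose_MBq = doses[i]
    )
  }) |> list_rbind()

  sim_blood <- function(an) {
    s <- simulate_plasma_input(config$plasma, config$parent,
                               config$sample_times,
                               noise_model(config$blood_noise_scale))
    list(samples = mutate(s$samples, animal = an, .before = 1),
         input = s$input)
  }
  per_animal <- setNames(lapply(animals, sim_blood), animals)
  blood <- list_rbind(map(per_animal, "samples"))
  inputs <- map(per_animal, "input")

  metab <- map(animals, function(an) {
    f_true <- predict(config$parent, config$metabolite_times)
    f_obs <- f_true + stats::rnorm(length(f_true), 0, config$parent_noise_pct)
    tibble(animal = an, time_min = config$metabolite_times,
           parent_pct = pmin(pmax(f_obs, 0.1), 100))
  }) |> list_rbind()

  tacs <- map(seq_len(nrow(truth)), function(j) {
    row <- truth[j, ]
    simulate_tac(row$K1, row$k2, row$Vb, inputs[[row$animal]],
                 config$schedule, noise_model(config$noise_scale),
                 region = row$region, hemisphere = row$hemisphere) |>
      mutate(animal = row$animal, .before = 1)
  }) |> list_rbind()

  autorad <- simulate_cohort_autorad(truth, config)

  structure(
    list(ground_truth = truth, blood = blood, metabolite = metab,
         tacs = tacs, inputs = inputs, autorad = autorad$plates,
         autorad_truth = autorad$truth, config = config),
    class = "sim_cohort"
  )
}

# in-vitro arm of the cohort: one film per animal, triplicate total and
# non-specific sections per region, co-exposed with the shared standards.
# True specific binding is proportional to the animal's (hemisphere-mean)
# true Vt so that in vivo and in vitro endpoints share the inflammation
# signal, as a common TSPO substrate implies.
simulate_cohort_autorad <- function(truth, config) {
  regs <- intersect(config$autorad_regions, unique(truth$region))
  if (length(regs) == 0) {
    return(list(plates = NULL, truth = NULL))
  }
  base <- truth |>
    filter(.data$region %in% regs) |>
    group_by(.data$animal, .data$group, .data$region) |>
    summarise(vt_region = mean(.data$vt), .groups = "drop") |>
    mutate(
      specific = config$autorad_scale * .data$vt_region,
      nonspecific = config$autorad_nonspecific,
      total = .data$specific + .data$nonspecific
    )
  plates <- map(unique(base$animal), function(an) {
    b <- base[base$animal == an, ]
    acts <- c(rep(b$total, each = 3), rep(b$nonspecific, each = 3))
    names(acts) <- paste(rep(rep(b$region, each = 3), 2),
                         rep(c("total", "nonspecific"), each = 3 * nrow(b)),
                         rep(1:3, 2 * nrow(b)), sep = ".")
    plate <- simulate_autorad_plate(
      config$autorad_standards, acts,
      od_response = config$autorad_response,
      noise = config$autorad_od_noise
    )
    info <- do.call(rbind, strsplit(plate$rois$roi, ".", fixed = TRUE))
    tibble(
      animal = an, region = info[, 1], condition = info[, 2],
      section = as.integer(info[, 3]), od = plate$rois$od
    )
  }) |> list_rbind()
  std_plate <- simulate_autorad_plate(
    config$autorad_standards, c(first = config$autorad_standards[1]),
    od_response = config$autorad_response, noise = 0
  )
  list(
    plates = list(standards = std_plate$standards, sections = plates),
    truth = base
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort>\n")
  cat(sprintf("  animals: %s\n",
              paste(sprintf("%s (n=%d)", names(x$config$group_sizes),
                            x$config$group_sizes), collapse = ", ")))
  cat(sprintf("  regions: %d region/hemisphere endpoints, %d frames\n",
              nrow(x$config$regions), nrow(x$config$schedule)))
  cat(sprintf("  noise scale: %.3g\n", x$config$noise_scale))
  invisible(x)
}

#' Simulate an autoradiogram optical-density plate
#'
#' Generates the optical densities that co-exposed calibration standards and
#' tissue ROIs of known activity would produce on film, by inverting a
#' configured monotone activity-vs-OD cubic `activity = g(OD)` over its
#' declared OD range. A noiseless plate round-trips exactly through
#' [fit_calibration()] and [quantify_roi()].
#'
#' @param standard_activities Activities of the calibration standards in
#'   kBq/mg (>= 4 distinct values).
#' @param roi_true_activities Named or unnamed vector of true ROI activities
#'   (kBq/mg).
#' @param od_response Cubic coefficients `c(c0, c1, c2, c3)` of
#'   `g(OD) = c0 + c1 OD + c2 OD^2 + c3 OD^3`; must be strictly monotone
#'   increasing over `od_range`.
#' @param od_range OD interval over which the response is used.
#' @param noise SD of Gaussian noise added to the generated ODs.
#' @param seed Optional seed.
#' @return List with tibbles `standards` (`od`, `kBq_per_mg`) and `rois`
#'   (`roi`, `od`, `true_kBq_per_mg`).
#' @export
simulate_autorad_plate <- function(standard_activities, roi_true_activities,
                                   od_response = c(0, 1.2, 0, 0.8),
                                   od_range = c(0, 2.5), noise = 0,
                                   seed = NULL) {
  if (length(unique(standard_activities)) < 4) {
    abort("need at least 4 distinct standard activities")
  }
  g <- function(od) cubic_eval(od_response, od)
  dg <- function(od) od_response[2] + 2 * od_response[3] * od +
    3 * od_response[4] * od^2
  grid <- seq(od_range[1], od_range[2], length.out = 201)
  if (any(dg(grid) <= 0)) {
    abort("`od_response` is not monotone increasing over `od_range`")
  }
  lohi <- g(od_range)
  all_act <- c(standard_activities, roi_true_activities)
  if (any(all_act < lohi[1] - 1e-9 | all_act > lohi[2] + 1e-9)) {
    abort("requested activities fall outside the response range of the film")
  }
  invert <- function(a) {
    stats::uniroot(function(od) g(od) - a, interval = od_range,
                   tol = 1e-12)$root
  }
  od_std <- unname(vapply(standard_activities, invert, numeric(1)))
  od_roi <- unname(vapply(as.numeric(roi_true_activities), invert, numeric(1)))
  if (noise > 0) {
    jitter <- function() {
      od_std <<- od_std + rnorm(length(od_std), 0, noise)
      od_roi <<- od_roi + rnorm(length(od_roi), 0, noise)
    }
    if (!is.null(seed)) withr::with_seed(seed, jitter()) else jitter()
  }
  roi_names <- names(roi_true_activities) %||%
    paste0("roi_", seq_along(roi_true_activities))
  list(
    standards = tibble(od = od_std, kBq_per_mg = standard_activities),
    rois = tibble(roi = roi_names, od = od_roi,
                  true_kBq_per_mg = as.numeric(roi_true_activities))
  )
}

cubic_eval <- function(coefs, x) {
  coefs[1] + coefs[2] * x + coefs[3] * x^2 + coefs[4] * x^3
}
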