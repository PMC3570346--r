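#' Read and write the package's tabular interchange formats
#'
#' Plain-CSV readers/writers for the study's tables: blood tables
#' (`time_min`, `whole_blood_kBq_ml`, `plasma_kBq_ml`,
#' `parent_fraction_pct`), metabolite tables (`time_min`, `parent_pct`) and
#' wide TAC tables (`frame_start_s`, `frame_dur_s`, one activity column per
#' VOI in kBq/ml).
#'
#' @param path File path.
#' @name tspopet-io
NULL

#' @rdname tspopet-io
#' @export
read_blood_table <- function(path) {
  df <- as_tibble(utils::read.csv(path))
  if (!"time_min" %in% names(df)) abort("blood table needs a `time_min` column")
  arrange(df, .data$time_min)
}

#' @rdname tspopet-io
#' @export
read_parent_table <- function(path) {
  df <- as_tibble(utils::read.csv(path))
  if (!all(c("time_min", "parent_pct") %in% names(df))) {
    abort("metabolite table needs columns `time_min`, `parent_pct`")
  }
  arrange(df, .data$time_min)
}

#' @rdname tspopet-io
#' @export
read_tac_table <- function(path) {
  df <- as_tibble(utils::read.csv(path, check.names = FALSE))
  if (!all(c("frame_start_s", "frame_dur_s") %in% names(df))) {
    abort("TAC table needs columns `frame_start_s`, `frame_dur_s`")
  }
  sched <- frame_schedule(df$frame_dur_s, start_s = df$frame_start_s[1])
  regions <- setdiff(names(df), c("frame_start_s", "frame_dur_s"))
  out <- map(regions, function(rg) {
    tac <- as_tibble(sched)
    tac$region <- rg
    tac$hemisphere <- "whole"
    tac$activity_kBq_ml <- df[[rg]]
    tac
  }) |> list_rbind()
  class(out) <- c("pet_tac", class(out))
  out
}

#' @rdname tspopet-io
#' @param tac A long `pet_tac` tibble (single animal).
#' @export
write_tac_table <- function(tac, path) {
  wide <- tac |>
    mutate(voi = paste(.data$region, .data$hemisphere, sep = "_")) |>
    select(dplyr::all_of(c("start_s", "dur_s", "voi", "activity_kBq_ml"))) |>
    tidyr::pivot_wider(names_from = "voi", values_from = "activity_kBq_ml") |>
    dplyr::rename(frame_start_s = "start_s", frame_dur_s = "dur_s")
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Emits, under `dir`: one blood CSV and one wide TAC CSV per animal, the
#' metabolite tables, the autoradiogram tables and a ground-truth JSON.
#' Output is deterministic for a given cohort, so identical seeds yield
#' byte-identical files.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "sim_cohort")) abort("`cohort` must be a sim_cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (an in unique(cohort$ground_truth$animal)) {
    utils::write.csv(cohort$blood[cohort$blood$animal == an, ],
                     file.path(dir, paste0(an, "_blood.csv")),
                     row.names = FALSE)
    write_tac_table(cohort$tacs[cohort$tacs$animal == an, ],
                    file.path(dir, paste0(an, "_tac.csv")))
  }
  utils::write.csv(cohort$metabolite, file.path(dir, "metabolite.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$autorad)) {
    utils::write.csv(cohort$autorad$standards,
                     file.path(dir, "autorad_standards.csv"), row.names = FALSE)
    utils::write.csv(cohort$autorad$sections,
                     file.path(dir, "autorad_sections.csv"), row.names = FALSE)
  }
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
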