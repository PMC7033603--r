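#' Write one run to disk
#'
#' The run format is a CSV (`time_s, ax, ay, az`; sensor frame, m/s^2) plus a
#' JSON sidecar holding participant, condition, sampling rate, 0-based
#' half-open segment intervals, speed and (optionally) the planted truth.
#'
#' @param run a `raw_run`.
#' @param dir output directory (created if needed).
#' @param stem file stem; default `participant_condition`.
#' @param include_truth write planted contacts/feet into the sidecar.
#' @return invisibly, the CSV path.
#' @export
write_run <- function(run, dir, stem = NULL, include_truth = FALSE) {
  stopifnot(inherits(run, "raw_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- stem %||% paste(run$participant, run$condition, sep = "_")
  csv <- file.path(dir, paste0(stem, ".csv"))
  n <- nrow(run$samples)
  readr::write_csv(
    tibble::tibble(
      time_s = (seq_len(n) - 1) / run$fs_hz,
      ax = run$samples[, 1], ay = run$samples[, 2], az = run$samples[, 3]
    ),
    csv
  )
  side <- list(
    participant = run$participant, condition = run$condition,
    fs_hz = run$fs_hz, segments = run$segments, speed_mps = run$speed_mps,
    units = "m/s2"
  )
  if (include_truth && !is.null(run$truth)) {
    side$truth <- list(
      contacts = run$truth$contacts, feet = run$truth$feet,
      rotation = run$truth$rotation
    )
  }
  jsonlite::write_json(side, file.path(dir, paste0(stem, ".json")),
    auto_unbox = TRUE, digits = NA
  )
  invisible(csv)
}

#' Read one run from disk
#'
#' @param csv_path path to the run CSV; the sidecar JSON is expected next to
#'   it with the same stem.
#' @return a `raw_run`.
#' @export
read_run <- function(csv_path) {
  if (!file.exists(csv_path)) {
    abort(sprintf("run file not found: %s", csv_path), class = "gaitenv_missing_file")
  }
  json_path <- sub("\\.csv$", ".json", csv_path)
  if (!file.exists(json_path)) {
    abort(sprintf("sidecar not found: %s", json_path), class = "gaitenv_missing_file")
  }
  df <- tryCatch(
    readr::read_csv(csv_path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(sprintf("malformed CSV: %s", csv_path),
      class = "gaitenv_malformed")
  )
  if (!identical(names(df), c("time_s", "ax", "ay", "az"))) {
    abort(sprintf("unexpected columns in %s (need time_s, ax, ay, az)", csv_path),
      class = "gaitenv_malformed"
    )
  }
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  segments <- side$segments
  if (is.matrix(segments)) segments <- asplit(segments, 1)
  segments <- lapply(segments, as.integer)
  validate_segments(segments, nrow(df))
  samples <- cbind(ax = df$ax, ay = df$ay, az = df$az)
  assert_that(nrow(samples) >= 2 * side$fs_hz, "run shorter than 2 s")
  truth <- side$truth
  if (!is.null(truth)) {
    truth$contacts <- as.integer(truth$contacts)
    if (!is.null(truth$rotation)) truth$rotation <- matrix(unlist(truth$rotation), 3, 3)
  }
  structure(
    list(
      samples = samples, fs_hz = side$fs_hz, segments = segments,
      condition = side$condition, participant = side$participant,
      speed_mps = side$speed_mps, truth = truth
    ),
    class = "raw_run"
  )
}

#' Write a cohort to disk
#'
#' Writes every run (CSV + JSON sidecar) plus `manifest.csv` (participant,
#' protocol, condition, role, file, speed, demographics) and `design.json`.
#'
#' @param dataset a `gait_dataset`.
#' @param dir output directory.
#' @param include_truth forwarded to [write_run()].
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(dataset, dir, include_truth = FALSE) {
  stopifnot(inherits(dataset, "gait_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(dataset$runs, function(run) {
    write_run(run, file.path(dir, "runs"), include_truth = include_truth)
  }, character(1))
  manifest <- dataset$manifest |>
    dplyr::mutate(file = file.path("runs", basename(files)))
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  jsonlite::write_json(unclass(dataset$design), file.path(dir, "design.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(file.path(dir, "manifest.csv"))
}

#' Load a cohort from a manifest
#'
#' Reads `manifest.csv` and every referenced run, validating columns,
#' sampling-rate consistency and (participant, condition) uniqueness.
#'
#' @param manifest_path path to a cohort `manifest.csv`.
#' @return a `gait_dataset`.
#' @export
load_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    abort(sprintf("manifest not found: %s", manifest_path),
      class = "gaitenv_missing_file"
    )
  }
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE,
    progress = FALSE)
  dup <- manifest |>
    dplyr::count(.data$participant, .data$condition) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "duplicate (participant, condition) entries: %s",
      paste(dup$participant, dup$condition, sep = "/", collapse = ", ")
    ), class = "gaitenv_duplicate")
  }
  base <- dirname(manifest_path)
  runs <- purrr::map(manifest$file, function(f) read_run(file.path(base, f)))
  fs <- unique(vapply(runs, function(r) r$fs_hz, numeric(1)))
  assert_that(length(fs) == 1, "inconsistent sampling rates across runs")
  train_p <- unique(manifest$participant[manifest$role == "training"])
  test_p <- unique(manifest$participant[manifest$role == "testing"])
  assert_that(!any(train_p %in% test_p),
    "testing participants must be disjoint from training participants")
  design_path <- file.path(base, "design.json")
  design <- if (file.exists(design_path)) {
    structure(jsonlite::read_json(design_path, simplifyVector = TRUE),
      class = "cohort_design")
  } else {
    NULL
  }
  structure(
    list(runs = runs, manifest = manifest, design = design),
    class = "gait_dataset"
  )
}
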