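#' Read and write sensor stream files
#'
#' Streams are plain delimited text with a fixed header and SI units:
#' IMU files carry `t,ax,ay,az,gx,gy,gz,mx,my,mz` (seconds, m/s^2, rad/s,
#' consistent magnetometer units), EMG files `t,emg_mV`, and angle traces
#' `t,roll_deg`. Readers validate the header, require finite numeric values
#' (malformed rows are reported with their line numbers) and return a
#' time-sorted tibble, warning when rows had to be reordered.
#'
#' @param path File path.
#' @return A tibble with the columns above.
#' @name stream_io
NULL

stream_headers <- list(
  imu = c("t", "ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz"),
  emg = c("t", "emg_mV"),
  angle = c("t", "roll_deg")
)

read_stream <- function(path, kind) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "trunkdx_format_error")
  }
  expected <- stream_headers[[kind]]
  df <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_double()),
    show_col_types = FALSE, progress = FALSE
  ))
  if (!identical(names(df), expected)) {
    abort(
      paste0(
        "Unexpected header in ", path, ": got `", paste(names(df), collapse = ","),
        "`, expected `", paste(expected, collapse = ","), "`."
      ),
      class = "trunkdx_format_error"
    )
  }
  probs <- readr::problems(df)
  bad <- which(!stats::complete.cases(df) | !apply(
    vapply(df, is.finite, logical(nrow(df))), 1, all
  ))
  if (nrow(probs) > 0 || length(bad) > 0) {
    lines <- sort(unique(c(probs$row, bad)) + 1) # +1 for the header line
    abort(
      paste0("Malformed rows in ", path, " at line(s): ", paste(lines, collapse = ", ")),
      class = "trunkdx_format_error"
    )
  }
  if (nrow(df) == 0) {
    abort(paste0("Empty stream: ", path), class = "trunkdx_empty_input")
  }
  if (is.unsorted(df$t)) {
    warn(paste0("Rows in ", path, " were not time-ordered; sorting by t."))
    df <- df[order(df$t), , drop = FALSE]
  }
  tibble::as_tibble(df)
}

#' @rdname stream_io
#' @export
read_imu_stream <- function(path) read_stream(path, "imu")

#' @rdname stream_io
#' @export
read_emg_stream <- function(path) read_stream(path, "emg")

#' @rdname stream_io
#' @export
read_angle_stream <- function(path) read_stream(path, "angle")

#' @rdname stream_io
#' @param data Tibble with the matching columns.
#' @export
write_imu_stream <- function(data, path) {
  readr::write_csv(data[stream_headers$imu], path)
  invisible(path)
}

#' @rdname stream_io
#' @export
write_emg_stream <- function(data, path) {
  readr::write_csv(data[stream_headers$emg], path)
  invisible(path)
}

#' @rdname stream_io
#' @export
write_angle_stream <- function(data, path) {
  readr::write_csv(data[stream_headers$angle], path)
  invisible(path)
}

#' Read paired duration measurements
#'
#' Delimited text with columns `subject,method_a,method_b` (durations in
#' seconds) and optionally a leading `test` column for multi-test files.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_paired_measurements <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "trunkdx_format_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject", "method_a", "method_b")
  if (!all(need %in% names(df))) {
    abort("Paired file needs columns subject, method_a, method_b.",
      class = "trunkdx_format_error"
    )
  }
  tibble::as_tibble(df)
}

#' Packaged method-comparison durations
#'
#' The packaged case study: ten volunteers each performed the four
#' endurance tests (STEET, TCSET, and both side bridge sides) twice — once
#' timed by an expert with a stopwatch (`method_a`, the traditional method)
#' and once by the instrumented system (`method_b`). Durations are in
#' seconds. This is the substrate of the reliability analysis in
#' [reliability_table()].
#'
#' @return A tibble with columns `test`, `subject`, `method_a`, `method_b`
#'   (40 rows).
#' @examples
#' case_study_durations() |> reliability_table()
#' @export
case_study_durations <- function() {
  path <- system.file("extdata", "case_study_durations.csv", package = "trunkdx")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  tibble::as_tibble(df)
}

#' Run the full assessment pipeline
#'
#' Composes the modules end to end for one session: read each test's IMU
#' (or precomputed angle) stream, estimate the trunk angle, run the test
#' state machine, summarize EMG fatigue, categorize, and compute endurance
#' ratios where both tests of a ratio are present (flexor/extensor from
#' TCSET/STEET totals, side ratio from the two SBET sides). A missing EMG
#' file degrades gracefully: durations and categories are still produced
#' and fatigue metrics are absent.
#'
#' @param config A list, or path to a YAML/JSON file, with fields
#'   `patient_id`, optional `date`, and `tests`: a list of entries each
#'   holding `protocol`, `start_times`, optional `stop_times`, and either
#'   `angle_path` or `imu_path` (plus optional `emg_path`, `beta`).
#' @return A list of class `session_record`: `patient_id`, `date`, `tests`
#'   (one-row summary per test, tibble), `attempts` (tibble), `ratios`
#'   (tibble).
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$patient_id) || is.null(cfg$tests) || length(cfg$tests) == 0) {
    abort("[config] needs `patient_id` and at least one `tests` entry.",
      class = "trunkdx_format_error"
    )
  }
  results <- purrr::map(cfg$tests, function(tc) {
    stage <- paste0("test ", tc$protocol %||% "?")
    withCallingHandlers(
      {
        if (!is.null(tc$angle_path)) {
          angle <- read_angle_stream(tc$angle_path)
        } else if (!is.null(tc$imu_path)) {
          imu <- read_imu_stream(tc$imu_path)
          fc <- filter_config(beta = tc$beta %||% 0.1)
          angle <- trunk_angle_stream(imu, cfg = fc)
        } else {
          abort("Test entry needs `angle_path` or `imu_path`.",
            class = "trunkdx_format_error"
          )
        }
        emg <- if (!is.null(tc$emg_path) && file.exists(tc$emg_path)) {
          read_emg_stream(tc$emg_path)
        } else {
          NULL
        }
        run_test(
          angle, tc$protocol,
          start_times = as.numeric(tc$start_times),
          stop_times = if (is.null(tc$stop_times)) NULL else as.numeric(tc$stop_times),
          emg_stream = emg
        )
      },
      error = function(e) {
        e$message <- paste0("[", stage, "] ", conditionMessage(e))
        stop(e)
      }
    )
  })
  tests <- dplyr::bind_rows(purrr::map(results, glance))
  attempts <- dplyr::bind_rows(purrr::map(results, tidy))
  structure(
    list(
      patient_id = as.character(cfg$patient_id),
      date = as.character(cfg$date %||% "1970-01-01"),
      tests = tests,
      attempts = attempts,
      ratios = session_ratios(tests)
    ),
    class = "session_record"
  )
}

session_ratios <- function(tests) {
  total_of <- function(p) {
    i <- which(tests$protocol == p)
    if (length(i) == 1) tests$total_duration[i] else NA_real_
  }
  out <- tibble::tibble(
    ratio = character(), value = double(), imbalanced = logical()
  )
  steet <- total_of("STEET")
  tcset <- total_of("TCSET")
  if (is.finite(steet) && is.finite(tcset) && steet > 0) {
    out <- dplyr::add_row(out,
      ratio = "flexor_extensor",
      value = flexor_extensor_ratio(tcset, steet), imbalanced = NA
    )
  }
  r <- total_of("SBET_RIGHT")
  l <- total_of("SBET_LEFT")
  if (is.finite(r) && is.finite(l) && l > 0) {
    sr <- side_ratio(r, l)
    out <- dplyr::add_row(out,
      ratio = "right_left", value = sr$ratio, imbalanced = sr$imbalanced
    )
  }
  out
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(paste0("Config file not found: ", config), class = "trunkdx_format_error")
    }
    if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  } else if (is.list(config)) {
    config
  } else {
    abort("config must be a list or a YAML/JSON path.", class = "trunkdx_format_error")
  }
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session> patient %s on %s: %d test(s)\n", x$patient_id, x$date, nrow(x$tests)))
  print(x$tests)
  if (nrow(x$ratios) > 0) print(x$ratios)
  invisible(x)
}

#' Session persistence
#'
#' Sessions are stored as one JSON file each inside a store directory,
#' named `<patient>_<date>_<k>.json`; angles are serialized in degrees,
#' times in seconds and EMG in mV. `write_session()`/`read_session()`
#' round-trip a [run_pipeline()] record losslessly; `save_session()` picks
#' the next free filename in the store.
#'
#' @param record A `session_record`.
#' @param path Target JSON path.
#' @return `read_session()` returns the `session_record`; the writers
#'   return the path invisibly.
#' @name session_store
#' @export
write_session <- function(record, path) {
  stopifnot(inherits(record, "session_record"))
  payload <- list(
    patient_id = record$patient_id,
    date = record$date,
    tests = record$tests,
    attempts = record$attempts,
    ratios = record$ratios
  )
  jsonlite::write_json(payload, path,
    dataframe = "columns", auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' @rdname session_store
#' @export
read_session <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Session file not found: ", path), class = "trunkdx_format_error")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_cols <- function(x, proto) {
    df <- tibble::as_tibble(as.data.frame(x, stringsAsFactors = FALSE))
    for (nm in names(proto)) {
      if (nm %in% names(df)) {
        df[[nm]] <- if (is.numeric(proto[[nm]])) as.numeric(df[[nm]]) else df[[nm]]
      }
    }
    df
  }
  structure(
    list(
      patient_id = as.character(raw$patient_id),
      date = as.character(raw$date),
      tests = as_cols(raw$tests, list(
        n_attempts = 1, total_duration = 1, rms = 1, arv = 1, mvc = 1
      )),
      attempts = as_cols(raw$attempts, list(
        attempt = 1, reference_angle = 1, duration = 1
      )),
      ratios = if (length(raw$ratios) == 0 || (is.list(raw$ratios) && length(raw$ratios$ratio) == 0)) {
        tibble::tibble(ratio = character(), value = double(), imbalanced = logical())
      } else {
        as_cols(raw$ratios, list(value = 1))
      }
    ),
    class = "session_record"
  )
}

#' @rdname session_store
#' @param store Store directory (created if missing).
#' @export
save_session <- function(record, store) {
  stopifnot(inherits(record, "session_record"))
  if (!dir.exists(store)) dir.create(store, recursive = TRUE)
  base <- paste0(record$patient_id, "_", record$date)
  k <- 1
  repeat {
    path <- file.path(store, paste0(base, "_", k, ".json"))
    if (!file.exists(path)) break
    k <- k + 1
  }
  write_session(record, path)
}

#' Patient history report
#'
#' Chronologically ordered per-test series of durations, categories and
#' fatigue metrics over all stored sessions of one patient.
#'
#' @param store Store directory of session JSON files.
#' @param patient_id Patient identifier.
#' @return A tibble with one row per (session, test), sorted by date.
#' @seealso [plot_history()]
#' @export
history_report <- function(store, patient_id) {
  files <- list.files(store, pattern = "\\.json$", full.names = TRUE)
  sessions <- purrr::map(files, read_session)
  sessions <- purrr::keep(sessions, \(s) identical(s$patient_id, as.character(patient_id)))
  if (length(sessions) == 0) {
    abort(paste0("No stored sessions for patient '", patient_id, "'."),
      class = "trunkdx_not_found"
    )
  }
  purrr::map(sessions, function(s) {
    dplyr::mutate(s$tests, patient_id = s$patient_id, date = s$date, .before = 1)
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$date, .data$protocol)
}

#' Plot a patient's endurance history
#'
#' Bar chart of total duration per test across stored sessions.
#'
#' @param history Tibble from [history_report()].
#' @return A ggplot object.
#' @export
plot_history <- function(history) {
  ggplot2::ggplot(
    history,
    ggplot2::aes(x = .data$date, y = .data$total_duration, fill = .data$category)
  ) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~protocol) +
    ggplot2::labs(x = "Session date", y = "Total duration (s)") +
    ggplot2::theme_minimal()
}

#' Plot a trunk-angle trace
#'
#' Angle trace with optional reference angle and droop-tolerance band.
#'
#' @param angle_stream Tibble with `t`, `roll_deg`.
#' @param reference Optional reference angle (degrees).
#' @param tolerance Optional droop tolerance (degrees) drawn about the
#'   reference.
#' @return A ggplot object.
#' @export
plot_trunk_angle <- function(angle_stream, reference = NULL, tolerance = NULL) {
  check_angle_frame(angle_stream)
  p <- ggplot2::ggplot(angle_stream, ggplot2::aes(x = .data$t, y = .data$roll_deg)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Trunk angle (deg)") +
    ggplot2::theme_minimal()
  if (!is.null(reference)) {
    p <- p + ggplot2::geom_hline(yintercept = reference, colour = "blue")
    if (!is.null(tolerance)) {
      p <- p + ggplot2::geom_hline(
        yintercept = reference + c(-tolerance, tolerance),
        colour = "red", linetype = "dashed"
      )
    }
  }
  p
}
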