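#' Endurance test protocols
#'
#' The three supported isometric trunk endurance tests:
#' * `STEET` — static trunk extensor endurance (Sorensen) test: prone
#'   horizontal hold beyond the bench edge; up to two attempts, scored on
#'   their sum; droop tolerance 10 degrees (coronal plane).
#' * `TCSET` — trunk curl static endurance test: 60-degree curled hold;
#'   one attempt, tolerance 30 degrees (coronal plane).
#' * `SBET_RIGHT` / `SBET_LEFT` — side bridge endurance test: lateral hold on
#'   elbow and feet; one attempt per side, tolerance 10 degrees (sagittal
#'   plane).
#'
#' Every attempt is capped at 240 s.
#'
#' @param name One of `"STEET"`, `"TCSET"`, `"SBET_RIGHT"`, `"SBET_LEFT"`.
#' @return A list of class `test_protocol` with fields `name`,
#'   `angle_tolerance` (degrees), `max_duration` (s), `attempts`, `plane`.
#' @examples
#' test_protocol("STEET")
#' @export
test_protocol <- function(name = c("STEET", "TCSET", "SBET_RIGHT", "SBET_LEFT")) {
  name <- match.arg(name)
  structure(
    list(
      name = name,
      angle_tolerance = if (name == "TCSET") 30 else 10,
      max_duration = 240,
      attempts = if (name == "STEET") 2L else 1L,
      plane = if (name %in% c("STEET", "TCSET")) "coronal" else "sagittal"
    ),
    class = "test_protocol"
  )
}

as_protocol <- function(protocol) {
  if (inherits(protocol, "test_protocol")) protocol else test_protocol(protocol)
}

#' Reference angle at the start event
#'
#' The trunk angle at the moment the operator starts the test is saved as the
#' reference against which droop is measured. The value is taken at the
#' sample at, or nearest preceding, `start_time`.
#'
#' @param angle_stream Data frame with columns `t` (s) and `roll_deg`.
#' @param start_time Start event time (s); must lie within the stream span.
#' @return Reference angle in degrees.
#' @export
capture_reference <- function(angle_stream, start_time) {
  check_angle_frame(angle_stream)
  t <- angle_stream$t
  if (!is.finite(start_time) || start_time < t[1] || start_time > t[length(t)]) {
    abort("Start event lies outside the angle stream span.",
      class = "trunkdx_out_of_range"
    )
  }
  i <- findInterval(start_time, t)
  angle_stream$roll_deg[i]
}

#' Termination decision for one sample
#'
#' A test attempt terminates when the absolute angular deviation from the
#' reference strictly exceeds the protocol tolerance, when the elapsed time
#' strictly exceeds 240 s, or when the operator stops it manually. When
#' several criteria fire on the same sample the reported reason follows the
#' priority manual > angle > time cap. Deviation is computed wrap-aware
#' (shorter arc), although trunk angles stay well within +/-90 degrees of
#' the reference in practice.
#'
#' @param protocol A [test_protocol()] or its name.
#' @param reference,current Reference and current trunk angles, degrees.
#' @param elapsed Elapsed time since the start event, seconds (>= 0).
#' @param manual_stop Has the operator pressed stop?
#' @return A list with `terminate` (logical) and `reason` (one of
#'   `"manual_stop"`, `"angle_exceeded"`, `"max_duration"`, or `NA` while the
#'   attempt continues).
#' @examples
#' check_termination("STEET", reference = 5, current = 16, elapsed = 30)
#' check_termination("TCSET", reference = 60, current = 31, elapsed = 100)
#' @export
check_termination <- function(protocol, reference, current, elapsed, manual_stop = FALSE) {
  p <- as_protocol(protocol)
  stopifnot(is.finite(reference), is.finite(current), is.finite(elapsed), elapsed >= 0)
  dev <- angle_deviation(current, reference)
  if (isTRUE(manual_stop)) {
    list(terminate = TRUE, reason = "manual_stop")
  } else if (dev > p$angle_tolerance) {
    list(terminate = TRUE, reason = "angle_exceeded")
  } else if (elapsed > p$max_duration) {
    list(terminate = TRUE, reason = "max_duration")
  } else {
    list(terminate = FALSE, reason = NA_character_)
  }
}

angle_deviation <- function(current, reference) {
  d <- abs(current - reference) %% 360
  pmin(d, 360 - d)
}

#' Run a single test attempt over an angle stream
#'
#' Captures the reference angle at `start_time`, then scans subsequent
#' samples until a termination criterion fires. The reported duration is the
#' stream time of the terminating sample minus `start_time` (capped at the
#' 240 s maximum), so results are reproducible offline and independent of
#' wall-clock time.
#'
#' @inheritParams capture_reference
#' @param protocol A [test_protocol()] or its name.
#' @param stop_time Optional operator stop event (s); the first sample at or
#'   after it terminates the attempt with reason `"manual_stop"`.
#' @return A one-row tibble: `reference_angle`, `duration`,
#'   `termination_reason`.
#' @section Errors: if the stream ends before any criterion fires, a
#'   `trunkdx_truncated_stream` error is raised carrying the partial
#'   duration in its `partial_duration` field.
#' @export
run_attempt <- function(angle_stream, protocol, start_time, stop_time = NULL) {
  p <- as_protocol(protocol)
  reference <- capture_reference(angle_stream, start_time)
  t <- angle_stream$t
  roll <- angle_stream$roll_deg
  idx <- which(t > start_time)
  for (i in idx) {
    elapsed <- t[i] - start_time
    manual <- !is.null(stop_time) && t[i] >= stop_time
    res <- check_termination(p, reference, roll[i], elapsed, manual_stop = manual)
    if (res$terminate) {
      return(tibble::tibble(
        reference_angle = reference,
        duration = min(elapsed, p$max_duration),
        termination_reason = res$reason
      ))
    }
  }
  partial <- if (length(idx) > 0) t[max(idx)] - start_time else 0
  abort(
    "Angle stream ended before any termination criterion fired.",
    class = "trunkdx_truncated_stream",
    partial_duration = min(partial, p$max_duration)
  )
}

#' Run a full endurance test
#'
#' Runs one attempt per start event (the Sorensen test allows up to two; the
#' second chance is optional), sums their durations into the test total,
#' summarizes muscle fatigue over the union of the attempt windows when an
#' EMG stream is supplied, and assigns the normative category.
#'
#' @inheritParams run_attempt
#' @param start_times Numeric vector of start events, one per attempt
#'   (length up to `protocol$attempts`).
#' @param stop_times Optional vector of manual stop events aligned with
#'   `start_times` (use `NA` for attempts without one).
#' @param emg_stream Optional EMG data frame (`t`, `emg_mV`); when missing,
#'   the fatigue summary is `NULL` and scoring proceeds on durations alone.
#' @param bins Category bins, see [category_bins()].
#' @return An object of class `endurance_test`: a list with `protocol`,
#'   `attempts` (tibble), `total_duration`, `fatigue` (one-row tibble or
#'   `NULL`) and `category`. Use [tidy()] for per-attempt rows and
#'   [glance()] for the one-row summary.
#' @examples
#' stream <- tibble::tibble(t = seq(0, 120, by = 1 / 51.2), roll_deg = 0)
#' stream$roll_deg[stream$t > 84] <- (stream$t[stream$t > 84] - 84) * 20
#' run_test(stream, "SBET_RIGHT", start_times = 0)
#' @export
run_test <- function(angle_stream, protocol, start_times, stop_times = NULL,
                     emg_stream = NULL, bins = category_bins()) {
  p <- as_protocol(protocol)
  stopifnot(length(start_times) >= 1)
  if (length(start_times) > p$attempts) {
    abort(
      paste0(p$name, " allows at most ", p$attempts, " attempt(s)."),
      class = "trunkdx_out_of_range"
    )
  }
  if (!is.null(stop_times) && length(stop_times) != length(start_times)) {
    abort("stop_times must align with start_times.", class = "trunkdx_out_of_range")
  }
  attempts <- purrr::imap(start_times, function(s, i) {
    st <- if (is.null(stop_times) || is.na(stop_times[i])) NULL else stop_times[i]
    run_attempt(angle_stream, p, s, stop_time = st)
  })
  attempts <- dplyr::bind_rows(attempts, .id = "attempt")
  attempts$attempt <- as.integer(attempts$attempt)
  total <- sum(attempts$duration)

  fatigue <- NULL
  if (!is.null(emg_stream)) {
    check_emg_frame(emg_stream)
    keep <- rep(FALSE, nrow(emg_stream))
    for (i in seq_len(nrow(attempts))) {
      keep <- keep | (emg_stream$t >= start_times[i] &
        emg_stream$t <= start_times[i] + attempts$duration[i])
    }
    if (any(keep)) fatigue <- emg_summary(emg_stream[keep, , drop = FALSE])
  }

  structure(
    list(
      protocol = p,
      attempts = attempts,
      total_duration = total,
      fatigue = fatigue,
      category = categorize(p$name, min(total, p$max_duration), bins = bins)
    ),
    class = "endurance_test"
  )
}

#' @export
print.endurance_test <- function(x, ...) {
  cat(sprintf(
    "<%s> total %.1f s (%d attempt%s) - category: %s\n",
    x$protocol$name, x$total_duration, nrow(x$attempts),
    if (nrow(x$attempts) > 1) "s" else "", x$category
  ))
  if (!is.null(x$fatigue)) {
    cat(sprintf(
      "  EMG: RMS %.3f / ARV %.3f / MVC %.3f mV\n",
      x$fatigue$rms, x$fatigue$arv, x$fatigue$mvc
    ))
  }
  invisible(x)
}

#' @rdname run_test
#' @param x An `endurance_test` object.
#' @param ... Unused.
#' @export
tidy.endurance_test <- function(x, ...) {
  dplyr::mutate(x$attempts, protocol = x$protocol$name, .before = 1)
}

#' @rdname run_test
#' @export
glance.endurance_test <- function(x, ...) {
  out <- tibble::tibble(
    protocol = x$protocol$name,
    n_attempts = nrow(x$attempts),
    total_duration = x$total_duration,
    category = x$category,
    rms = NA_real_, arv = NA_real_, mvc = NA_real_
  )
  if (!is.null(x$fatigue)) {
    out$rms <- x$fatigue$rms
    out$arv <- x$fatigue$arv
    out$mvc <- x$fatigue$mvc
  }
  out
}

check_angle_frame <- function(data) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort("Angle stream must be a data frame with at least one sample.",
      class = "trunkdx_empty_input"
    )
  }
  if (!all(c("t", "roll_deg") %in% names(data))) {
    abort("Angle stream needs columns `t` and `roll_deg`.", class = "trunkdx_format_error")
  }
  invisible(data)
}
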