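#' EMG fatigue indices
#'
#' Amplitude-domain indices of muscle fatigue computed over an epoch of
#' surface-EMG samples (mV): the root mean square (`emg_rms`), the average
#' rectified value (`emg_arv`) and the maximum contraction amplitude
#' (`emg_mvc`). By the power-mean inequality `arv <= rms <= mvc` whenever
#' `mvc` is taken over the rectified signal, which is the default: a strongly
#' negative-going burst then counts toward the maximum. Set
#' `rectify = FALSE` for the plain maximum of the raw trace.
#'
#' @param x Numeric vector of EMG samples in mV; must be non-empty and finite.
#' @param rectify For `emg_mvc()`: take the maximum of `abs(x)` (default)
#'   rather than of `x` itself.
#' @return A single numeric value in mV.
#' @examples
#' emg_rms(c(3, -4)) # sqrt((9 + 16) / 2)
#' emg_arv(c(3, -4)) # 3.5
#' emg_mvc(c(3, -4)) # 4 (rectified)
#' @name emg_indices
NULL

check_epoch <- function(x) {
  if (length(x) == 0) {
    abort("EMG epoch must contain at least one sample.", class = "trunkdx_empty_input")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort("EMG epoch contains non-finite samples.", class = "trunkdx_invalid_sample")
  }
  invisible(x)
}

#' @rdname emg_indices
#' @export
emg_rms <- function(x) {
  check_epoch(x)
  sqrt(mean(x^2))
}

#' @rdname emg_indices
#' @export
emg_arv <- function(x) {
  check_epoch(x)
  mean(abs(x))
}

#' @rdname emg_indices
#' @export
emg_mvc <- function(x, rectify = TRUE) {
  check_epoch(x)
  if (rectify) max(abs(x)) else max(x)
}

#' Fatigue metrics over consecutive epochs
#'
#' Splits an EMG stream into consecutive non-overlapping epochs of
#' `epoch_len` seconds and computes RMS, ARV and MVC per epoch. A trailing
#' partial epoch is kept only when it is at least half full, so a 1.4 s
#' stream under 1 s epochs yields a single epoch. An optional mean
#' subtraction (whole-stream mean) can remove DC offset before computing the
#' indices; it is off by default.
#'
#' @param data Data frame with columns `t` (s) and `emg_mV`.
#' @param epoch_len Epoch length in seconds (> 0). Default 1.
#' @param sample_rate Sampling rate in Hz; if `NULL`, inferred from the
#'   median timestamp spacing.
#' @param demean Subtract the whole-stream mean first? Default `FALSE`.
#' @param rectify Passed to [emg_mvc()].
#' @return A tibble with one row per epoch: `t_start`, `n`, `rms`, `arv`,
#'   `mvc`.
#' @seealso [emg_summary()] for whole-test values.
#' @export
epoch_metrics <- function(data, epoch_len = 1, sample_rate = NULL,
                          demean = FALSE, rectify = TRUE) {
  check_emg_frame(data)
  stopifnot(is.numeric(epoch_len), length(epoch_len) == 1, epoch_len > 0)
  if (is.null(sample_rate)) sample_rate <- infer_rate(data$t)
  x <- data$emg_mV
  if (demean) x <- x - mean(x)
  n_epoch <- max(1L, as.integer(round(epoch_len * sample_rate)))
  starts <- seq(1L, length(x), by = n_epoch)
  rows <- purrr::map(starts, function(i) {
    idx <- i:min(i + n_epoch - 1L, length(x))
    if (length(idx) < n_epoch / 2) {
      return(NULL)
    }
    seg <- x[idx]
    tibble::tibble(
      t_start = data$t[i], n = length(idx),
      rms = emg_rms(seg), arv = emg_arv(seg), mvc = emg_mvc(seg, rectify = rectify)
    )
  })
  empty <- tibble::tibble(
    t_start = double(), n = integer(),
    rms = double(), arv = double(), mvc = double()
  )
  dplyr::bind_rows(empty, rows)
}

#' Whole-test EMG summary
#'
#' Single RMS/ARV/MVC values over an entire test recording, as shown on a
#' per-test results summary.
#'
#' @inheritParams epoch_metrics
#' @return A one-row tibble: `n`, `duration_s`, `rms`, `arv`, `mvc`.
#' @export
emg_summary <- function(data, demean = FALSE, rectify = TRUE) {
  check_emg_frame(data)
  x <- data$emg_mV
  if (demean) x <- x - mean(x)
  tibble::tibble(
    n = length(x),
    duration_s = max(data$t) - min(data$t),
    rms = emg_rms(x), arv = emg_arv(x), mvc = emg_mvc(x, rectify = rectify)
  )
}

check_emg_frame <- function(data) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort("EMG stream must be a data frame with at least one sample.",
      class = "trunkdx_empty_input"
    )
  }
  if (!all(c("t", "emg_mV") %in% names(data))) {
    abort("EMG stream needs columns `t` and `emg_mV`.", class = "trunkdx_format_error")
  }
  invisible(data)
}

infer_rate <- function(t) {
  if (length(t) < 2) {
    return(51.2)
  }
  dt <- median(diff(t))
  if (!is.finite(dt) || dt <= 0) 51.2 else 1 / dt
}
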