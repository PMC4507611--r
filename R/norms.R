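#' Normative endurance references
#'
#' Published reference values for healthy young adults: the Sorensen
#' (STEET) average hold spans 62-131 s; the trunk curl (TCSET) mean is
#' 134 s; the side bridge (SBET) mean is 84 s with SD 24.5 s. The normal
#' flexor-to-extensor endurance ratio is 0.77 and the right-to-left side
#' bridge ratio 0.96; a side-to-side deviation greater than 0.05 suggests
#' unbalanced endurance.
#'
#' @return A list of class `reference_norms`.
#' @export
reference_norms <- function() {
  structure(
    list(
      steet_range = c(62, 131),
      tcset_mean = 134,
      sbet_mean = 84,
      sbet_sd = 24.5,
      flexor_extensor_ref = 0.77,
      right_left_ref = 0.96,
      side_imbalance_threshold = 0.05
    ),
    class = "reference_norms"
  )
}

#' Category bins per test
#'
#' Duration bins mapping a total test duration onto the labels "bad",
#' "good" and "perfect": STEET 0-61 / 62-131 / 132-240 s; SBET 0-60 /
#' 61-108 / 109-240 s; TCSET has two labels only, 0-131 ("bad") and
#' 132-240 ("good"). Bins are right-open at the printed integer edges so
#' integer durations map exactly as printed while every continuous duration
#' in \[0, 240\] receives exactly one label. Clinics can override the table,
#' e.g. for stratified norms.
#'
#' @return A tibble with columns `test`, `label`, `lower`, `upper`
#'   (duration bounds in seconds; a duration `d` falls in a bin when
#'   `lower <= d < upper`, except the top bin which includes 240).
#' @export
category_bins <- function() {
  tibble::tribble(
    ~test, ~label, ~lower, ~upper,
    "STEET", "bad", 0, 62,
    "STEET", "good", 62, 132,
    "STEET", "perfect", 132, 240,
    "TCSET", "bad", 0, 132,
    "TCSET", "good", 132, 240,
    "SBET", "bad", 0, 61,
    "SBET", "good", 61, 109,
    "SBET", "perfect", 109, 240
  )
}

#' Categorize a test duration
#'
#' @param test Test name (`"STEET"`, `"TCSET"`, `"SBET"`, `"SBET_RIGHT"` or
#'   `"SBET_LEFT"` — both side bridge sides share the SBET bins).
#' @param duration Total test duration(s) in seconds, within \[0, 240\].
#' @param bins Bin table, see [category_bins()].
#' @return A character vector of labels, one per duration.
#' @examples
#' categorize("STEET", 100) # "good"
#' categorize("SBET", 109) # "perfect"
#' @export
categorize <- function(test, duration, bins = category_bins()) {
  stopifnot(is.character(test), length(test) == 1)
  test <- if (startsWith(test, "SBET")) "SBET" else test
  b <- bins[bins$test == test, , drop = FALSE]
  if (nrow(b) == 0) {
    abort(paste0("No category bins for test '", test, "'."), class = "trunkdx_out_of_range")
  }
  if (any(!is.finite(duration)) || any(duration < 0) || any(duration > 240)) {
    abort("Duration must lie within [0, 240] s.", class = "trunkdx_out_of_range")
  }
  vapply(duration, function(d) {
    hit <- which(d >= b$lower & (d < b$upper | (d <= b$upper & b$upper == max(b$upper))))
    b$label[hit[1]]
  }, character(1))
}

#' Flexor-to-extensor endurance ratio
#'
#' Ratio of trunk flexor (TCSET) to extensor (STEET) endurance; the normal
#' reference is 0.77, and a reduced ratio helps discriminate low back pain
#' patients from healthy individuals.
#'
#' @param tcset_s,steet_s Test durations in seconds; `steet_s` must be > 0.
#' @return The dimensionless ratio `tcset_s / steet_s`.
#' @examples
#' flexor_extensor_ratio(77, 100)
#' @export
flexor_extensor_ratio <- function(tcset_s, steet_s) {
  stopifnot(is.finite(tcset_s), is.finite(steet_s))
  if (steet_s <= 0) {
    abort("Extensor (STEET) duration must be positive.", class = "trunkdx_undefined_ratio")
  }
  tcset_s / steet_s
}

#' Side-to-side endurance ratio
#'
#' Right-to-left side bridge endurance ratio. The normal reference is 0.96;
#' under the default reading a deviation of the ratio from that reference
#' greater than `threshold` flags unbalanced lateral endurance. Set
#' `center = "unity"` to measure the deviation from 1 instead.
#'
#' @param right_s,left_s Side bridge durations in seconds; `left_s` > 0.
#' @param norms A [reference_norms()] list.
#' @param center Deviation reference: the published norm (0.96) or unity.
#' @return A one-row tibble: `ratio`, `imbalanced`.
#' @examples
#' side_ratio(48, 50)
#' @export
side_ratio <- function(right_s, left_s, norms = reference_norms(),
                       center = c("norm", "unity")) {
  center <- match.arg(center)
  stopifnot(is.finite(right_s), is.finite(left_s))
  if (left_s <= 0) {
    abort("Left-side duration must be positive.", class = "trunkdx_undefined_ratio")
  }
  ratio <- right_s / left_s
  ref <- if (center == "norm") norms$right_left_ref else 1
  tibble::tibble(
    ratio = ratio,
    imbalanced = abs(ratio - ref) > norms$side_imbalance_threshold
  )
}
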