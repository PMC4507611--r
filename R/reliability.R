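#' One-way random-effects intraclass correlation
#'
#' Inter-method reliability of paired measurements under the one-way random
#' model `x_ij = mu + b_i + e_ij` (subjects random, the two methods treated
#' as interchangeable raters). From the one-way ANOVA mean squares — between
#' subjects `MSB` and within subjects `MSW` — the single-measures form is
#' `(MSB - MSW) / (MSB + (k - 1) MSW)` and the average-measures form
#' `(MSB - MSW) / MSB` with `k = 2` raters. The average-measures form is the
#' default, reflecting agreement of the mean of the two methods.
#'
#' The confidence interval is the exact F-based construction: with
#' `F0 = MSB / MSW` on `(n - 1, n(k - 1))` degrees of freedom, the
#' average-measures bounds are `1 - Fq / F0` for the appropriate F quantiles;
#' single-measures bounds are the corresponding `(F - 1) / (F + k - 1)`
#' transforms.
#'
#' @param data Data frame with one row per subject and numeric columns
#'   `method_a` and `method_b` (override with `method_a =` / `method_b =`).
#' @param form `"average"` (default) or `"single"` measures.
#' @param conf_level Confidence level, default 0.95.
#' @param method_a,method_b Column names holding the two methods' values.
#' @return An object of class `icc_oneway` with the estimate, CI, mean
#'   squares and F statistic. Use [tidy()] / [glance()] for tibble output.
#' @examples
#' pm <- simulate_paired_study(20, sigma_between = 20, sigma_within = 6, seed = 1)
#' icc_oneway(pm)
#' @export
icc_oneway <- function(data, form = c("average", "single"), conf_level = 0.95,
                       method_a = "method_a", method_b = "method_b") {
  form <- match.arg(form)
  pm <- check_paired(data, method_a, method_b)
  n <- nrow(pm)
  k <- 2
  ms <- oneway_ms(pm$a, pm$b)
  if (ms$msb <= 0 && ms$msw <= 0) {
    abort("Measurements carry no variance; ICC is undefined.",
      class = "trunkdx_degenerate_data"
    )
  }
  est <- if (form == "average") {
    (ms$msb - ms$msw) / ms$msb
  } else {
    (ms$msb - ms$msw) / (ms$msb + (k - 1) * ms$msw)
  }
  df1 <- n - 1
  df2 <- n * (k - 1)
  alpha <- 1 - conf_level
  if (ms$msw == 0) {
    f0 <- Inf
    ci <- c(1, 1)
  } else {
    f0 <- ms$msb / ms$msw
    fl <- f0 / qf(1 - alpha / 2, df1, df2)
    fu <- f0 * qf(1 - alpha / 2, df2, df1)
    ci <- if (form == "average") {
      c(1 - 1 / fl, 1 - 1 / fu)
    } else {
      c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    }
  }
  structure(
    list(
      estimate = est, conf.low = ci[1], conf.high = ci[2],
      form = form, conf_level = conf_level,
      msb = ms$msb, msw = ms$msw, f0 = f0, df1 = df1, df2 = df2,
      n = n, k = k,
      p.value = if (is.finite(f0)) pf(f0, df1, df2, lower.tail = FALSE) else 0
    ),
    class = "icc_oneway"
  )
}

# One-way ANOVA mean squares for n subjects x 2 raters.
oneway_ms <- function(a, b) {
  n <- length(a)
  k <- 2
  subj_mean <- (a + b) / 2
  grand <- mean(c(a, b))
  msb <- k * sum((subj_mean - grand)^2) / (n - 1)
  msw <- sum((a - subj_mean)^2 + (b - subj_mean)^2) / (n * (k - 1))
  list(msb = msb, msw = msw)
}

#' @export
print.icc_oneway <- function(x, ...) {
  cat(sprintf(
    "One-way random ICC (%s measures, k = %d, n = %d): %.3f [%.3f, %.3f] (%.0f%% CI)\n",
    x$form, x$k, x$n, x$estimate, x$conf.low, x$conf.high, 100 * x$conf_level
  ))
  invisible(x)
}

#' @rdname icc_oneway
#' @param x An `icc_oneway` object.
#' @param ... Unused.
#' @export
tidy.icc_oneway <- function(x, ...) {
  tibble::tibble(
    term = paste0("icc_", x$form),
    estimate = x$estimate,
    conf.low = x$conf.low,
    conf.high = x$conf.high
  )
}

#' @rdname icc_oneway
#' @export
glance.icc_oneway <- function(x, ...) {
  tibble::tibble(
    msb = x$msb, msw = x$msw, statistic = x$f0,
    df1 = x$df1, df2 = x$df2, p.value = x$p.value,
    n = x$n, k = x$k, conf_level = x$conf_level
  )
}

#' Cronbach's alpha for two raters
#'
#' Internal-consistency reliability of the paired measurements treated as
#' `k = 2` items: `alpha = (k / (k - 1)) (1 - sum(item variances) /
#' var(item sums))`, with `n - 1` denominators.
#'
#' @inheritParams icc_oneway
#' @return A single numeric value.
#' @export
cronbach_alpha <- function(data, method_a = "method_a", method_b = "method_b") {
  pm <- check_paired(data, method_a, method_b)
  vs <- var(pm$a + pm$b)
  if (vs == 0) {
    abort("Sum of measurements carries no variance; alpha is undefined.",
      class = "trunkdx_degenerate_data"
    )
  }
  2 * (1 - (var(pm$a) + var(pm$b)) / vs)
}

#' Bland-Altman agreement analysis
#'
#' Differences between the two methods are summarized by their mean and the
#' limits of agreement `mean +/- 1.96 sd` (sample SD, `n - 1` denominator).
#' Differences are oriented as `method_a - method_b`; per-subject
#' `(average, difference)` pairs are retained for plotting via
#' [autoplot()].
#'
#' @inheritParams icc_oneway
#' @return An object of class `bland_altman`. [glance()] gives `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `n`; [tidy()] the per-subject pairs.
#' @export
bland_altman <- function(data, method_a = "method_a", method_b = "method_b") {
  pm <- check_paired(data, method_a, method_b)
  d <- pm$a - pm$b
  m <- mean(d)
  s <- sd(d)
  structure(
    list(
      mean_diff = m, sd_diff = s,
      loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
      n = nrow(pm),
      pairs = tibble::tibble(
        subject = pm$subject,
        average = (pm$a + pm$b) / 2,
        difference = d
      )
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): mean difference %.2f, limits of agreement [%.2f, %.2f]\n",
    x$n, x$mean_diff, x$loa_low, x$loa_high
  ))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @export
tidy.bland_altman <- function(x, ...) x$pairs

#' @rdname bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(
    mean_diff = x$mean_diff, sd_diff = x$sd_diff,
    loa_low = x$loa_low, loa_high = x$loa_high, n = x$n
  )
}

#' @rdname bland_altman
#' @param object A `bland_altman` object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$average, y = .data$difference)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_diff, colour = "blue") +
    ggplot2::geom_hline(
      yintercept = c(object$loa_low, object$loa_high),
      colour = "red", linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "Average of methods (s)", y = "Difference between methods (s)",
      title = "Bland-Altman agreement"
    ) +
    ggplot2::theme_minimal()
}

#' Reliability table across tests
#'
#' One row of agreement statistics per endurance test: average-measures
#' one-way ICC with its exact 95% CI, Cronbach's alpha, Bland-Altman mean
#' difference and limits of agreement, plus the conventional qualitative
#' labels (ICC: poor < 0.4, fair-to-good 0.4-0.75, excellent > 0.75;
#' alpha: unacceptable < 0.5, then poor, questionable, acceptable, good,
#' excellent > 0.9). Values are returned at full precision; round for
#' display.
#'
#' @param data Data frame with columns `test`, `subject`, `method_a`,
#'   `method_b` (long over tests, wide over methods), e.g.
#'   [case_study_durations()].
#' @param form ICC form, see [icc_oneway()].
#' @param conf_level Confidence level for the ICC interval.
#' @return A tibble with one row per test.
#' @examples
#' reliability_table(case_study_durations())
#' @export
reliability_table <- function(data, form = "average", conf_level = 0.95) {
  if (!all(c("test", "subject", "method_a", "method_b") %in% names(data))) {
    abort("Need columns test, subject, method_a, method_b.", class = "trunkdx_format_error")
  }
  data |>
    dplyr::group_by(.data$test) |>
    dplyr::group_modify(function(df, key) {
      fit <- icc_oneway(df, form = form, conf_level = conf_level)
      ba <- glance(bland_altman(df))
      tibble::tibble(
        n = fit$n,
        icc = fit$estimate,
        icc_low = fit$conf.low,
        icc_high = fit$conf.high,
        alpha = cronbach_alpha(df),
        mean_diff = ba$mean_diff,
        loa_low = ba$loa_low,
        loa_high = ba$loa_high
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      icc_label = icc_label(.data$icc),
      alpha_label = alpha_label(.data$alpha)
    )
}

icc_label <- function(icc) {
  dplyr::case_when(
    icc < 0.4 ~ "poor",
    icc <= 0.75 ~ "fair to good",
    TRUE ~ "excellent"
  )
}

alpha_label <- function(alpha) {
  dplyr::case_when(
    alpha < 0.5 ~ "unacceptable",
    alpha < 0.6 ~ "poor",
    alpha < 0.7 ~ "questionable",
    alpha < 0.8 ~ "acceptable",
    alpha <= 0.9 ~ "good",
    TRUE ~ "excellent"
  )
}

check_paired <- function(data, method_a = "method_a", method_b = "method_b") {
  if (!is.data.frame(data)) {
    abort("Paired measurements must be a data frame.", class = "trunkdx_format_error")
  }
  miss <- setdiff(c(method_a, method_b), names(data))
  if (length(miss) > 0) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")),
      class = "trunkdx_format_error"
    )
  }
  a <- data[[method_a]]
  b <- data[[method_b]]
  if (length(a) < 2) {
    abort("Need at least two subjects.", class = "trunkdx_degenerate_data")
  }
  if (anyNA(a) || anyNA(b) || any(!is.finite(a)) || any(!is.finite(b))) {
    abort("Paired measurements must be finite.", class = "trunkdx_invalid_sample")
  }
  subject <- if ("subject" %in% names(data)) data$subject else seq_along(a)
  tibble::tibble(subject = subject, a = as.numeric(a), b = as.numeric(b))
}
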