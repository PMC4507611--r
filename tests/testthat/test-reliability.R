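steet <- function() {
  df <- case_study_durations()
  df[df$test == "STEET", ]
}

test_that("hand ANOVA decomposition agrees with stats::aov", {
  df <- steet()
  ms <- aov_ms(df$method_a, df$method_b)
  fit <- icc_oneway(df)
  g <- glance(fit)
  expect_equal(g$msb, ms$msb, tolerance = 1e-12)
  expect_equal(g$msw, ms$msw, tolerance = 1e-12)
})

test_that("single and average ICC forms relate as expected", {
  df <- steet()
  avg <- icc_oneway(df, form = "average")
  sng <- icc_oneway(df, form = "single")
  # frozen from the ANOVA oracle: MSB/MSW decomposition by hand
  expect_equal(round(sng$estimate, 3), 0.845)
  expect_equal(round(avg$estimate, 2), 0.92)
  # average >= single whenever single > 0 (Spearman-Brown step-up)
  expect_gt(avg$estimate, sng$estimate)
  expect_equal(avg$estimate, 2 * sng$estimate / (1 + sng$estimate), tolerance = 1e-12)
})

test_that("identical columns give perfect reliability with a degenerate CI", {
  df <- tibble::tibble(subject = 1:8, method_a = c(3, 9, 4, 7, 1, 5, 8, 2))
  df$method_b <- df$method_a
  fit <- icc_oneway(df)
  expect_equal(fit$estimate, 1)
  expect_equal(c(fit$conf.low, fit$conf.high), c(1, 1))
  expect_equal(cronbach_alpha(df), 1)
})

test_that("degenerate (zero-variance) data is rejected", {
  flat <- tibble::tibble(subject = 1:5, method_a = rep(3, 5), method_b = rep(3, 5))
  expect_error(icc_oneway(flat), class = "trunkdx_degenerate_data")
  expect_error(cronbach_alpha(flat), class = "trunkdx_degenerate_data")
  one <- tibble::tibble(subject = 1, method_a = 1, method_b = 2)
  expect_error(icc_oneway(one), class = "trunkdx_degenerate_data")
})

test_that("ICC and alpha are location- and scale-invariant", {
  df <- steet()
  shifted <- dplyr::mutate(df, method_a = method_a * 3 + 11, method_b = method_b * 3 + 11)
  expect_equal(icc_oneway(shifted)$estimate, icc_oneway(df)$estimate, tolerance = 1e-12)
  expect_equal(cronbach_alpha(shifted), cronbach_alpha(df), tolerance = 1e-12)
})

test_that("Bland-Altman summarizes oriented differences with 1.96 SD limits", {
  df <- steet()
  ba <- bland_altman(df)
  d <- df$method_a - df$method_b
  expect_equal(ba$mean_diff, mean(d)) # = -5.4 for these data
  expect_equal(ba$mean_diff, -5.4)
  expect_equal(ba$sd_diff, sd(d))
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d))
  expect_equal(nrow(tidy(ba)), nrow(df))
  expect_equal(tidy(ba)$average, (df$method_a + df$method_b) / 2)

  # identical columns: zero mean and collapsed limits
  same <- tibble::tibble(subject = 1:5, method_a = 1:5, method_b = 1:5)
  expect_equal(glance(bland_altman(same))$loa_high, 0)

  # on Normal(0, sigma) differences ~95% fall inside the limits
  set.seed(123)
  big <- tibble::tibble(
    subject = 1:10000, method_a = rnorm(10000, 100, 4), method_b = 100
  )
  bb <- bland_altman(big)
  inside <- mean(bb$pairs$difference > bb$loa_low & bb$pairs$difference < bb$loa_high)
  expect_equal(inside, 0.95, tolerance = 0.01)

  p <- autoplot(ba)
  expect_s3_class(p, "ggplot")
})

test_that("the reliability table is permutation- and label-stable", {
  df <- case_study_durations()
  tab <- reliability_table(df)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$icc_label == "excellent"))
  expect_equal(
    tab$alpha_label[match(c("STEET", "TCSET", "SBET_RIGHT", "SBET_LEFT"), tab$test)],
    c("excellent", "good", "good", "acceptable")
  )

  # permuting subject order changes nothing
  set.seed(31)
  perm <- df[sample(nrow(df)), ]
  expect_equal(reliability_table(perm), tab, tolerance = 1e-12)

  # swapping the method columns flips the Bland-Altman mean, not ICC/alpha
  swapped <- dplyr::rename(df, method_a = method_b, method_b = method_a)
  tab2 <- reliability_table(swapped)
  expect_equal(tab2$icc, tab$icc, tolerance = 1e-12)
  expect_equal(tab2$alpha, tab$alpha, tolerance = 1e-12)
  expect_equal(tab2$mean_diff, -tab$mean_diff, tolerance = 1e-12)
})

test_that("estimated ICC recovers the generating value across replicates", {
  # one-way model with true average-measures ICC 0.9
  sigma_b <- 20
  sigma_w <- sigma_b * sqrt(2 / 9) # 2 vb / (2 vb + vw) = 0.9
  hits <- 0
  for (r in 1:200) {
    pm <- simulate_paired_study(200, sigma_b, sigma_w, seed = 5000 + r)
    expect_equal(attr(pm, "true_icc"), 0.9, tolerance = 1e-12)
    est <- icc_oneway(pm)$estimate
    if (abs(est - 0.9) <= 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.9)
})
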