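test_that("tumor volume follows the ellipsoid formula", {
  expect_equal(tumor_volume(6, 5, 4), 20 * pi)
  d <- 7.3
  expect_equal(tumor_volume(d, d, d), pi * d^3 / 6) # sphere of diameter d
  expect_equal(tumor_volume(0, 5, 4), 0)
  # symmetric in its arguments
  expect_equal(tumor_volume(2, 3, 4), tumor_volume(4, 2, 3))
  expect_error(tumor_volume(-1, 2, 3), class = "tftg_error_negative_dimension")
})

test_that("exponential growth rates are recovered from log-linear data", {
  days <- c(0, 7, 14, 21)
  doubling <- tibble::tibble(
    tumor_id = "t1", day = days, volume = 100 * 2^(days / 7)
  )
  fit <- fit_growth(doubling)
  expect_equal(fit$rate_k, log(2) / 7, tolerance = 1e-10)
  expect_equal(fit$v0, 100, tolerance = 1e-8)
  expect_equal(fit$fold_increase, 8)

  constant <- tibble::tibble(tumor_id = "t2", day = days, volume = 50)
  fitc <- fit_growth(constant)
  expect_equal(fitc$rate_k, 0)
  expect_equal(fitc$fold_increase, 1)

  t5 <- seq(0, 20, by = 5)
  exact <- tibble::tibble(tumor_id = "t3", day = t5, volume = 100 * exp(0.2 * t5))
  expect_equal(fit_growth(exact)$rate_k, 0.2, tolerance = 1e-10)
})

test_that("growth fitting excludes zero volumes and enforces its domain", {
  m <- tibble::tibble(
    tumor_id = "t1", day = c(0, 3, 6, 9),
    volume = c(0, 100, 200, 400)
  )
  expect_message(fit <- fit_growth(m), "1 zero-volume")
  expect_equal(fit$n_points, 3L)
  expect_equal(fit$n_dropped, 1L)
  expect_equal(fit$fold_increase, 4) # baseline = first positive measurement

  short <- tibble::tibble(tumor_id = "t", day = c(0, 5), volume = c(0, 10))
  expect_error(suppressMessages(fit_growth(short)),
               class = "tftg_error_growth_points")

  # caliper columns are converted through tumor_volume
  cal <- tibble::tibble(
    tumor_id = "t", day = c(0, 7), L = c(6, 6), W = c(5, 5), H = c(4, 8)
  )
  expect_equal(fit_growth(cal)$fold_increase, 2)

  # scaling all volumes leaves the rate unchanged
  m2 <- tibble::tibble(tumor_id = "t", day = 0:4,
                       volume = 100 * exp(0.15 * (0:4)) * c(1, 1.1, 0.9, 1.05, 1))
  expect_equal(
    fit_growth(m2)$rate_k,
    fit_growth(dplyr::mutate(m2, volume = volume * 37))$rate_k,
    tolerance = 1e-12
  )

  # day window restricts the fit
  m3 <- tibble::tibble(
    tumor_id = "t", day = c(0, 5, 10, 15),
    volume = c(100, 100, 100 * exp(1), 100 * exp(2))
  )
  expect_equal(fit_growth(m3, day_min = 5)$rate_k, 0.2, tolerance = 1e-10)
})

test_that("interaction ANOVA matches the textbook decomposition on a 2x2x3 fixture", {
  df <- tibble::tibble(
    vector = rep(c("empty", "shRNA"), each = 6),
    treatment = rep(rep(c("saline", "drug"), each = 3), 2),
    endpoint = c(
      12.1, 11.4, 12.8, 8.6, 9.1, 8.2,   # empty: saline, drug
      11.8, 12.6, 11.9, 4.2, 3.7, 4.9    # shRNA: saline, drug
    )
  )
  fit <- interaction_anova(df, endpoint = "endpoint")
  oracle <- anova_ss_oracle(df$endpoint, df$vector, df$treatment)
  expect_equal(fit$F_interaction, oracle$F_interaction, tolerance = 1e-10)
  expect_equal(fit$p_interaction, oracle$p_interaction, tolerance = 1e-10)
  # and both agree with R's sequential table for the last term
  tab <- tidy(fit)
  expect_equal(tab$statistic[tab$term == "vector:treatment"],
               fit$F_interaction, tolerance = 1e-12)
  expect_equal(nrow(fit$cell_means), 4L)
  expect_equal(glance(fit)$p_interaction, fit$p_interaction)
})

test_that("additive cell means give zero interaction and F is scale-free", {
  # additive means (drug effect identical in both vectors), symmetric +/-1 noise
  base <- c(empty.saline = 10, empty.drug = 6, shRNA.saline = 8, shRNA.drug = 4)
  df <- tidyr::expand_grid(
    vector = c("empty", "shRNA"), treatment = c("saline", "drug"),
    sign = c(1, -1)
  )
  df$endpoint <- base[paste(df$vector, df$treatment, sep = ".")] + df$sign
  fit <- interaction_anova(df, endpoint = "endpoint")
  expect_equal(fit$F_interaction, 0, tolerance = 1e-12)

  # doubling the endpoint leaves F unchanged
  set.seed(606)
  df2 <- tidyr::expand_grid(
    vector = c("a", "b"), treatment = c("x", "y"), rep = 1:4
  )
  df2$endpoint <- rnorm(nrow(df2), 5, 1)
  f1 <- interaction_anova(df2, endpoint = "endpoint")$F_interaction
  f2 <- interaction_anova(
    dplyr::mutate(df2, endpoint = endpoint * 2), endpoint = "endpoint"
  )$F_interaction
  expect_equal(f1, f2, tolerance = 1e-12)

  # singleton cells are refused
  expect_error(interaction_anova(df2[c(1, 2, 5, 6, 9, 13), ], endpoint = "endpoint"),
               class = "tftg_error_cell_size")
})

test_that("interaction ANOVA handles unbalanced designs via the partial SS", {
  set.seed(607)
  df <- tibble::tibble(
    vector = rep(c("empty", "shRNA"), c(7, 5)),
    treatment = c(rep(c("saline", "drug"), c(4, 3)), rep(c("saline", "drug"), c(2, 3))),
    endpoint = rnorm(12, 10, 2)
  )
  fit <- interaction_anova(df, endpoint = "endpoint")
  # oracle: drop in RSS from additive to full model, computed with raw lm
  full <- lm(endpoint ~ vector * treatment, data = df)
  red <- lm(endpoint ~ vector + treatment, data = df)
  ss <- sum(resid(red)^2) - sum(resid(full)^2)
  f_or <- ss / (sum(resid(full)^2) / full$df.residual)
  expect_equal(fit$F_interaction, f_or, tolerance = 1e-10)
  expect_true(fit$p_interaction >= 0 && fit$p_interaction <= 1)
})
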