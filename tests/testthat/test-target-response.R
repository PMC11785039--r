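test_that("fold changes are treated-minus-control means per phenotype", {
  design <- make_design(2L)
  mat <- matrix(0, nrow = 2, ncol = 8,
                dimnames = list(c("g1", "g2"), design$sample))
  # g1: control mean 1, treated mean 3 in the reference phenotype only
  mat["g1", design$treatment == "control" & design$phenotype == "NT"] <- 1
  mat["g1", design$treatment == "drug" & design$phenotype == "NT"] <- 3
  mat["g2", ] <- 5 # globally constant
  fc <- fold_changes(mat, design, targets = "g1")
  expect_equal(fc$fc_ref, c(2, 0))
  expect_equal(fc$fc_alt, c(0, 0))
  expect_equal(fc$delta, c(2, 0))
  expect_equal(fc$is_target, c(TRUE, FALSE))
})

test_that("delta equals minus the fitted interaction on balanced designs", {
  set.seed(404)
  for (rep in 1:25) {
    r <- sample(c(2L, 3L, 5L), 1L)
    design <- make_design(r)
    mat <- matrix(rnorm(4 * nrow(design), 7, 1.5), nrow = 4,
                  dimnames = list(paste0("g", 1:4), design$sample))
    fc <- fold_changes(mat, design)
    fits <- fit_interactions(mat, design)
    expect_equal(fc$fc_alt - fc$fc_ref, fits$e, tolerance = 1e-10)
  }
})

test_that("target summaries report group means, CIs and Welch tests", {
  set.seed(505)
  n_t <- 40L
  n_n <- 200L
  records <- tibble::tibble(
    gene = sprintf("g%03d", seq_len(n_t + n_n)),
    fc_ref = c(rnorm(n_t, 1.0, 0.2), rnorm(n_n, 0.2, 0.2)),
    fc_alt = c(rnorm(n_t, 0.4, 0.2), rnorm(n_n, 0.2, 0.2)),
    is_target = rep(c(TRUE, FALSE), c(n_t, n_n))
  )
  records$delta <- records$fc_ref - records$fc_alt
  out <- summarize_by_target(records)
  expect_s3_class(out, "target_summary")
  sm <- out$summary
  expect_equal(nrow(sm), 6L)
  expect_true(all(sm$ci_low <= sm$mean & sm$mean <= sm$ci_high))
  tgt_delta <- sm$mean[sm$group == "target" & sm$quantity == "delta"]
  expect_equal(tgt_delta, mean(records$delta[records$is_target]))
  expect_equal(
    out$delta_of_deltas,
    mean(records$delta[records$is_target]) -
      mean(records$delta[!records$is_target])
  )
  wd <- out$welch[out$welch$quantity == "delta", ]
  expect_lt(wd$welch_p, 1e-3)
  expect_false(wd$degenerate)

  # tidy/glance accessors
  expect_identical(tidy(out), out$summary)
  expect_equal(glance(out)$delta_of_deltas, out$delta_of_deltas)
})

test_that("Welch p is symmetric under stratum swap; t changes sign only", {
  set.seed(506)
  records <- tibble::tibble(
    gene = sprintf("g%02d", 1:30),
    fc_ref = rnorm(30), fc_alt = rnorm(30),
    is_target = rep(c(TRUE, FALSE), c(12, 18))
  )
  records$delta <- records$fc_ref - records$fc_alt
  swapped <- dplyr::mutate(records, is_target = !is_target)
  a <- summarize_by_target(records)$welch
  b <- summarize_by_target(swapped)$welch
  expect_equal(a$welch_p, b$welch_p, tolerance = 1e-12)
  expect_equal(a$welch_t, -b$welch_t, tolerance = 1e-12)
})

test_that("equal-n equal-variance strata give the pooled Welch df", {
  # algebraic identity of Welch-Satterthwaite when n1 = n2 and s1 = s2
  x <- c(1, 2, 3, 4, 5)
  y <- x + 3 # same spread, shifted
  records <- tibble::tibble(
    gene = sprintf("g%02d", 1:10),
    fc_ref = c(x, y), fc_alt = 0, delta = c(x, y),
    is_target = rep(c(TRUE, FALSE), each = 5)
  )
  out <- summarize_by_target(records)
  wd <- out$welch[out$welch$quantity == "delta", ]
  expect_equal(wd$welch_df, 8) # n1 + n2 - 2
})

test_that("degenerate strata are flagged instead of fabricating statistics", {
  records <- tibble::tibble(
    gene = sprintf("g%02d", 1:10),
    fc_ref = rep(c(0.6, 0), c(4, 6)),
    fc_alt = 0,
    delta = rep(c(0.6, 0), c(4, 6)),
    is_target = rep(c(TRUE, FALSE), c(4, 6))
  )
  out <- summarize_by_target(records)
  sm <- out$summary
  # zero spread: zero-width CIs at the mean
  expect_equal(sm$ci_low, sm$mean)
  expect_equal(sm$ci_high, sm$mean)
  expect_equal(out$delta_of_deltas, 0.6)
  expect_true(all(out$welch$degenerate[out$welch$quantity == "delta"]))

  # identical constant strata: t = 0, p = 1
  same <- dplyr::mutate(records, fc_ref = 1, delta = 1)
  w <- summarize_by_target(same)$welch
  expect_equal(w$welch_t[w$quantity == "delta"], 0)
  expect_equal(w$welch_p[w$quantity == "delta"], 1)

  # empty stratum is an error; singleton stratum omits tests with a flag
  expect_error(
    summarize_by_target(dplyr::mutate(records, is_target = FALSE)),
    class = "tftg_error_empty_stratum"
  )
  single <- records
  single$is_target <- c(TRUE, rep(FALSE, 9L))
  out1 <- summarize_by_target(single)
  expect_true(all(is.na(out1$summary$ci_low[out1$summary$group == "target"])))
  expect_true(all(out1$welch$degenerate))
})

test_that("fold-change plots build", {
  design <- make_design(2L)
  set.seed(507)
  mat <- matrix(rnorm(80), nrow = 10,
                dimnames = list(sprintf("g%02d", 1:10), design$sample))
  fc <- fold_changes(mat, design, targets = c("g01", "g02"))
  expect_s3_class(plot_fold_changes(fc), "ggplot")
  expect_s3_class(plot_target_summary(summarize_by_target(fc)), "ggplot")
})
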