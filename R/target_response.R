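#' Per-gene drug fold-changes in each phenotype
#'
#' For every gene, the log2 fold-change induced by treatment within each
#' phenotype: mean of treated samples minus mean of control samples, on the
#' log2 scale (`fc_ref` in the reference phenotype, `fc_alt` in the other).
#' `delta = fc_ref - fc_alt` measures how much more the gene responds in the
#' reference phenotype; on balanced designs it equals minus the fitted
#' interaction `e`. Genes are flagged by membership in the supplied target
#' set.
#'
#' @param mat Log2 expression matrix, genes x samples.
#' @param design Sample design aligned to the matrix columns.
#' @param targets Character vector: the transcription factor's annotated
#'   target genes.
#' @return Tibble, one row per gene in matrix order: `gene`, `fc_ref`,
#'   `fc_alt`, `delta`, `is_target`.
#' @export
fold_changes <- function(mat, design, targets = character()) {
  check_expression_matrix(mat)
  if ("sample" %in% names(design)) {
    design <- check_design(design, colnames(mat), require_cells = FALSE)
  }
  design <- validate_fit_design(design, ncol(mat))
  treat <- design$treatment == levels(design$treatment)[2L]
  alt <- design$phenotype == levels(design$phenotype)[2L]

  cell_mean <- function(keep) rowMeans(mat[, keep, drop = FALSE])
  fc_ref <- cell_mean(treat & !alt) - cell_mean(!treat & !alt)
  fc_alt <- cell_mean(treat & alt) - cell_mean(!treat & alt)
  tibble::tibble(
    gene = rownames(mat),
    fc_ref = unname(fc_ref),
    fc_alt = unname(fc_alt),
    delta = unname(fc_ref - fc_alt),
    is_target = rownames(mat) %in% targets
  )
}

mean_ci <- function(x, level = 0.95) {
  n <- length(x)
  m <- mean(x)
  if (n < 2L) {
    return(c(mean = m, ci_low = NA_real_, ci_high = NA_real_))
  }
  half <- qt(1 - (1 - level) / 2, df = n - 1L) * sd(x) / sqrt(n)
  c(mean = m, ci_low = m - half, ci_high = m + half)
}

welch_row <- function(x, y, quantity) {
  degenerate <- sd(x) == 0 && sd(y) == 0
  if (degenerate || length(x) < 2L || length(y) < 2L) {
    if (degenerate && mean(x) == mean(y)) {
      # identical constant strata: no evidence of difference
      return(tibble::tibble(
        quantity = quantity, welch_t = 0, welch_df = NA_real_,
        welch_p = 1, degenerate = TRUE
      ))
    }
    return(tibble::tibble(
      quantity = quantity, welch_t = NA_real_, welch_df = NA_real_,
      welch_p = NA_real_, degenerate = TRUE
    ))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  tibble::tibble(
    quantity = quantity,
    welch_t = unname(tt$statistic),
    welch_df = unname(tt$parameter),
    welch_p = tt$p.value,
    degenerate = FALSE
  )
}

#' Average fold-changes for targets versus non-targets
#'
#' Summarizes the fold-change records into the target / non-target contrast:
#' group means of `fc_ref`, `fc_alt` and the per-gene `delta`, each with a
#' 95% t-based confidence interval, plus two-tailed Welch t-tests (unequal
#' variances, Welch-Satterthwaite degrees of freedom) comparing targets with
#' non-targets on each quantity. The headline number, `delta_of_deltas`, is
#' the difference in mean `delta` between targets and non-targets — the
#' aggregate shift of the target program relative to the background.
#'
#' @param records Fold-change tibble from [fold_changes()]; both strata must
#'   be non-empty, and need >= 2 genes each for CIs and tests.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A list of class `target_summary`:
#'   * `summary` — tibble, one row per group x quantity, with `n`, `mean`,
#'     `ci_low`, `ci_high`;
#'   * `welch` — tibble of Welch tests (targets vs non-targets) for `delta`,
#'     `fc_ref` and `fc_alt`, with a `degenerate` flag for zero-variance
#'     strata;
#'   * `delta_of_deltas` — numeric.
#' @export
summarize_by_target <- function(records, conf_level = 0.95) {
  tg <- dplyr::filter(records, .data$is_target)
  ng <- dplyr::filter(records, !.data$is_target)
  if (nrow(tg) == 0L || nrow(ng) == 0L) {
    tftg_abort("empty_stratum", "both target and non-target strata must be non-empty")
  }
  quantities <- c("fc_ref", "fc_alt", "delta")
  one_group <- function(df, label) {
    purrr::map_dfr(quantities, function(q) {
      ci <- mean_ci(df[[q]], conf_level)
      tibble::tibble(
        group = label, quantity = q, n = nrow(df),
        mean = ci[["mean"]], ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]]
      )
    })
  }
  summary <- dplyr::bind_rows(
    one_group(tg, "target"),
    one_group(ng, "non-target")
  )
  welch <- if (nrow(tg) >= 2L && nrow(ng) >= 2L) {
    purrr::map_dfr(quantities, function(q) welch_row(tg[[q]], ng[[q]], q))
  } else {
    tibble::tibble(
      quantity = quantities, welch_t = NA_real_, welch_df = NA_real_,
      welch_p = NA_real_, degenerate = TRUE
    )
  }
  structure(
    list(
      summary = summary,
      welch = welch,
      delta_of_deltas = mean(tg$delta) - mean(ng$delta)
    ),
    class = "target_summary"
  )
}

#' @export
print.target_summary <- function(x, ...) {
  cat("Target vs non-target response summary\n")
  cat(sprintf("  delta of deltas (target - non-target): %.4f\n", x$delta_of_deltas))
  print(x$summary)
  cat("Welch tests (target vs non-target):\n")
  print(x$welch)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.target_summary <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.target_summary <- function(x, ...) {
  wd <- x$welch[x$welch$quantity == "delta", ]
  tibble::tibble(
    delta_of_deltas = x$delta_of_deltas,
    welch_t = wd$welch_t, welch_df = wd$welch_df, welch_p = wd$welch_p
  )
}

#' Scatter plot of per-gene fold-changes by phenotype
#'
#' Each measurable gene is placed by its drug-induced log2 fold-change in the
#' reference phenotype (x) versus the other phenotype (y); target genes of
#' the factor under study are highlighted. Points below the identity line
#' respond more strongly in the reference phenotype.
#'
#' @param records Fold-change tibble from [fold_changes()].
#' @return A ggplot object.
#' @export
plot_fold_changes <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(
    x = .data$fc_ref, y = .data$fc_alt,
    colour = .data$is_target, shape = .data$is_target
  )) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue", `TRUE` = "red3")) +
    ggplot2::labs(
      x = "log2 fold-change, reference phenotype",
      y = "log2 fold-change, alternate phenotype",
      colour = "target", shape = "target"
    ) +
    ggplot2::theme_minimal()
}

#' Mean fold-changes with confidence intervals, by stratum
#'
#' @param summary A `target_summary` from [summarize_by_target()].
#' @return A ggplot object (means with 95% CI error bars, side by side).
#' @export
plot_target_summary <- function(summary) {
  df <- summary$summary
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$quantity, y = .data$mean, fill = .data$group
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "mean log2 fold-change (95% CI)", fill = NULL) +
    ggplot2::theme_minimal()
}
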