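#' Ellipsoid tumor volume from caliper measurements
#'
#' Volume in cubic millimetres from length, width and height in millimetres,
#' using `V = L * W * H * pi / 6` (the ellipsoid approximation; equal
#' dimensions give the volume of a sphere of that diameter). Vectorized and
#' symmetric in its arguments.
#'
#' @param L,W,H Tumor length, width and height in mm (non-negative).
#' @return Volume(s) in mm^3.
#' @examples
#' tumor_volume(6, 5, 4) # 20 * pi
#' @export
tumor_volume <- function(L, W, H) {
  if (any(L < 0 | W < 0 | H < 0, na.rm = TRUE)) {
    tftg_abort("negative_dimension", "caliper dimensions must be non-negative")
  }
  L * W * H * pi / 6
}

# Exponential rate for one tumor: OLS of ln(V) on day. Zero volumes are
# excluded (count reported via attribute handled by the caller).
fit_one_growth <- function(day, volume) {
  keep <- volume > 0
  n_dropped <- sum(!keep)
  day <- day[keep]
  volume <- volume[keep]
  if (length(day) < 2L) {
    tftg_abort("growth_points", "need >=2 timepoints with positive volume")
  }
  if (any(diff(day) <= 0)) {
    tftg_abort("day_order", "measurement days must be strictly increasing")
  }
  fit <- stats::lm.fit(cbind(1, day), log(volume))
  list(
    rate_k = unname(fit$coefficients[2L]),
    v0 = exp(unname(fit$coefficients[1L])),
    fold_increase = volume[length(volume)] / volume[1L],
    n_points = length(day),
    n_dropped = n_dropped
  )
}

#' Fit exponential growth kinetics per tumor
#'
#' For each tumor, computes caliper volumes, then the exponential growth
#' rate `k` as the slope of the least-squares line of `ln(V)` on day
#' (`V(t) = v0 * exp(k t)`), and the fold-increase in volume from the first
#' to the last recorded measurement. Zero-volume measurements are excluded
#' from the rate fit (a message reports how many).
#'
#' @param measurements Tibble with columns `tumor_id`, `day` and either
#'   `L`, `W`, `H` (mm) or a precomputed `volume` (mm^3); grouping columns
#'   such as `vector` and `treatment` are carried through.
#' @param day_min,day_max Optional window bounds (inclusive); measurements
#'   outside are ignored, e.g. to fit rates over the treatment window only.
#' @return Tibble, one row per tumor: grouping columns, `rate_k` (per day),
#'   `v0` (mm^3), `fold_increase`, `n_points`, `n_dropped`.
#' @export
fit_growth <- function(measurements, day_min = NULL, day_max = NULL) {
  m <- tibble::as_tibble(measurements)
  if (!"volume" %in% names(m)) {
    m <- dplyr::mutate(m, volume = tumor_volume(.data$L, .data$W, .data$H))
  }
  if (!is.null(day_min)) m <- dplyr::filter(m, .data$day >= day_min)
  if (!is.null(day_max)) m <- dplyr::filter(m, .data$day <= day_max)
  group_cols <- intersect(c("tumor_id", "vector", "treatment"), names(m))
  out <- m |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::summarise(
      fit = list(fit_one_growth(.data$day, .data$volume)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("fit")
  dropped <- sum(out$n_dropped)
  if (dropped > 0L) {
    rlang::inform(sprintf("excluded %d zero-volume measurement(s)", dropped))
  }
  out
}

#' Two-way interaction ANOVA on per-tumor endpoints
#'
#' Tests whether a genetic perturbation sensitizes tumors to chemotherapy:
#' a two-way fixed-effects ANOVA of a per-tumor endpoint (fold-increase in
#' volume, or growth rate) on `vector`, `treatment` and their interaction.
#' The interaction sum of squares is `SS(vector:treatment | main effects)` —
#' computed as the drop in residual sum of squares from the additive to the
#' full model — which coincides with the sequential (Type I, term last) and,
#' on balanced data, partial (Type III) decompositions for the
#' highest-order term.
#'
#' @param data Data frame with one row per tumor.
#' @param endpoint,vector,treatment Column names (strings) of the endpoint
#'   and the two two-level factors. Each of the four cells needs >= 2
#'   tumors.
#' @return An object of class `growth_anova`: list with `F_interaction`,
#'   `p_interaction`, `cell_means` (tibble), `table` (full ANOVA tibble) and
#'   the underlying `lm` fit. [tidy()] returns the ANOVA table; [glance()]
#'   the interaction F and p.
#' @export
interaction_anova <- function(data, endpoint = "endpoint",
                              vector = "vector", treatment = "treatment") {
  df <- data.frame(
    y = as.numeric(data[[endpoint]]),
    vector = two_level_factor(data[[vector]], what = vector),
    treatment = two_level_factor(data[[treatment]], what = treatment)
  )
  cells <- table(df$vector, df$treatment)
  if (any(cells < 2L)) {
    tftg_abort("cell_size", "each vector x treatment cell needs >= 2 tumors")
  }
  full <- lm(y ~ vector * treatment, data = df)
  additive <- lm(y ~ vector + treatment, data = df)
  rss_full <- sum(stats::residuals(full)^2)
  ss_int <- sum(stats::residuals(additive)^2) - rss_full
  df_resid <- full$df.residual
  ms_resid <- rss_full / df_resid
  f_int <- if (ms_resid > 0) (ss_int / 1) / ms_resid else NA_real_
  p_int <- if (is.na(f_int)) NA_real_ else pf(f_int, 1, df_resid, lower.tail = FALSE)

  tab <- as.data.frame(anova(full))
  tab <- tibble::tibble(term = rownames(tab), tibble::as_tibble(tab))
  names(tab) <- c("term", "df", "sumsq", "meansq", "statistic", "p.value")
  cm <- df |>
    dplyr::group_by(.data$vector, .data$treatment) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$y), sd = sd(.data$y),
      .groups = "drop"
    )
  structure(
    list(
      F_interaction = f_int, p_interaction = p_int,
      cell_means = cm, table = tab, fit = full
    ),
    class = "growth_anova"
  )
}

#' @export
print.growth_anova <- function(x, ...) {
  cat("Two-way interaction ANOVA (vector x treatment)\n")
  cat(sprintf(
    "  interaction: F = %.4g, p = %.4g\n", x$F_interaction, x$p_interaction
  ))
  print(x$cell_means)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.growth_anova <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.growth_anova <- function(x, ...) {
  tibble::tibble(
    F_interaction = x$F_interaction,
    p_interaction = x$p_interaction,
    df_residual = x$fit$df.residual
  )
}

#' Spaghetti plot of tumor growth on the log scale
#'
#' @param measurements Measurement tibble as accepted by [fit_growth()].
#' @return A ggplot object: per-tumor volume trajectories, log10 y-axis,
#'   faceted by treatment when present.
#' @export
plot_growth <- function(measurements) {
  m <- tibble::as_tibble(measurements)
  if (!"volume" %in% names(m)) {
    m <- dplyr::mutate(m, volume = tumor_volume(.data$L, .data$W, .data$H))
  }
  p <- ggplot2::ggplot(m, ggplot2::aes(
    x = .data$day, y = .data$volume, group = .data$tumor_id
  ))
  if ("vector" %in% names(m)) {
    p <- p + ggplot2::aes(colour = .data$vector)
  }
  p <- p + ggplot2::geom_line(alpha = 0.6) + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "day", y = expression(volume ~ (mm^3))) +
    ggplot2::theme_minimal()
  if ("treatment" %in% names(m)) {
    p <- p + ggplot2::facet_wrap(~treatment)
  }
  p
}
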