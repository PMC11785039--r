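# Fisher-exact enrichment of gene sets in the responsive selection.

# Sample odds ratio (a*d)/(b*c); Haldane-Anscombe 0.5 correction applied to
# all cells when any cell is zero, keeping volcano coordinates finite.
cross_odds <- function(a, b, cc, dd) {
  if (min(a, b, cc, dd) == 0L) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; dd <- dd + 0.5
  }
  (a * dd) / (b * cc)
}

contingency_counts <- function(responsive, set_in_u, n_universe) {
  a <- length(intersect(responsive, set_in_u))
  b <- length(responsive) - a
  cc <- length(set_in_u) - a
  dd <- n_universe - a - b - cc
  c(a = a, b = b, c = cc, d = dd)
}

#' Fisher exact enrichment of one gene set
#'
#' Tests whether a gene set is over- or under-represented among the
#' responsive genes, within a stated universe. The 2x2 table counts
#' `a` = responsive genes in the set, `b` = responsive genes outside it,
#' `c` = non-responsive set members, `d` = the rest of the universe. The
#' p-value is the two-tailed Fisher exact test (sum of hypergeometric
#' probabilities of all tables with the observed margins whose point
#' probability does not exceed the observed table's). The odds ratio is the
#' sample cross-product `(a d)/(b c)`, with the Haldane-Anscombe half-count
#' correction when any cell is zero.
#'
#' @param responsive Character vector of responsive genes, a subset of
#'   `universe`.
#' @param gene_set Character vector of set members; its intersection with
#'   the universe must be non-empty.
#' @param universe Character vector of genes eligible for selection.
#' @return One-row tibble: `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`.
#' @examples
#' u <- paste0("g", 1:20)
#' fisher_enrichment(u[1:10], u[c(1, 2, 11, 12)], u) # OR = 1, p = 1
#' @export
fisher_enrichment <- function(responsive, gene_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) tftg_abort("empty_universe", "universe is empty")
  responsive <- unique(responsive)
  if (length(setdiff(responsive, universe))) {
    tftg_abort("responsive_outside_universe",
               "responsive genes must be a subset of the universe")
  }
  set_in_u <- intersect(unique(gene_set), universe)
  if (!length(set_in_u)) {
    tftg_abort("set_not_represented", "set not represented in the universe")
  }
  ct <- contingency_counts(responsive, set_in_u, length(universe))
  p <- stats::fisher.test(matrix(ct, nrow = 2L))$p.value
  tibble::tibble(
    a = ct[["a"]], b = ct[["b"]], c = ct[["c"]], d = ct[["d"]],
    odds_ratio = cross_odds(ct[["a"]], ct[["b"]], ct[["c"]], ct[["d"]]),
    p_value = min(p, 1)
  )
}

#' Directional odds ratios for one gene set
#'
#' Recomputes the enrichment odds ratio three ways: with the full responsive
#' set, with the top tail only (genes preferentially induced / less
#' suppressed in the non-reference phenotype) and with the bottom tail only
#' — each against the rest of the universe, with the same zero-cell
#' correction. The tail-specific ratios reveal which phenotype drives an
#' association.
#'
#' @param selection A `responsive_selection` from [rank_and_select()].
#' @inheritParams fisher_enrichment
#' @return One-row tibble: `or_all`, `or_top`, `or_bottom`.
#' @export
directional_enrichment <- function(selection, gene_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) tftg_abort("empty_universe", "universe is empty")
  set_in_u <- intersect(unique(gene_set), universe)
  if (!length(set_in_u)) {
    tftg_abort("set_not_represented", "set not represented in the universe")
  }
  one_or <- function(genes) {
    genes <- intersect(genes, universe)
    ct <- contingency_counts(genes, set_in_u, length(universe))
    cross_odds(ct[["a"]], ct[["b"]], ct[["c"]], ct[["d"]])
  }
  tibble::tibble(
    or_all = one_or(responsive_genes(selection)),
    or_top = one_or(responsive_genes(selection, "top")),
    or_bottom = one_or(responsive_genes(selection, "bottom"))
  )
}

#' Enrich a whole gene-set collection against a responsive selection
#'
#' Applies [fisher_enrichment()] and [directional_enrichment()] to every set
#' of a collection. The universe defaults to the intersection of measured
#' genes with genes appearing in at least one set (`"intersect"`); set
#' `universe_mode = "measured"` to use all measured genes. Sets with fewer
#' than `min_set_size` members in the universe are flagged `too_small` and
#' not tested.
#'
#' @param selection A `responsive_selection`; genes outside the universe are
#'   ignored.
#' @param sets Gene-set collection tibble, as from [read_gmt()].
#' @param measured Character vector of all measured gene identifiers.
#' @param universe_mode `"intersect"` (default) or `"measured"`.
#' @param min_set_size Minimum represented set size to test (default 2).
#' @return A tibble of class `tftg_enrichment`, one row per set, in
#'   collection order: counts `a`-`d`, `odds_ratio`, `or_top`, `or_bottom`,
#'   `p_value`, `too_small`. Attribute `universe_size` records the universe.
#' @export
enrich_sets <- function(selection, sets, measured,
                        universe_mode = c("intersect", "measured"),
                        min_set_size = 2L) {
  universe_mode <- match.arg(universe_mode)
  measured <- unique(measured)
  universe <- switch(universe_mode,
    intersect = intersect(measured, unique(unlist(sets$genes))),
    measured = measured
  )
  if (!length(universe)) tftg_abort("empty_universe", "universe is empty")

  resp_all <- intersect(responsive_genes(selection), universe)
  resp_top <- intersect(responsive_genes(selection, "top"), universe)
  resp_bottom <- intersect(responsive_genes(selection, "bottom"), universe)

  rows <- purrr::map(seq_len(nrow(sets)), function(i) {
    set_in_u <- intersect(sets$genes[[i]], universe)
    if (length(set_in_u) < min_set_size) {
      return(tibble::tibble(
        set_name = sets$set_name[i], n_set = length(set_in_u),
        a = NA_integer_, b = NA_integer_, c = NA_integer_, d = NA_integer_,
        odds_ratio = NA_real_, or_top = NA_real_, or_bottom = NA_real_,
        p_value = NA_real_, too_small = TRUE
      ))
    }
    ct <- contingency_counts(resp_all, set_in_u, length(universe))
    p <- stats::fisher.test(matrix(ct, nrow = 2L))$p.value
    ct_top <- contingency_counts(resp_top, set_in_u, length(universe))
    ct_bot <- contingency_counts(resp_bottom, set_in_u, length(universe))
    tibble::tibble(
      set_name = sets$set_name[i], n_set = length(set_in_u),
      a = ct[["a"]], b = ct[["b"]], c = ct[["c"]], d = ct[["d"]],
      odds_ratio = cross_odds(ct[["a"]], ct[["b"]], ct[["c"]], ct[["d"]]),
      or_top = cross_odds(ct_top[["a"]], ct_top[["b"]], ct_top[["c"]], ct_top[["d"]]),
      or_bottom = cross_odds(ct_bot[["a"]], ct_bot[["b"]], ct_bot[["c"]], ct_bot[["d"]]),
      p_value = min(p, 1), too_small = FALSE
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
    class = c("tftg_enrichment", class(out)),
    universe_size = length(universe), universe_mode = universe_mode
  )
}

#' Rank transcription factors by enrichment p-value
#'
#' Sorts enrichment records ascending by p-value (ties broken by set name;
#' untested records last) and flags significance at a fixed cutoff. The
#' default `alpha = 1e-5` is a conservative Bonferroni-style threshold for a
#' compendium of fewer than 2,000 factors; significance is strict
#' (`p < alpha`).
#'
#' @param records Enrichment tibble from [enrich_sets()] (or with columns
#'   `set_name`, `p_value`).
#' @param alpha Significance cutoff on the raw p-value.
#' @return The records, re-ordered, with a logical `significant` column.
#' @export
rank_tfs <- function(records, alpha = 1e-5) {
  out <- dplyr::arrange(tibble::as_tibble(records), .data$p_value, .data$set_name)
  dplyr::mutate(out,
    significant = !is.na(.data$p_value) & .data$p_value < alpha
  )
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: for sorted p-values
#' `q_(i) = min over j >= i of m p_(j) / j`, capped at 1, returned in input
#' order. Used for pathway collections, where a fixed Bonferroni-style
#' cutoff would be needlessly conservative.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NA allowed and
#'   propagated).
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_qvalues <- function(p_values) {
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) tftg_abort("p_range", "p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Append q-values to an enrichment table
#'
#' @param records Enrichment tibble with a `p_value` column.
#' @return The records with a `q_value` column ([bh_qvalues()] over the
#'   tested sets).
#' @export
add_qvalues <- function(records) {
  dplyr::mutate(records, q_value = bh_qvalues(.data$p_value))
}

#' Volcano coordinates for an enrichment table
#'
#' @param records Enrichment tibble with `set_name`, `odds_ratio`,
#'   `p_value` (untested rows are dropped).
#' @param alpha Cutoff used for the `significant` flag when the records do
#'   not already carry one.
#' @return Tibble with `set_name`, `log2_odds_ratio`, `neg_log10_p` (clipped
#'   at 300) and `significant`.
#' @export
volcano_table <- function(records, alpha = 1e-5) {
  records <- dplyr::filter(tibble::as_tibble(records), !is.na(.data$p_value))
  sig <- if ("significant" %in% names(records)) {
    records$significant
  } else {
    records$p_value < alpha
  }
  tibble::tibble(
    set_name = records$set_name,
    log2_odds_ratio = log2(records$odds_ratio),
    neg_log10_p = pmin(-log10(records$p_value), 300),
    significant = sig
  )
}

#' Volcano plot of gene-set enrichment
#'
#' @inheritParams volcano_table
#' @param label_top Number of most significant sets to label.
#' @return A ggplot object.
#' @export
plot_volcano <- function(records, alpha = 1e-5, label_top = 5L) {
  vt <- volcano_table(records, alpha = alpha)
  lab <- head(dplyr::arrange(vt, dplyr::desc(.data$neg_log10_p)), label_top)
  ggplot2::ggplot(vt, ggplot2::aes(
    x = .data$log2_odds_ratio, y = .data$neg_log10_p,
    colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dotted") +
    ggplot2::geom_text(
      data = lab, ggplot2::aes(label = .data$set_name),
      vjust = -0.6, size = 3, show.legend = FALSE
    ) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "red3")) +
    ggplot2::labs(
      x = "log2 odds ratio", y = "-log10 p (Fisher exact)",
      colour = paste0("p < ", format(alpha))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_volcano
#' @param object A `tftg_enrichment` object.
#' @param ... Passed to [plot_volcano()].
#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.tftg_enrichment <- function(object, ...) plot_volcano(object, ...)
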