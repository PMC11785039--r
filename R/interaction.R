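#' Fit the factorial interaction model for one gene
#'
#' Ordinary least squares on the 2x2 factorial layout with treatment
#' (reference-level) coding. With the untreated control and the reference
#' phenotype as baselines, the coefficients are: `mu`, the baseline log2
#' level; `d`, the treatment effect in the reference phenotype; `c`, the
#' phenotype offset under control; and `e`, the interaction — the
#' difference-of-differences quantifying how much the drug response differs
#' between the two phenotypes. `e > 0` means the non-reference phenotype
#' responds more strongly.
#'
#' @param values Numeric vector of log2 levels, one per sample, in design
#'   row order.
#' @param design Tibble with columns `treatment`, `phenotype` (two-level
#'   factors, reference first) and `replicate`; all four cells non-empty.
#' @param gene Optional gene identifier carried into the result.
#' @return One-row tibble: `gene`, `mu`, `d`, `c`, `e`, `resid_sd`, `n_obs`.
#'   `resid_sd` uses n - 4 denominator degrees of freedom and is 0 for a
#'   saturated design (n = 4).
#' @examples
#' design <- tibble::tibble(
#'   sample = paste0("s", 1:8),
#'   treatment = factor(rep(c("control", "drug"), each = 4),
#'     levels = c("control", "drug")),
#'   phenotype = factor(rep(c("NT", "CSC"), 4), levels = c("NT", "CSC")),
#'   replicate = rep(1:2, 4)
#' )
#' fit_gene_model(c(1, 1, 1, 1, 3, 2, 3, 2), design) # e = -1
#' @export
fit_gene_model <- function(values, design, gene = NA_character_) {
  design <- validate_fit_design(design, length(values))
  df <- data.frame(
    y = as.numeric(values),
    treatment = design$treatment,
    phenotype = design$phenotype
  )
  fit <- stats::lm(y ~ treatment * phenotype, data = df)
  cf <- coef(fit)
  n <- nrow(df)
  rss <- sum(stats::residuals(fit)^2)
  resid_sd <- if (n > 4L) sqrt(rss / (n - 4L)) else 0
  tibble::tibble(
    gene = gene,
    mu = unname(cf[1L]),
    d = unname(cf[2L]),
    c = unname(cf[3L]),
    e = unname(cf[4L]),
    resid_sd = resid_sd,
    n_obs = n
  )
}

validate_fit_design <- function(design, n_values) {
  if (nrow(design) != n_values) {
    tftg_abort("design_mismatch", "one value per design row is required")
  }
  design$treatment <- two_level_factor(design$treatment, what = "treatment")
  design$phenotype <- two_level_factor(design$phenotype, what = "phenotype")
  cells <- table(design$treatment, design$phenotype)
  if (any(cells == 0L)) {
    tftg_abort("empty_cell", "each treatment x phenotype cell needs >=1 sample")
  }
  design
}

#' Fit the interaction model to every gene of a matrix
#'
#' Row-wise version of [fit_gene_model()], solved in one closed-form least
#' squares pass (the design matrix is shared by all genes), so it scales to
#' array-sized matrices. Results are identical to calling [fit_gene_model()]
#' per row.
#'
#' @param mat Numeric log2 expression matrix, genes x samples.
#' @param design Sample design aligned to `colnames(mat)` (matched by the
#'   `sample` column when present).
#' @return Tibble with one row per gene, in matrix row order: `gene`, `mu`,
#'   `d`, `c`, `e`, `resid_sd`, `n_obs`.
#' @export
fit_interactions <- function(mat, design) {
  check_expression_matrix(mat)
  if ("sample" %in% names(design)) {
    design <- check_design(design, colnames(mat), require_cells = FALSE)
  }
  design <- validate_fit_design(design, ncol(mat))

  X <- stats::model.matrix(~ treatment * phenotype, data = design)
  n <- nrow(X)
  Y <- t(mat)                      # samples x genes
  XtX <- crossprod(X)
  B <- solve(XtX, crossprod(X, Y)) # 4 x genes
  resid <- Y - X %*% B
  rss <- colSums(resid^2)
  resid_sd <- if (n > 4L) sqrt(pmax(rss, 0) / (n - 4L)) else rep(0, ncol(Y))
  tibble::tibble(
    gene = rownames(mat),
    mu = unname(B[1L, ]),
    d = unname(B[2L, ]),
    c = unname(B[3L, ]),
    e = unname(B[4L, ]),
    resid_sd = unname(resid_sd),
    n_obs = n
  )
}

#' Select responsive genes from the interaction ranking
#'
#' Ranks genes by the signed interaction estimate `e` and takes the extreme
#' tails: the `k` largest (preferential response in the non-reference
#' phenotype) and the `k` smallest (preferential response in the reference
#' phenotype), with `k = max(1, floor(fraction * n_genes))`. Ties at a tail
#' boundary are broken by gene identifier so the selection is deterministic
#' and invariant to input order.
#'
#' @param fits Tibble with columns `gene` and `e`, as from
#'   [fit_interactions()].
#' @param fraction Tail fraction per side, in (0, 0.5); default 0.05 selects
#'   the top 5% plus bottom 5% as "responsive".
#' @return A tibble of class `responsive_selection` with columns `gene`, `e`,
#'   `tail` (`"top"` rows first, highest `e` first, then `"bottom"`, lowest
#'   `e` first). Attributes `fraction` and `k` record the selection rule.
#' @export
rank_and_select <- function(fits, fraction = 0.05) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 0.5) {
    tftg_abort("fraction", "fraction must lie strictly between 0 and 0.5")
  }
  if (anyDuplicated(fits$gene)) {
    tftg_abort("duplicate_gene", "duplicate gene identifiers in fits")
  }
  n <- nrow(fits)
  k <- max(1L, floor(fraction * n))
  if (2L * k > n) {
    tftg_abort("too_few_genes", "need at least two tail-sizes worth of genes")
  }
  # one full ranking: e descending, identifier ascending on ties
  ord <- order(-fits$e, fits$gene)
  top <- fits[head(ord, k), c("gene", "e")]
  bottom <- fits[rev(tail(ord, k)), c("gene", "e")]
  out <- dplyr::bind_rows(
    dplyr::mutate(top, tail = "top"),
    dplyr::mutate(bottom, tail = "bottom")
  )
  structure(out,
    class = c("responsive_selection", class(out)),
    fraction = fraction, k = k
  )
}

#' Genes in a responsive selection
#'
#' @param selection A `responsive_selection` from [rank_and_select()].
#' @param tail `"both"`, `"top"` or `"bottom"`.
#' @return Character vector of gene identifiers.
#' @export
responsive_genes <- function(selection, tail = c("both", "top", "bottom")) {
  tail <- match.arg(tail)
  if (tail == "both") selection$gene else selection$gene[selection$tail == tail]
}
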