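#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share one empirical distribution: each
#' value is replaced by the mean, across columns, of the values at its rank.
#' Tied values within a column receive the mean of the reference values over
#' their tied rank range, so within-column rank order is preserved and a
#' second pass is a no-op.
#'
#' @param mat Numeric matrix, genes (or probes) x samples, finite values.
#' @return Matrix of the same shape and dimnames; all columns share the same
#'   multiset of values.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
#' rownames(m) <- paste0("g", 1:3)
#' quantile_normalize(m) # both columns become 2.5, 3.5, 4.5
#' @export
quantile_normalize <- function(mat) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (nrow(mat) == 0L || ncol(mat) == 0L) {
    tftg_abort("empty_matrix", "cannot quantile-normalize an empty matrix")
  }
  if (!all(is.finite(mat))) {
    tftg_abort("nonfinite", "quantile normalization requires finite values")
  }
  if (ncol(mat) == 1L) return(mat)
  ref <- unname(rowMeans(apply(mat, 2L, function(col) sort(col, method = "quick"))))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    o <- order(mat[, j])
    # mean of ref over each run of tied input values = mean over tied ranks
    normalized <- stats::ave(ref, match(mat[o, j], mat[o, j]))
    out[o, j] <- normalized
  }
  out
}

#' Summarize probe-level intensities to gene level
#'
#' Excludes "promiscuous" probes (those mapping to more than one gene), drops
#' probes absent from the map (with a message giving the count), then
#' averages the remaining probes of each gene per sample. Gene rows are
#' returned in lexicographic order.
#'
#' @param probe_matrix Numeric matrix, probes x samples.
#' @param probe_map Tibble with columns `probe`, `gene` as from
#'   [read_probe_map()]; repeated probe rows encode multi-gene probes.
#' @return Numeric matrix, genes x samples.
#' @export
summarize_probes <- function(probe_matrix, probe_map) {
  check_expression_matrix(probe_matrix, "probe matrix")
  probes <- rownames(probe_matrix)

  unmapped <- setdiff(probes, probe_map$probe)
  if (length(unmapped)) {
    rlang::inform(sprintf("dropping %d unmapped probe(s)", length(unmapped)))
  }
  genes_per_probe <- table(unique(probe_map[c("probe", "gene")])$probe)
  promiscuous <- names(genes_per_probe)[genes_per_probe > 1L]
  keep_map <- probe_map[
    probe_map$probe %in% probes & !probe_map$probe %in% promiscuous,
  ]
  if (nrow(keep_map) == 0L) {
    tftg_abort("no_probes", "no uniquely-mapping probe survives summarization")
  }

  sub <- probe_matrix[keep_map$probe, , drop = FALSE]
  genes <- sort(unique(keep_map$gene))
  grp <- factor(keep_map$gene, levels = genes)
  out <- apply(sub, 2L, function(col) {
    tapply(col, grp, mean)
  })
  out <- matrix(out,
    nrow = length(genes),
    dimnames = list(genes, colnames(probe_matrix))
  )
  out
}

#' Log2-transform an intensity matrix
#'
#' @param mat Numeric matrix of strictly positive intensities.
#' @return Elementwise base-2 logarithm of `mat`.
#' @export
log2_transform <- function(mat) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  bad <- which(!(is.finite(mat) & mat > 0), arr.ind = TRUE)
  if (nrow(bad)) {
    g <- if (!is.null(rownames(mat))) rownames(mat)[bad[1L, 1L]] else bad[1L, 1L]
    s <- if (!is.null(colnames(mat))) colnames(mat)[bad[1L, 2L]] else bad[1L, 2L]
    tftg_abort(
      "nonpositive",
      sprintf("non-positive or non-finite value at gene '%s', sample '%s'", g, s)
    )
  }
  log2(mat)
}

#' Preprocess probe intensities into a gene-level log2 matrix
#'
#' Convenience wrapper mirroring the usual array flow: quantile-normalize the
#' probe matrix across samples, log2-transform, then summarize probes to
#' genes (mean of uniquely-mapping probes). Either step can be skipped when
#' the input is already normalized or on the log scale, and probe means can
#' be taken before the log transform instead via `summarize_when`.
#'
#' @param mat Probe- or gene-level intensity matrix.
#' @param probe_map Optional probe map; when `NULL`, `mat` is treated as
#'   gene-level and no summarization happens.
#' @param quantile,log2 Logical; apply the respective step.
#' @param summarize_when `"after_log2"` (default) or `"before_log2"`.
#' @return Gene-level log2 expression matrix.
#' @export
preprocess_expression <- function(mat, probe_map = NULL, quantile = TRUE,
                                  log2 = TRUE,
                                  summarize_when = c("after_log2", "before_log2")) {
  summarize_when <- match.arg(summarize_when)
  if (quantile) mat <- quantile_normalize(mat)
  if (!is.null(probe_map) && summarize_when == "before_log2") {
    mat <- summarize_probes(mat, probe_map)
  }
  if (log2) mat <- log2_transform(mat)
  if (!is.null(probe_map) && summarize_when == "after_log2") {
    mat <- summarize_probes(mat, probe_map)
  }
  mat
}
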