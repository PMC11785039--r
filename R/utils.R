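# Internal helpers shared across modules.

# Classed errors so callers (and tests) can dispatch on the failure mode
# rather than matching message text.
tftg_abort <- function(class, message, ...) {
  rlang::abort(message, class = c(paste0("tftg_error_", class), "tftg_error"), ...)
}

# A two-level factor with an explicit reference level. `ref = NULL` keeps the
# first level in order of appearance (file order for sample sheets).
two_level_factor <- function(x, ref = NULL, what = "factor") {
  levs <- if (is.factor(x)) levels(droplevels(x)) else unique(as.character(x))
  if (length(levs) != 2L) {
    tftg_abort(
      "factor_levels",
      sprintf(
        "factor not two-level: '%s' has %d level(s): %s",
        what, length(levs), paste(levs, collapse = ", ")
      )
    )
  }
  if (!is.null(ref)) {
    if (!ref %in% levs) {
      tftg_abort(
        "factor_levels",
        sprintf("reference level '%s' not found among levels of '%s'", ref, what)
      )
    }
    levs <- c(ref, setdiff(levs, ref))
  }
  factor(as.character(x), levels = levs)
}

# Validate an expression matrix: numeric, finite, unique dimnames.
check_expression_matrix <- function(mat, what = "expression matrix") {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    tftg_abort("nonnumeric", sprintf("%s must be a numeric matrix", what))
  }
  if (nrow(mat) == 0L || ncol(mat) == 0L) {
    tftg_abort("empty_matrix", sprintf("%s has zero rows or columns", what))
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    tftg_abort("missing_ids", sprintf("%s must carry row and column names", what))
  }
  if (anyDuplicated(rownames(mat))) {
    dup <- rownames(mat)[duplicated(rownames(mat))][1L]
    tftg_abort("duplicate_gene", sprintf("duplicate row identifier: '%s'", dup))
  }
  if (anyDuplicated(colnames(mat))) {
    dup <- colnames(mat)[duplicated(colnames(mat))][1L]
    tftg_abort("duplicate_sample", sprintf("duplicate sample identifier: '%s'", dup))
  }
  if (!all(is.finite(mat))) {
    idx <- which(!is.finite(mat), arr.ind = TRUE)[1L, ]
    tftg_abort(
      "nonfinite",
      sprintf(
        "non-finite value at gene '%s', sample '%s'",
        rownames(mat)[idx[1L]], colnames(mat)[idx[2L]]
      )
    )
  }
  invisible(mat)
}

# Align a sample design to the columns of a matrix; errors if any column has
# no design row or a design row matches no column.
check_design <- function(design, sample_ids, require_cells = TRUE) {
  needed <- c("sample", "treatment", "phenotype", "replicate")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols)) {
    tftg_abort(
      "design_columns",
      sprintf("sample sheet lacks column(s): %s", paste(missing_cols, collapse = ", "))
    )
  }
  if (anyDuplicated(design$sample)) {
    dup <- design$sample[duplicated(design$sample)][1L]
    tftg_abort("duplicate_sample", sprintf("sample '%s' listed more than once", dup))
  }
  unassigned <- setdiff(sample_ids, design$sample)
  if (length(unassigned)) {
    tftg_abort(
      "unassigned_sample",
      sprintf("unassigned sample(s) not in sheet: %s", paste(unassigned, collapse = ", "))
    )
  }
  extra <- setdiff(design$sample, sample_ids)
  if (length(extra)) {
    tftg_abort(
      "unknown_sample",
      sprintf("sheet sample(s) absent from matrix: %s", paste(extra, collapse = ", "))
    )
  }
  design <- design[match(sample_ids, design$sample), , drop = FALSE]
  if (require_cells) {
    cells <- table(design$treatment, design$phenotype)
    if (any(cells == 0L)) {
      tftg_abort("empty_cell", "each treatment x phenotype cell needs at least one sample")
    }
  }
  design
}

# Strip surrounding whitespace from identifiers; case is preserved.
strip_ws <- function(x) trimws(x, which = "both")
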