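#' Read an expression matrix and its sample sheet
#'
#' Reads a genes x samples TSV of log2 intensities together with a sample
#' sheet assigning each array to a treatment level, a phenotype level and a
#' replicate index, and cross-validates the two. Column order of the matrix is
#' preserved; the returned design rows are aligned to it.
#'
#' The matrix TSV has a header row of sample identifiers and gene identifiers
#' in the first column; tab-delimited, no quoting, decimal point only.
#' Missing or non-numeric cells are rejected rather than imputed. The sample
#' sheet TSV has columns `sample`, `treatment`, `phenotype`, `replicate`.
#' Treatment and phenotype must each have exactly two levels; the reference
#' level (untreated control, reference phenotype) defaults to the first level
#' in sheet order and can be fixed with `treatment_ref` / `phenotype_ref`.
#'
#' @param matrix_path Path to the expression TSV.
#' @param sample_sheet_path Path to the sample sheet TSV.
#' @param treatment_ref,phenotype_ref Optional reference level names.
#' @return A list with elements `matrix` (numeric matrix, genes x samples)
#'   and `design` (tibble with columns sample, treatment, phenotype,
#'   replicate; treatment and phenotype are two-level factors).
#' @examples
#' mat <- matrix(rnorm(24), 3, 8,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:8))
#' )
#' mp <- tempfile(fileext = ".tsv"); sp <- tempfile(fileext = ".tsv")
#' write.table(data.frame(gene = rownames(mat), mat),
#'   mp, sep = "\t", quote = FALSE, row.names = FALSE)
#' write.table(
#'   data.frame(
#'     sample = paste0("s", 1:8),
#'     treatment = rep(c("control", "irinotecan"), each = 4),
#'     phenotype = rep(c("NT", "CSC"), times = 4),
#'     replicate = rep(1:2, 4)
#'   ),
#'   sp, sep = "\t", quote = FALSE, row.names = FALSE
#' )
#' expt <- read_expression(mp, sp)
#' dim(expt$matrix)
#' @export
read_expression <- function(matrix_path, sample_sheet_path,
                            treatment_ref = NULL, phenotype_ref = NULL) {
  raw <- readr::read_tsv(
    matrix_path,
    col_types = readr::cols(
      readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE, locale = readr::locale(decimal_mark = ".")
  )
  if (ncol(raw) < 2L) {
    tftg_abort("matrix_shape", "expression TSV needs a gene column and >=1 sample column")
  }
  genes <- strip_ws(as.character(raw[[1L]]))
  vals <- raw[, -1L, drop = FALSE]
  bad <- vapply(vals, function(col) any(is.na(col)), logical(1L))
  if (any(bad)) {
    tftg_abort(
      "nonnumeric",
      sprintf(
        "non-numeric or missing cell(s) in sample column(s): %s",
        paste(names(vals)[bad], collapse = ", ")
      )
    )
  }
  mat <- as.matrix(vals)
  rownames(mat) <- genes
  colnames(mat) <- strip_ws(colnames(vals))
  check_expression_matrix(mat)

  sheet <- readr::read_tsv(
    sample_sheet_path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  names(sheet) <- tolower(names(sheet))
  design <- check_design(
    dplyr::mutate(sheet, sample = strip_ws(.data$sample)),
    colnames(mat),
    require_cells = FALSE
  )
  design <- tibble::tibble(
    sample = design$sample,
    treatment = two_level_factor(design$treatment, treatment_ref, "treatment"),
    phenotype = two_level_factor(design$phenotype, phenotype_ref, "phenotype"),
    replicate = as.integer(design$replicate)
  )
  if (any(is.na(design$replicate)) || any(design$replicate < 1L)) {
    tftg_abort("replicate_index", "replicate must be a positive integer")
  }
  list(matrix = mat, design = design)
}

#' Read a GMT gene-set collection
#'
#' Parses the standard MSigDB-style GMT dialect: one set per tab-separated
#' line with fields name, description, then member genes. Member lists are
#' whitespace-stripped and deduplicated; the order of sets is preserved.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set_name`, `description` and a list-column
#'   `genes` (character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble::tibble(
      set_name = character(), description = character(), genes = list()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    tftg_abort(
      "gmt_fields",
      sprintf("GMT line %d has fewer than 3 tab-separated fields", short[1L])
    )
  }
  set_name <- strip_ws(vapply(fields, `[[`, character(1L), 1L))
  if (anyDuplicated(set_name)) {
    dup <- set_name[duplicated(set_name)][1L]
    tftg_abort("duplicate_set", sprintf("duplicate set name: '%s'", dup))
  }
  genes <- lapply(fields, function(f) {
    g <- strip_ws(f[-(1:2)])
    unique(g[nzchar(g)])
  })
  empty <- which(lengths(genes) == 0L)
  if (length(empty)) {
    tftg_abort(
      "empty_set",
      sprintf("gene set '%s' has no members", set_name[empty[1L]])
    )
  }
  tibble::tibble(
    set_name = set_name,
    description = vapply(fields, `[[`, character(1L), 2L),
    genes = genes
  )
}

#' Write a gene-set collection to GMT
#'
#' @param sets Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(
      c(sets$set_name[i], sets$description[i], sets$genes[[i]]),
      collapse = "\t"
    )
  }, character(1L))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a probe-to-gene map
#'
#' Two-column TSV (`probe`, `gene`); a probe mapping to several genes appears
#' on several rows. Such "promiscuous" probes are excluded later by
#' [summarize_probes()].
#'
#' @param path Path to the map TSV.
#' @return A tibble with character columns `probe` and `gene`, one row per
#'   distinct probe-gene pair.
#' @export
read_probe_map <- function(path) {
  map <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  names(map) <- tolower(names(map))
  if (!all(c("probe", "gene") %in% names(map))) {
    tftg_abort("probe_map_columns", "probe map needs columns 'probe' and 'gene'")
  }
  out <- dplyr::distinct(
    tibble::tibble(
      probe = strip_ws(map$probe),
      gene = strip_ws(map$gene)
    )
  )
  if (any(!nzchar(out$gene))) {
    tftg_abort("empty_gene", "probe map contains an empty gene identifier")
  }
  out
}

#' Write a results table as TSV
#'
#' Writes any tabular result (enrichment records, fits, summaries) with a
#' header row, one row per record, in the order given, at full double
#' precision: numbers are serialized with the shortest representation that
#' round-trips exactly, so write-then-read is the identity on values.
#'
#' @param records A data frame of records sharing a schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  listcols <- vapply(records, is.list, logical(1L))
  records[listcols] <- lapply(records[listcols], function(col) {
    vapply(col, function(x) paste(x, collapse = ","), character(1L))
  })
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}
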