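#' Run the full differential-response analysis pipeline
#'
#' Wires the stages end to end — (simulate or load) -> preprocess -> fit the
#' interaction model -> select responsive tails -> gene-set enrichment ->
#' target-response summary — writing every stage's table plus a
#' machine-readable JSON manifest to an output directory. All randomness
#' flows from one top-level seed, so rerunning with the same configuration
#' reproduces identical result tables.
#'
#' The configuration is a flat list (or path to a YAML file) with keys:
#' \describe{
#'   \item{outdir}{Output directory (required unless passed as argument).}
#'   \item{seed}{Integer seed (default 1).}
#'   \item{simulation}{Optional list of [simulation_config()] arguments;
#'     when present the expression experiment is simulated and also written
#'     to the output directory.}
#'   \item{matrix, sample_sheet}{Paths to the expression TSV and sample
#'     sheet (used when no simulation block is given).}
#'   \item{probe_map}{Optional probe-map TSV; triggers probe
#'     summarization.}
#'   \item{gmt}{Path to the gene-set collection (required unless
#'     simulating, which generates its own).}
#'   \item{quantile, log2}{Logicals; apply the respective preprocessing
#'     step to loaded matrices (both default `FALSE`: input is assumed
#'     gene-level log2).}
#'   \item{fraction}{Responsive tail fraction (default 0.05).}
#'   \item{alpha}{TF significance cutoff (default 1e-5).}
#'   \item{universe_mode}{`"intersect"` or `"measured"` (default
#'     `"intersect"`).}
#'   \item{tf}{Factor whose targets drive the target-response stage;
#'     defaults to the top enrichment hit.}
#' }
#'
#' @param config List or path to a YAML file.
#' @param outdir Output directory; overrides `config$outdir`.
#' @param seed Integer seed; overrides `config$seed`.
#' @return Invisibly, the manifest list. Side effects: stage TSVs and
#'   `manifest.json` under `outdir`.
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) tftg_abort("config", "config must be a list or YAML path")
  outdir <- outdir %||% config$outdir
  if (is.null(outdir)) tftg_abort("config", "an output directory is required")
  seed <- as.integer(seed %||% config$seed %||% 1L)
  fraction <- config$fraction %||% 0.05
  alpha <- config$alpha %||% 1e-5
  universe_mode <- config$universe_mode %||% "intersect"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(
        sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = "tftg_error_stage", parent = e
      )
    })
  }
  out_path <- function(f) file.path(outdir, f)
  counts <- list()

  # --- inputs: simulate or load ------------------------------------------
  if (!is.null(config$simulation)) {
    expt <- stage("simulate", {
      sim_args <- config$simulation
      if (isTRUE(sim_args)) sim_args <- list()
      sim_args$seed <- seed
      simulate_experiment(do.call(simulation_config, sim_args))
    })
    mat <- expt$matrix
    design <- expt$design
    sets <- expt$sets
    write_results_table(
      tibble::tibble(gene = rownames(mat), as.data.frame(mat)),
      out_path("expression_matrix.tsv")
    )
    write_results_table(expt$design, out_path("sample_sheet.tsv"))
    write_gmt(sets, out_path("gene_sets.gmt"))
    write_results_table(expt$truth, out_path("truth.tsv"))
  } else {
    expt <- stage("load", {
      if (is.null(config$matrix) || is.null(config$sample_sheet)) {
        tftg_abort("config", "matrix and sample_sheet paths (or a simulation block) are required")
      }
      read_expression(config$matrix, config$sample_sheet,
        treatment_ref = config$treatment_ref,
        phenotype_ref = config$phenotype_ref
      )
    })
    mat <- expt$matrix
    design <- expt$design
    sets <- stage("enrich", {
      if (is.null(config$gmt)) tftg_abort("config", "a GMT path is required")
      read_gmt(config$gmt)
    })
    mat <- stage("preprocess", {
      probe_map <- if (!is.null(config$probe_map)) read_probe_map(config$probe_map)
      preprocess_expression(mat,
        probe_map = probe_map,
        quantile = isTRUE(config$quantile),
        log2 = isTRUE(config$log2)
      )
    })
  }
  rlang::inform(sprintf(
    "input: %d genes x %d samples; %d gene sets",
    nrow(mat), ncol(mat), nrow(sets)
  ))
  counts$genes <- nrow(mat)
  counts$samples <- ncol(mat)
  counts$gene_sets <- nrow(sets)

  # --- interaction model and responsive selection ------------------------
  fits <- stage("fit", fit_interactions(mat, design))
  write_results_table(fits, out_path("interaction_fits.tsv"))
  selection <- stage("select", rank_and_select(fits, fraction = fraction))
  write_results_table(
    tibble::as_tibble(selection), out_path("responsive_selection.tsv")
  )
  rlang::inform(sprintf(
    "fit %d genes; selected %d responsive (%d per tail)",
    nrow(fits), nrow(selection), attr(selection, "k")
  ))
  counts$fits <- nrow(fits)
  counts$responsive <- nrow(selection)

  # --- enrichment ---------------------------------------------------------
  enrichment <- stage("enrich", {
    rank_tfs(
      enrich_sets(selection, sets, measured = rownames(mat),
                  universe_mode = universe_mode),
      alpha = alpha
    )
  })
  write_results_table(enrichment, out_path("enrichment.tsv"))
  write_results_table(volcano_table(enrichment, alpha = alpha),
                      out_path("volcano.tsv"))
  tested <- sum(!enrichment$too_small)
  rlang::inform(sprintf(
    "enrichment: %d/%d sets tested, %d significant at p < %g",
    tested, nrow(enrichment), sum(enrichment$significant), alpha
  ))
  counts$sets_tested <- tested
  counts$sets_significant <- sum(enrichment$significant)
  top_hit <- enrichment$set_name[1L]

  # --- target response ----------------------------------------------------
  tf <- config$tf %||% top_hit
  target_stage <- stage("target-response", {
    idx <- match(tf, sets$set_name)
    if (is.na(idx)) {
      tftg_abort("config", sprintf("factor '%s' not in the collection", tf))
    }
    fc <- fold_changes(mat, design, targets = sets$genes[[idx]])
    list(fc = fc, summary = summarize_by_target(fc))
  })
  write_results_table(target_stage$fc, out_path("fold_changes.tsv"))
  write_results_table(target_stage$summary$summary, out_path("target_summary.tsv"))
  write_results_table(target_stage$summary$welch, out_path("target_welch.tsv"))
  rlang::inform(sprintf(
    "target response for '%s': delta of deltas = %.4f",
    tf, target_stage$summary$delta_of_deltas
  ))

  manifest <- list(
    package = "tftgenrich",
    version = as.character(utils::packageVersion("tftgenrich")),
    seed = seed,
    parameters = list(
      fraction = fraction, alpha = alpha, universe_mode = universe_mode,
      tf = tf, simulation = config$simulation
    ),
    counts = counts,
    top_hit = top_hit,
    top_hit_p = enrichment$p_value[1L],
    delta_of_deltas = target_stage$summary$delta_of_deltas,
    outputs = list.files(outdir, pattern = "\\.(tsv|gmt)$")
  )
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
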