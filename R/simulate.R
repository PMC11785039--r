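#' Configuration for the factorial expression simulator
#'
#' Defaults emulate the deposited microarray design the analysis was built
#' for: 8 arrays = 2 treatments x 2 phenotypes x 2 replicates of log2-scale
#' intensities; 10,000 genes; a compendium of 50 transcription factors with
#' 200 annotated targets each; and one active factor whose target program is
#' induced by treatment (`treatment_effect` = 1 log2 unit) in the reference
#' phenotype but dampened by `dampening` = 0.6 log2 units in the other — the
#' planted interaction the pipeline should recover. Non-target genes receive
#' small random main and interaction effects (`background_effect_sd`) so
#' tail selection is non-degenerate under the null; measurement noise is
#' Gaussian with `noise_sd` = 0.25 log2 units.
#'
#' @param n_genes Number of genes.
#' @param n_tfs Number of transcription-factor target sets.
#' @param targets_per_tf Targets annotated per factor.
#' @param overlap_fraction Fraction of each set drawn from a shared pool
#'   (0 = disjoint sets).
#' @param reps_per_cell Replicates per treatment x phenotype cell.
#' @param baseline_mean,baseline_sd Log2 baseline expression distribution.
#' @param treatment_effect Planted treatment effect on active-factor
#'   targets, log2 units.
#' @param dampening Planted reduction of that effect in the non-reference
#'   phenotype, log2 units (the true interaction is `-dampening`).
#' @param dampening_spread SD of per-target heterogeneity around the planted
#'   interaction (default 0: constant shift).
#' @param background_effect_sd SD of random `d`, `c`, `e` effects on
#'   non-target genes, log2 units.
#' @param noise_sd SD of per-measurement Gaussian noise, log2 units.
#' @param active_tf Name of the factor carrying the planted program.
#' @param seed Integer seed; every random draw flows from it.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 10000L, n_tfs = 50L,
                              targets_per_tf = 200L, overlap_fraction = 0,
                              reps_per_cell = 2L,
                              baseline_mean = 7, baseline_sd = 1.5,
                              treatment_effect = 1.0, dampening = 0.6,
                              dampening_spread = 0,
                              background_effect_sd = 0.25, noise_sd = 0.25,
                              active_tf = NULL, seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
    targets_per_tf = as.integer(targets_per_tf),
    overlap_fraction = overlap_fraction,
    reps_per_cell = as.integer(reps_per_cell),
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    treatment_effect = treatment_effect, dampening = dampening,
    dampening_spread = dampening_spread,
    background_effect_sd = background_effect_sd, noise_sd = noise_sd,
    active_tf = if (is.null(active_tf)) tf_names(n_tfs)[1L] else active_tf,
    seed = as.integer(seed)
  )
  counts <- c(cfg$n_genes, cfg$n_tfs, cfg$targets_per_tf, cfg$reps_per_cell)
  if (any(counts < 1L)) tftg_abort("config", "all counts must be positive")
  if (cfg$overlap_fraction < 0 || cfg$overlap_fraction > 1) {
    tftg_abort("config", "overlap_fraction must lie in [0, 1]")
  }
  sds <- c(cfg$baseline_sd, cfg$dampening_spread, cfg$background_effect_sd, cfg$noise_sd)
  if (any(sds < 0)) tftg_abort("config", "standard deviations must be >= 0")
  structure(cfg, class = "sim_config")
}

tf_names <- function(n) sprintf("TF%03d", seq_len(n))

#' Simulate a 2x2 factorial expression experiment with a planted program
#'
#' Draws per-gene truth (`mu`, `d`, `c`, `e`), builds the log2 expression
#' matrix as `x = mu + d [treated] + c [alt phenotype] + e [treated & alt] +
#' N(0, noise_sd)` per sample, and assembles the transcription-factor target
#' collection. Targets of the active factor carry `d = treatment_effect` and
#' `e = -dampening` (sign per the reference coding: their induction is
#' weaker in the non-reference phenotype); all other effects are background
#' draws centred at zero. The same config and seed reproduce the output
#' bit-for-bit.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @param seed Optional override of `config$seed`.
#' @return List: `matrix` (genes x samples log2 matrix), `design` (tibble),
#'   `sets` (gene-set tibble as from [read_gmt()]), `truth` (tibble of
#'   per-gene true parameters and target status) and `config`.
#' @export
simulate_experiment <- function(config = simulation_config(), seed = NULL) {
  cfg <- config
  if (!inherits(cfg, "sim_config")) tftg_abort("config", "config must be a sim_config")
  if (is.null(seed)) seed <- cfg$seed
  set.seed(seed)

  genes <- sprintf(paste0("gene%0", nchar(cfg$n_genes), "d"), seq_len(cfg$n_genes))
  tfs <- tf_names(cfg$n_tfs)
  if (!cfg$active_tf %in% tfs) {
    tftg_abort("config", "active_tf must be one of the simulated factors")
  }

  # target assignment: optionally a shared pool, remainder disjoint
  n_shared <- round(cfg$overlap_fraction * cfg$targets_per_tf)
  n_own <- cfg$targets_per_tf - n_shared
  if (n_own * cfg$n_tfs > cfg$n_genes) {
    tftg_abort(
      "too_many_targets",
      "targets_per_tf x n_tfs exceeds n_genes at this overlap fraction"
    )
  }
  shared_pool <- if (n_shared > 0) sample(genes, cfg$targets_per_tf) else character()
  own_pool <- sample(setdiff(genes, shared_pool))
  sets <- tibble::tibble(
    set_name = tfs,
    description = paste("simulated targets of", tfs),
    genes = purrr::map(seq_len(cfg$n_tfs), function(i) {
      own <- if (n_own > 0L) {
        own_pool[((i - 1L) * n_own + 1L):(i * n_own)]
      } else {
        character()
      }
      shared <- if (n_shared > 0) sample(shared_pool, n_shared) else character()
      sort(unique(c(own, shared)))
    })
  )
  targets <- sets$genes[[match(cfg$active_tf, tfs)]]
  is_target <- genes %in% targets

  truth <- tibble::tibble(
    gene = genes,
    mu = rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd),
    d = ifelse(is_target, cfg$treatment_effect,
               rnorm(cfg$n_genes, 0, cfg$background_effect_sd)),
    c = rnorm(cfg$n_genes, 0, cfg$background_effect_sd),
    e = ifelse(is_target,
               -cfg$dampening + rnorm(cfg$n_genes, 0, cfg$dampening_spread),
               rnorm(cfg$n_genes, 0, cfg$background_effect_sd)),
    is_target = is_target
  )

  design <- tidyr::expand_grid(
    phenotype = factor(c("NT", "CSC"), levels = c("NT", "CSC")),
    treatment = factor(c("control", "irinotecan"),
                       levels = c("control", "irinotecan")),
    replicate = seq_len(cfg$reps_per_cell)
  )
  design <- tibble::tibble(
    sample = sprintf("%s_%s_r%d", design$phenotype, design$treatment,
                     design$replicate),
    treatment = design$treatment,
    phenotype = design$phenotype,
    replicate = design$replicate
  )

  treated <- as.numeric(design$treatment == "irinotecan")
  alt <- as.numeric(design$phenotype == "CSC")
  signal <- cbind(1, treated, alt, treated * alt) # samples x 4
  mean_mat <- as.matrix(truth[, c("mu", "d", "c", "e")]) %*% t(signal)
  noise <- matrix(
    rnorm(length(mean_mat), 0, cfg$noise_sd),
    nrow = cfg$n_genes
  )
  mat <- mean_mat + noise
  dimnames(mat) <- list(genes, design$sample)

  cfg$seed <- as.integer(seed)
  list(matrix = mat, design = design, sets = sets, truth = truth, config = cfg)
}

#' Simulate caliper measurement series for a 2x2 xenograft experiment
#'
#' Generates per-tumor volume trajectories `V(t) = v0 * exp(k t) *
#' exp(N(0, noise_sd))` for each cell of a vector x treatment design, then
#' inverts the ellipsoid volume formula with `L = W = H` so that
#' [tumor_volume()] reproduces the simulated volumes exactly.
#'
#' @param n_per_cell Tumors per design cell.
#' @param rates Named numeric vector of per-day exponential rates, one per
#'   cell, names `"<vector>.<treatment>"` — e.g.
#'   `c(empty.saline = 0.20, empty.drug = 0.12, shRNA.saline = 0.20,
#'   shRNA.drug = 0.04)`.
#' @param v0 Common day-0 volume, mm^3 (> 0).
#' @param noise_sd SD of multiplicative log-volume noise.
#' @param days Measurement schedule (non-negative, strictly increasing).
#' @param seed Integer seed.
#' @return Measurement tibble: `tumor_id`, `vector`, `treatment`, `day`,
#'   `L`, `W`, `H` (mm).
#' @export
simulate_growth <- function(n_per_cell = 5L,
                            rates = c(
                              empty.saline = 0.20, empty.irinotecan = 0.12,
                              shRNA.saline = 0.20, shRNA.irinotecan = 0.04
                            ),
                            v0 = 100, noise_sd = 0.1,
                            days = seq(0, 24, by = 4), seed = 1L) {
  if (v0 <= 0) tftg_abort("config", "v0 must be positive")
  if (any(diff(days) <= 0)) tftg_abort("config", "days must be strictly increasing")
  parts <- strsplit(names(rates), ".", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    tftg_abort("config", "rates must be named '<vector>.<treatment>'")
  }
  set.seed(seed)
  cells <- tibble::tibble(
    vector = vapply(parts, `[[`, character(1L), 1L),
    treatment = vapply(parts, `[[`, character(1L), 2L),
    rate = unname(rates)
  )
  out <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    purrr::map_dfr(seq_len(n_per_cell), function(t_idx) {
      vol <- v0 * exp(cells$rate[i] * days) *
        exp(rnorm(length(days), 0, noise_sd))
      diam <- (6 * vol / pi)^(1 / 3)
      tibble::tibble(
        tumor_id = sprintf("%s_%s_t%d", cells$vector[i], cells$treatment[i], t_idx),
        vector = cells$vector[i],
        treatment = cells$treatment[i],
        day = days, L = diam, W = diam, H = diam
      )
    })
  })
  out
}
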