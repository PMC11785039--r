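# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately naive (enumeration, closed forms, textbook
# decompositions) and share no code with the implementation they check.

make_design <- function(r = 2L,
                        treat_levels = c("control", "drug"),
                        phen_levels = c("NT", "CSC")) {
  grid <- expand.grid(
    replicate = seq_len(r),
    treatment = treat_levels,
    phenotype = phen_levels,
    stringsAsFactors = FALSE
  )
  tibble::tibble(
    sample = sprintf("s%02d", seq_len(nrow(grid))),
    treatment = factor(grid$treatment, levels = treat_levels),
    phenotype = factor(grid$phenotype, levels = phen_levels),
    replicate = grid$replicate
  )
}

# interaction as an explicit difference-of-differences of cell means
dod_oracle <- function(values, design) {
  cm <- tapply(values, list(design$treatment, design$phenotype), mean)
  (cm[2L, 2L] - cm[1L, 2L]) - (cm[2L, 1L] - cm[1L, 1L])
}

# two-tailed Fisher exact p by exhaustive enumeration over all tables with
# the observed margins (probability-mass definition, 1e-7 relative slack)
fisher_enum_p <- function(a, b, cc, dd) {
  R <- a + b
  S <- a + cc
  N <- a + b + cc + dd
  support <- max(0L, R + S - N):min(R, S)
  probs <- dhyper(support, S, N - S, R)
  p_obs <- dhyper(a, S, N - S, R)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# naive quadratic Benjamini-Hochberg step-up
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, numeric(1L))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# textbook balanced two-way ANOVA sums-of-squares decomposition
anova_ss_oracle <- function(y, A, B) {
  A <- as.factor(A)
  B <- as.factor(B)
  gm <- mean(y)
  am <- tapply(y, A, mean)
  bm <- tapply(y, B, mean)
  cm <- tapply(y, list(A, B), mean)
  n_cell <- table(A, B)
  stopifnot(length(unique(c(n_cell))) == 1L) # balanced only
  n <- n_cell[1L, 1L]
  ss_a <- sum(table(A) * (am - gm)^2)
  ss_b <- sum(table(B) * (bm - gm)^2)
  dev <- sweep(sweep(cm, 1L, am, "-"), 2L, bm, "-") + gm
  ss_ab <- n * sum(dev^2)
  fitted <- cm[cbind(A, B)]
  ss_within <- sum((y - fitted)^2)
  df_resid <- length(y) - nlevels(A) * nlevels(B)
  f_ab <- (ss_ab / 1) / (ss_within / df_resid)
  list(
    ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab, ss_within = ss_within,
    F_interaction = f_ab,
    p_interaction = pf(f_ab, 1, df_resid, lower.tail = FALSE)
  )
}

# write a matrix + sheet pair to temp files, return the two paths
write_expt_files <- function(mat, design, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  mp <- file.path(dir, "matrix.tsv")
  sp <- file.path(dir, "sheet.tsv")
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(design), sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(matrix = mp, sheet = sp)
}

# small deterministic gene-set tibble
make_sets <- function(...) {
  sets <- list(...)
  tibble::tibble(
    set_name = names(sets),
    description = paste("set", names(sets)),
    genes = unname(sets)
  )
}
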