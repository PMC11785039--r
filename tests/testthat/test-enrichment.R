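test_that("fisher_enrichment handles the independence and zero-cell examples", {
  u <- paste0("g", 1:20)
  # responsive = 10 of 20, set of 4 with overlap 2: exactly the expected count
  rec <- fisher_enrichment(u[1:10], u[c(1, 2, 11, 12)], u)
  expect_equal(rec$odds_ratio, 1)
  expect_equal(rec$p_value, 1)
  expect_equal(unlist(rec[c("a", "b", "c", "d")]),
               c(a = 2, b = 8, c = 2, d = 8))

  # a = 5, b = 5, c = 0, d = 10 -> Haldane-Anscombe corrected OR = 21
  u2 <- paste0("g", 1:20)
  resp <- u2[1:10]
  set <- u2[1:5] # entirely responsive
  rec2 <- fisher_enrichment(resp, set, u2)
  expect_equal(unlist(rec2[c("a", "b", "c", "d")]),
               c(a = 5, b = 5, c = 0, d = 10))
  expect_equal(rec2$odds_ratio, 21.0)

  expect_error(fisher_enrichment(resp, character(), u2),
               class = "tftg_error_set_not_represented")
  expect_error(fisher_enrichment(resp, set, character()),
               class = "tftg_error_empty_universe")
  expect_error(fisher_enrichment(c(resp, "not_in_u"), set, u2),
               class = "tftg_error_responsive_outside_universe")
})

test_that("fisher p-values match exhaustive enumeration on small universes", {
  # sampled margin combinations up to universe 18; the full sweep to 25 runs
  # in the acceptance suite
  set.seed(9)
  for (rep in 1:60) {
    N <- sample(3:18, 1L)
    R <- sample(1:(N - 1L), 1L)
    S <- sample(1:(N - 1L), 1L)
    support <- max(0L, R + S - N):min(R, S)
    a <- support[sample.int(length(support), 1L)]
    u <- paste0("g", seq_len(N))
    resp <- u[seq_len(R)]
    set_genes <- c(head(resp, a), head(setdiff(u, resp), S - a))
    if (length(set_genes) == 0L) next
    rec <- fisher_enrichment(resp, set_genes, u)
    expect_equal(rec$p_value, fisher_enum_p(rec$a, rec$b, rec$c, rec$d),
                 tolerance = 1e-12)
  }
})

test_that("swapping the responsive and set roles leaves OR and p unchanged", {
  set.seed(10)
  u <- paste0("g", 1:40)
  resp <- sample(u, 12)
  set_genes <- sample(u, 9)
  r1 <- fisher_enrichment(resp, set_genes, u)
  r2 <- fisher_enrichment(set_genes, resp, u)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$odds_ratio, r2$odds_ratio, tolerance = 1e-12)
})

test_that("directional odds ratios resolve which tail carries a set", {
  fits <- tibble::tibble(gene = sprintf("g%03d", 1:100),
                         e = seq(-2, 2, length.out = 100))
  sel <- rank_and_select(fits, fraction = 0.1) # 10 per tail
  u <- fits$gene

  top_set <- responsive_genes(sel, "top")[1:5]
  d_top <- directional_enrichment(sel, top_set, u)
  expect_gt(d_top$or_top, d_top$or_bottom)

  middle_set <- fits$gene[45:54] # disjoint from both tails
  d_mid <- directional_enrichment(sel, middle_set, u)
  expect_lt(d_mid$or_all, 1)
  expect_lt(d_mid$or_top, 1)
  expect_lt(d_mid$or_bottom, 1)

  # or_all reproduces fisher_enrichment's OR on the union
  rec <- fisher_enrichment(responsive_genes(sel), middle_set, u)
  expect_equal(d_mid$or_all, rec$odds_ratio)
})

test_that("enrich_sets builds records per set with universe control", {
  fits <- tibble::tibble(gene = sprintf("g%03d", 1:100),
                         e = seq(-2, 2, length.out = 100))
  sel <- rank_and_select(fits, fraction = 0.1)
  sets <- make_sets(
    TFtop = responsive_genes(sel, "top"),
    TFnull = fits$gene[41:60],
    TFtiny = c(fits$gene[1L], "unmeasured_gene")
  )
  enr <- enrich_sets(sel, sets, measured = fits$gene, universe_mode = "measured")
  expect_equal(attr(enr, "universe_size"), 100L)
  expect_equal(enr$set_name, sets$set_name)
  expect_false(any(enr$too_small[1:2]))
  expect_true(enr$too_small[3L]) # one measured member < min size 2
  expect_true(is.na(enr$p_value[3L]))
  expect_gt(enr$odds_ratio[1L], enr$odds_ratio[2L])
  expect_equal(enr$a[1L] + enr$b[1L] + enr$c[1L] + enr$d[1L], 100L)

  # intersect mode shrinks the universe to genes covered by the collection
  enr2 <- enrich_sets(sel, sets, measured = fits$gene)
  expect_equal(attr(enr2, "universe_size"),
               length(intersect(fits$gene, unique(unlist(sets$genes)))))
})

test_that("rank_tfs orders by p with strict significance at the cutoff", {
  records <- tibble::tibble(
    set_name = c("B", "A", "C", "D"),
    p_value = c(1e-6, 1e-5, 1e-6, NA_real_),
    too_small = c(FALSE, FALSE, FALSE, TRUE)
  )
  ranked <- rank_tfs(records, alpha = 1e-5)
  expect_equal(ranked$set_name, c("B", "C", "A", "D")) # p asc, name breaks tie
  expect_equal(ranked$significant, c(TRUE, TRUE, FALSE, FALSE)) # 1e-5 not < 1e-5
  expect_equal(nrow(rank_tfs(records[0L, ])), 0L)
  expect_equal(rank_tfs(records[sample(4L), ]), ranked)
})

test_that("bh_qvalues matches the naive quadratic step-up definition", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  expect_equal(bh_qvalues(0.5), 0.5)
  expect_equal(bh_qvalues(c(0.04, 0.01)), c(0.04, 0.02))
  expect_error(bh_qvalues(c(0.5, 1.2)), class = "tftg_error_p_range")

  set.seed(12)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1L))^sample(1:3, 1L)
    expect_equal(bh_qvalues(p), naive_bh(p), tolerance = 1e-12)
  }

  # permutation equivariance
  p <- runif(25)
  perm <- sample(25L)
  expect_equal(bh_qvalues(p)[perm], bh_qvalues(p[perm]), tolerance = 1e-12)
})

test_that("volcano coordinates are finite with clipped significance", {
  records <- tibble::tibble(
    set_name = c("A", "B", "C", "D"),
    odds_ratio = c(1, 2, 0.5, 4),
    p_value = c(1, 0.5, 1e-320, NA_real_)
  )
  vt <- volcano_table(records, alpha = 1e-5)
  expect_equal(nrow(vt), 3L) # untested record dropped
  expect_equal(vt$log2_odds_ratio[1L], 0)
  expect_equal(vt$neg_log10_p[1L], 0)
  expect_equal(vt$neg_log10_p[3L], 300) # clipped
  expect_equal(vt$significant, c(FALSE, FALSE, TRUE))
  p <- plot_volcano(records)
  expect_s3_class(p, "ggplot")
})
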