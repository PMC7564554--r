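test_that("the generator is deterministic given a seed", {
  s1 <- tiny_sim(seed = 61)
  s2 <- tiny_sim(seed = 61)
  expect_identical(s1$counts$values, s2$counts$values)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$gene_sets$sets, s2$gene_sets$sets)
  expect_identical(s1$truth$de_genes, s2$truth$de_genes)
  s3 <- tiny_sim(seed = 62)
  expect_false(identical(s1$counts$values, s3$counts$values))
})

test_that("biotype counts and zero rows match the configuration", {
  cfg <- sim_config(n_genes = 1000, seed = 67)
  sim <- simulate_ball_cohort(cfg)
  tab <- table(sim$annotation$biotype)
  for (bt in names(cfg$biotype_proportions)) {
    n_bt <- if (bt %in% names(tab)) tab[[bt]] else 0L
    expect_lte(abs(n_bt - cfg$biotype_proportions[[bt]] * 1000), 1)
  }
  zero_rows <- rownames(sim$counts$values)[
    rowSums(sim$counts$values) == 0]
  expect_setequal(zero_rows, sim$truth$all_zero_ids)
  expect_equal(length(zero_rows), round(cfg$frac_all_zero * 1000))
})

test_that("module genes share one strict post-UQUA ordering per module", {
  sim <- tiny_sim(seed = 71)
  cm <- suppressMessages(filter_nonzero(sim$counts))
  uq <- uqua_normalize(cm)
  for (m in sim$truth$modules) {
    for (id in c(m$lnc_ids, m$mrna_ids)) {
      v <- uq$values[id, ]
      expect_false(anyDuplicated(v) > 0)
      expect_identical(order(v), m$ordering)
    }
    # the ordering splits the groups cleanly (module genes are DE)
    grp <- as.character(uq$group)[m$ordering]
    expect_equal(length(rle(grp)$lengths), 2)
  }
})

test_that("gene coordinates never overlap except for deliberate injections", {
  sim <- simulate_ball_cohort(
    sim_config(n_genes = 500, n_modules = 2, lnc_per_module = 1,
               mrna_per_module = 3, n_overlap_injections = 1,
               n_disease_sets = 1, n_background_sets = 1, seed = 73))
  gr <- annotation_granges(sim$annotation)
  GenomicRanges::strand(gr) <- "*"
  hits <- GenomicRanges::findOverlaps(gr, ignore.strand = TRUE,
                                      drop.self = TRUE,
                                      drop.redundant = TRUE)
  inj <- sim$truth$overlap_pairs
  expect_equal(length(hits), nrow(inj))
  expect_equal(nrow(inj), 1)
  got <- sort(c(gr$gene_id[S4Vectors::queryHits(hits)],
                gr$gene_id[S4Vectors::subjectHits(hits)]))
  expect_equal(got, sort(c(inj$lncRNA, inj$mRNA)))
})

test_that("the injected overlap is excluded from the network", {
  sim <- simulate_ball_cohort(
    sim_config(n_genes = 500, n_modules = 2, lnc_per_module = 1,
               mrna_per_module = 3, n_overlap_injections = 1,
               n_disease_sets = 1, n_background_sets = 1, seed = 73))
  res <- suppressMessages(suppressWarnings(
    run_all(sim$counts, sim$annotation)))
  net <- res$objects$network
  inj <- sim$truth$overlap_pairs
  expect_true(nrow(net$excluded) >= 1)
  expect_true(any(net$excluded$lncRNA == inj$lncRNA &
                    net$excluded$mRNA == inj$mRNA))
  expect_false(any(net$edges$lncRNA == inj$lncRNA &
                     net$edges$mRNA == inj$mRNA))
})

test_that("reference flips control concordance exactly at the extremes", {
  sim <- tiny_sim(seed = 79)
  truth_lfc <- setNames(sim$truth$de_genes$true_log2fc,
                        sim$truth$de_genes$gene_id)
  ref0 <- simulate_reference_de(sim$truth, 0, seed = 3)
  expect_equal(count_concordant(
    truth_lfc, setNames(ref0$table$log2FC, ref0$table$gene_id))$k,
    length(truth_lfc))
  ref1 <- simulate_reference_de(sim$truth, 1, seed = 3)
  expect_equal(count_concordant(
    truth_lfc, setNames(ref1$table$log2FC, ref1$table$gene_id))$k, 0)

  # intermediate flip fractions remove the chosen number of genes
  reff <- simulate_reference_de(sim$truth, 0.5, seed = 3)
  k <- count_concordant(
    truth_lfc, setNames(reff$table$log2FC, reff$table$gene_id))$k
  expect_equal(k, nrow(reff$table) - round(0.5 * nrow(reff$table)))
  expect_identical(simulate_reference_de(sim$truth, 0.5, seed = 3),
                   reff)
})

test_that("degenerate configurations are rejected or handled", {
  expect_error(sim_config(n_genes = -5))
  expect_error(sim_config(mrna_per_module = 2))
  expect_error(sim_config(module_within_ratio = 1))
  # proportions are normalized to sum to one
  cfg <- sim_config(biotype_proportions = c(protein_coding = 2,
                                            lincRNA = 1, other = 1))
  expect_equal(sum(cfg$biotype_proportions), 1)
  # a module-free null configuration still simulates
  null_sim <- simulate_ball_cohort(
    sim_config(n_genes = 300, n_modules = 0, n_disease_sets = 0,
               n_background_sets = 1, seed = 83))
  expect_equal(nrow(null_sim$truth$de_genes), 0)
  expect_equal(nrow(null_sim$counts$values), 300)
})
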