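# six-sample UQUA-scale matrix with two perfect partners and noise
perfect_pair_matrix <- function() {
  set.seed(6)
  ord <- c(3, 10, 25, 80, 160, 300)
  m <- rbind(lncA = ord,
             mr1 = ord * 2 + 1,          # same rank order
             mr2 = rev(ord),             # exactly reversed
             mr3 = c(3, 10, 25, 80, 300, 160),  # one swap: rho < 1
             mr4 = runif(6, 10, 400))
  colnames(m) <- paste0("s", 1:6)
  count_matrix(m, rep(c("healthy", "tumour"), each = 3), "uqua")
}

test_that("only perfect monotone pairs survive the default edge filter", {
  cm <- perfect_pair_matrix()
  net <- build_network(cm, "lncA", c("mr1", "mr2", "mr3", "mr4"))
  expect_setequal(net$edges$mRNA, c("mr1", "mr2"))
  expect_equal(abs(net$edges$rho), c(1, 1))
  expect_equal(net$edges$p, rep(2 / 720, 2))
  expect_equal(net$n_pairs_tested, 4L)
  # the reversed partner is dropped when only positive pairs are allowed
  pos <- build_network(cm, "lncA", c("mr1", "mr2", "mr3", "mr4"),
                       positive_only = TRUE)
  expect_setequal(pos$edges$mRNA, "mr1")
})

test_that("genomically overlapping pairs are excluded and logged", {
  cm <- perfect_pair_matrix()
  ann <- data.frame(gene_id = c("lncA", "mr1", "mr2"),
                    symbol = c("lncA", "mr1", "mr2"),
                    biotype = c("lincRNA", "protein_coding",
                                "protein_coding"),
                    chrom = c("chr1", "chr1", "chr2"),
                    start = c(100L, 150L, 150L),
                    end = c(200L, 300L, 300L),
                    strand = c("+", "-", "+"))
  expect_message(
    net <- build_network(cm, "lncA", c("mr1", "mr2"), ann = ann),
    "overlapping")
  expect_equal(nrow(net$excluded), 1L)
  expect_equal(net$excluded$mRNA, "mr1")
  expect_setequal(net$edges$mRNA, "mr2")
})

test_that("constant partners are skipped, and loosening cutoffs only adds edges", {
  cm <- perfect_pair_matrix()
  m <- rbind(cm$values, flat = rep(7, 6))
  cmf <- count_matrix(m, cm$group, "uqua")
  net <- build_network(cmf, "lncA", c("mr1", "mr3", "flat"))
  expect_equal(net$skipped$mRNA, "flat")

  strict <- build_network(cm, "lncA", c("mr1", "mr2", "mr3", "mr4"))
  loose <- build_network(cm, "lncA", c("mr1", "mr2", "mr3", "mr4"),
                         rho_min = 0.9, p_max = 0.02)
  key <- function(n) paste(n$edges$lncRNA, n$edges$mRNA)
  expect_true(all(key(strict) %in% key(loose)))
  expect_true("mr3" %in% loose$edges$mRNA)  # rho = 0.943, p = 12/720
})

test_that("the network is exactly bipartite with consistent degrees", {
  sim <- tiny_sim(seed = 29)
  res <- suppressMessages(suppressWarnings(
    run_all(sim$counts, sim$annotation, sim$gene_sets)))
  net <- res$objects$network
  g <- as_igraph_network(net)
  expect_true(igraph::bipartite_mapping(g)$res)
  deg <- igraph::degree(g)
  lncs <- unique(net$edges$lncRNA)
  expect_equal(sum(deg[lncs]), nrow(net$edges))
  expect_equal(sum(deg[setdiff(names(deg), lncs)]), nrow(net$edges))
})

test_that("lncRNA clusters follow shared co-expressed mRNAs", {
  ed <- edge_df(c("A", "A", "B", "B", "C"),
                c("m1", "m2", "m2", "m3", "m4"))
  cl <- cluster_lncrnas(fake_network(ed))
  expect_equal(cl$n_components, 2L)
  mem <- cl$membership
  expect_equal(mem$component[mem$lncRNA == "A"],
               mem$component[mem$lncRNA == "B"])
  expect_true(mem$acting_alone[mem$lncRNA == "C"])
  expect_false(any(mem$acting_alone[mem$lncRNA %in% c("A", "B")]))

  # identical neighbour sets share an exact-set group
  ed2 <- edge_df(c("A", "A", "B", "B"), c("m1", "m2", "m1", "m2"))
  cl2 <- cluster_lncrnas(fake_network(ed2))
  expect_equal(cl2$membership$exact_group[1], cl2$membership$exact_group[2])
})

test_that("planted modules come back as distinct clusters", {
  sim <- simulate_ball_cohort(
    sim_config(n_genes = 1200, n_modules = 3, lnc_per_module = 2,
               mrna_per_module = 3, seed = 37))
  res <- suppressMessages(suppressWarnings(
    run_all(sim$counts, sim$annotation)))
  cl <- res$objects$clusters
  expect_equal(cl$n_components, 3L)
  # each component is exactly one module's lncRNA pair
  comp_sets <- lapply(cl$components, sort)
  truth_sets <- lapply(sim$truth$modules, function(m) sort(m$lnc_ids))
  expect_setequal(vapply(comp_sets, paste, "", collapse = ","),
                  vapply(truth_sets, paste, "", collapse = ","))
})

test_that("pathway subnetwork censuses count nodes and edges correctly", {
  ed <- edge_df(c("A", "A", "B", "B", "C"),
                c("m1", "m2", "m2", "m3", "m4"))
  net <- fake_network(ed)
  empty <- pathway_subnetwork(net, c("zz1", "zz2"))
  expect_equal(unname(empty$census), c(0, 0, 0))
  full <- pathway_subnetwork(net, unique(ed$mRNA))
  expect_equal(unname(full$census), c(3, 4, 5))
  one <- pathway_subnetwork(net, c("m2"))
  expect_equal(unname(one$census), c(2, 1, 2))
})

test_that("pathway censuses on simulated data match the planted design", {
  sim <- tiny_sim(seed = 41)
  res <- suppressMessages(suppressWarnings(
    run_all(sim$counts, sim$annotation, sim$gene_sets)))
  net <- res$objects$network
  for (set_id in names(sim$truth$pathway_modules)) {
    mods <- sim$truth$pathway_modules[[set_id]]
    want_mrna <- unlist(lapply(sim$truth$modules[mods], `[[`, "mrna_ids"))
    want_lnc <- unlist(lapply(sim$truth$modules[mods], `[[`, "lnc_ids"))
    census <- pathway_subnetwork(net, sim$gene_sets$sets[[set_id]])$census
    expect_equal(unname(census["n_mrna"]), length(want_mrna))
    expect_equal(unname(census["n_lnc"]), length(want_lnc))
    expect_equal(unname(census["n_edges"]),
                 length(want_mrna) * length(want_lnc) /
                   length(mods))
  }
})
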