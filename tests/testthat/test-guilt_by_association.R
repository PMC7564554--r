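test_that("hypergeometric enrichment matches exhaustive enumeration", {
  universe <- paste0("u", 1:20)
  sets <- gene_set_collection(list(TERM = universe[1:4],
                                   OTHER = universe[10:15]))
  query <- c(universe[c(1, 2, 3)], universe[18:19])  # overlap 3 of 5
  res <- suppressMessages(hypergeom_enrich(query, sets, universe))
  p_term <- res$p[res$set_id == "TERM"]
  expect_equal(p_term, oracle_hyper_p(20, 4, 5, 3), tolerance = 1e-12)

  # zero overlap can never look enriched
  p_other <- res$p[res$set_id == "OTHER"]
  expect_equal(p_other, 1)
  expect_false(res$pass_log10p[res$set_id == "OTHER"])
  expect_false(res$pass_fdr[res$set_id == "OTHER"])
})

test_that("an exact query-term match is the most enriched set", {
  universe <- paste0("u", 1:100)
  sets <- gene_set_collection(list(EXACT = universe[1:6],
                                   HALF = universe[c(1:3, 50:52)],
                                   NONE = universe[80:90]))
  res <- suppressMessages(hypergeom_enrich(universe[1:6], sets, universe))
  expect_equal(res$set_id[1], "EXACT")
  expect_true(res$p[res$set_id == "EXACT"] <
                res$p[res$set_id == "HALF"])
  # query genes outside the universe are dropped with a message
  expect_message(hypergeom_enrich(c(universe[1:3], "alien"), sets,
                                  universe), "not in universe")
})

test_that("Cohen's kappa matches a contingency-table recomputation", {
  pop <- paste0("g", 1:40)
  expect_equal(cohen_kappa(pop[1:10], pop[1:10], pop), 1)
  expect_lt(cohen_kappa(pop[1:10], pop[11:20], pop), 0)
  set.seed(53)
  for (i in 1:20) {
    a <- sample(pop, sample(3:20, 1))
    b <- sample(pop, sample(3:20, 1))
    expect_equal(cohen_kappa(a, b, pop), oracle_kappa(a, b, pop),
                 tolerance = 1e-12)
  }
})

test_that("the kappa term graph links redundant terms into clusters", {
  universe <- paste0("u", 1:200)
  sets <- gene_set_collection(list(T1 = universe[1:10],
                                   T2 = universe[1:10],
                                   T3 = universe[100:110]))
  res <- suppressMessages(
    hypergeom_enrich(universe[1:10], sets, universe))
  kg <- kappa_term_graph(res, filter = "fdr")
  expect_true(all(c("T1", "T2") %in% kg$terms))
  expect_equal(kg$edges$kappa, 1)
  expect_setequal(unlist(kg$edges[, c("term_a", "term_b")]), c("T1", "T2"))

  thin <- res[res$set_id == "T1", ]
  class(thin) <- class(res)
  expect_warning(expect_null(kappa_term_graph(thin)), "fewer than 2")
})

test_that("lncRNA function assignment follows its co-expressed mRNAs", {
  ed <- edge_df(c("A", "B", "B", "C"), c("m1", "m1", "m2", "m9"))
  net <- fake_network(ed)
  universe <- c(paste0("m", 1:20), paste0("x", 1:80))
  sets <- gene_set_collection(list(DIS1 = c("m1", "m2", "x1"),
                                   DIS2 = c("m9", "x2", "x3"),
                                   BG = paste0("x", 4:13)))
  gba <- assign_lnc_functions(net, sets, universe,
                              disease_set_ids = c("DIS1", "DIS2"))
  asn <- gba$assignments
  expect_equal(asn$disease_sets[asn$lncRNA == "A"], "DIS1")
  expect_equal(asn$disease_sets[asn$lncRNA == "C"], "DIS2")
  expect_equal(asn$disease_sets[asn$lncRNA == "B"], "DIS1")
  expect_equal(gba$n_in_disease_sets, 3)
  # m1 is shared between A and B; m2 and m9 are unique
  expect_equal(asn$n_shared_mrna[asn$lncRNA == "A"], 1)
  expect_equal(asn$n_unique_mrna[asn$lncRNA == "B"], 1)
  expect_equal(gba$overlap_links$n_shared, 1)
  expect_setequal(unlist(gba$overlap_links[, c("lnc_a", "lnc_b")]),
                  c("A", "B"))

  # identical neighbour lists give identical assignments plus a link
  ed2 <- edge_df(c("P", "P", "Q", "Q"), c("m1", "m2", "m1", "m2"))
  gba2 <- assign_lnc_functions(fake_network(ed2), sets, universe,
                               disease_set_ids = c("DIS1", "DIS2"))
  a2 <- gba2$assignments
  expect_equal(a2$disease_sets[1], a2$disease_sets[2])
  expect_equal(a2$assigned_terms[1], a2$assigned_terms[2])
  expect_equal(nrow(gba2$overlap_links), 1)
  expect_error(assign_lnc_functions(net, sets, universe,
                                    disease_set_ids = "NOPE"), "NOPE")
})

test_that("assignments on simulated data match the planted pathway design", {
  sim <- tiny_sim(seed = 59)
  res <- suppressMessages(suppressWarnings(
    run_all(sim$counts, sim$annotation, sim$gene_sets,
            disease_set_ids = grep("^DISEASE",
                                   names(sim$gene_sets$sets),
                                   value = TRUE))))
  gba <- res$objects$gba
  for (i in seq_along(sim$truth$modules)) {
    m <- sim$truth$modules[[i]]
    owner <- names(Filter(function(mods) i %in% mods,
                          sim$truth$pathway_modules))
    for (l in m$lnc_ids) {
      got <- gba$assignments$disease_sets[gba$assignments$lncRNA == l]
      expect_true(all(owner %in% strsplit(got, ",")[[1]]))
    }
  }
  # rerunning the assignment is a pure function of its inputs
  gba2 <- assign_lnc_functions(res$objects$network, sim$gene_sets,
                               res$objects$partition$pcg_ids,
                               disease_set_ids =
                                 grep("^DISEASE",
                                      names(sim$gene_sets$sets),
                                      value = TRUE))
  expect_equal(gba2$assignments, gba$assignments)
})
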