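test_that("count TSV round-trip preserves ids and values", {
  cm <- toy_counts()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(cm, path)
  back <- read_counts(path, c(s1 = "healthy", s2 = "tumour"))
  expect_identical(dim(back), c(3L, 2L))
  expect_equal(back$values, cm$values)
  expect_equal(as.character(back$group), as.character(cm$group))

  set.seed(1)
  m <- matrix(rpois(60, 20), 10, 6,
              dimnames = list(paste0("G", 1:10), paste0("S", 1:6)))
  cm2 <- count_matrix(m, rep(c("healthy", "tumour"), each = 3))
  write_counts(cm2, path)
  gm <- setNames(as.character(cm2$group), colnames(m))
  expect_equal(read_counts(path, gm)$values, m)
})

test_that("malformed count input is rejected with a useful error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), path)
  expect_error(read_counts(path, c(s1 = "healthy", s2 = "tumour")), "gA")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\tx", "gB\t3\t4"), path)
  expect_error(read_counts(path, c(s1 = "healthy", s2 = "tumour")),
               "non-numeric")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2"), path)
  expect_error(read_counts(path, c(s1 = "healthy")), "without group")
  m <- matrix(1.5, 1, 1, dimnames = list("g", "s"))
  expect_error(count_matrix(m, "healthy"), "integers")
})

test_that("BioMart TSV and GTF annotation dialects agree", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsymbol\tbiotype\tchrom\tstart\tend\tstrand",
               "ENSG1\tFOO\tlincRNA\tchr2\t100\t200\t+",
               "ENSG2\tBAR\tprotein_coding\tchr3\t500\t900\t-"), tsv)
  a_tsv <- read_annotation(tsv, "biomart_tsv")
  expect_equal(a_tsv$start, c(100L, 500L))
  expect_equal(a_tsv$end, c(200L, 900L))

  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr2\ttest\tgene\t100\t200\t.\t+\t.\t",
           'gene_id "ENSG1"; gene_name "FOO"; gene_biotype "lincRNA";'),
    paste0("chr3\ttest\tgene\t500\t900\t.\t-\t.\t",
           'gene_id "ENSG2"; gene_name "BAR"; gene_biotype "protein_coding";'),
    paste0("chr3\ttest\texon\t500\t600\t.\t-\t.\t",
           'gene_id "ENSG2"; gene_biotype "protein_coding";')), gtf)
  a_gtf <- read_annotation(gtf, "gtf")
  expect_equal(a_gtf[order(a_gtf$gene_id), ],
               a_tsv[order(a_tsv$gene_id), ],
               ignore_attr = TRUE)
})

test_that("invalid annotations are rejected", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsymbol\tbiotype\tchrom\tstart\tend\tstrand",
               "ENSGX\tZ\tlincRNA\tchr1\t201\t200\t+"), tsv)
  expect_error(read_annotation(tsv, "biomart_tsv"), "ENSGX")
  writeLines(c("gene_id\tsymbol\tchrom\tstart\tend\tstrand",
               "ENSGX\tZ\tchr1\t100\t200\t+"), tsv)
  expect_error(read_annotation(tsv, "biomart_tsv"), "biotype")
})

test_that("biotype partition is a disjoint cover with correct percentages", {
  ann <- data.frame(gene_id = paste0("g", 1:10),
                    symbol = paste0("s", 1:10),
                    biotype = c(rep("protein_coding", 7),
                                rep("lincRNA", 3)),
                    chrom = "chr1", start = 1:10 * 100,
                    end = 1:10 * 100 + 50, strand = "+")
  part <- partition_by_biotype(ann)
  expect_equal(part$summary$percent[part$summary$class == "protein_coding"],
               70)
  expect_equal(part$summary$percent[part$summary$class == "lncRNA"], 30)
  expect_length(intersect(part$lnc_ids, part$pcg_ids), 0)
  expect_setequal(c(part$lnc_ids, part$pcg_ids, part$other_ids),
                  ann$gene_id)

  ann$biotype[1] <- "weird_novel_class"
  part2 <- partition_by_biotype(ann)
  expect_true(ann$gene_id[1] %in% part2$other_ids)
})

test_that("partition of a simulated annotation reproduces the generator's proportions", {
  sim <- tiny_sim()
  part <- partition_by_biotype(sim$annotation)
  props <- sim$truth$config$biotype_proportions
  expect_equal(part$summary$percent[part$summary$class == "protein_coding"],
               100 * props[["protein_coding"]], tolerance = 0.01)
  lnc_expected <- 100 * sum(props[default_lnc_biotypes()])
  expect_equal(part$summary$percent[part$summary$class == "lncRNA"],
               lnc_expected, tolerance = 0.02)
})

test_that("GMT round-trip is lossless and empty sets are skipped", {
  gsc <- gene_set_collection(list(SET1 = c("a", "b", "c"),
                                  SET2 = c("d", "e", "f")),
                             c(SET1 = "first", SET2 = "second"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gsc, path)
  back <- read_gmt(path)
  expect_equal(back$sets, gsc$sets)
  expect_equal(back$names, gsc$names)

  writeLines(c("SETA\tdesc\tx\ty", "EMPTY\tdesc"), path)
  expect_warning(g2 <- read_gmt(path), "EMPTY")
  expect_named(g2$sets, "SETA")
})

test_that("edge export writes one row per edge", {
  ed <- edge_df(rep(c("l1", "l2"), c(7, 6)), paste0("m", 1:13))
  net <- fake_network(ed)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edges(net, path)
  out <- read.delim(path)
  expect_equal(nrow(out), 13)
  expect_named(out, c("lncRNA", "mRNA", "rho", "p", "overlap_excluded",
                      "direction_consistent"))
})
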