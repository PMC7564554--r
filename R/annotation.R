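#' Read a gene annotation table
#'
#' Loads per-gene biotype and genomic coordinates from either a
#' BioMart-style TSV export or a GTF file. Coordinates are 1-based
#' inclusive (GTF convention) in both dialects.
#'
#' The TSV dialect expects a header with columns `gene_id`, `symbol`,
#' `biotype`, `chrom`, `start`, `end`, `strand` (extra columns ignored).
#' The GTF dialect keeps only `gene` features and reads the `gene_id`,
#' `gene_name` and `gene_biotype` attributes.
#'
#' @param path file path.
#' @param dialect `"biomart_tsv"` or `"gtf"`.
#' @return data.frame with columns `gene_id`, `symbol`, `biotype`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
read_annotation <- function(path, dialect = c("biomart_tsv", "gtf")) {
  dialect <- match.arg(dialect)
  ann <- switch(dialect,
    biomart_tsv = {
      df <- utils::read.delim(path, header = TRUE, sep = "\t",
                              check.names = FALSE,
                              stringsAsFactors = FALSE)
      need <- c("gene_id", "symbol", "biotype", "chrom", "start", "end",
                "strand")
      miss <- setdiff(need, colnames(df))
      if (length(miss))
        stop("annotation TSV lacks column(s): ", paste(miss, collapse = ", "))
      df[need]
    },
    gtf = {
      gr <- rtracklayer::import(path, format = "gtf")
      gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
      if (!length(gr)) stop("GTF contains no 'gene' features")
      if (is.null(gr$gene_biotype))
        stop("GTF gene features lack a gene_biotype attribute")
      sym <- if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
      data.frame(gene_id = gr$gene_id,
                 symbol = ifelse(is.na(sym), gr$gene_id, sym),
                 biotype = gr$gene_biotype,
                 chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr),
                 end = GenomicRanges::end(gr),
                 strand = as.character(GenomicRanges::strand(gr)),
                 stringsAsFactors = FALSE)
    })
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  ann$start <- as.integer(ann$start)
  ann$end <- as.integer(ann$end)
  dup <- unique(ann$gene_id[duplicated(ann$gene_id)])
  if (length(dup)) stop("duplicate gene ids in annotation: ",
                        paste(dup, collapse = ", "))
  if (any(is.na(ann$biotype) | !nzchar(ann$biotype)))
    stop("empty biotype for gene(s): ",
         paste(ann$gene_id[is.na(ann$biotype) | !nzchar(ann$biotype)],
               collapse = ", "))
  bad <- ann$gene_id[ann$start > ann$end]
  if (length(bad)) stop("start > end for gene(s): ",
                        paste(bad, collapse = ", "))
  ann$strand[!ann$strand %in% c("+", "-")] <- "."
  rownames(ann) <- NULL
  ann
}

#' Write an annotation table in the BioMart-style TSV dialect
#'
#' @param ann annotation data.frame as returned by [read_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert an annotation table to GRanges
#'
#' @param ann annotation data.frame.
#' @return A `GRanges` with `gene_id`, `symbol` and `biotype` metadata.
#' @export
annotation_granges <- function(ann) {
  GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end),
    strand = ifelse(ann$strand %in% c("+", "-"), ann$strand, "*"),
    gene_id = ann$gene_id, symbol = ann$symbol, biotype = ann$biotype)
}

#' Default long non-coding biotype classes
#'
#' Biotype strings counted as lncRNA by [partition_by_biotype()]. Ensembl
#' renamed several of these classes across releases, which is why the
#' list is configurable rather than hard-wired.
#'
#' @return character vector of biotype names.
#' @export
default_lnc_biotypes <- function() {
  c("antisense", "lincRNA", "processed_transcript", "sense_intronic",
    "sense_overlapping", "3prime_overlapping_ncRNA")
}

#' Partition annotated genes into lncRNA / protein-coding / other classes
#'
#' @param ann annotation data.frame.
#' @param lnc_biotypes biotype strings counted as lncRNA.
#' @param pcg_biotypes biotype strings counted as protein coding.
#' @return list with `lnc_ids`, `pcg_ids`, `other_ids` and `summary`, a
#'   data.frame of per-class gene counts and percentages of annotated genes.
#' @export
partition_by_biotype <- function(ann,
                                 lnc_biotypes = default_lnc_biotypes(),
                                 pcg_biotypes = "protein_coding") {
  cls <- ifelse(ann$biotype %in% lnc_biotypes, "lncRNA",
         ifelse(ann$biotype %in% pcg_biotypes, "protein_coding", "other"))
  lnc_ids <- ann$gene_id[cls == "lncRNA"]
  pcg_ids <- ann$gene_id[cls == "protein_coding"]
  other_ids <- ann$gene_id[cls == "other"]
  if (!length(lnc_ids)) warning("no lncRNA genes in annotation")
  if (!length(pcg_ids)) warning("no protein-coding genes in annotation")
  tab <- table(factor(cls, levels = c("protein_coding", "lncRNA", "other")))
  summary <- data.frame(class = names(tab),
                        n = as.integer(tab),
                        percent = 100 * as.integer(tab) / nrow(ann))
  by_bt <- table(ann$biotype)
  list(lnc_ids = lnc_ids, pcg_ids = pcg_ids, other_ids = other_ids,
       summary = summary,
       biotype_counts = data.frame(biotype = names(by_bt),
                                   n = as.integer(by_bt),
                                   percent = 100 * as.integer(by_bt) /
                                     nrow(ann)))
}
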