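de_status <- function(log2fc, padj, t_log2fc, alpha) {
  ifelse(padj <= alpha & log2fc >= t_log2fc, "up",
  ifelse(padj <= alpha & log2fc <= -t_log2fc, "down", "not_de"))
}

#' Ingest an externally computed differential-expression table
#'
#' Reads a TSV with columns `gene_id`, `log2FC`, `padj` and assigns the
#' up / down / not_de status by the |log2FC| and adjusted-p thresholds.
#'
#' @param path TSV file path.
#' @param t_log2fc absolute log2 fold-change threshold (default 1.5).
#' @param alpha adjusted p-value threshold (default 0.05).
#' @return A `de_table` data.frame: `gene_id`, `log2FC`, `padj`,
#'   `mean_group_a`, `mean_group_b` (NA when absent from the file),
#'   `status`.
#' @export
ingest_de_table <- function(path, t_log2fc = 1.5, alpha = 0.05) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "log2FC", "padj")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("DE table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(df$padj < 0 | df$padj > 1, na.rm = TRUE))
    stop("padj outside [0, 1]")
  out <- data.frame(gene_id = df$gene_id, log2FC = df$log2FC,
                    padj = df$padj,
                    mean_group_a =
                      if ("mean_group_a" %in% colnames(df))
                        df$mean_group_a else NA_real_,
                    mean_group_b =
                      if ("mean_group_b" %in% colnames(df))
                        df$mean_group_b else NA_real_,
                    stringsAsFactors = FALSE)
  out$status <- de_status(out$log2FC, out$padj, t_log2fc, alpha)
  class(out) <- c("de_table", class(out))
  attr(out, "thresholds") <- c(t_log2fc = t_log2fc, alpha = alpha)
  out
}

#' Internal two-group differential expression
#'
#' Self-contained stand-in for an external DE step so that synthetic runs
#' need no download: log2 fold changes are computed from UQUA-normalized
#' group means with a pseudocount of 1 (guarding near-zero means), p-values
#' from a two-sided Welch t-test on VST values, and adjusted p-values by
#' Benjamini-Hochberg.
#'
#' @param cm_vst [count_matrix] in `vst` state.
#' @param cm_uqua [count_matrix] in `uqua` state, same genes and samples.
#' @param reference group label treated as baseline (denominator of the
#'   fold change); defaults to `"healthy"` when present, otherwise the
#'   first factor level.
#' @param t_log2fc,alpha status thresholds as in [ingest_de_table()].
#' @return A `de_table` data.frame (see [ingest_de_table()]); `mean_group_a`
#'   is the reference (baseline) UQUA mean, `mean_group_b` the contrast.
#' @export
internal_de <- function(cm_vst, cm_uqua, reference = NULL,
                        t_log2fc = 1.5, alpha = 0.05) {
  stopifnot(inherits(cm_vst, "count_matrix"),
            inherits(cm_uqua, "count_matrix"))
  if (!identical(rownames(cm_vst$values), rownames(cm_uqua$values)) ||
      !identical(colnames(cm_vst$values), colnames(cm_uqua$values)))
    stop("VST and UQUA matrices must share genes and samples")
  grp <- cm_vst$group
  if (nlevels(grp) != 2) stop("internal_de needs exactly two groups")
  if (any(tabulate(grp) < 2)) stop("need >= 2 samples per group")
  if (is.null(reference))
    reference <- if ("healthy" %in% levels(grp)) "healthy" else
      levels(grp)[1L]
  if (!reference %in% levels(grp)) stop("unknown reference group")
  contrast <- setdiff(levels(grp), reference)
  a <- grp == reference; b <- grp == contrast

  mean_a <- rowMeans(cm_uqua$values[, a, drop = FALSE])
  mean_b <- rowMeans(cm_uqua$values[, b, drop = FALSE])
  log2fc <- log2((mean_b + 1) / (mean_a + 1))

  va <- cm_vst$values[, a, drop = FALSE]
  vb <- cm_vst$values[, b, drop = FALSE]
  na <- sum(a); nb <- sum(b)
  ma <- rowMeans(va); mb <- rowMeans(vb)
  s2a <- apply(va, 1, stats::var); s2b <- apply(vb, 1, stats::var)
  se2 <- s2a / na + s2b / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((s2a / na)^2 / (na - 1) + (s2b / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate rows: no variance in either group
  degen <- se2 == 0
  p[degen] <- ifelse(ma[degen] == mb[degen], 1,
                     0)  # equal constants -> no evidence; distinct -> exact
  p[is.na(p)] <- 1
  padj <- stats::p.adjust(p, method = "BH")

  out <- data.frame(gene_id = rownames(cm_vst$values), log2FC = log2fc,
                    padj = padj, mean_group_a = mean_a, mean_group_b = mean_b,
                    pvalue = p, stringsAsFactors = FALSE)
  out$status <- de_status(out$log2FC, out$padj, t_log2fc, alpha)
  rownames(out) <- NULL
  class(out) <- c("de_table", class(out))
  attr(out, "thresholds") <- c(t_log2fc = t_log2fc, alpha = alpha)
  attr(out, "contrast") <- c(reference = reference, contrast = contrast)
  out
}

#' Intersect PCA-selected lncRNAs with differentially expressed lncRNAs
#'
#' The candidate set is the intersection of the PCA-based selection with
#' the DE lncRNAs. Candidates are ranked by log2 fold change within each
#' direction (down-regulated by increasing log2FC, up-regulated by
#' decreasing), mirroring the usual candidate-table layout.
#'
#' @param pca_selected character vector of PCA-selected lncRNA ids.
#' @param de a `de_table`.
#' @param lnc_ids character vector of lncRNA gene ids (biotype partition).
#' @return A `candidate_set`: list with `candidates` (ranked data.frame of
#'   gene_id, log2FC, padj, direction), `pca_selected`, `de_lnc`,
#'   `n_up`, `n_down`.
#' @export
intersect_candidates <- function(pca_selected, de, lnc_ids) {
  stopifnot(is.character(pca_selected), inherits(de, "data.frame"))
  de_lnc <- de$gene_id[de$status != "not_de" & de$gene_id %in% lnc_ids]
  ids <- intersect(pca_selected, de_lnc)
  if (!length(ids)) warning("empty candidate set")
  sub <- de[match(ids, de$gene_id), c("gene_id", "log2FC", "padj", "status")]
  names(sub)[names(sub) == "status"] <- "direction"
  down <- sub[sub$direction == "down", , drop = FALSE]
  up <- sub[sub$direction == "up", , drop = FALSE]
  down <- down[order(down$log2FC), , drop = FALSE]
  up <- up[order(-up$log2FC), , drop = FALSE]
  cand <- rbind(down, up)
  rownames(cand) <- NULL
  structure(list(candidates = cand,
                 pca_selected = pca_selected,
                 de_lnc = de_lnc,
                 n_up = nrow(up), n_down = nrow(down)),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d candidates (%d down, %d up)\n",
              nrow(x$candidates), x$n_down, x$n_up))
  invisible(x)
}
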