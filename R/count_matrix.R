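#' Construct a gene x sample count matrix object
#'
#' The central expression container of the pipeline: a numeric gene x sample
#' matrix together with a per-sample group label and a record of which
#' normalization has been applied. Raw matrices must hold non-negative
#' integers; `uqua` (upper-quartile normalized) and `vst`
#' (variance-stabilized) matrices hold reals.
#'
#' @param values numeric matrix, genes in rows, samples in columns; both
#'   dimensions must carry unique names (gene ids / sample ids).
#' @param group character or factor of per-sample group labels, length
#'   `ncol(values)`. Typically `"healthy"` / `"tumour"`.
#' @param normalization one of `"raw"`, `"uqua"`, `"vst"`.
#' @return An object of class `count_matrix`: a list with elements
#'   `values`, `group` (named factor) and `normalization`.
#' @export
count_matrix <- function(values, group,
                         normalization = c("raw", "uqua", "vst")) {
  normalization <- match.arg(normalization)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have row (gene) and column (sample) names")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  if (any(!is.finite(values)))
    stop("'values' contains non-finite entries")
  if (normalization == "raw") {
    if (any(values < 0) || any(values != round(values)))
      stop("raw counts must be non-negative integers")
  }
  if (length(group) != ncol(values))
    stop("'group' must have one label per sample")
  group <- factor(as.character(group))
  names(group) <- colnames(values)
  structure(list(values = values, group = group,
                 normalization = normalization),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$normalization))
  cat("groups:", paste(sprintf("%s=%d", levels(x$group),
                               tabulate(x$group)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

# replace the value matrix, keeping sample metadata; used by normalizers
set_values <- function(cm, values, normalization) {
  count_matrix(values, cm$group[colnames(values)], normalization)
}

#' Read a count matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#'
#' @param path file path of a tab-separated count table.
#' @param group_map named character vector mapping sample id -> group label;
#'   every sample in the file must be covered.
#' @return A [count_matrix] in `raw` state.
#' @export
read_counts <- function(path, group_map) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("count table needs a gene id column plus samples")
  gene_ids <- df[[1L]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) stop("duplicate gene ids: ", paste(dup, collapse = ", "))
  samples <- colnames(df)[-1L]
  vals <- matrix(NA_real_, nrow(df), length(samples),
                 dimnames = list(gene_ids, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) & !is.na(df[[j + 1L]]))
    if (length(bad))
      stop(sprintf("non-numeric count at row %d (gene %s), column '%s'",
                   bad[1L], gene_ids[bad[1L]], samples[j]))
    if (anyNA(v))
      stop(sprintf("missing count in column '%s'", samples[j]))
    vals[, j] <- v
  }
  missing <- setdiff(samples, names(group_map))
  if (length(missing))
    stop("samples without group label: ", paste(missing, collapse = ", "))
  count_matrix(vals, unname(group_map[samples]), "raw")
}

#' Write a count matrix as TSV
#'
#' Inverse of [read_counts()]: first column `gene_id`, then one column per
#' sample.
#'
#' @param cm a [count_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(gene_id = rownames(cm$values), cm$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
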