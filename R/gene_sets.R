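#' Read gene sets in GMT format
#'
#' GMT lines are `set_id TAB description TAB member TAB member ...`.
#' Lines without members are skipped with a warning; member ids are
#' de-duplicated within each set.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: list with `sets` (named list of
#'   character vectors) and `names` (named character vector of set
#'   descriptions).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); descs <- character()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    members <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (length(f) < 3 || !length(members)) {
      warning("skipping empty gene set line: ", f[1L])
      next
    }
    sets[[f[1L]]] <- members
    descs[f[1L]] <- f[2L]
  }
  gene_set_collection(sets, descs)
}

#' Construct a gene set collection
#'
#' @param sets named list of character vectors of member gene ids.
#' @param names optional named character vector of set descriptions.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, names = NULL) {
  if (!length(sets) || is.null(base::names(sets)))
    stop("'sets' must be a non-empty named list")
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (any(!lengths(sets))) stop("every gene set must be non-empty")
  if (is.null(names)) {
    names <- base::names(sets)
    base::names(names) <- base::names(sets)
  }
  structure(list(sets = sets, names = names[base::names(sets)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, %d distinct genes\n",
              length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}

#' Write gene sets in GMT format
#'
#' @param gsc a `gene_set_collection`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(id) {
    paste(c(id, gsc$names[[id]], gsc$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
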