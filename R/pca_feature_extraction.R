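#' Principal component analysis of samples in feature space
#'
#' Centers each gene across samples (no unit scaling: the VST input already
#' equalizes variances) and decomposes the sample x gene matrix by SVD.
#' With `s` samples at most `s - 1` eigenvalues are non-zero.
#'
#' @param cm [count_matrix], typically VST-transformed and restricted to
#'   lncRNAs via `features`.
#' @param features optional character vector of gene ids to restrict to.
#' @return A `pca_selection`: list with `scores` (sample x PC), `eigenvalues`
#'   (variance per PC), `explained_fraction`, `cumulative_fraction`,
#'   `loadings` (gene x PC), `group`, `k_selected` (NA until
#'   [select_pcs()]).
#' @export
run_pca <- function(cm, features = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  vals <- cm$values
  if (!is.null(features)) {
    miss <- setdiff(features, rownames(vals))
    if (length(miss))
      stop("features absent from matrix: ", paste(utils::head(miss, 5),
                                                  collapse = ", "))
    vals <- vals[features, , drop = FALSE]
  }
  if (ncol(vals) < 3) stop("PCA needs at least 3 samples")
  x <- t(vals)                      # samples x genes
  x <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(x) < 1e-12)) stop("constant matrix: no variance to decompose")
  sv <- svd(x)
  n <- nrow(x)
  eig <- sv$d^2 / (n - 1)
  keep <- eig > max(eig) * 1e-12    # drop numerically-zero components
  eig <- eig[keep]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep],
                                                nrow = sum(keep))
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(sum(keep))))
  loadings <- sv$v[, keep, drop = FALSE]
  dimnames(loadings) <- list(colnames(x), colnames(scores))
  frac <- eig / sum(eig)
  structure(list(scores = scores, eigenvalues = eig,
                 explained_fraction = frac,
                 cumulative_fraction = cumsum(frac),
                 loadings = loadings, group = cm$group,
                 k_selected = NA_integer_),
            class = "pca_selection")
}

#' @export
print.pca_selection <- function(x, ...) {
  cat(sprintf("pca_selection: %d PCs over %d samples; cumulative var: %s\n",
              length(x$eigenvalues), nrow(x$scores),
              paste(sprintf("%.2f", x$cumulative_fraction), collapse = " ")))
  invisible(x)
}

#' Choose the number of retained principal components
#'
#' Retains the smallest k whose cumulative explained-variance fraction
#' reaches the threshold (default 0.6, i.e. the top components carrying
#' "most" of the variance), or a fixed k when given.
#'
#' @param sel a `pca_selection`.
#' @param cum_threshold cumulative explained-variance threshold in (0, 1].
#' @param fixed_k overrides the threshold rule when non-NULL.
#' @return The `pca_selection` with `k_selected` set.
#' @export
select_pcs <- function(sel, cum_threshold = 0.6, fixed_k = NULL) {
  stopifnot(inherits(sel, "pca_selection"))
  if (!is.null(fixed_k)) {
    k <- min(as.integer(fixed_k), length(sel$eigenvalues))
  } else {
    if (cum_threshold <= 0 || cum_threshold > 1)
      stop("cum_threshold must be in (0, 1]")
    k <- which(sel$cumulative_fraction >= cum_threshold - 1e-12)[1L]
    if (is.na(k)) k <- length(sel$eigenvalues)
  }
  sel$k_selected <- as.integer(k)
  sel
}

#' Extract features significantly associated with the retained PCs
#'
#' For each retained PC, computes the Pearson correlation between every
#' feature's expression profile and the PC's sample scores, with two-sided
#' p-values and Benjamini-Hochberg FDR within each PC. A feature is
#' selected when `|r| >= r_min` and `q <= q_max` for at least one retained
#' PC (both cutoffs independently configurable; either can be disabled by
#' setting it to 0 / 1). Features qualifying on several PCs are assigned
#' uniquely to the PC with the largest |r|.
#'
#' @param sel a `pca_selection` with `k_selected` set.
#' @param cm the [count_matrix] the PCA was run on (same scale).
#' @param features optional restriction to these gene ids (the same set
#'   given to [run_pca()]).
#' @param r_min minimum |Pearson r| (default 0.8).
#' @param q_max maximum BH-FDR q (default 0.05).
#' @param fdr_scope `"per_pc"` (default) corrects within each retained PC;
#'   `"global"` corrects across all (feature, PC) tests at once.
#' @return list with `feature_assoc` (long data.frame: gene_id, pc, r, p, q,
#'   selected), `selected` (data.frame gene_id, assigned_pc, r, q),
#'   `per_pc_counts` (unique features per PC), `k_selected`.
#' @export
extract_features <- function(sel, cm, features = NULL, r_min = 0.8,
                             q_max = 0.05,
                             fdr_scope = c("per_pc", "global")) {
  stopifnot(inherits(sel, "pca_selection"), inherits(cm, "count_matrix"))
  fdr_scope <- match.arg(fdr_scope)
  if (is.na(sel$k_selected)) stop("call select_pcs() first")
  vals <- cm$values
  if (!is.null(features)) vals <- vals[features, , drop = FALSE]
  n <- ncol(vals)
  if (n < 4) stop("feature-PC correlation needs at least 4 samples")
  k <- sel$k_selected
  assoc <- vector("list", k)
  for (pc in seq_len(k)) {
    sc <- sel$scores[colnames(vals), pc]
    r <- suppressWarnings(as.numeric(stats::cor(t(vals), sc)))
    r[!is.finite(r)] <- 0           # constant features carry no association
    r <- pmin(pmax(r, -1), 1)
    tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
    p <- 2 * stats::pt(-tt, n - 2)
    assoc[[pc]] <- data.frame(gene_id = rownames(vals),
                              pc = paste0("PC", pc), r = r, p = p,
                              stringsAsFactors = FALSE)
  }
  assoc <- do.call(rbind, assoc)
  if (fdr_scope == "per_pc") {
    assoc$q <- stats::ave(assoc$p, assoc$pc,
                          FUN = function(p) stats::p.adjust(p, "BH"))
  } else {
    assoc$q <- stats::p.adjust(assoc$p, "BH")
  }
  assoc$selected <- abs(assoc$r) >= r_min & assoc$q <= q_max
  hits <- assoc[assoc$selected, , drop = FALSE]
  if (nrow(hits)) {
    # unique PC assignment: max |r| wins
    hits <- hits[order(hits$gene_id, -abs(hits$r)), , drop = FALSE]
    selected <- hits[!duplicated(hits$gene_id),
                     c("gene_id", "pc", "r", "q"), drop = FALSE]
    names(selected)[2L] <- "assigned_pc"
  } else {
    selected <- data.frame(gene_id = character(), assigned_pc = character(),
                           r = numeric(), q = numeric(),
                           stringsAsFactors = FALSE)
  }
  rownames(selected) <- NULL
  counts <- table(factor(selected$assigned_pc,
                         levels = paste0("PC", seq_len(k))))
  list(feature_assoc = assoc, selected = selected,
       per_pc_counts = as.data.frame(counts,
                                     responseName = "n_unique"),
       k_selected = k)
}

#' Confirm that selected features separate the groups
#'
#' Reruns the PCA on the selected features only and reports (i) the mean
#' silhouette width of the group labels in the (PC1, PC2) plane and (ii)
#' whether the groups are linearly separable there (hard-margin linear SVM
#' reaching zero training error).
#'
#' @param cm [count_matrix] on the PCA scale (e.g. VST).
#' @param selected character vector of selected feature ids.
#' @return list with `silhouette` (mean width), `separable` (logical),
#'   `pca` (the rerun `pca_selection`); `NULL` with a warning when fewer
#'   than 2 features are supplied.
#' @export
confirm_separation <- function(cm, selected) {
  stopifnot(inherits(cm, "count_matrix"))
  if (length(selected) < 2) {
    warning("fewer than 2 selected features; skipping separation check")
    return(NULL)
  }
  sel <- run_pca(cm, features = selected)
  k2 <- min(2L, ncol(sel$scores))
  xy <- sel$scores[, seq_len(k2), drop = FALSE]
  grp <- cm$group
  sil <- cluster::silhouette(as.integer(grp), stats::dist(xy))
  msil <- mean(sil[, "sil_width"])
  fit <- e1071::svm(xy, grp, kernel = "linear", cost = 1e7, scale = FALSE)
  separable <- all(stats::predict(fit, xy) == grp)
  list(silhouette = msil, separable = separable, pca = sel)
}
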