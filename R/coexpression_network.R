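#' Build the perfect-correlation bipartite lncRNA-mRNA network
#'
#' Tests every candidate lncRNA against every differentially expressed
#' protein-coding gene with [spearman_exact()] on upper-quartile-normalized
#' expression, retains pairs with `|rho| >= rho_min` (within 1e-12) and
#' `p < p_max`, and excludes retained pairs whose gene bodies overlap on
#' the same chromosome (strand-agnostic, any shared base). At n = 6
#' samples the defaults (`rho_min = 1`, `p_max = 0.005`) retain only
#' perfectly monotone pairs: the exact two-sided p of |rho| = 1 is 2/720
#' and the next attainable |rho| (0.9429) already has p = 12/720 > 0.005.
#'
#' @param cm_uqua [count_matrix] in `uqua` state.
#' @param candidates a `candidate_set` (see [intersect_candidates()]) or a
#'   character vector of candidate lncRNA ids.
#' @param pcg_de_ids character vector of DE protein-coding gene ids.
#' @param ann annotation data.frame (for the genomic-overlap exclusion);
#'   pairs with a gene missing from the annotation are kept, with a note in
#'   the log.
#' @param rho_min minimum |rho| (default 1: perfect correlation).
#' @param p_max exact p-value cutoff (default 0.005).
#' @param positive_only retain only rho >= +rho_min when `TRUE`; the
#'   default keeps both signs (perfectly concordant or perfectly reversed
#'   rank orders).
#' @param de optional `de_table` used to flag per-edge fold-change sign
#'   consistency.
#' @return A `coexpression_network`: list with `edges` (retained,
#'   non-overlapping: lncRNA, mRNA, rho, p, overlap_excluded = FALSE,
#'   direction_consistent), `excluded` (edges dropped by the overlap rule),
#'   `skipped` (constant-vector pairs), `n_pairs_tested`, thresholds.
#' @export
build_network <- function(cm_uqua, candidates, pcg_de_ids, ann = NULL,
                          rho_min = 1, p_max = 0.005,
                          positive_only = FALSE, de = NULL) {
  stopifnot(inherits(cm_uqua, "count_matrix"))
  lnc_ids <- if (inherits(candidates, "candidate_set"))
    candidates$candidates$gene_id else as.character(candidates)
  if (!length(lnc_ids) || !length(pcg_de_ids))
    stop("need non-empty candidate lncRNA and DE PCG id sets")
  vals <- cm_uqua$values
  lnc_ids <- intersect(lnc_ids, rownames(vals))
  pcg_de_ids <- intersect(pcg_de_ids, rownames(vals))

  rows <- list(); skipped <- list(); tested <- 0L
  tol <- 1e-12
  for (ln in lnc_ids) {
    x <- vals[ln, ]
    for (mr in pcg_de_ids) {
      tested <- tested + 1L
      res <- spearman_exact(x, vals[mr, ])
      if (res$method == "degenerate") {
        skipped[[length(skipped) + 1L]] <-
          data.frame(lncRNA = ln, mRNA = mr, reason = "constant vector")
        next
      }
      keep <- if (positive_only) res$rho >= rho_min - tol else
        abs(res$rho) >= rho_min - tol
      if (keep && res$p < p_max)
        rows[[length(rows) + 1L]] <-
          data.frame(lncRNA = ln, mRNA = mr, rho = res$rho, p = res$p,
                     stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lncRNA = character(), mRNA = character(), rho = numeric(),
               p = numeric(), stringsAsFactors = FALSE)
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(lncRNA = character(), mRNA = character(),
               reason = character(), stringsAsFactors = FALSE)

  edges$overlap_excluded <- FALSE
  if (!is.null(ann) && nrow(edges)) {
    ia <- match(edges$lncRNA, ann$gene_id)
    ib <- match(edges$mRNA, ann$gene_id)
    have <- !is.na(ia) & !is.na(ib)
    if (any(have)) {
      aa <- ann[ia[have], , drop = FALSE]
      ab <- ann[ib[have], , drop = FALSE]
      same_chr <- aa$chrom == ab$chrom
      ov <- as.logical(IRanges::poverlaps(
        IRanges::IRanges(aa$start, aa$end),
        IRanges::IRanges(ab$start, ab$end), type = "any"))
      edges$overlap_excluded[have] <- same_chr & ov
    }
  }
  excluded <- edges[edges$overlap_excluded, , drop = FALSE]
  edges <- edges[!edges$overlap_excluded, , drop = FALSE]
  if (nrow(excluded))
    message(sprintf("build_network: excluded %d genomically overlapping pair(s)",
                    nrow(excluded)))

  edges$direction_consistent <- NA
  if (!is.null(de) && nrow(edges)) {
    fa <- de$log2FC[match(edges$lncRNA, de$gene_id)]
    fb <- de$log2FC[match(edges$mRNA, de$gene_id)]
    edges$direction_consistent <- sign(fa) == sign(fb)
  }
  rownames(edges) <- NULL
  structure(list(edges = edges, excluded = excluded, skipped = skipped,
                 n_pairs_tested = tested,
                 thresholds = c(rho_min = rho_min, p_max = p_max),
                 positive_only = positive_only),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf(
    "coexpression_network: %d edges (%d lncRNAs x %d mRNAs), %d pairs tested, %d overlap-excluded\n",
    nrow(x$edges), length(unique(x$edges$lncRNA)),
    length(unique(x$edges$mRNA)), x$n_pairs_tested, nrow(x$excluded)))
  invisible(x)
}

#' Group lncRNAs by shared co-expressed mRNAs
#'
#' Primary definition: connected components of the lncRNA-lncRNA graph
#' with an edge whenever two lncRNAs share at least one co-expressed mRNA.
#' Also reports exact-set groups (identical mRNA neighbour sets) and flags
#' lncRNAs sharing no mRNA with any other as "acting alone".
#'
#' @param net a `coexpression_network`.
#' @return list with `components` (named list of lncRNA id vectors),
#'   `membership` (data.frame lncRNA, component, exact_group, acting_alone),
#'   `n_components`.
#' @export
cluster_lncrnas <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  ed <- net$edges
  lncs <- unique(ed$lncRNA)
  if (!length(lncs))
    return(list(components = list(),
                membership = data.frame(lncRNA = character(),
                                        component = integer(),
                                        exact_group = integer(),
                                        acting_alone = logical()),
                n_components = 0L))
  nbr <- lapply(lncs, function(l) sort(unique(ed$mRNA[ed$lncRNA == l])))
  names(nbr) <- lncs
  pairs <- list()
  if (length(lncs) > 1) {
    cmb <- utils::combn(lncs, 2)
    share <- apply(cmb, 2, function(pr)
      length(intersect(nbr[[pr[1]]], nbr[[pr[2]]])) > 0)
    if (any(share)) pairs <- cmb[, share, drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(lncs), name = lncs)
  if (length(pairs)) g <- igraph::add_edges(g, as.vector(pairs))
  comp <- igraph::components(g)
  sig <- vapply(nbr, function(v) paste(v, collapse = "|"), character(1))
  exact_group <- as.integer(factor(sig, levels = unique(sig)))
  member <- data.frame(lncRNA = lncs,
                       component = as.integer(comp$membership[lncs]),
                       exact_group = exact_group,
                       acting_alone = igraph::degree(g)[lncs] == 0,
                       stringsAsFactors = FALSE)
  comps <- split(member$lncRNA, member$component)
  list(components = comps, membership = member,
       n_components = comp$no)
}

#' Census of the network restricted to one pathway's mRNAs
#'
#' @param net a `coexpression_network`.
#' @param gene_set character vector of mRNA ids (pathway members).
#' @param de optional `de_table`; attaches per-node direction for
#'   rendering.
#' @return list with `edges` (subnetwork edge table), `census`
#'   (n_lnc, n_mrna, n_edges), `nodes` (id, side, direction).
#' @export
pathway_subnetwork <- function(net, gene_set, de = NULL) {
  stopifnot(inherits(net, "coexpression_network"))
  sub <- net$edges[net$edges$mRNA %in% gene_set, , drop = FALSE]
  lncs <- unique(sub$lncRNA); mrnas <- unique(sub$mRNA)
  nodes <- data.frame(id = c(lncs, mrnas),
                      side = rep(c("lncRNA", "mRNA"),
                                 c(length(lncs), length(mrnas))),
                      stringsAsFactors = FALSE)
  nodes$direction <- if (!is.null(de))
    de$status[match(nodes$id, de$gene_id)] else
      rep(NA_character_, nrow(nodes))
  list(edges = sub,
       census = c(n_lnc = length(lncs), n_mrna = length(mrnas),
                  n_edges = nrow(sub)),
       nodes = nodes)
}

#' Convert a co-expression network to an igraph bipartite graph
#'
#' @param net a `coexpression_network`.
#' @return An igraph graph; vertices carry a logical `type` attribute
#'   (TRUE for mRNAs) and edges carry `rho` and `p`.
#' @export
as_igraph_network <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  ed <- net$edges
  lncs <- unique(ed$lncRNA); mrnas <- unique(ed$mRNA)
  g <- igraph::graph_from_data_frame(
    ed[, c("lncRNA", "mRNA", "rho", "p")], directed = FALSE,
    vertices = data.frame(name = c(lncs, mrnas),
                          type = rep(c(FALSE, TRUE),
                                     c(length(lncs), length(mrnas)))))
  g
}

#' Write network edges as TSV (plus optional GraphML export)
#'
#' @param net a `coexpression_network`.
#' @param path TSV output path (columns lncRNA, mRNA, rho, p,
#'   overlap_excluded, direction_consistent).
#' @param graphml_path optional GraphML output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(net, path, graphml_path = NULL) {
  stopifnot(inherits(net, "coexpression_network"))
  out <- net$edges
  full <- net$excluded
  if (nrow(full)) {
    full$direction_consistent <- NA
    out <- rbind(out, full[, names(out), drop = FALSE])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(as_igraph_network(net), graphml_path,
                        format = "graphml")
  invisible(path)
}
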