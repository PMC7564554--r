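#' Hypergeometric gene-set enrichment
#'
#' Upper-tail (cumulative) hypergeometric p-value per gene set, with
#' Benjamini-Hochberg correction across sets. Two significance filters are
#' reported side by side: `-log10(p) > log10p_min` (Metascape-style,
#' default 6) and `q <= q_max` (FDR-style, default 0.05). Query genes
#' absent from the universe are dropped and reported; each set is
#' intersected with the universe.
#'
#' @param query_genes character vector of query gene ids.
#' @param sets a `gene_set_collection`.
#' @param universe character vector: the background gene population.
#' @param log10p_min -log10(p) filter threshold (default 6).
#' @param q_max BH-FDR filter threshold (default 0.05).
#' @return An `enrichment_result` data.frame: set_id, name, overlap,
#'   query_size, term_size, universe_size, p, q, minus_log10_p,
#'   pass_log10p, pass_fdr, overlap_genes (comma-separated).
#' @export
hypergeom_enrich <- function(query_genes, sets, universe,
                             log10p_min = 6, q_max = 0.05) {
  stopifnot(inherits(sets, "gene_set_collection"))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  dropped <- setdiff(query_genes, universe)
  if (length(dropped))
    message(sprintf("hypergeom_enrich: %d query gene(s) not in universe, dropped",
                    length(dropped)))
  query <- intersect(unique(query_genes), universe)
  N <- length(universe); qn <- length(query)
  rows <- lapply(names(sets$sets), function(id) {
    term <- intersect(sets$sets[[id]], universe)
    ov <- intersect(query, term)
    m <- length(term); k <- length(ov)
    # P(X >= k), X ~ Hypergeom(term = m, non-term = N - m, draws = qn)
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, m, N - m, qn, lower.tail = FALSE)
    data.frame(set_id = id, name = unname(sets$names[id]), overlap = k,
               query_size = qn, term_size = m, universe_size = N,
               p = p, overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, "BH")
  res$minus_log10_p <- -log10(res$p)
  res$pass_log10p <- res$minus_log10_p > log10p_min
  res$pass_fdr <- res$q <= q_max
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", class(res))
  attr(res, "dropped_query") <- dropped
  res
}

#' Cohen's kappa between two gene memberships
#'
#' Chance-corrected agreement of two binary membership vectors over a
#' common gene population: `kappa = (po - pe) / (1 - pe)`.
#'
#' @param a,b character vectors of member gene ids.
#' @param population character vector of genes over which membership is
#'   compared.
#' @return Cohen's kappa in [-1, 1].
#' @export
cohen_kappa <- function(a, b, population) {
  population <- unique(population)
  n <- length(population)
  if (n < 2) stop("population too small for kappa")
  ia <- population %in% a; ib <- population %in% b
  n11 <- sum(ia & ib); n00 <- sum(!ia & !ib)
  po <- (n11 + n00) / n
  pe <- (sum(ia) * sum(ib) + sum(!ia) * sum(!ib)) / n^2
  if (pe >= 1) return(1)  # both memberships cover everything or nothing
  (po - pe) / (1 - pe)
}

#' Kappa-similarity graph over significant enrichment terms
#'
#' Computes Cohen's kappa between the overlap-gene memberships of each
#' pair of significant terms (over the union of their genes) and connects
#' term pairs with `kappa > kappa_min`; connected components are reported
#' as term clusters.
#'
#' @param result an `enrichment_result`.
#' @param kappa_min kappa threshold (default 0.3).
#' @param filter which significance filter defines "significant":
#'   `"either"` (default), `"log10p"` or `"fdr"`.
#' @return list with `terms` (significant set ids), `edges` (data.frame
#'   term_a, term_b, kappa), `clusters` (named membership vector),
#'   `n_clusters`; `NULL` with a warning when fewer than 2 terms are
#'   significant.
#' @export
kappa_term_graph <- function(result, kappa_min = 0.3,
                             filter = c("either", "log10p", "fdr")) {
  stopifnot(inherits(result, "enrichment_result"))
  filter <- match.arg(filter)
  sig <- switch(filter,
                either = result$pass_log10p | result$pass_fdr,
                log10p = result$pass_log10p,
                fdr = result$pass_fdr)
  res <- result[sig, , drop = FALSE]
  if (nrow(res) < 2) {
    warning("fewer than 2 significant terms; no kappa graph")
    return(NULL)
  }
  members <- lapply(strsplit(res$overlap_genes, ",", fixed = TRUE),
                    function(v) v[nzchar(v)])
  names(members) <- res$set_id
  population <- unique(unlist(members))
  cmb <- utils::combn(res$set_id, 2)
  kap <- apply(cmb, 2, function(pr)
    cohen_kappa(members[[pr[1]]], members[[pr[2]]], population))
  edges <- data.frame(term_a = cmb[1, ], term_b = cmb[2, ], kappa = kap,
                      stringsAsFactors = FALSE)
  keep <- edges[edges$kappa > kappa_min, , drop = FALSE]
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(res), name = res$set_id)
  if (nrow(keep))
    g <- igraph::add_edges(g, as.vector(t(as.matrix(keep[, 1:2]))))
  comp <- igraph::components(g)
  list(terms = res$set_id, edges = keep,
       clusters = comp$membership, n_clusters = comp$no)
}

#' Guilt-by-association functional assignment of lncRNAs
#'
#' For each lncRNA in the network, enriches its co-expressed mRNA set
#' against the supplied gene sets, records which disease pathways contain
#' at least one of its mRNAs, and builds the mRNA-sharing overlap table
#' (per lncRNA: mRNAs unique to it vs shared with other lncRNAs, plus
#' pairwise lncRNA overlap links).
#'
#' @param net a `coexpression_network`.
#' @param sets a `gene_set_collection`.
#' @param universe background gene ids for the enrichment.
#' @param disease_set_ids set ids regarded as disease pathways (default:
#'   all sets).
#' @param log10p_min,q_max significance filters passed to
#'   [hypergeom_enrich()].
#' @return list with `assignments` (per lncRNA: n_mrna, disease_sets,
#'   assigned_terms, n_unique_mrna, n_shared_mrna), `enrichments` (named
#'   list of `enrichment_result`s), `overlap_links` (data.frame lnc_a,
#'   lnc_b, n_shared), `n_in_disease_sets`.
#' @export
assign_lnc_functions <- function(net, sets, universe,
                                 disease_set_ids = names(sets$sets),
                                 log10p_min = 6, q_max = 0.05) {
  stopifnot(inherits(net, "coexpression_network"),
            inherits(sets, "gene_set_collection"))
  bad <- setdiff(disease_set_ids, names(sets$sets))
  if (length(bad)) stop("unknown disease set id(s): ",
                        paste(bad, collapse = ", "))
  ed <- net$edges
  lncs <- unique(ed$lncRNA)
  nbr <- lapply(lncs, function(l) unique(ed$mRNA[ed$lncRNA == l]))
  names(nbr) <- lncs
  all_counts <- table(unlist(nbr))

  enr <- list()
  rows <- lapply(lncs, function(l) {
    ms <- nbr[[l]]
    e <- suppressMessages(
      hypergeom_enrich(ms, sets, universe, log10p_min, q_max))
    enr[[l]] <<- e
    assigned <- e$set_id[e$pass_log10p | e$pass_fdr]
    dsets <- disease_set_ids[vapply(disease_set_ids, function(s)
      length(intersect(sets$sets[[s]], ms)) > 0, logical(1))]
    shared <- sum(all_counts[ms] > 1)
    data.frame(lncRNA = l, n_mrna = length(ms),
               disease_sets = paste(dsets, collapse = ","),
               assigned_terms = paste(assigned, collapse = ","),
               n_unique_mrna = length(ms) - shared,
               n_shared_mrna = shared, stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  links <- data.frame(lnc_a = character(), lnc_b = character(),
                      n_shared = integer(), stringsAsFactors = FALSE)
  if (length(lncs) > 1) {
    cmb <- utils::combn(lncs, 2)
    ns <- apply(cmb, 2, function(pr)
      length(intersect(nbr[[pr[1]]], nbr[[pr[2]]])))
    links <- data.frame(lnc_a = cmb[1, ], lnc_b = cmb[2, ],
                        n_shared = ns, stringsAsFactors = FALSE)
    links <- links[links$n_shared > 0, , drop = FALSE]
    rownames(links) <- NULL
  }
  list(assignments = assignments, enrichments = enr,
       overlap_links = links,
       n_in_disease_sets = sum(nzchar(assignments$disease_sets)))
}
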