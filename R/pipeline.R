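#' Pipeline configuration
#'
#' Collects every stage threshold in one validated list.
#'
#' @param t_log2fc absolute log2FC threshold for DE status (default 1.5).
#' @param alpha adjusted-p threshold for DE status (default 0.05).
#' @param cum_var_threshold cumulative explained-variance threshold for PC
#'   retention (default 0.6).
#' @param fixed_k optional fixed number of retained PCs.
#' @param r_min,q_max feature-PC association cutoffs (default 0.8, 0.05).
#' @param fdr_scope `"per_pc"` or `"global"` (see [extract_features()]).
#' @param rho_min,p_max co-expression edge cutoffs (default 1, 0.005).
#' @param positive_only retain only positively correlated pairs.
#' @param enrich_log10p_min,enrich_q_max enrichment filters (default 6,
#'   0.05).
#' @param kappa_min kappa-graph edge threshold (default 0.3).
#' @param min_nonzero_samples gene filter (default 1).
#' @param uqua_rescale rescale UQUA values by the mean upper quartile.
#' @param vst_fallback_pseudocount pseudocount of the VST log2 fallback.
#' @return A validated `run_config` list.
#' @export
run_config <- function(t_log2fc = 1.5, alpha = 0.05,
                       cum_var_threshold = 0.6, fixed_k = NULL,
                       r_min = 0.8, q_max = 0.05,
                       fdr_scope = "per_pc",
                       rho_min = 1, p_max = 0.005,
                       positive_only = FALSE,
                       enrich_log10p_min = 6, enrich_q_max = 0.05,
                       kappa_min = 0.3,
                       min_nonzero_samples = 1L,
                       uqua_rescale = TRUE,
                       vst_fallback_pseudocount = 1) {
  stopifnot(t_log2fc >= 0, alpha > 0, alpha <= 1,
            cum_var_threshold > 0, cum_var_threshold <= 1,
            r_min >= 0, r_min <= 1, q_max > 0, q_max <= 1,
            rho_min >= 0, rho_min <= 1, p_max > 0, p_max <= 1,
            kappa_min >= -1, kappa_min <= 1,
            min_nonzero_samples >= 1,
            vst_fallback_pseudocount > 0)
  fdr_scope <- match.arg(fdr_scope, c("per_pc", "global"))
  structure(list(t_log2fc = t_log2fc, alpha = alpha,
                 cum_var_threshold = cum_var_threshold, fixed_k = fixed_k,
                 r_min = r_min, q_max = q_max, fdr_scope = fdr_scope,
                 rho_min = rho_min, p_max = p_max,
                 positive_only = positive_only,
                 enrich_log10p_min = enrich_log10p_min,
                 enrich_q_max = enrich_q_max, kappa_min = kappa_min,
                 min_nonzero_samples = as.integer(min_nonzero_samples),
                 uqua_rescale = uqua_rescale,
                 vst_fallback_pseudocount = vst_fallback_pseudocount),
            class = "run_config")
}

stage_log <- function(report, name, ...) {
  info <- list(...)
  message(sprintf("[%s] %s", name,
                  paste(names(info), unlist(info), sep = "=",
                        collapse = " ")))
  report$stages[[name]] <- info
  report
}

#' Run the full discovery pipeline
#'
#' Orchestrates: annotation restriction, zero-count filtering, UQUA and
#' VST normalization, differential expression (ingested or internal),
#' PCA-based feature extraction of lncRNAs, candidate intersection,
#' perfect-correlation network construction, lncRNA clustering, pathway
#' subnetworks, guilt-by-association enrichment, and (when a reference is
#' supplied) binomial sign-concordance validation.
#'
#' @param counts raw [count_matrix].
#' @param annotation annotation data.frame ([read_annotation()]).
#' @param gene_sets optional `gene_set_collection`; enrichment and
#'   pathway stages are skipped when absent.
#' @param config a [run_config()].
#' @param de_table optional externally computed `de_table`
#'   ([ingest_de_table()]); when absent [internal_de()] is used.
#' @param reference optional reference DE summary: list with `table`
#'   (data.frame gene_id, log2FC) and census `n_de_down`, `n_de_up`,
#'   `n_total` (as from [simulate_reference_de()]).
#' @param disease_set_ids set ids treated as disease pathways (default:
#'   all sets).
#' @param output_dir optional directory; when given, writes the JSON run
#'   report, edge/candidate/feature tables and a GraphML network export.
#' @return list with `report` (cardinalities, thresholds; JSON-ready) and
#'   `objects` (every intermediate result keyed by stage).
#' @export
run_all <- function(counts, annotation, gene_sets = NULL,
                    config = run_config(), de_table = NULL,
                    reference = NULL, disease_set_ids = NULL,
                    output_dir = NULL) {
  stopifnot(inherits(counts, "count_matrix"),
            inherits(config, "run_config"))
  if (!is.null(gene_sets) && !inherits(gene_sets, "gene_set_collection"))
    stop("'gene_sets' must be a gene_set_collection (see read_gmt)")
  if (!is.null(reference) &&
      !all(c("table", "n_de_down", "n_de_up", "n_total") %in%
             names(reference)))
    stop("'reference' must carry table, n_de_down, n_de_up, n_total")
  report <- list(thresholds = unclass(config), stages = list())
  objects <- list()

  # restrict to annotated genes
  keep <- rownames(counts$values) %in% annotation$gene_id
  cm <- set_values(counts, counts$values[keep, , drop = FALSE], "raw")
  report <- stage_log(report, "annotate", n_in = length(keep),
                      n_annotated = sum(keep),
                      n_dropped = sum(!keep))

  cm <- suppressMessages(filter_nonzero(cm, config$min_nonzero_samples))
  report <- stage_log(report, "filter_nonzero",
                      n_removed = attr(cm, "n_removed"),
                      n_out = nrow(cm$values))

  cm_uqua <- uqua_normalize(cm, rescale = config$uqua_rescale)
  cm_vst <- vst_transform(cm, config$vst_fallback_pseudocount)
  report <- stage_log(report, "normalize",
                      uqua = TRUE,
                      vst_fallback = attr(cm_vst, "vst_model")$fallback)

  part <- partition_by_biotype(
    annotation[annotation$gene_id %in% rownames(cm$values), , drop = FALSE])
  report <- stage_log(report, "partition",
                      n_lnc = length(part$lnc_ids),
                      n_pcg = length(part$pcg_ids),
                      n_other = length(part$other_ids))

  de <- if (!is.null(de_table)) de_table else
    internal_de(cm_vst, cm_uqua, t_log2fc = config$t_log2fc,
                alpha = config$alpha)
  de_ids <- de$gene_id[de$status != "not_de"]
  de_lnc <- intersect(de_ids, part$lnc_ids)
  de_pcg <- intersect(de_ids, part$pcg_ids)
  report <- stage_log(report, "differential_expression",
                      n_de = length(de_ids), n_de_lnc = length(de_lnc),
                      n_de_pcg = length(de_pcg),
                      source = if (is.null(de_table)) "internal"
                      else "ingested")

  lnc_in <- intersect(part$lnc_ids, rownames(cm_vst$values))
  pca <- run_pca(cm_vst, features = lnc_in)
  pca <- select_pcs(pca, config$cum_var_threshold, config$fixed_k)
  fe <- extract_features(pca, cm_vst, features = lnc_in,
                         r_min = config$r_min, q_max = config$q_max,
                         fdr_scope = config$fdr_scope)
  sep <- if (nrow(fe$selected) >= 2)
    confirm_separation(cm_vst, fe$selected$gene_id) else NULL
  report <- stage_log(report, "pca_feature_extraction",
                      n_lnc_in = length(lnc_in),
                      k_selected = pca$k_selected,
                      n_selected = nrow(fe$selected),
                      silhouette = if (is.null(sep)) NA else
                        round(sep$silhouette, 4),
                      separable = if (is.null(sep)) NA else sep$separable)

  cand <- suppressWarnings(
    intersect_candidates(fe$selected$gene_id, de, part$lnc_ids))
  report <- stage_log(report, "intersect_candidates",
                      n_candidates = nrow(cand$candidates),
                      n_down = cand$n_down, n_up = cand$n_up)

  net <- NULL; clusters <- NULL
  if (nrow(cand$candidates) && length(de_pcg)) {
    net <- suppressMessages(
      build_network(cm_uqua, cand, de_pcg, ann = annotation,
                    rho_min = config$rho_min, p_max = config$p_max,
                    positive_only = config$positive_only, de = de))
    clusters <- cluster_lncrnas(net)
    report <- stage_log(report, "coexpression_network",
                        n_pairs_tested = net$n_pairs_tested,
                        n_edges = nrow(net$edges),
                        n_excluded = nrow(net$excluded),
                        n_lnc = length(unique(net$edges$lncRNA)),
                        n_mrna = length(unique(net$edges$mRNA)),
                        n_clusters = clusters$n_components)
  } else {
    report <- stage_log(report, "coexpression_network", skipped = TRUE)
  }

  subnets <- NULL; gba <- NULL
  if (!is.null(gene_sets) && !is.null(net)) {
    if (is.null(disease_set_ids))
      disease_set_ids <- names(gene_sets$sets)
    subnets <- lapply(gene_sets$sets, function(s)
      pathway_subnetwork(net, s, de))
    gba <- assign_lnc_functions(net, gene_sets, universe = part$pcg_ids,
                                disease_set_ids = disease_set_ids,
                                log10p_min = config$enrich_log10p_min,
                                q_max = config$enrich_q_max)
    report <- stage_log(report, "guilt_by_association",
                        n_sets = length(gene_sets$sets),
                        n_lnc_in_disease_sets = gba$n_in_disease_sets)
    report$pathway_census <- lapply(subnets, function(s)
      as.list(s$census))
  } else {
    report <- stage_log(report, "guilt_by_association", skipped = TRUE)
  }

  conc <- NULL
  if (!is.null(reference) && nrow(cand$candidates)) {
    ext <- reference$table$log2FC
    names(ext) <- reference$table$gene_id
    conc <- validate_concordance(cand$candidates, ext,
                                 n_de_down = reference$n_de_down,
                                 n_de_up = reference$n_de_up,
                                 n_total = reference$n_total)
    report <- stage_log(report, "concordance",
                        n_compared = conc$n_candidates,
                        k_concordant = conc$n_concordant,
                        p0 = round(conc$p0, 4),
                        p_value = conc$p_value)
  } else {
    report <- stage_log(report, "concordance", skipped = TRUE)
  }

  objects <- list(cm_filtered = cm, cm_uqua = cm_uqua, cm_vst = cm_vst,
                  partition = part, de = de, pca = pca, features = fe,
                  separation = sep, candidates = cand, network = net,
                  clusters = clusters, subnetworks = subnets, gba = gba,
                  concordance = conc)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(output_dir, "run_report.json"))
    utils::write.table(cand$candidates,
                       file.path(output_dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fe$feature_assoc,
                       file.path(output_dir, "feature_assoc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    scree <- data.frame(pc = seq_along(pca$eigenvalues),
                        eigenvalue = pca$eigenvalues,
                        fraction = pca$explained_fraction,
                        cumulative = pca$cumulative_fraction)
    utils::write.table(scree, file.path(output_dir, "scree.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(net))
      write_edges(net, file.path(output_dir, "edges.tsv"),
                  graphml_path = file.path(output_dir, "network.graphml"))
  }
  list(report = report, objects = objects)
}

#' Write a run report (or any JSON-serializable list) as JSON
#'
#' @param obj a list, e.g. the `report` element of [run_all()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(obj, path) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}
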