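#' Configuration for the synthetic B-ALL-like cohort generator
#'
#' Defaults emulate a two-group (3 vs 3) bulk RNA-seq cohort: negative
#' binomial counts with a parametric dispersion-mean trend
#' `alpha(mu) = a/mu + a0`, a biotype composition matching a typical
#' annotated human gene census (73% protein coding, 13.6% lncRNA split
#' across sub-biotypes, 3.1% short non-coding, 9.8% pseudogene, 0.37%
#' other; normalized to sum to 1), planted perfect-correlation
#' lncRNA-mRNA modules whose genes share one strict per-sample ordering
#' after upper-quartile normalization, and GMT pathways built over the
#' module mRNAs. `de_fraction` controls additional non-module DE genes
#' (default 0: the modules are the planted differential signal).
#'
#' @param n_genes total genes (default 2500).
#' @param biotype_proportions named proportions per biotype.
#' @param samples_per_group named integer vector, e.g.
#'   `c(healthy = 3, tumour = 3)`.
#' @param mean_range log-uniform range of baseline NB means.
#' @param dispersion_a,dispersion_a0 trend parameters `a` and `a0`.
#' @param de_fraction fraction of non-module genes given a planted group
#'   effect.
#' @param de_lfc_range |log2FC| range of planted non-module DE genes.
#' @param de_min_base_mean minimum baseline mean of genes eligible for a
#'   planted group effect; fold changes on near-zero baselines are not
#'   detectable in any 3 vs 3 design.
#' @param n_modules planted perfect-correlation modules.
#' @param lnc_per_module,mrna_per_module module composition (mRNAs >= 3).
#' @param module_base_mean_range baseline mean range of module genes.
#' @param module_within_ratio multiplicative gap between within-group
#'   expression levels (controls how robustly the planted ordering
#'   survives sampling noise).
#' @param module_between_ratio multiplicative gap between the two groups'
#'   level blocks; the planted module |log2FC| is `log2` of this.
#' @param module_dispersion NB dispersion of module genes (small, so the
#'   planted ordering is recoverable).
#' @param frac_all_zero fraction of genes with all-zero counts.
#' @param n_disease_sets,n_background_sets,background_set_size GMT design.
#' @param n_overlap_injections modules whose lncRNA is deliberately placed
#'   overlapping one of its mRNAs (to exercise the exclusion rule).
#' @param max_retries redraw budget per module gene for the
#'   ordering/ties rejection step.
#' @param seed RNG seed; a fixed seed makes the output byte-identical.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2500,
                       biotype_proportions = c(
                         protein_coding = 0.73,
                         antisense = 0.059, lincRNA = 0.047,
                         processed_transcript = 0.009,
                         sense_intronic = 0.017,
                         sense_overlapping = 0.0036,
                         "3prime_overlapping_ncRNA" = 0.0002,
                         miRNA = 0.031, pseudogene = 0.098,
                         other = 0.0037),
                       samples_per_group = c(healthy = 3, tumour = 3),
                       mean_range = c(0.5, 5000),
                       dispersion_a = 3, dispersion_a0 = 0.05,
                       de_fraction = 0, de_lfc_range = c(1.5, 5.3),
                       de_min_base_mean = 100,
                       n_modules = 5, lnc_per_module = 2,
                       mrna_per_module = 4,
                       module_base_mean_range = c(20000, 60000),
                       module_within_ratio = 1.1,
                       module_between_ratio = 32,
                       module_dispersion = 1e-4,
                       frac_all_zero = 0.02,
                       n_disease_sets = 4, n_background_sets = 6,
                       background_set_size = 15,
                       n_overlap_injections = 0,
                       max_retries = 50, seed = 1) {
  stopifnot(n_genes > 0, all(biotype_proportions >= 0),
            length(samples_per_group) == 2,
            all(samples_per_group >= 2),
            de_fraction >= 0, de_fraction < 1,
            n_modules >= 0, mrna_per_module >= 3, lnc_per_module >= 1,
            module_within_ratio > 1, module_between_ratio > 1,
            frac_all_zero >= 0, frac_all_zero < 1)
  s <- sum(biotype_proportions)
  if (abs(s - 1) > 1e-9)
    biotype_proportions <- biotype_proportions / s
  cfg <- list(n_genes = as.integer(n_genes),
              biotype_proportions = biotype_proportions,
              samples_per_group = samples_per_group,
              mean_range = mean_range,
              dispersion_a = dispersion_a, dispersion_a0 = dispersion_a0,
              de_fraction = de_fraction, de_lfc_range = de_lfc_range,
              de_min_base_mean = de_min_base_mean,
              n_modules = as.integer(n_modules),
              lnc_per_module = as.integer(lnc_per_module),
              mrna_per_module = as.integer(mrna_per_module),
              module_base_mean_range = module_base_mean_range,
              module_within_ratio = module_within_ratio,
              module_between_ratio = module_between_ratio,
              module_dispersion = module_dispersion,
              frac_all_zero = frac_all_zero,
              n_disease_sets = as.integer(n_disease_sets),
              n_background_sets = as.integer(n_background_sets),
              background_set_size = as.integer(background_set_size),
              n_overlap_injections = as.integer(n_overlap_injections),
              max_retries = as.integer(max_retries),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

rnb_trend <- function(n, mu, a, a0) {
  stats::rnbinom(n, mu = mu, size = 1 / (a / mu + a0))
}

# draw one module gene's counts and check the strict post-UQUA ordering
draw_module_gene <- function(mean_s, disp, fac, ord, max_retries) {
  for (i in seq_len(max_retries)) {
    cnt <- stats::rnbinom(length(mean_s), mu = mean_s, size = 1 / disp)
    norm <- cnt / fac
    if (!anyDuplicated(norm) && identical(order(norm), ord))
      return(cnt)
  }
  stop("module gene redraw budget exceeded; increase module_within_ratio ",
       "or module_between_ratio for a wider mean separation")
}

#' Simulate a synthetic two-group cohort with planted ground truth
#'
#' Generates raw NB counts, a gene annotation with non-overlapping
#' coordinates (except deliberate injections), GMT gene sets over the
#' planted module mRNAs, and a truth table for recovery tests. Module
#' genes are given strictly ordered per-sample means (distinct orderings
#' across modules, group-separated so module genes are also
#' differentially expressed and discriminative) and redrawn until every
#' module member shares its module's strict ordering after upper-quartile
#' normalization with no rank ties.
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` (raw [count_matrix]), `annotation`,
#'   `gene_sets` (`gene_set_collection`), `truth` (list: `de_genes`,
#'   `modules`, `module_edges`, `all_zero_ids`, `overlap_pairs`,
#'   `pathway_modules`, `n_lnc_total`, `config`).
#' @export
simulate_ball_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(cfg$seed, simulate_ball_cohort_impl(cfg))
}

simulate_ball_cohort_impl <- function(cfg) {
  G <- cfg$n_genes
  groups <- rep(names(cfg$samples_per_group), cfg$samples_per_group)
  n <- length(groups)
  samples <- paste0(substr(groups, 1, 1), unlist(lapply(
    cfg$samples_per_group, seq_len)))
  gene_ids <- sprintf("SYNTG%06d", seq_len(G))

  ## --- annotation: biotypes and non-overlapping coordinates -------------
  props <- cfg$biotype_proportions
  n_per <- floor(props * G)
  rem <- G - sum(n_per)
  if (rem > 0) {
    extra <- order(props * G - n_per, decreasing = TRUE)[seq_len(rem)]
    n_per[extra] <- n_per[extra] + 1
  }
  biotype <- sample(rep(names(props), n_per))
  chrom <- paste0("chr", ((seq_len(G) - 1) %% 22) + 1)
  width <- sample(500:20000, G, replace = TRUE)
  start <- integer(G)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    gaps <- sample(1000:5000, length(idx), replace = TRUE)
    start[idx] <- cumsum(c(1L, utils::head(width[idx] + gaps, -1)))
  }
  ann <- data.frame(gene_id = gene_ids,
                    symbol = paste0("SYM", seq_len(G)),
                    biotype = biotype, chrom = chrom, start = start,
                    end = start + width - 1L,
                    strand = sample(c("+", "-"), G, replace = TRUE),
                    stringsAsFactors = FALSE)

  lnc_classes <- default_lnc_biotypes()
  lnc_pool <- gene_ids[biotype %in% lnc_classes]
  pcg_pool <- gene_ids[biotype == "protein_coding"]

  ## --- planted modules --------------------------------------------------
  need_lnc <- cfg$n_modules * cfg$lnc_per_module
  need_mrna <- cfg$n_modules * cfg$mrna_per_module
  if (need_lnc > length(lnc_pool) || need_mrna > length(pcg_pool))
    stop("n_genes too small for the requested modules")
  mod_lnc <- matrix(sample(lnc_pool, need_lnc),
                    nrow = max(cfg$n_modules, 1))
  mod_mrna <- matrix(sample(pcg_pool, need_mrna),
                     nrow = max(cfg$n_modules, 1))
  low_first <- groups == groups[1L]
  modules <- list()
  orderings_seen <- character()
  for (m in seq_len(cfg$n_modules)) {
    direction <- if (m %% 2 == 1) "up" else "down"
    repeat {
      # strict per-sample level assignment: the "low" block gets levels
      # (1, w, w^2) in random order, the "high" block b*(1, w, w^2)
      w <- cfg$module_within_ratio; b <- cfg$module_between_ratio
      lv <- numeric(n)
      low_is_healthy <- direction == "up"
      low_idx <- which((groups == "healthy") == low_is_healthy)
      high_idx <- setdiff(seq_len(n), low_idx)
      lv[low_idx] <- w^(sample(length(low_idx)) - 1)
      lv[high_idx] <- b * w^(sample(length(high_idx)) - 1)
      # a module ordering must differ from every other module's ordering
      # AND its reversal, else cross-module pairs would be perfectly
      # correlated (rho = +1 or -1) by construction
      sig <- paste(order(lv), collapse = ",")
      rsig <- paste(rev(order(lv)), collapse = ",")
      if (!sig %in% orderings_seen && !rsig %in% orderings_seen) {
        orderings_seen <- c(orderings_seen, sig, rsig)
        break
      }
    }
    modules[[m]] <- list(lnc_ids = mod_lnc[m, ], mrna_ids = mod_mrna[m, ],
                         direction = direction, levels = lv,
                         ordering = order(lv),
                         true_log2fc = (if (direction == "up") 1 else -1) *
                           log2(cfg$module_between_ratio))
  }
  module_gene_ids <- unlist(lapply(modules, function(m)
    c(m$lnc_ids, m$mrna_ids)))

  ## --- extra (non-module) DE genes and all-zero genes -------------------
  mu <- exp(stats::runif(G, log(cfg$mean_range[1]),
                         log(cfg$mean_range[2])))
  names(mu) <- gene_ids
  free <- setdiff(gene_ids, module_gene_ids)
  n_zero <- round(cfg$frac_all_zero * G)
  zero_ids <- if (n_zero) sample(free, n_zero) else character()
  free <- setdiff(free, zero_ids)
  n_extra_de <- round(cfg$de_fraction * G)
  # planted group effects go to reasonably expressed genes: a fold change
  # on a near-zero baseline is undetectable at 3 + 3 by any method
  de_pool <- free[mu[free] >= cfg$de_min_base_mean]
  if (length(de_pool) < n_extra_de) {
    extra_needed <- n_extra_de - length(de_pool)
    rest <- setdiff(free, de_pool)
    de_pool <- c(de_pool, rest[order(-mu[rest])][seq_len(extra_needed)])
  }
  extra_de_ids <- if (n_extra_de) sample(de_pool, n_extra_de) else
    character()
  extra_lfc <- if (n_extra_de)
    stats::runif(n_extra_de, cfg$de_lfc_range[1], cfg$de_lfc_range[2]) *
      sample(c(-1, 1), n_extra_de, replace = TRUE) else numeric()
  names(extra_lfc) <- extra_de_ids

  ## --- baseline counts ---------------------------------------------------
  counts <- matrix(0L, G, n, dimnames = list(gene_ids, samples))
  tumour <- groups == "tumour"
  for (g in seq_len(G)) {
    id <- gene_ids[g]
    if (id %in% zero_ids || id %in% module_gene_ids) next
    if (id %in% extra_de_ids) {
      l <- extra_lfc[id]
      mu_h <- mu[g] * 2^(-l / 2); mu_t <- mu[g] * 2^(l / 2)
      mus <- ifelse(tumour, mu_t, mu_h)
      tries <- 0L
      repeat {
        counts[g, ] <- vapply(mus, function(m)
          rnb_trend(1, m, cfg$dispersion_a, cfg$dispersion_a0),
          numeric(1))
        tries <- tries + 1L
        if (sum(counts[g, ]) > 0 || tries >= 100L) break
      }
      if (sum(counts[g, ]) == 0) counts[g, which.max(mus)] <- 1L
    } else {
      counts[g, ] <- rnb_trend(n, mu[g], cfg$dispersion_a,
                               cfg$dispersion_a0)
    }
  }

  # low-mean genes can draw all-zero rows by chance; redraw them so the
  # planted all-zero set is exactly the truth table's
  for (g in seq_len(G)) {
    id <- gene_ids[g]
    if (id %in% zero_ids || id %in% module_gene_ids ||
        id %in% extra_de_ids) next
    tries <- 0L
    while (sum(counts[g, ]) == 0 && tries < 100L) {
      counts[g, ] <- rnb_trend(n, mu[g], cfg$dispersion_a,
                               cfg$dispersion_a0)
      tries <- tries + 1L
    }
    if (sum(counts[g, ]) == 0) counts[g, sample(n, 1)] <- 1L
  }

  ## --- module counts with post-UQUA ordering guarantee -------------------
  mod_base <- exp(stats::runif(length(module_gene_ids),
                               log(cfg$module_base_mean_range[1]),
                               log(cfg$module_base_mean_range[2])))
  names(mod_base) <- module_gene_ids
  # provisional draw so UQUA factors can be computed
  for (m in modules) for (id in c(m$lnc_ids, m$mrna_ids)) {
    mean_s <- mod_base[id] * m$levels / mean(m$levels)
    counts[id, ] <- stats::rnbinom(n, mu = mean_s,
                                   size = 1 / cfg$module_dispersion)
  }
  # iterate: compute UQUA factors, redraw module genes violating their
  # module's strict ordering, until a full pass is consistent. The
  # target means are planted on the post-UQUA scale (raw means are
  # multiplied by the current per-sample factors), so the normalized
  # values follow the module's level ordering irrespective of
  # library-size noise.
  for (pass in seq_len(cfg$max_retries)) {
    uq <- apply(counts, 2, upper_quartile_nonzero)
    fac <- uq / mean(uq)
    ok <- TRUE
    for (m in modules) {
      for (id in c(m$lnc_ids, m$mrna_ids)) {
        norm <- counts[id, ] / fac
        if (anyDuplicated(norm) || !identical(order(norm), m$ordering)) {
          ok <- FALSE
          mean_s <- mod_base[id] * m$levels / mean(m$levels) * fac
          counts[id, ] <- draw_module_gene(mean_s, cfg$module_dispersion,
                                           fac, m$ordering,
                                           cfg$max_retries)
        }
      }
    }
    if (ok) break
    if (pass == cfg$max_retries)
      stop("could not stabilize module orderings; widen module ratios")
  }

  ## --- truth table --------------------------------------------------------
  mod_rows <- do.call(rbind, lapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    ids <- c(m$lnc_ids, m$mrna_ids)
    data.frame(gene_id = ids,
               biotype = ann$biotype[match(ids, ann$gene_id)],
               direction = m$direction, true_log2fc = m$true_log2fc,
               is_module = TRUE, module = i, stringsAsFactors = FALSE)
  }))
  extra_rows <- if (n_extra_de)
    data.frame(gene_id = extra_de_ids,
               biotype = ann$biotype[match(extra_de_ids, ann$gene_id)],
               direction = ifelse(extra_lfc > 0, "up", "down"),
               true_log2fc = unname(extra_lfc), is_module = FALSE,
               module = NA_integer_, stringsAsFactors = FALSE) else NULL
  de_genes <- rbind(mod_rows, extra_rows)
  if (is.null(de_genes))
    de_genes <- data.frame(gene_id = character(), biotype = character(),
                           direction = character(),
                           true_log2fc = numeric(), is_module = logical(),
                           module = integer(), stringsAsFactors = FALSE)

  module_edges <- do.call(rbind, lapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    expand.grid(lncRNA = m$lnc_ids, mRNA = m$mrna_ids,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }))

  ## --- overlap injections -------------------------------------------------
  overlap_pairs <- data.frame(lncRNA = character(), mRNA = character(),
                              stringsAsFactors = FALSE)
  n_inj <- min(cfg$n_overlap_injections, cfg$n_modules)
  if (n_inj > 0) {
    for (m in seq_len(n_inj)) {
      l <- modules[[m]]$lnc_ids[1L]; r <- modules[[m]]$mrna_ids[1L]
      ri <- match(r, ann$gene_id); li <- match(l, ann$gene_id)
      ann$chrom[li] <- ann$chrom[ri]
      ann$start[li] <- ann$start[ri] + 10L
      ann$end[li] <- ann$start[li] + 400L
      overlap_pairs <- rbind(overlap_pairs,
                             data.frame(lncRNA = l, mRNA = r,
                                        stringsAsFactors = FALSE))
    }
  }

  ## --- gene sets -----------------------------------------------------------
  sets <- list(); pathway_modules <- list()
  if (cfg$n_modules > 0 && cfg$n_disease_sets > 0) {
    for (s in seq_len(cfg$n_disease_sets)) {
      mods <- seq_len(cfg$n_modules)[(seq_len(cfg$n_modules) - 1) %%
                                       cfg$n_disease_sets == s - 1]
      if (!length(mods)) next
      members <- unlist(lapply(modules[mods], `[[`, "mrna_ids"))
      pad <- sample(setdiff(pcg_pool, c(module_gene_ids, zero_ids)),
                    min(5, length(pcg_pool)))
      id <- sprintf("DISEASE_%02d", s)
      sets[[id]] <- c(members, pad)
      pathway_modules[[id]] <- mods
    }
  }
  for (s in seq_len(cfg$n_background_sets)) {
    id <- sprintf("BACKGROUND_%02d", s)
    sets[[id]] <- sample(setdiff(pcg_pool, zero_ids),
                         min(cfg$background_set_size, length(pcg_pool)))
  }
  gsc <- if (length(sets)) gene_set_collection(sets) else NULL

  cm <- count_matrix(counts, groups, "raw")
  truth <- list(de_genes = de_genes, modules = modules,
                module_edges = module_edges,
                all_zero_ids = zero_ids, overlap_pairs = overlap_pairs,
                pathway_modules = pathway_modules,
                n_lnc_total = length(lnc_pool), config = cfg)
  list(counts = cm, annotation = ann, gene_sets = gsc, truth = truth)
}

#' Simulate a reference-dataset DE summary for concordance testing
#'
#' Produces a reference log2FC table whose signs agree with the planted
#' truth except for a chosen fraction of flipped genes, plus the
#' (down, up, total) census [estimate_p0()] needs.
#'
#' @param truth the `truth` element of [simulate_ball_cohort()].
#' @param flip_fraction fraction of DE genes whose reference sign is
#'   flipped (rounded to a whole number of genes).
#' @param seed RNG seed.
#' @return list with `table` (data.frame gene_id, log2FC), `n_de_down`,
#'   `n_de_up`, `n_total`, `flipped_ids`.
#' @export
simulate_reference_de <- function(truth, flip_fraction = 0, seed = 1) {
  stopifnot(flip_fraction >= 0, flip_fraction <= 1)
  with_local_seed(seed, {
    de <- truth$de_genes
    n <- nrow(de)
    jit <- stats::rnorm(n, 0, 0.25)
    lfc <- de$true_log2fc + jit
    # jitter must not cross zero: concordance is about the sign
    lfc <- ifelse(sign(lfc) == sign(de$true_log2fc), lfc,
                  de$true_log2fc)
    n_flip <- round(flip_fraction * n)
    flipped <- if (n_flip) sample(de$gene_id, n_flip) else character()
    lfc[de$gene_id %in% flipped] <- -lfc[de$gene_id %in% flipped]
    is_lnc <- de$biotype %in% default_lnc_biotypes()
    list(table = data.frame(gene_id = de$gene_id, log2FC = lfc,
                            stringsAsFactors = FALSE),
         n_de_down = sum(lfc[is_lnc] < 0),
         n_de_up = sum(lfc[is_lnc] > 0),
         n_total = truth$n_lnc_total,
         flipped_ids = flipped)
  })
}
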