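# shared fixture builders; everything is generated in code

toy_counts <- function() {
  m <- matrix(c(5L, 8L, 0L, 3L, 12L, 7L), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  count_matrix(m, c("healthy", "tumour"))
}

# a small six-sample matrix with a clean two-group structure in some genes
grouped_counts <- function(n_signal = 5, n_noise = 40, seed = 42) {
  set.seed(seed)
  n <- 6
  sig <- t(vapply(seq_len(n_signal), function(i)
    c(rpois(3, 50), rpois(3, 1500)), numeric(n)))
  noise <- matrix(rnbinom(n_noise * n, mu = 300, size = 10), n_noise, n)
  m <- rbind(sig, noise)
  dimnames(m) <- list(sprintf("g%03d", seq_len(nrow(m))),
                      c("h1", "h2", "h3", "t1", "t2", "t3"))
  count_matrix(m, rep(c("healthy", "tumour"), each = 3))
}

# small simulated cohort for fast tests
tiny_sim <- function(seed = 5, ...) {
  simulate_ball_cohort(sim_config(n_genes = 600, n_modules = 2,
                                  lnc_per_module = 1, mrna_per_module = 3,
                                  n_disease_sets = 2,
                                  n_background_sets = 2,
                                  seed = seed, ...))
}

# minimal hand-built network object for graph-side unit tests
fake_network <- function(edges) {
  structure(list(edges = edges,
                 excluded = edges[0, , drop = FALSE],
                 skipped = data.frame(),
                 n_pairs_tested = nrow(edges),
                 thresholds = c(rho_min = 1, p_max = 0.005),
                 positive_only = FALSE),
            class = "coexpression_network")
}

# permute a per-sample label vector under a fixed seed
with_seed_sample <- function(group, seed) {
  set.seed(seed)
  out <- factor(sample(as.character(group)), levels = levels(group))
  names(out) <- names(group)
  out
}

edge_df <- function(lnc, mrna) {
  data.frame(lncRNA = lnc, mRNA = mrna, rho = 1, p = 2 / 720,
             overlap_excluded = FALSE, direction_consistent = NA,
             stringsAsFactors = FALSE)
}
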