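#' Drop genes with insufficient non-zero counts
#'
#' The default removes only genes whose counts are zero in every sample,
#' the weakest filter consistent with working on non-zero counts; stricter
#' filters are available through `min_nonzero_samples`.
#'
#' @param cm raw [count_matrix].
#' @param min_nonzero_samples minimum number of samples with a non-zero
#'   count a gene needs to be retained (default 1).
#' @return Filtered [count_matrix]; the number of removed genes is attached
#'   as attribute `n_removed` and reported via `message()`.
#' @export
filter_nonzero <- function(cm, min_nonzero_samples = 1L) {
  stopifnot(inherits(cm, "count_matrix"))
  keep <- rowSums(cm$values > 0) >= min_nonzero_samples
  out <- set_values(cm, cm$values[keep, , drop = FALSE], cm$normalization)
  message(sprintf("filter_nonzero: removed %d of %d genes",
                  sum(!keep), length(keep)))
  attr(out, "n_removed") <- sum(!keep)
  out
}

# 75th percentile of the non-zero counts of one sample (type-7 quantile,
# linear interpolation between order statistics).
upper_quartile_nonzero <- function(x) {
  nz <- x[x > 0]
  if (length(nz) < 4)
    stop("sample has fewer than 4 non-zero genes; cannot compute upper quartile")
  stats::quantile(nz, 0.75, names = FALSE, type = 7)
}

#' Upper-quartile (UQUA) normalization
#'
#' Divides each sample by the 75th percentile of its non-zero counts. With
#' `rescale = TRUE` (default) the result is multiplied by the across-sample
#' mean of those percentiles, keeping values on a count-like scale; pure
#' division changes nothing for the rank- and correlation-based stages
#' downstream.
#'
#' @param cm raw, zero-filtered [count_matrix].
#' @param rescale multiply by the mean upper quartile (default `TRUE`).
#' @return [count_matrix] in `uqua` state; per-sample scale factors attached
#'   as attribute `scale_factors`.
#' @export
uqua_normalize <- function(cm, rescale = TRUE) {
  stopifnot(inherits(cm, "count_matrix"))
  if (cm$normalization != "raw")
    stop("uqua_normalize expects raw counts")
  uq <- apply(cm$values, 2, upper_quartile_nonzero)
  fac <- if (rescale) uq / mean(uq) else uq
  vals <- sweep(cm$values, 2, fac, "/")
  out <- set_values(cm, vals, "uqua")
  attr(out, "scale_factors") <- fac
  out
}

# DESeq-style median-of-ratios size factors. Genes with a zero anywhere do
# not contribute. Falls back to upper-quartile factors (scaled to geometric
# mean 1) when no gene is all-positive.
size_factors_mor <- function(counts) {
  logs <- log(counts)
  loggeo <- rowMeans(logs)
  usable <- is.finite(loggeo)
  if (sum(usable) >= 1) {
    sf <- apply(logs[usable, , drop = FALSE], 2,
                function(lc) exp(stats::median(lc - loggeo[usable])))
  } else {
    uq <- apply(counts, 2, upper_quartile_nonzero)
    sf <- uq / exp(mean(log(uq)))
  }
  sf
}

#' Variance-stabilizing transformation for negative-binomial counts
#'
#' Normalizes by median-of-ratios size factors, estimates gene-wise
#' dispersions by method of moments, fits the parametric dispersion-mean
#' trend `alpha(mu) = a/mu + a0` by least squares on genes with positive
#' dispersion estimates, and applies the closed-form NB
#' variance-stabilizing transform implied by the trend:
#' `vst(q) = log2( (1 + a + 2*a0*q + 2*sqrt(a0*q*(1 + a + a0*q))) / (4*a0) )`.
#' The transform is strictly increasing in `q`. When the trend cannot be
#' fitted (`a0 <= 0` or fewer than 10 usable genes) the fallback
#' `log2(q + pseudocount)` is used and flagged.
#'
#' @param cm raw, zero-filtered [count_matrix] with at least 2 samples.
#' @param fallback_pseudocount pseudocount of the log2 fallback (default 1).
#' @return [count_matrix] in `vst` state, with attribute `vst_model`: a list
#'   of `size_factors`, `a_slope`, `a0_intercept`, `n_disp_genes` and
#'   `fallback` (logical).
#' @export
vst_transform <- function(cm, fallback_pseudocount = 1) {
  stopifnot(inherits(cm, "count_matrix"))
  if (cm$normalization != "raw")
    stop("vst_transform expects raw counts")
  if (ncol(cm$values) < 2)
    stop("vst_transform needs at least 2 samples")
  counts <- cm$values
  sf <- size_factors_mor(counts)
  q <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(q)
  v <- apply(q, 1, stats::var)
  # E[var of normalized counts] = mu * mean(1/sf) + alpha * mu^2
  xim <- mean(1 / sf)
  ok <- mu > 0
  disp <- (v[ok] - xim * mu[ok]) / mu[ok]^2
  mu_ok <- mu[ok]
  # method-of-moments estimates at tiny means or with extreme values are
  # uninformative; exclude them from the trend fit
  use <- is.finite(disp) & disp > 1e-8 & disp < 20 & mu_ok > 1
  a <- NA_real_; a0 <- NA_real_; fallback <- TRUE
  if (sum(use) >= 10) {
    co <- fit_dispersion_trend(disp[use], mu_ok[use])
    a0 <- co[["a0"]]
    a <- max(co[["a"]], 0)
    if (is.finite(a0) && a0 > 0) fallback <- FALSE
  }
  if (fallback) {
    vals <- log2(q + fallback_pseudocount)
    message("vst_transform: dispersion trend unusable, using log2 fallback")
  } else {
    vals <- log2((1 + a + 2 * a0 * q +
                    2 * sqrt(a0 * q * (1 + a + a0 * q))) / (4 * a0))
  }
  out <- set_values(cm, vals, "vst")
  attr(out, "vst_model") <- list(size_factors = sf, a_slope = a,
                                 a0_intercept = a0,
                                 n_disp_genes = sum(use),
                                 pseudocount = fallback_pseudocount,
                                 fallback = fallback)
  out
}

# Least-squares start, then a Gamma GLM with identity link (dispersion
# estimates have multiplicative, not additive, noise) iterated with
# trimming of extreme-ratio outliers.
fit_dispersion_trend <- function(disp, mu) {
  co <- unname(stats::coef(stats::lm(disp ~ I(1 / mu))))
  for (i in 1:10) {
    g <- tryCatch(suppressWarnings(
      stats::glm(disp ~ I(1 / mu), family = Gamma(link = "identity"),
                 start = pmax(co, c(1e-4, 1e-4)))),
      error = function(e) NULL)
    if (is.null(g)) break
    co <- unname(stats::coef(g))
    ratio <- disp / (co[1] + co[2] / mu)
    keep <- ratio > 1e-4 & ratio < 15
    if (all(keep) || sum(keep) < 10) break
    disp <- disp[keep]; mu <- mu[keep]
  }
  c(a0 = co[1], a = co[2])
}

# the closed-form transform on its own; used by tests for monotonicity
vst_closed_form <- function(q, a, a0) {
  log2((1 + a + 2 * a0 * q + 2 * sqrt(a0 * q * (1 + a + a0 * q))) /
         (4 * a0))
}
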