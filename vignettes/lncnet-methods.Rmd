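---
title: "lncnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the statistical model behind each pipeline stage,
the tunable parameters with their defaults and rationale, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where more than one defensible choice existed.

## The problem setting

The pipeline targets two-group bulk RNA-seq cohorts at the smallest
sample sizes that occur in clinical pilot studies — three tumour samples
against three healthy donors. At n = 6 nothing asymptotic can be trusted:
Spearman correlation p-values must come from the exact permutation null,
fold-change estimates need pseudocounts against near-zero means, and any
"significant correlation" claim must survive the observation that with
six samples only 720 rank orders exist. The pipeline's core design
choices all flow from taking this small-n regime seriously.

## Normalization

**Upper-quartile (UQUA).** Each sample is divided by the 75th percentile
of its non-zero counts (type-7 quantile, linear interpolation — quantile
dialects differ, so this is fixed and documented). By default the result
is rescaled by the across-sample mean of those percentiles so values stay
on a count-like scale; a `uqua.rescale = FALSE` option performs pure
division. The choice is immaterial for every downstream rank- or
correlation-based stage.

**Variance-stabilizing transform (VST).** Counts are normalized by
median-of-ratios size factors, gene-wise NB dispersions are estimated by
method of moments, and the parametric trend α(μ) = a/μ + α₀ is fitted —
first by least squares for a starting value, then by a Gamma GLM with
identity link (dispersion estimates carry multiplicative noise), iterated
with trimming of points whose ratio to the fit is outside [1e-4, 15].
Method-of-moments estimates at μ ≤ 1 or outside (1e-8, 20) are excluded
from the fit as uninformative. The closed-form transform for this trend,

$$\mathrm{vst}(q) = \log_2\!\frac{1 + a + 2\alpha_0 q +
2\sqrt{\alpha_0 q (1 + a + \alpha_0 q)}}{4 \alpha_0},$$

is strictly increasing in the normalized count $q$, approaches log2 for
large counts, and compresses the noisy low-count range. When the fit is
unusable (α₀ ≤ 0 or fewer than 10 usable genes) the pipeline falls back
to log2(q + 1) and flags the fallback in the returned model. The
acceptance surface of this component is the variance-flattening property
— the SD of transformed values across low/mid/high mean strata — not
bit-equality with any particular external implementation.

On NB data simulated under the default trend, the stratum-SD ratio of the
VST is ≈ 1.2 (flat); the same ratio for log2(count + 1) is ≈ 3. A useful
bound to know: under α(μ) = 3/μ + 0.05 the per-gene SD of
log2(1 + count) is maximised near μ ≈ 3 at ≈ 1.17 and floors at
√(ln 1.05)/ln 2 ≈ 0.32 for large μ, so the log2 stratum ratio cannot
exceed ≈ 3.6 whatever mean grid is used.

**"Filtered for non-zero counts"** is read as the weakest filter
consistent with the wording: only genes with zero counts in *every*
sample are dropped (`filter.min_nonzero_samples = 1`); stricter per-group
filters are a configuration option.

## PCA-based unsupervised feature extraction

PCA runs on the VST values of the lncRNAs only, genes centred but *not*
unit-scaled — the VST is the variance equalizer, and rescaling would undo
it. With s samples at most s − 1 eigenvalues are non-zero. Components are
retained up to a cumulative explained-variance threshold (default 0.6,
i.e. the leading components that carry "most" of the variance at this
cohort scale; a fixed k is available).

Feature selection applies **both** |Pearson r| ≥ 0.8 against a retained
PC's sample scores **and** BH-FDR ≤ 0.05 on the two-sided correlation
p-value. The conjunction is deliberate: an r-threshold alone ignores
multiplicity over thousands of lncRNAs, an FDR threshold alone admits
weak correlations at larger n; each criterion is independently
configurable. |r| rather than signed r is used because the sign of a
principal component is arbitrary. The FDR is computed within each
retained PC by default (`fdr_scope = "global"` is available) since
extraction is performed per component. Features qualifying on several PCs
are assigned uniquely to the PC with maximal |r|, so per-PC counts
partition the selection. The selected set is re-checked by rerunning PCA
on it alone and reporting the group-label silhouette in the (PC1, PC2)
plane plus a hard-margin linear separability flag.

## Differential expression

The primary route ingests an externally computed table (gene, log2FC,
padj) and applies the candidate thresholds |log2FC| ≥ 1.5, padj ≤ 0.05.
The self-contained internal route exists so synthetic runs need no
external input: log2FC = log2((mean_tumour + 1)/(mean_healthy + 1)) on
UQUA values (the pseudocount guards the near-zero means that real
candidate tables exhibit), p-values from a two-sided Welch t-test on VST
values, Benjamini–Hochberg correction. This is a deliberately simple
stand-in for a full NB shrinkage model, adequate for the large planted
effects the generator produces; it is not a DESeq2 reimplementation, and
at 3 + 3 its Welch degrees of freedom (~4) put a floor of roughly 1e-6 on
attainable p-values.

Candidates are the intersection of the PCA selection with the DE
lncRNAs, ranked by log2FC within each direction (most down-regulated
first, then most up-regulated), mirroring the conventional candidate
table layout.

## The perfect-correlation network

Spearman's rho is computed from average ranks. For tie-free data with
n ≤ 9 the p-value is exact: the null distribution of rho over all n!
permutations is enumerated once per n and cached. With ties, average
ranks cannot reach |rho| = 1 and the null is no longer the tie-free
table, so a deterministic Monte-Carlo permutation p (1e5 draws under a
fixed internal seed, restoring the caller's RNG state) is used. For
n > 9 the t approximation is adequate and enumeration would be wasteful.

At n = 6 the exact null makes the edge filter interpretable: the
two-sided p for |rho| = 1 is 2/720 ≈ 0.00278 < 0.005, while the
second-largest attainable |rho| (0.9429, one adjacent transposition) has
p = 12/720 ≈ 0.017. The default filter rho_min = 1 (within 1e-12),
p < 0.005 therefore retains exactly the perfectly monotone pairs — and
the 0.005 cutoff is only meaningful *because* the p-value is exact; the
t approximation is invalid here.

Both signs are retained by default (perfectly concordant or perfectly
reversed orders); a `positive_only` switch restricts to rho = +1. Edges
whose two genes overlap on the same chromosome (strand-agnostic, any
shared base) are excluded and logged — co-expression of overlapping loci
is more parsimoniously explained by shared sequence or antisense
transcription than by regulation. lncRNA clusters are connected
components of the lncRNA–lncRNA graph with an edge when two lncRNAs share
at least one co-expressed mRNA; exact-set groups (identical mRNA
neighbour sets) and "acting alone" singletons are reported alongside,
since both coarse and exact sharing are biologically meaningful
groupings.

## Concordance validation

For candidates measured in a second cohort, concordance means agreement
of log2FC sign; zero fold changes are indeterminate and excluded from the
denominator rather than counted discordant. The null success probability
p0 is the reference cohort's background DE rate (down + up)/total — the
probability that a random lncRNA would be "concordant-eligible" by
chance. The test is the exact one-sided upper binomial tail
P(X ≥ k), summed term by term; no normal approximation. One-sidedness is
the correct alternative: the claim under test is *excess* concordance.
p0 is used at full precision by default, with the option to supply a
rounded published value directly for comparison against printed results.

## Guilt-by-association

Each lncRNA inherits the functional annotation of its co-expressed mRNA
set via cumulative hypergeometric enrichment against user-supplied GMT
sets over a configurable universe (default: all annotated protein-coding
genes in the matrix — the background such analyses condition on; query genes
absent from the universe are dropped and logged). Two significance
filters are reported side by side — −log10 p > 6 (a stringent,
Metascape-style cutoff) and BH-FDR ≤ 0.05 — because practice differs
between tools and the package takes no side. Redundancy among
significant terms is summarized by Cohen's kappa between their
overlap-gene membership vectors over the union of significant-term
genes, with term clusters as connected components at kappa > 0.3.
External enrichment services are deliberately not called: they are
irreproducible dependencies.

## The synthetic-data generator

`sim_config()` defaults define the reference study conditions: 2500
genes, 3 + 3 samples, NB counts with trend α(μ) = 3/μ + 0.05, baseline
means log-uniform on [0.5, 5000], biotype proportions matching an
annotated human gene census (73% protein-coding; 13.6% lncRNA split
5.9/4.7/0.9/1.7/0.36/0.02 across antisense, lincRNA,
processed-transcript, sense-intronic, sense-overlapping and 3'
overlapping classes; 3.1% short non-coding; 9.8% pseudogene; 0.37%
other), 2% all-zero rows, five planted modules of 2 lncRNAs + 4 mRNAs,
and GMT sets built over the module mRNAs plus random background sets.

**How perfect modules are planted.** Each module draws one strict
per-sample ordering (the low-expression block gets levels (1, w, w²) in
random order, the high block b·(1, w, w²); tumour is the high block for
up-modules). Counts are drawn NB around these targets *multiplied by the
current upper-quartile factors*, and redrawn until every module gene's
post-UQUA values follow the module ordering with no ties — planting on
the post-UQUA scale is the only way to guarantee rho = 1 with discrete
counts under library-size noise. Orderings are rejection-drawn distinct
from every other module's ordering *and its reversal*; otherwise
cross-module pairs would be perfectly (anti-)correlated by construction.

**Why the module genes are highly expressed.** Defaults w = 1.1, b = 32
(planted |log2FC| = 5, within the span such candidate tables report),
base means 20000–60000, module dispersion 1e-4. Two constraints force the
high-expression regime: the within-group level gaps (10%) must dominate
Poisson noise, or the ordering-rejection step selectively accepts draws
with inflated within-group spread (a conditioning bias that quietly
destroys the Welch t statistic); and at 3 + 3 with BH over 2500 genes a
module gene needs p ≲ 1e-4 to stay significant, which at df ≈ 4 requires
t ≳ 15. Both are comfortably met when Poisson CV ≈ 3% ≪ 10% gaps.

**Extra DE genes.** `de_fraction` (default 0) plants additional
non-module group effects with |log2FC| uniform on [1.5, 5.3], restricted
to genes with baseline mean ≥ 100 — a fold change on a near-zero baseline
is undetectable in any 3 + 3 design, and planting undetectable truths
makes recovery metrics meaningless. The default is zero because
non-module DE genes share the group structure with the candidates: for
two fully rank-separated same-direction genes, P(identical within-group
orders) = 1/36 per pair, an order of magnitude above the exchangeable
null rate 2/720. With extra DE genes present, "false" perfect pairs are
therefore an intrinsic property of group-structured data, not an
implementation artifact; the default keeps the co-expression ground truth
unambiguous, and DE-power experiments switch `de_fraction` on explicitly.

**What the generator does not emulate:** batch effects, sample-quality
gradients, correlated null genes, GC/length biases, isoform-level
structure, and realistic (partial, noisy) co-expression — planted modules
are exact by design. Passing recovery tests therefore demonstrates that
the pipeline's machinery is correct under its own assumptions, not that
real cohorts of this size yield reliable candidates.

## Numerical choices and degenerate inputs

* Perfect-correlation tolerance: |rho − 1| ≤ 1e-12; rank ties disqualify
  perfection (average ranks cannot reach 1 with ties).
* Constant expression vectors make rho undefined: the pair is skipped and
  logged, never silently scored.
* Welch test with zero variance in both groups: p = 1 for equal means
  (no evidence), 0 for distinct constant means (exact separation).
* Quantiles are type-7 throughout; coordinates are 1-based inclusive
  (GTF convention) everywhere.
* Genes absent from the annotation are dropped with a logged count before
  any analysis stage.
* The Monte-Carlo Spearman path and the generator use fixed/derived seeds
  and restore the caller's RNG state, so `run_all()` is a pure function
  of (inputs, configuration).

## Problem sizes used by the test suite

Unit tests run on 300–1200-gene simulations; the end-to-end recovery and
null-specificity checks use the full 2500-gene default configuration and
20 replicates of an 800-gene null configuration respectively. These sizes
were chosen so the entire suite exercises every stage, including full-
scale recovery, in well under a minute on one CPU.

## Known limitations

* The internal DE route is a stand-in, not a shrinkage estimator; with
  real data an externally computed table is the intended input.
* The exact Spearman null is enumerated only to n = 9 (9! = 362,880
  orders); beyond that the t approximation is used, which is exactly the
  regime where it is safe.
* Enrichment treats gene sets as flat lists; no ontology-graph
  redundancy collapsing is attempted beyond the kappa clusters.
* The silhouette/separability report quantifies separation in the first
  two PCs only, matching how such analyses are read in practice.
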