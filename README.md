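# lncnet

Candidate long non-coding RNA (lncRNA) discovery from small two-group bulk
RNA-seq cohorts, with function prediction by guilt-by-association.

Many lncRNAs are expressed at low levels and have no annotated function,
yet show strikingly disease-specific expression — which makes them
attractive diagnostic biomarkers in settings such as paediatric B-cell
acute lymphoblastic leukaemia (B-ALL), where cohorts are often tiny
(3 patients vs 3 healthy donors). `lncnet` implements a complete,
reproducible discovery pipeline for exactly this regime:

1. **Normalization** — upper-quartile (UQUA) scaling of raw counts, and a
   closed-form negative-binomial variance-stabilizing transform (VST)
   under a fitted parametric dispersion trend α(μ) = a/μ + α₀.
2. **PCA-based unsupervised feature extraction** — principal components
   are retained up to a cumulative explained-variance threshold (default
   60%); lncRNAs with |Pearson r| ≥ 0.8 and BH-FDR ≤ 0.05 against a
   retained PC's sample scores are selected and uniquely assigned to the
   PC with maximal |r|.
3. **Differential expression** — an external DE table can be ingested, or
   a self-contained internal route is used (Welch t on VST values, BH
   correction), with candidate status at |log2FC| ≥ 1.5 and padj ≤ 0.05.
   Candidates are the intersection of the PCA selection with the DE
   lncRNAs.
4. **Perfect-correlation co-expression network** — every candidate lncRNA
   is tested against every DE protein-coding gene with Spearman's rho and
   an **exact permutation p-value**: at n ≤ 9 samples the full n!
   permutation null is enumerated (cached per n), so at n = 6 the edge
   filter rho = ±1, p < 0.005 provably retains only perfectly monotone
   pairs (p = 2/720 ≈ 0.0028; the next attainable |rho| = 0.943 already
   has p = 12/720). Edges between genomically overlapping genes are
   excluded. lncRNAs sharing co-expressed mRNAs are clustered.
5. **Cross-cohort validation** — fold-change sign concordance of the
   candidates against a reference dataset, scored with an exact one-sided
   binomial tail P(X ≥ k), X ~ Binomial(n, p0), where p0 is the reference
   cohort's background DE rate.
6. **Guilt-by-association annotation** — cumulative hypergeometric
   enrichment of each lncRNA's co-expressed mRNA set against user-supplied
   GMT pathways (filters −log10 p > 6 or FDR ≤ 0.05), a Cohen's-kappa
   similarity graph over significant terms (edges at kappa > 0.3), and
   per-lncRNA disease-pathway membership with mRNA-sharing statistics.

A first-class synthetic-data generator (`simulate_ball_cohort()`) plants
NB counts with a known dispersion trend, biotype-annotated genes,
perfect-correlation lncRNA–mRNA modules that survive UQUA by
construction, non-overlapping genomic coordinates and GMT pathways — with
full ground-truth bookkeeping, so every stage is testable end to end.

## Worked example

```r
library(lncnet)

sim <- simulate_ball_cohort(sim_config(seed = 1))
ref <- simulate_reference_de(sim$truth, flip_fraction = 0.1, seed = 1)
res <- run_all(sim$counts, sim$annotation, sim$gene_sets, reference = ref)
```

The run emits one structured log line per stage:

```
[annotate] n_in=2500 n_annotated=2500 n_dropped=0
[filter_nonzero] n_removed=50 n_out=2450
[normalize] uqua=TRUE vst_fallback=FALSE
[partition] n_lnc=333 n_pcg=1792 n_other=325
[differential_expression] n_de=30 n_de_lnc=10 n_de_pcg=20 source=internal
[pca_feature_extraction] n_lnc_in=333 k_selected=1 n_selected=11 silhouette=0.9701 separable=1
[intersect_candidates] n_candidates=10 n_down=4 n_up=6
[coexpression_network] n_pairs_tested=200 n_edges=40 n_excluded=0 n_lnc=10 n_mrna=20 n_clusters=5
[guilt_by_association] n_sets=10 n_lnc_in_disease_sets=10
[concordance] n_compared=10 k_concordant=9 p0=0.0294 p_value=1.60338871773375e-13
```

Reading the funnel: of 333 lncRNAs, 11 are selected by PCA-based feature
extraction and 10 survive the DE intersection (these are exactly the 10
planted module lncRNAs; the selection silhouette 0.97 confirms the groups
separate in the (PC1, PC2) plane). All 40 planted lncRNA–mRNA pairs come
back at rho = 1 with the exact p = 2/720, none of the 200 tested pairs is
a false positive, and the five planted modules reappear as the five
lncRNA clusters. Against the reference table (10% of signs deliberately
flipped) 9 of 10 candidates are sign-concordant; with this cohort's
background DE rate p0 = 0.029 the exact binomial tail is ~1.6e-13.

```r
print(res$objects$network)
#> coexpression_network: 40 edges (10 lncRNAs x 20 mRNAs), 200 pairs tested, 0 overlap-excluded
print(res$objects$concordance)
#> concordance: 9/10 concordant; p0 = 0.0294; exact binomial p = 1.60339e-13
head(res$objects$candidates$candidates, 3)
#>       gene_id    log2FC         padj direction
#> 1 SYNTG001448 -5.037732 0.0004050153      down
#> 2 SYNTG001859 -5.023747 0.0004050153      down
#> 3 SYNTG000324 -5.017296 0.0004832953      down
```

Real data enter the same way through `read_counts()`,
`read_annotation()` (BioMart-style TSV or GTF), `read_gmt()` and
optionally `ingest_de_table()`; `run_all(..., output_dir = "out")` writes
the run report (JSON), candidate/feature/scree/edge tables (TSV) and a
GraphML network export.

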