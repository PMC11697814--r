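# oostage

Chromatin-stage inference and methylome dynamics for fully-grown mouse
GV oocytes.

During the final stage of its growth, the mouse germinal-vesicle (GV)
oocyte reorganizes its chromatin from a *non-surrounded nucleolus* (NSN)
configuration to a *surrounded nucleolus* (SN) ring around the nucleolus.
The transition coincides with genome-wide transcriptional silencing, the
loss of more than a thousand transcript species, a late gain of DNA
methylation concentrated in intermediately methylated domains, and an
unusual joint enrichment of H3K36me3 with H3K27me3 at late-methylating
regions. `oostage` packages the quantitative machinery needed to study
this transition from three data modalities — single-oocyte RNA-seq
counts, sparse single-cell bisulfite (scBS-seq) calls and histone-mark
ChIP tracks — together with seeded synthetic-data generators carrying
planted ground truth, so that every stage of the analysis can be
exercised and validated without access to the original sequencing data.

It is intended for computational biologists analysing oocyte
single-cell multi-omics, and for groups using transgenic mouse models
who need a transcriptome-based quality control for skewed NSN:SN ratios.

## What it computes

**Transcriptome complexity and differential expression.** Per-sample
detected-transcript counts (count ≥ 1), a depth-matched Wilcoxon
rank-sum comparison, the "SN-missing" filter (≥ 1 count in ≥ 7/9 NSN
oocytes and 0 counts in ≥ 10/16 SN oocytes, generalized to fractions),
expression-quartile bias chi-square, an over-dispersion comparison, and
a negative-binomial Wald differential-expression test: median-of-ratios
size factors *s<sub>j</sub>*, a trended dispersion
α(μ) = a₀ + a₁/μ, the per-transcript GLM

> K<sub>ij</sub> ~ NB(μ<sub>ij</sub>, α),  log μ<sub>ij</sub> = log s<sub>j</sub> + β₀ + β₁·stage<sub>j</sub>

with a Wald test on β₁, BH adjustment, and a normal-prior shrunken LFC.

**The 100-transcript NSN–SN classifier.** Significant transcripts
(padj < 0.05) are intersected with an external reference DEG list, the
top 65 down-regulated and top 35 up-regulated transcripts by FDR form
the marker panel, reference samples are Z-scored and projected by PCA,
and query samples (single-cell or bulk) are called by nearest centroid
with a distance-ratio rule d<sub>near</sub>/d<sub>far</sub> ≤ 0.8 —
samples without a clear signature stay `unclassified`.

**Consensus DMR calling for sparse single-cell methylomes.** The genome
is segmented into unmethylated (< 25%), intermediate and methylated
(> 70%) domains. Cells are pooled into 3 random pseudobulk groups of 4
per stage; each of 100 iterations tests every domain covered in all six
groups with a grouped binomial logistic regression (stage as predictor)
and requires a pooled NSN–SN difference of strictly more than 10
percentage points. Domains called with consistent sign in at least 50%
of their testable iterations are the consensus DMRs. Interval feature
enrichment (odds ratio, log2 fold enrichment versus seeded size-matched
random draws) follows.

**Joint histone-mark window categories.** RPKM over a fixed 2-kb window
tiling, an input-control validity band (0.04 ≤ input RPKM ≤ 2), per-mark
enrichment at RPKM > 1 (strict), the seven joint categories of
H3K4me3 / H3K27me3 / H3K36me3 plus `none`, category composition across
methylation-domain classes, and category enrichment inside query
interval sets against seeded random domain sets.

## Worked example

```r
library(oostage)

# A 9 NSN + 16 SN synthetic cohort with planted degradation signatures
sim <- simulate_counts(sim_config(seed = 1, n_transcripts = 2000))
de  <- differential_expression(sim$counts, sim$meta)
head(de, 3)
#>   transcript_id base_mean   lfc shrunk_lfc se_lfc  p_value     padj direction
#> 1 tx00324           116.  -2.00      -1.97 0.0968 8.94e-95 1.79e-91        -1
#> 2 tx01114            43.8 -1.96      -1.93 0.0956 1.71e-93 1.71e-90        -1
#> 3 tx00341           328.  -2.01      -1.97 0.110  1.51e-74 1.00e-71        -1
```

The top transcripts recover the planted 4-fold SN decrease (LFC ≈ −2).
Building and applying the 100-transcript classifier:

```r
model <- build_classifier(de, c(sim$truth$degraded_ids, sim$truth$up_ids))
model <- fit_reference(model, sim$counts, sim$meta)
model
#> <nsn_sn_classifier> 100 markers (65 down, 35 up in SN); fitted

query <- simulate_counts(sim_config(seed = 2, transcriptome_seed = 1,
                                    n_transcripts = 2000, n_nsn = 4, n_sn = 8))
calls <- classify_stage(model, query$counts)
table(call = calls$call, truth = query$truth$stage[calls$sample_id])
#>      truth
#> call  NSN SN
#>   NSN   4  0
#>   SN    0  8
```

Every query cell is called, and every call matches the planted stage.
Consensus DMR calling on a 12 NSN + 28 SN synthetic methylome with 20
planted 30-point hyper-DMRs:

```r
cfg  <- sim_config(seed = 1, n_nsn = 12, n_sn = 28)
sm   <- simulate_methylomes(cfg)
dmrs <- call_dmrs(sm$cells, sm$domains, seed = 1)
glance(dmrs)
#>   n_dmrs n_hyper n_hypo pct_hyper n_iterations consensus diff_threshold
#> 1     20      20      0       100          100       0.5             10

head(tidy(dmrs), 3)
#>   domain_id pct_nsn pct_sn mean_diff consensus_frac n_testable class       domain_class
#> 1 dom00044     67.8   97.4      29.6              1        100 hyper_in_SN intermediate
#> 2 dom00049     30.8   58.1      27.3              1        100 hyper_in_SN intermediate
#> 3 dom00123     35.1   65.5      30.4              1        100 hyper_in_SN intermediate
```

All 20 planted hyper-DMRs are recovered with no false discoveries, at
consensus fractions of 100%, and each sits in an intermediate domain —
the domain class where late methylation gain concentrates. `plot_volcano()`,
`plot_stage_calls()`, `plot_domain_methylation()` and
`plot_category_enrichment()` give ggplot views of these results, and
`run_pipeline()` chains all four stages with a reproducibility manifest.

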