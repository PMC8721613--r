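# cocultex

Mixture deconvolution and additivity screening for two-population coculture
transcriptomes.

When mesenchymal stromal cells (MSCs) and chondrocytes are pelleted
together, the coculture is sequenced as one bulk RNA-seq sample. `cocultex`
answers two questions about such data:

1. **How much of the coculture's RNA comes from each population?** In a
   sex-mismatched design (male MSC donors, female chondrocyte donor),
   Y-chromosome transcripts can only come from the MSCs. For each chrY
   marker gene *m*, `100 × RPKM_coculture(m) / RPKM_MSCmono(m)` estimates
   the surviving MSC signal; the mixing fraction π is the mean of these
   ratios over markers, pooled across donors.
2. **Which genes deviate from a pure mixture?** Under additivity the
   expected coculture expression of gene *g* is the convex combination

       RPKM_expected(g) = π · RPKM_MSCmono(g) + (1 − π) · RPKM_CHmono(g)

   and the deviation statistic is Fc(g) = RPKM_observed(g) / RPKM_expected(g).
   Genes with Fc > 2 are called interaction up-regulated, Fc < 0.5
   down-regulated, after a floor filter requiring RPKM strictly above 0.3
   in each sample of the donor-pair trio. Calls are intersected across
   donor pairs into consensus (Venn) sets.

A synthetic-data generator with known ground truth (`generate_dataset()`,
`recovery_experiment()`) validates every stage, and an optional
parametric-bootstrap p-value (`deviation_pvalue()`) is available for
fold-change deviations (off by default).

## Worked example

The packaged 7-marker fixture (two male MSC donors A211 and A283, one
shared female chondrocyte donor) reproduces the marker-based estimate:

```r
library(cocultex)
fx <- table1_fixture()
est <- lapply(c("A211", "A283"), function(p)
  estimate_proportion(fx$matrix, fx$design, fx$markers, p))
pool_proportions(est, rounding = 2)
```

```
Mixing fraction pi = 0.57 (complement 0.43) pooled over 2 pairs
```

The per-donor estimates print the full ratio table; for A211:

```
Proportion estimate for pair A211 (7 markers)
  RPS4Y1      62.54992 %
  DDX3Y       55.65730 %
  PRKY        50.55364 %
  USP9Y       52.52960 %
  KDM5D       73.88393 %
  ZFY         52.67286 %
  EIF1AY      53.05829 %
  Average     57.27222 %
```

i.e. 57% of the coculture transcriptome is MSC-derived — down from the 80%
seeding ratio, a 23-point attrition (`attrition_report(0.57, 0.8)`).
Screening a synthetic three-pair dataset end to end:

```r
sim <- generate_dataset(sim_config(noise_sigma = 0, seed = 1))
res <- detect_pair(sim$matrix, sim$design, "P01", 0.57)
res
#> Additivity screen for pair P01 (pi = 0.57): 46 up, 45 down, 1657 additive, 259 filtered
call_performance(res, sim$truth)[1:2]
#> sensitivity specificity
#>           1           1
```

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (marker-table reproduction, zero-noise validation, noisy
parameter recovery), writing their tables under `results/`.

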