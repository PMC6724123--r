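# coldcascade

Cascade classification of two-line cold-stress RNA-seq time courses.

Cold acclimation — the gain in freezing tolerance after exposure to low
but non-freezing temperature — distinguishes winter-hardy from
frost-sensitive pea lines. Given a gene × sample count matrix from a
2 lines (frost-tolerant `Ch`, frost-sensitive `Te`) × 2 treatments
(low-temperature `LT`, control `N`) × 3 times (`T0`,`T1`,`T2`) × 2
replicates design, this package:

1. normalizes counts with median-of-ratios size factors and tests nine
   condition contrasts (`ChNT0:TeNT0`, and `T1`/`T2` vs `T0` within
   each line × treatment) with a per-gene negative-binomial Wald test
   (`variance = μ + αμ²`, method-of-moments dispersion with shrinkage);
2. selects differentially expressed genes (DEGs) by testability, total
   normalized count > 48, BH-adjusted p ≤ 0.02 in ≥ 1 contrast, and
   best-hit E-value ≤ 9 × 10⁻⁴;
3. partitions DEGs with a line × treatment ANOVA cascade on
   `log2(normalized + 1)` — line-only → **LR** (Line Response),
   treatment-only → **TCR** (Temperature Common Response), both →
   **TLSR** (Temperature Line-Specific Response);
4. splits each set into expression-pattern subsets (LR: 2, TCR: 2,
   TLSR: 4) by average-linkage clustering on `1 − Pearson correlation`
   of standardized 12-condition profiles, labelling clusters by the
   signs of Δline = mean(Ch) − mean(Te) and Δ_LT = mean(LT T1,T2) −
   mean(LT T0);
5. builds functional summary tables (kinases, transcription factors,
   cold-related GO terms GO:0009409 / GO:0009631 / GO:0070417, with a
   hypergeometric enrichment test) and a qPCR corroboration statistic,
   the uncentered correlation `R = Σxy / √(Σx² Σy²)`.

A synthetic-count generator plants known LR / TCR / TLSR archetypes on
the factorial design so every stage is verifiable against ground truth.
See `vignettes/cascade-methods.Rmd` for the model, parameter choices
and limitations.

## Worked example

The `analysis/` scripts run the whole study on the default synthetic
data (1000 null genes + 100 per planted archetype, base mean 100,
dispersion 0.05, offset 1.5 log2, slope 1.0 log2 per LT step, seed 42):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_classify.R
Rscript analysis/04_cluster.R
Rscript analysis/05_summarize.R
Rscript analysis/06_qpcr.R
```

Stage 2–4 print, on this data:

```
genes:             1800
testable:          1800
> 48 norm counts:  1800
DEGs (p_adj<=.02): 801
annotated DEGs:    801

DEG universe:         801
LR  (line only):      177
remaining after LR:   624
TCR (treatment only): 199
TLSR (both factors):  402
NS among DEGs:        23
planted set-label recovery: 96.0%

subset-label recovery among correctly-set genes: 100.0%
```

Reading: of the 1800 simulated genes, the four filters keep 801 (the
800 planted non-null genes minus those the 2-replicate contrasts miss,
plus a handful of null false positives). The cascade recovers 96% of
planted set labels — the shortfall is almost entirely LR genes whose
single informative contrast (`ChNT0:TeNT0`, 2 vs 2 samples) misses the
DEG cut — and clustering assigns every correctly-set gene to its true
pattern subset. The subtraction identities mirror the serial procedure:
801 − 177 = 624 genes enter the treatment stage, 624 − 199 = 425 =
TLSR + NS. Stage 6 prints the corroboration `R = 0.958` for qPCR noise
sd 0.5 (noise-free links give exactly 1).

Equivalently in R:

```r
library(coldcascade)
run <- run_pipeline(run_config(seed = 42))
run                              # stage counts
recovery_report(run$truth, run$classification, run$subsets)
```

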