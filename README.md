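# miRNoise

Quantifying the effect of microRNAs on the expression **noise** of their
target genes in single cells.

## The problem

miRNAs repress their target mRNAs post-transcriptionally. Beyond lowering
mean expression, they are expected to dampen cell-to-cell variability
("noise") of their targets. Paired single-cell mRNA and single-cell miRNA
profiles (read-based Smart-seq protocols plus small-RNA sequencing of the
same cell population) make this testable — but single-cell noise is
dominated by its dependence on the mean, and by technical noise (dropout,
amplification). This package implements the analysis for that setting, for
computational biologists who have gene × cell count/RPKM matrices, a
miRNA × cell count matrix, and a miRNA→target table.

## The statistic

Across genes, log10 of the coefficient of variation (CV = SD/mean) falls
roughly linearly with log10 of the mean. The package fits, per cell group
and per normalization layer, the ordinary-least-squares trend

    log10(CV_g) = a + b · log10(mean_g) + ε_g

and defines each gene's **residual CV**

    RCV_g = log10(CV_g) − (a + b · log10(mean_g)),

its noise relative to genes of equal expression. The analysis then:

1. stratifies miRNAs into four expression groups along a log10 gradient
   of their mean expression fraction;
2. forms each group's **union target set** and compares RCV distributions
   between every pair of groups with two-sample Kolmogorov–Smirnov tests
   (noise of targets of abundant miRNAs should be stochastically lower);
3. for differentially expressed (DE) miRNAs between two cell groups, runs
   per-miRNA t-tests of target log-mean and RCV with Benjamini–Hochberg
   correction, counts combinatorial targeting frequencies, selects the
   100 commonest targets per direction, scores their mixing under
   hierarchical clustering, and summarizes per-gene log fold changes of
   mean and noise.

Denoised matrices from external tools (e.g. a ZINB autoencoder's
`mean.tsv`) are ingested and normalized exactly like RPKM, so "total
noise" (RPKM layer) and "reconstructed biological noise" (denoised layer)
are analyzed side by side. A negative-binomial, dropout-aware simulator
with planted noise-reduction effects provides ground truth for
calibration and power checks.

## Worked example

Simulate a 2,000-gene × 30-cell experiment with 100 miRNAs whose targets
have graded planted noise reduction, then run the full noise pathway:

```r
library(miRNoise)
res <- runNoisePathway(list(
    simulate = list(nGenes = 2000, nCells = 30, nMiRNAs = 100),
    seed = 42))
res$fits[["rpkm.cells"]]
res$partition
round(res$ksMatrices$rpkm$cells, 4)
```

```
discarding 3 cell(s) with library size < 1e+05: cell03 (99493), cell20 (75819), cell26 (81289)
30 gene(s) removed by prevalence filter; 1970 retained
RegressionFit: log10(CV) = 0.1239 -0.1202 * log10(mean); n = 1970, R2 = 0.434
GroupPartition: 100 miRNAs in 4 expression groups

 1  2  3  4
27 37 17 19
  group_i group_j      d      p neglog10p n_i n_j
1       1       2 0.0418 0.5370    0.2700 658 849
2       1       3 0.0587 0.3230    0.4908 658 441
3       1       4 0.1043 0.0047    2.3315 658 483
4       2       3 0.0766 0.0662    1.1795 849 441
5       2       4 0.1302 0.0001    4.2310 849 483
6       3       4 0.0909 0.0443    1.3534 441 483
```

Reading the output: cells below 0.1 million reads are discarded and genes
expressed in five or fewer cells are dropped before analysis. The fitted
mean–CV trend has negative slope (noisier when rare). The KS matrix shows
the planted pattern: comparisons involving group 4 (targets of the most
abundant miRNAs, here simulated with biological CV scaled by 0.7) are the
most significant — pair (1,4) and (2,4) reach p < 0.005 — while adjacent
groups barely differ. On real data the same call takes `mrna_path`,
`mirna_path`, `lengths_path`, `target_path` and a cell-group table
instead of `simulate`.

The two-group DE pathway runs analogously:

```r
d <- runDifferentialPathway(list(
    simulate = list(nGenes = 2000, nCellsPerGroup = 30, nMiRNAs = 100,
                    nDE = 40),
    two_group = TRUE, seed = 1))
sum(d$differential$fdr < 0.05)   # 0 under the null design
```

## Package layout

- `R/` — S4 classes (`ExpressionMatrix`, `MiRNAProfile`, `TargetMap`,
  `GroupPartition`, `RegressionFit`) and the analysis functions, grouped
  by stage: ingest/normalization, denoise adapter, noise model, target
  analysis, differential analysis, simulator, pipeline orchestration.
- `vignettes/mirna-target-noise.Rmd` — the methods vignette: model,
  assumptions, parameter choices, simulator design, limitations.
- `tests/testthat/` — unit, property and end-to-end statistical tests.
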