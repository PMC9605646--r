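---
title: "Measuring miRNA effects on target expression noise in single cells"
author: "miRNoise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring miRNA effects on target expression noise in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRNoise)
```

# The model

## Noise and its mean dependence

For one cell group and one gene $g$, expression noise is the coefficient
of variation of the normalized values across cells,
$\mathrm{CV}_g = s_g / \bar{x}_g$, with the sample standard deviation
($n-1$ denominator — the convention in the expression-noise literature;
the choice matters little at 15–30 cells but is fixed here for
reproducibility). In single-cell data $\log_{10}\mathrm{CV}$ falls
approximately linearly with $\log_{10}$ mean, a mixture of Poisson
sampling ($\mathrm{CV} \approx 1/\sqrt{\mu}$ at low expression) and a
biological/technical noise floor. Comparing raw CVs between gene sets
therefore mostly compares their expression levels.

The package removes this confounder by ordinary least squares across
genes:

$$\log_{10}\mathrm{CV}_g = a + b\,\log_{10}\bar{x}_g + \varepsilon_g,
\qquad \mathrm{RCV}_g = \widehat{\varepsilon}_g .$$

RCV (residual CV) is a gene's noise relative to the average gene of equal
expression. Two exact identities follow from OLS-with-intercept and are
enforced by tests: residuals sum to zero over the fitted genes, and RCV is
invariant to multiplying the whole matrix by a positive constant (the CV
is scale-free, so rescaling only translates the predictor). OLS rather
than a smoother is the defining choice: a flexible trend would absorb part
of the signal of interest, and the fitted statistic must be the same
simple object on every layer. The fit uses all eligible genes of the
post-filter matrix — the only matrix that enters the analysis — and is
refit separately per cell group and per normalization layer; no pooled
fit, so layers and groups remain comparable only through the residual
scale.

Genes with zero mean or zero CV have no defined $\log_{10}$ value: they
are flagged ineligible, excluded from the fit, and carry `NA` RCV rather
than being silently dropped or patched with a pseudocount. A pseudocount
would distort the low-expression end of the regression, which is exactly
where the mean–CV relation is steepest.

## Normalization

mRNA values are compared on RPKM-type scales:
$x_{gc} = k_{gc} \cdot 10^9 / (L_g \cdot N_c)$ with $L_g$ the effective
gene length (bp) and $N_c$ the cell's library size. Library size is the
column total over all genes present *before* the prevalence filter —
sequencing depth, not post-hoc filtered depth — so the pipeline
normalizes first and subsets afterwards. Externally denoised count
matrices go through the identical formula (layer `denoised-normalized`),
which keeps the two noise layers on one scale; the denoisers themselves
(ZINB autoencoders, consensus-clustering imputation) are consumed as
files, never re-implemented, because the package's contribution is
downstream of them.

miRNA counts become per-cell fractions of total miRNA content, floored at
$10^{-4}$, then $\log_2$-transformed. The floor is a detection limit:
small-RNA libraries of $\sim 10^5$ reads cannot distinguish fractions
below $10^{-4}$ from zero, and an unfloored $\log_2$ would be undefined at
zero. The source convention this follows is written "10e−4", which is
read as $1\times 10^{-4}$ (scientific-notation shorthand); because the
reading is ambiguous the floor is an explicit parameter (`mirna_floor`).
Per-miRNA mean fractions are computed on the post-floor, pre-log scale.

## Filters

Cells with library size strictly below 0.1 million reads are discarded
(the boundary is retained — the rule is "< 0.1 million"). Genes count as
expressed in a cell when their value is strictly positive (no count
threshold is imposed: with read-based protocols a single mapped read is
evidence of expression, and any higher cutoff would interact with the
dropout model); a gene is retained when its expressed-cell count strictly
exceeds `min_cells_expressed` (default 5) in at least one cell group, or
overall when groups are not meaningful.

# Target-group analysis

miRNAs are stratified into `n_groups` (default 4) bins along
$\log_{10}$(mean fraction). Bins are equal-width over the observed range;
each bin is closed at its lower edge and the top bin at both edges. The
original stratification used tabulated boundaries that are not available,
so equal width realizes "a gradient on the log scale" deterministically;
explicit boundaries can be supplied to override.

A group's target set is the union of its member miRNAs' targets,
intersected with the analyzable genes. Union sets of different groups may
overlap — a gene targeted by both a weak and a strong miRNA appears in
both samples. This mirrors the definition of combinatorial targeting; an
`exclusiveTargets` flag removes shared genes for sensitivity analysis,
and shared genes can only shrink the KS distance, making the default
conservative. Pairs are compared by the two-sided two-sample
Kolmogorov–Smirnov test with the asymptotic p-value: target sets number
hundreds to thousands of genes, where the asymptotic form is standard and
the exact small-sample computation adds nothing but ties-handling
caveats.

# Differential-miRNA analysis

DE miRNA labels (which miRNA is higher in which cell group) are inputs —
the package never calls a differential-expression method for miRNAs; it
evaluates the labels' downstream consequences.

Per miRNA and per metric ($\log_{10}$ mean and RCV, on each layer), its
expressed targets are compared between the two cell groups with the
unpaired pooled-variance two-tailed Student's t-test, then
Benjamini–Hochberg adjusted per metric across miRNAs. The unpaired test
is the default deliberately: gene identity does link the two groups, and
because persistent gene properties (base expression, intrinsic noise)
correlate across groups, the unpaired test is conservative — the right
direction of error for an analysis whose headline finding is a negative
result. A paired-by-gene variant would be the sensitivity analysis, not
the default. Genes with zero mean in either group are excluded from that
miRNA's mean-metric test ($\log_{10}$ undefined); a zero pooled variance
yields p = 1 with a warning rather than an error, so screens keep
running.

Targeting frequency counts, for each expressed gene, how many DE miRNAs
of one direction target it; the top `k` (default 100) are the "commonest
targets". Ties are broken by descending overall mean expression (the
across-group average of per-group means — using a single group's mean
would preferentially select genes high *by chance* in that group and
bias the subsequent fold-change centroid) and then lexicographic gene id,
so the report is fully deterministic.

The two commonest-target sets are clustered (genes × cells,
$\log(\text{count}+1)$ with the natural log, Euclidean distance, average
linkage — the common heatmap defaults; both are parameters since no
particular linkage is canonical) and scored by the fraction of adjacent
dendrogram leaves with different direction labels; perfect mixing of a
proportion-$p$ labelling gives $\approx 2p(1-p)$, separation gives
$\approx 1/(n-1)$.

Per-gene change summaries use $\mathrm{lfc} = \log_2(\bar{x}^{B}_g /
\bar{x}^{A}_g)$ for the mean and $\Delta\mathrm{RCV} = \mathrm{RCV}^B_g -
\mathrm{RCV}^A_g$ for noise. RCV is already a $\log_{10}$ quantity, so
the difference *is* the log fold change of CV at matched mean; a ratio of
CVs would re-introduce the mean dependence that RCV removed. The centroid
of the commonest targets in this plane, with standard errors, quantifies
whether the combinatorial targets collectively shift.

# The simulator

The generator produces data with the statistical structure the analysis
assumes, plus ground truth:

- gene base means $\sim$ log-normal (meanlog $\log 20$, sdlog 1.5):
  a long-tailed expression distribution whose column sums land near
  $10^5$–$2\times 10^5$ reads for 2,000 genes, so the library-size filter
  is exercised realistically;
- per-cell library factors $\sim$ log-normal (sdlog 0.2);
- per-gene intrinsic biological CV $\sim$ log-normal around `cvBio`
  (default 0.55, sdlog `cvBioSdLog` = 0.15). Genes differ persistently in
  how noisy they are; this heterogeneity is what makes per-gene noise
  correlated between cell groups, as in real data. The default spread is
  a calibration: large enough that the unpaired per-miRNA test is
  conservative under the null (no spurious FDR hits), small enough that
  the planted group-4 effect stays detectable with high power at the
  default scale;
- biological heterogeneity enters as a per-gene-per-cell log-normal
  factor with that CV, multiplying the mean surface $\mu_{gc}$; the
  planted miRNA effect multiplies a target's biological CV by the
  `noiseMultipliers` entry of the highest-expression miRNA stratum
  targeting it (defaults 1/0.9/0.8/0.7), and optionally its mean by
  `meanRepression` (defaults 1/1/1/0.8). Planting the noise effect in
  the mean surface (rather than in the count-level dispersion) makes the
  "denoised truth" layer — the matrix of $\mu_{gc}$, which is what a
  mean-reporting denoiser estimates — carry the biological signal, so
  the denoised pathway can recover the planted ordering; it also keeps
  the level and noise knobs independent, so the two claims (repression
  of means vs reduction of noise) are separately testable;
- counts $\sim$ negative binomial around $\mu_{gc}$ with technical
  dispersion 0.2 (read-based protocols are overdispersed beyond Poisson
  by amplification), followed by logistic dropout: a false zero with
  probability $\mathrm{logit}^{-1}(s(m - \log\mu_{gc}))$, midpoint
  $m = 0$ and slope $s = 1$, i.e. $\sim$50% dropout at mean 1 and
  negligible dropout above $\sim$50;
- miRNA true fractions log-uniform over $[10^{-4}, 10^{-1}]$ (the
  observed dynamic range of miRNA fractions), counts multinomial with
  $10^5$ reads per cell;
- the two-group design shares genes, base means, intrinsic CVs and the
  target map between groups, shifts DE miRNA fractions by
  `deLog2Shift`, and by default plants *no* downstream mRNA effect —
  the null that the differential pathway should report as such.

Every generator is a pure function of its parameters and seed; the
caller's RNG stream is untouched.

What the simulator does **not** emulate: amplification/PCR duplication
structure (UMIs), spike-ins, batch effects, correlated gene programs, or
mean-dependent dispersion beyond the Poisson term. Passing tests
therefore demonstrate internal statistical correctness and calibration,
not that real datasets of this size would show the same effect strength;
real target maps are also far from uniformly random.

# Numerical choices and degenerate inputs

- Base-10 logs throughout the noise model; base-2 only for miRNA
  fractions and fold changes.
- KS p-values are floored at $10^{-300}$ so $-\log_{10} p$ stays finite
  after underflow.
- Groups with fewer than 10 eligible target genes are excluded from KS
  comparisons (a warning, not an error); miRNAs with fewer than 3 usable
  targets are skipped per metric.
- Duplicate gene ids, unlabeled cells, non-numeric entries, zero-total
  miRNA cells, missing gene lengths and sub-50% denoised/raw gene overlap
  are hard errors with the offending identifiers named.
- Fractional "raw counts" (expected counts from EM quantifiers) are
  accepted with a warning.
- The default analysis scale used by the end-to-end statistical tests and
  the acceptance script — 2,000 genes, 30 cells per group, 100 miRNAs,
  30 targets per miRNA, 50 simulation seeds (20 for the two-group
  pathway) — was chosen to keep a full run in the minutes range on one
  CPU while leaving the KS comparisons well powered.

# Known limitations

- The mean–CV trend is fitted linearly; strongly bimodal layers (e.g.
  heavily zero-inflated data without denoising) can curve, inflating RCV
  at the extremes of expression.
- The asymptotic KS p-value is approximate below a few dozen genes per
  set; such comparisons are skipped rather than computed exactly.
- Overlapping union target sets make neighboring-group comparisons
  conservative; the `exclusiveTargets` flag trades that against smaller
  samples.
- DE miRNA directions are trusted as given; label errors propagate
  silently into the combinatorial analysis.
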