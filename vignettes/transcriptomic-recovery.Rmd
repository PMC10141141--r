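---
title: "Methods: transcriptomic recovery scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptomic recovery scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txrecovery)
```

# The design and the statistic

`txrecovery` evaluates a therapy in a three-condition RNA-seq design:
healthy control (CNT), disease (DIS), and one or more treated arms. The
core statistic is per-gene percent recovery,

$$\%R_g = 100 \cdot
\frac{\bar{y}_{g,\mathrm{treated}} - \bar{y}_{g,\mathrm{disease}}}
     {\bar{y}_{g,\mathrm{control}} - \bar{y}_{g,\mathrm{disease}}},$$

evaluated on size-factor-normalized mean counts. Raw means would confound
library size with rescue, so normalized means are used throughout. The
denominator is the disease shift itself; when control and disease means
are closer than `eps` (default 1 normalized count) the ratio is dominated
by noise and the gene is marked *undefined* and excluded from category
counts, rather than contributing an arbitrary large value.

Defined values are binned: **unrecovered** below 10 (this includes
negative values, where treatment pushed expression further from control),
**partial** $[10, 50)$, **total** $[50, 150]$, **over-recovered** above
150. The boundary inclusivity ($[10,50)$, $[50,150]$, $(150,\infty)$) is a
convention; the boundaries are a `bins` argument so sensitivity to them
can be probed directly.

# Differential expression machinery

Disease-related genes are the altered genes of the CNT-vs-DIS contrast at
BH-adjusted $p < 0.05$ and $|\log_2 \mathrm{FC}| \ge 1$. The fold-change
threshold is taken as inclusive ($\ge 1$); the alternative strict reading
shifts calls only for genes exactly on the boundary.

The test machinery is implemented inside the package:

- **Normalization**: median-of-ratios size factors over genes expressed in
  every sample, rescaled to geometric mean 1; with no such gene the
  estimator degrades to total-count ratios. Scaling a column by $k$ scales
  its size factor by $k$, leaving normalized counts invariant.
- **Dispersion**: the NB variance is $\mu + \phi\mu^2$. Per gene,
  $\hat\phi_g = \max\{(s^2_g - \bar y_g)/\bar y_g^2,\ 10^{-8}\}$ from
  pooled within-group moments, shrunk toward a lowess trend of $\hat\phi$
  against log mean with weight $\mathrm{df}/(\mathrm{df} +
  \mathrm{df}_\mathrm{prior})$, $\mathrm{df}_\mathrm{prior} = 10$. With 4
  samples per group the gene-wise estimate carries weight 0.375, which
  stabilises the exact test at small $n$ without erasing gene-level
  signal.
- **Exact test**: normalized counts are rounded to pseudo-counts; group
  sums $Y_A \sim \mathrm{NB}(n_A\mu,\ \phi/n_A)$ (similarly $Y_B$) are
  compared conditional on $t = y_A + y_B$ with null mean $\mu = t/(n_A +
  n_B)$. The two-sided p-value doubles the smaller conditional tail
  (observed outcome included), capped at 1; $t = 0$ gives $p = 1$. The
  conditional support is truncated where the NB quantile functions put
  less than $10^{-14}$ mass, which bounds the per-gene cost without
  affecting the sum at working precision.
- **Multiplicity**: Benjamini–Hochberg via `stats::p.adjust`, behind a
  validating wrapper.
- **Low-expression filter**: genes with mean raw count below 5 across all
  samples are dropped before testing (configurable); near-zero counts
  cannot support the moment estimates above and only dilute the BH
  budget.
- **Fold changes** use a pseudo-count of 0.5 on normalized means, so zero
  means give large but finite estimates.

Under a simulated global null (2000 genes, $n = 4$, $\phi = 0.1$) the raw
p-values are near-uniform (the acceptance suite checks the rejection rate
at 0.05 and the Kolmogorov–Smirnov distance); at 4-fold effects and mean
100 the altered-gene call has recall above 0.9 with empirical FDR well
under 0.10. These are statements about this machinery on NB data, not a
claim of numeric equality with any external DGE package, though a rank
cross-check against an independently implemented exact test is part of
the suite.

# Reversals, intersection ratios, hard targets

A **reversal** is a disease-related gene that the DIS-vs-treated contrast
calls altered with sign opposite to its disease direction. The per-arm
summary is the share of *all* treatment-altered genes that are reversals.
A companion *improvement* fraction is reported alongside; under the
default rule the two coincide, and the second slot exists so a stricter
magnitude-aware definition can be compared without changing the schema.

The **intersection ratio** between two arms is the Jaccard index
$|A \cap B| / |A \cup B|$ of their recovered-gene sets. The union reading
is a documented interpretation choice; two empty sets give 0 with a
warning rather than 0/0.

The **hard-target report** tabulates log2FC and altered flags for an
externally supplied target list (e.g., validated targets of the miRNA
being inhibited) in each DIS-vs-treated contrast. Targets absent from the
tested genes are listed, never silently dropped. This is the specificity
readout: a site-directed oligonucleotide should leave the panel flat,
while a miRNA-directed one de-represses many targets at once.

# Splicing events

Group PSI is computed from **pooled** junction reads (sum across the
group's samples, then $100 \cdot \mathrm{inc}/(\mathrm{inc} +
\mathrm{exc})$), not as a mean of per-sample PSI — pooling matches how
merged-sample splicing quantification reaches adequate read depth and
weights samples by their coverage. dPSI is the difference of pooled PSI
(disease − control; treated − disease). Per event, a two-sided Fisher
exact test on the pooled 2×2 inclusion/exclusion table with BH adjustment
across events provides the significance component. The filter retains
events with $|dPSI| > 25$, at least 10 pooled reads in each group, and
adjusted $p < 0.05$.

A splicing **reversal** requires the treated shift to oppose the disease
shift's sign *and* move at least `min_move` = 5 percentage points — pure
sign flips at noise scale should not count. **PSR%** applies the same
three-point recovery formula on the PSI scale, with a 1-percentage-point
denominator guard; the function accepts pre-quantified percentages
(e.g., densitometry) as well as junction-read PSI.

# The synthetic generator

The generator encodes the study conditions and the ground truth needed to
test parameter recovery:

- Baseline gene means are log-normal (location 4, scale 1.5 on the natural
  log), spanning roughly 1–20,000 counts — lowly and highly expressed
  genes in realistic proportion.
- Counts are NB with variance $\mu + \phi\mu^2$; $\phi = 0.1$ globally by
  default (a typical bulk RNA-seq magnitude), with per-gene override.
  $\phi = 0$ falls back to Poisson draws.
- A fraction of genes (default 10%) are disease genes with
  $|\delta_g| \sim U(1, 2.5)$ log2 units and random sign; the disease mean
  is $\mu_{\mathrm{ctl}} 2^{\delta_g}$.
- A treated arm's mean interpolates **linearly** between disease and
  control, $\mu_{\mathrm{dis}} + \rho(\mu_{\mathrm{ctl}} -
  \mu_{\mathrm{dis}})$ — deliberately on the count scale, not the log
  scale, so the recovery statistic has expectation exactly $100\rho$ and
  truth and estimate are commensurable.
- Off-target perturbations ($2^\varepsilon$ with $\varepsilon \sim N(0,
  \sigma)$, or a fixed log2 magnitude with random sign when a simulation
  pins the effect size) apply only to arms flagged antagomiR-like — this
  is the specificity contrast the hard-target report measures.
- Four samples per group by default, a common replicate count for
  cell-line bulk RNA-seq contrasts.
- Splice events draw per-sample total coverage as Poisson (default mean
  100) and inclusion reads as Binomial(coverage, PSI/100).

What the generator does **not** emulate: gene–gene correlation, GC or
length bias, batch structure, outlier samples, or fold-change structure
copied from any real deposited dataset. Passing tests therefore
demonstrate that the estimators recover the truth of this NB world at the
stated sizes; they do not certify behaviour under real-data artefacts the
model omits. The validation targets are *properties* — calibration,
power, specificity contrast, reversal recovery — under known truth, not
any particular published gene counts.

# Assay formulas

- **Percent inhibition**: `100 − (abs − mean_media) · 100 /
  mean_untransfected`. The denominator is deliberately not
  media-subtracted; this mirrors the plate-normalization convention the
  formula comes from. On this scale 0 is fully viable and TC50 is where
  the fitted curve crosses 50.
- **TC50**: least-squares four-parameter logistic on $\log_{10}$ dose via
  Levenberg–Marquardt (`minpack.lm::nlsLM`). Because responses arrive
  percent-normalized, the default pins the asymptotes at 0 and 100 — on a
  six-point dose screen the midpoint and hill slope are then well
  identified, whereas a fully free four-parameter fit on the same design
  misses ±20% of the true TC50 in roughly one run in five at 5-point
  noise; that is a property of the design, not the optimizer.
  `free_asymptotes = TRUE` restores the free fit, initialized from data
  quantiles with deterministic restarts (no RNG use). Flat data or
  non-convergence return a flagged result, never an exception.
- **2^−ΔΔCt**: per-sample $\Delta Ct$ (target minus reference Ct), group
  means of $\Delta Ct$ (not ratios of means), calibrator-group
  subtraction; the calibrator's relative quantity is exactly 1 by
  construction.
- **Grip strength**: `100 · (mean post / mean pre) / body weight`;
  **central nuclei**: `100 · central / total`; **mean pixel intensity**:
  intensity sum over area (thresholding belongs to the imaging step).

# Determinism and problem sizes

Every simulation takes an explicit integer seed, and the pipeline's
output bundle contains no timestamps, so a fixed seed reproduces every
file byte-for-byte; `manifest.json` records md5 checksums to make this
checkable. The validation suite runs at deliberately desk-scale sizes —
2000-gene matrices for calibration, 1000 for power, 800 genes × 100 seeds
for the specificity contrast, 200 splice events, 100 dose-response refits
— chosen as the smallest sizes at which the Monte-Carlo bands in use are
comfortably stable.

# Known limitations

- The DGE machinery targets the two-group exact-test setting only: no
  GLMs, covariates, or batch correction.
- Percent recovery is a ratio estimator; with $n = 4$ it carries a small
  upward bias from denominator noise (a mean estimate near 82 when truth
  is 80 in the calibration study), shrinking as the disease effect or
  replication grows.
- The splicing module models binomial junction sampling only — no
  intron-retention-specific handling, coordinates, or annotation.
- The intersection-ratio and PSR definitions are documented
  interpretation choices; both are isolated behind single functions so an
  alternative reading is a one-line change.
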