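---
title: "Methods: how actinscreen models a stellate-cell deactivation screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how actinscreen models a stellate-cell deactivation screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actinscreen)
```

## The assay and its central statistic

Activated hepatic stellate cells (aHSCs) are flat myofibroblasts packed
with filamentous-actin stress fibers; quiescent-like cells (qHSCs, or
deactivated daHSCs) are small, dendritic and nearly fiber-free. A live
F-actin stain therefore reads out the activation state of a whole well.
The pipeline's central statistic is the **Actin score**,

$$\text{Actin score} \;=\; \frac{\text{total stain intensity over positive pixels}}
{\text{number of positive pixels}},$$

an *intensive* quantity: it measures how actin-dense the average piece of
stained cell is, so it does not change when a well simply holds more cells
of the same kind. Deactivating compounds lower it; that is the screen's
selection signal.

`segment_actin_area()` defines "positive" as: subtract the image median
(a robust background estimate for sparsely seeded wells), log-compress
the residual, and apply Otsu's threshold. Two numerical choices matter
here and are deliberate:

* **Log compression before Otsu.** Stress-fiber pixels form a long right
  tail far above the cell-body plateau. On the raw scale that tail can
  dominate the between-class variance so that Otsu splits *inside* the
  cells (body vs. fiber) instead of between cells and background. Taking
  `log1p` first collapses the tail and restores the intended split. The
  score's scale-equivariance (multiplying the image by $c$ multiplies the
  score by $c$) survives because the log shifts all classes equally, so
  the selected pixel set is unchanged.
* **A contrast guard for empty wells.** On a cell-free well Otsu still
  bisects the background noise. The mask is accepted only when the
  threshold clears the sub-threshold pixels by three robust SDs of their
  own spread; otherwise the well is flagged `EMPTY_WELL`, its score is
  undefined, and it is excluded from plate statistics and hit calling
  rather than contributing a division-by-zero or a spurious low score.

A `LOW_AREA` flag (default: positive area below 0.5% of the image) marks
wells whose ratio rests on too few pixels to be stable; saturated images
are flagged `SATURATED`. Both raw and background-subtracted totals are
reported, since instrument conventions differ on this point.

## Plate quality control

Two standard statistics decide whether a plate is usable
(`validate_plate()`): the coefficient of variation of the DMSO
negative-control scores, $\mathrm{CV} = 100\,s/\bar{x}$, bounded at 10%,
and the Z'-factor

$$Z' = 1 - \frac{3\,(s_\text{pos} + s_\text{neg})}
{\lvert \bar{x}_\text{pos} - \bar{x}_\text{neg} \rvert} \le 1,$$

bounded below at 0.5. The positive-control arm models wells treated with
a six-compound deactivation cocktail. Sample ($n-1$) standard deviations
are used throughout — control counts per plate are small (16 negative, 8
positive by default), where the distinction matters. The criteria are
applied as closed comparisons (`<=` / `>=`); exact boundary hits are
measure-zero in practice but are annotated in the report rather than
silently resolved.

## Hit calling and the screening funnel

Hits are wells whose score falls **strictly below**
$\bar{x} - k\,s$ computed **per plate** (default $k = 2$). By default
only compound wells enter the mean and SD: with a strong positive
control present, including controls would inflate the spread and bury
hits; a `population = "all"` switch restores the alternative reading.
Under pure noise the rule fires on roughly the Gaussian one-sided 2-SD
tail (≈ 2.3% of wells), which is the calibration the tests check.

`run_funnel()` stages the selection the way the screen is run on the
bench: the full library is scored at the primary dose (2 µM) and again at
the secondary dose (400 nM), hits are called independently per tier with
per-plate statistics, and the secondary selection is the intersection
with the primary picks — so candidate sets are nested by compound
identity by construction. Note the secondary tier re-screens the *whole
library* rather than re-plating only the primary picks: re-plating would
fill secondary plates mostly with actives, making the plate mean − 2 SD
statistic degenerate.

The tertiary tier is a qPCR confirmation across 125/500/2000 nM:
`classify_deactivation()` keeps a compound when, at the top dose, both
activation markers fall below the vehicle level (*ACTA2*, *COL1A1* < 1)
and all three quiescence markers rise above it (*TCF21*, *LRAT*,
*LHX2* > 1). The thresholds (`down_max`, `up_min`, `min_up`) default to
1/1/3 — the strictest reading of "suppressed and induced relative to
DMSO" — and are configurable because the decision boundary is a
screening policy, not a measured constant. A compound meeting only the
suppression rule is reported `"partial"`.

## ΔΔCt quantification

`delta_delta_ct()` assumes perfect doubling (amplification efficiency 2,
no standard-curve correction): per replicate
$\Delta Ct = Ct_\text{target} - Ct_\text{reference}$ (reference *GAPDH*
by default), then
$\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_\text{calibrator}$
and fold change $2^{-\Delta\Delta Ct}$. The calibrator is a
per-experiment parameter (a vehicle control in the confirmation screen,
an untreated baseline elsewhere), never a constant.

One convention deserves emphasis: the per-condition point estimate is
$2^{-\overline{\Delta\Delta Ct}}$ — the **geometric mean** of the
replicate folds — implemented as a difference of means so that the
calibrator's estimate cancels to exactly 1, bit for bit, at any noise
level. An arithmetic mean of replicate folds is biased upward under
noise (Jensen's inequality) and would leave the calibrator above 1; it
is still reported (`fold_mean`, `fold_sd`) as the bench-style summary.
Statistical testing (`anova_vs_control()`) runs on ΔCt values, which are
approximately normal, rather than on folds; with one condition versus
the control this is the classical one-way ANOVA F test, significant at
p < 0.05, uncorrected by default (a Bonferroni option exists).

## Expression profiling

The RNA-seq analytics start from a gene × sample count matrix with gene
lengths; alignment and transcript quantification are out of scope.

* **TPM** (`counts_to_tpm()`): counts over length in kb, rescaled so
  each sample sums to $10^6$; effective length is the annotated length.
* **Z-scores** (`zscore_genes()`): per gene across samples, sample SD;
  zero-variance genes are dropped and reported.
* **Clustering** (`correlation_cluster()`): distance $1 - r$ (Pearson),
  average linkage by default (the common default of heatmap tools;
  complete/single/ward are available), on the 500 most variable genes by
  default (variance of $\log_2(x+1)$) — concentrating the metric on the
  regulated transcriptome; `top_n = Inf` uses all genes. Dendrograms
  export to newick via `cluster_newick()`.
* **PCA** (`pca_samples()`): on $\log_2(\mathrm{TPM}+1)$, gene-centred,
  unscaled.
* **Volcano** (`volcano_stats()`):
  $\log_2\!\frac{\overline{\mathrm{TPM}}_b + 1}{\overline{\mathrm{TPM}}_a + 1}$
  with a pseudocount of 1, and a two-sided Welch t-test on
  $\log_2(\mathrm{TPM}+1)$. No published differential-expression
  framework is wrapped here on purpose: the screen's claims rest on fold
  direction and a plain test, and the simple convention is transparent
  and exactly testable.

## What the synthetic generators emulate

Everything is exercised on seeded synthetic data; every generator is a
pure function of its parameters and seed.

**Well images** (`render_well_image()`). Cells are elliptical footprints
whose size shrinks with `deactivation_level` $d \in [0,1]$; stress
fibers are one-pixel chords across the footprint whose count and
brightness scale with $1-d$; thin dendritic branches grow in as $d$
rises. A Gaussian point-spread blur, additive Gaussian background and
16-bit quantization follow, in that order. Fibers are the *only* driver
of the intensity-per-area contrast, which gives the generator its design
guarantee: the expected Actin score decreases monotonically in $d$. The
default 60 cells per 192-px field is this package's scaling of a 5000
cells / 20 µL seeding to a small rendered field. No optics simulation,
no multi-channel rendering, no plate-spatial effects: the images are
cartoons with controllable truth, not microscope emulations — passing
image tests says the *quantification logic* is right, not that the
segmenter would survive real debris, uneven illumination or confluent
growth.

**Screens** (`generate_screen()`). True hits follow a saturating
one-site dose-response $d(\text{dose}) =
\text{max\_effect}\cdot\text{dose}/(\text{dose}+\text{potency})$ (Hill
coefficient 1 — the simplest monotone model); the number of hits is
`round(n_compounds * hit_fraction)`, deterministic so recovery is
exactly checkable. The default *fast mode* draws well scores directly
from $\mathcal{N}(\mu(d),\; c_v\,\mu(d))$ with
$\mu(d) = 100\,(1 - 0.8\,d)$ arbitrary units: DMSO wells at 100,
fully-deactivated wells at 20 (an 80% assay window), and a 5%
well-to-well CV. These defaults are the validation conditions of the
simulated assay; the well CV is a free parameter, not an instrument
calibration, since real control-well variance is not published for this
assay. Fast mode keeps a library-scale funnel (1000 compounds × 2 tiers
plus the qPCR confirmation) under a minute on one core.

**Ct tables** (`generate_ct_table()`). $Ct = \text{baseline}(gene) -
\log_2\!FC + \mathcal{N}(0, \sigma_{Ct})$, reference gene fixed at
$\log_2\!FC \equiv 0$; with $\sigma_{Ct} = 0$ the downstream ΔΔCt
pipeline recovers the programme to machine precision — the identity the
round-trip tests pin down. Bench-style defaults: three technical
replicates, $\sigma_{Ct} = 0.2$ cycles.

**Count matrices** (`generate_expression_matrix()`). Negative-binomial
counts (dispersion 0.05) around programmed log2 means for four groups —
qHSC day 0, aHSC day 7, aHSC day 10, daHSC day 10, three samples each.
Two layers carry the biology: the explicit nine-gene marker program
(activation markers high in aHSC; quiescence markers restored in daHSC;
*NGFR* deliberately **not** restored, reflecting partial reversion) and
a global activation program — 40% of 500 filler genes shift along an
activation axis scored 0 / 1 / 1.1 / 0.25 for the four groups, with
$\mathcal{N}(0, 1.2)$ loadings. The second layer matters: sample
correlations over a transcriptome are dominated by genome-wide shifts,
and with only nine structured genes the four-group geometry would drown
in counting noise. The daHSC score of 0.25 encodes "partially reverted
toward quiescence", which is exactly the structure the clustering and
PCA checks assert (deactivated samples join the quiescent branch,
day-7 and day-10 activated samples join each other).

## Problem sizes and determinism

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which the Monte-Carlo checks are stable:
200 replicate validation plates for the QC pass-rate, 500 null plates
(180,000 wells) for the false-positive calibration, a 1000-compound
two-tier funnel with 20 strong hits for recovery, 100 random instances
per brute-force oracle, and 50 renders per level for the image
monotonicity trend. All randomness flows from explicit integer seeds
through child streams, so every reported number is reproducible by
re-running with the same seed.

## Known limitations

* The image generator's morphology is qualitative; absolute Actin-score
  values are meaningless outside a given parameterization. Only
  contrasts and rankings are interpreted.
* The mean − 2 SD rule assumes roughly symmetric well noise; a heavy
  left tail would inflate the hit rate. No plate-spatial normalization
  (B-score, median polish) is applied, matching the raw per-plate
  protocol it models.
* The deactivation classifier's thresholds at exactly 1 are maximally
  permissive about effect size; real campaigns would tighten them after
  inspecting vehicle variability.
* The expression layer models group means and NB noise only — no batch
  effects, no library-composition bias, no gene-length bias beyond the
  TPM correction.
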