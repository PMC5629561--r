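---
title: "Inferring splicing-centric modulators of transcription factor activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring splicing-centric modulators of transcription factor activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicemod)
```

## The question and the model

A transcription factor (TF) drives its target genes, but the strength — even
the direction — of that drive can depend on the state of a third protein, a
*modulator* (M). `splicemod` considers a specific, splicing-centric form of
modulation: the modulator's state is the inclusion level (percent spliced in,
PSI) of one of its alternatively spliced exons. The data are a
genes-by-samples expression matrix, an events-by-samples PSI matrix, and a
list of TF-target pairs; the question, asked for every
(target, TF, event) *triplet*, is whether the TF-target relationship changes
with the exon's inclusion level.

Each triplet is fit by ordinary least squares:

$$
Y'_{target} \;=\; \beta_0 + \beta_1\,X'_{tf} + \beta_2\,X'_m +
\beta_3\,X'_{tf}X'_m + \epsilon
$$

where primes denote transformed variables (next section). $\beta_1$ and
$\beta_2$ capture the marginal effects of the TF and of exon inclusion;
$\beta_3$, the interaction coefficient, is the quantity of interest — a
non-zero $\beta_3$ means the TF's slope on the target depends on inclusion,
i.e. a modulation relationship. $\beta_3$ is tested two-sided with a t
statistic on $n-4$ degrees of freedom, and the scan is corrected jointly by
Benjamini–Hochberg across all fit triplets (the pooled correction is the
default; a per-TF option exists).

## Variable transforms and preprocessing

Three fixed transforms put the variables on the model's scale:

* **Expression**: $x \mapsto \log_2(x + 1)$, for both TF and target.
* **PSI clamp**: inclusion values of exactly 0 or 1 are reset to 0.01 / 0.99;
  interior values are untouched (so the clamp is idempotent). Values that are
  merely *near* the boundary are legitimate measurements and pass through.
* **PSI transform**: $\psi \mapsto \log_2\!\big(\tfrac{\psi}{1-\psi} + 1\big)$,
  a strictly increasing function of the inclusion odds, finite on the whole
  open interval $(0,1)$ once exact endpoints are clamped.

Before fitting, samples are filtered per triplet:

1. keep samples with finite values in all three vectors;
2. drop a sample if the TF **or** the target expression lies outside that
   gene's mean $\pm$ 3 sd band (the union rule). Outlier statistics are
   computed per gene, once, on the gene's full finite vector, on the **raw**
   scale, before any log transform — this keeps the mask deterministic and
   independent of which triplet the gene appears in. The sd is the sample
   (n−1) estimator; at cohort sizes of several hundred the choice between the
   population and sample estimator is numerically negligible, but one must be
   fixed for reproducibility. Note a lone extreme point can only fall outside
   its own 3 sd band when $n \ge 11$, since a single spike inflates the sd it
   is compared against (max $|z| = (n-1)/\sqrt{n}$).

Tunable parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `min_samples_gene` | 400 | non-missing expression samples a gene needs to enter the scan |
| `min_samples_triplet` | 30 | retained samples below which a triplet is skipped (a 4-parameter model on fewer than ~30 points is fragile) |
| `outlier_sd` | 3 | width of the per-gene outlier band |
| `psi_clamp` | 0.01 / 0.99 | endpoint replacement values |
| `alpha` | 0.05 | FDR level (`mode = "pvalue"` with a threshold such as 0.01 is available) |

Skipped and unfit triplets are *recorded*, never silently dropped: every
attempted (pair × event) combination yields exactly one result row, and
rank-deficient designs (e.g. an event whose PSI is constant) are flagged
`unfit` with a reason rather than raising an error mid-scan.

## Modes of action

A significant $\beta_3$ says the TF-target relationship changes with
inclusion; the *mode of action* says how. Samples are split into low- and
high-PSI groups — the bottom and top `floor(0.30 * n)` samples by raw PSI,
ties broken by sample identifier for determinism — and the Pearson
correlation between TF and target (on the transformed expression scale, the
scale the model uses) is tested in each group at level `alpha_corr`. Each
group gets a state: `+`, `-`, or `Non-sig`. The low-to-high transition is
categorized:

* **Inverts** — the state flips sign (`+`→`-` or `-`→`+`);
* **Repress** — both states share the same significant sign (with an
  annotation of whether the magnitude was *reduced*, $|r_{high}| < |r_{low}|$);
* **Active** — exactly one side is `Non-sig` (correlation appears or
  disappears);
* `Non-sig`→`Non-sig` is reported as **Uncalled**, outside the three
  categories: the triplet's interaction is significant but the stratified
  correlations cannot resolve a direction of change.

The modulation *sign* (positive/negative) is taken from $\beta_3$ itself.
`alpha_corr = 0.05` is the default for calling group states; how "no
correlation" should be decided is genuinely open — it is the least
constrained choice in the whole procedure, and it is exposed prominently as
a parameter rather than buried.

Grouping uses raw PSI deliberately: membership in the top/bottom 30% is
invariant under the monotone clamp-and-transform, so grouping before or
after transformation is equivalent, and raw values are the simpler
specification.

## Networks

Calls are aggregated per (TF, event): `pct_influenced` is
$100 \times$ (significant triplets) / (fit triplets) over that TF's targets.
The denominator is the *tested* targets — skipped and unfit triplets are
excluded, so a TF scanned against few usable targets is not diluted by
unusable ones. Thresholding is strict (`pct > min_pct`, "more than"
semantics), with 30, 20 and 10 as conventional presets. If a protein-protein
interaction edge list is supplied, each edge is flagged by whether the
unordered (TF, event host gene) pair has documented physical interaction;
filtering changes membership only, never the percentages.

## The synthetic-data generator

`simulate_dataset()` generates the full input bundle with known ground
truth. Transformed TF expression is Normal($\mu$=8, $\sigma$=2), an
RSEM/TPM-like log2 scale; PSI is Beta(2, 2) — broad, boundary-avoiding
inclusion; each target follows the interaction model against its TF and one
*designated* event, plus Gaussian noise (sd 1 by default); the default
cohort is 479 samples with 2% missing cells. Expression is emitted on the
raw scale through the exact inverse $2^x - 1$ of the pipeline's
$\log_2(x+1)$, so ground-truth coefficients live on the transformed scale
the model fits — the pipeline's own transforms are part of what is under
test. Two consequences of that design are worth stating:

* PSI is *not* logit-transformed at generation; the generator draws the
  fraction directly and the model equation uses its clamped-and-transformed
  value, exactly as the pipeline will recompute it.
* The inverse transform can produce a negative raw value only in the extreme
  lower normal tail (roughly $3\times10^{-5}$ per cell at the defaults);
  such values are clamped to 0 so the expression-matrix invariant holds.

For false-discovery calibration the generator is used with **one event per
target** (e.g. 500 targets × 1 event for a 500-triplet scan): every
regression is then well-specified and the nulls are exact. With several
events per target, a modulated target regressed against a *non-designated*
event has the true interaction in its error term — $\beta_3$ is still zero
in expectation, but the error is heteroscedastic in $X_{tf}$ and those
triplets are not clean nulls; they are realistic, and the package scans them
happily, but they are not the right instrument for measuring the size of
the test.

`simulate_transition_triplet()` plants a mode-of-action transition by
constructing, within the bottom- and top-30% PSI groups, expression pairs
whose **sample** correlation equals the intended $r$ exactly (a Gram–Schmidt
construction). Planting the empirical correlation rather than a noisy draw
makes the intended state deterministic: a planted `Non-sig` side has
$r = 0$ hence $p = 1$, instead of tripping the 5% false-positive rate of the
correlation test — which is precisely the property a label-recovery
benchmark needs. Same-sign (Repress) transitions default to magnitude
`effect` in the low group and `0.375 * effect` in the high group, a
reduced-magnitude correlation; both correlations can be overridden.

## Validation sizes and what they show

The test suite validates, among other properties: agreement of the triplet
fit with an independent normal-equations solver to well below $10^{-8}$
(100 random triplets, $n \in \{10, 50, 400\}$); exact recovery of a
noise-free triplet; a type-I error within [0.035, 0.065] over 2000 null
triplets at $n = 400$; empirical FDR $\le 0.075$ over 200 replicates of
500-triplet scans with 10% alternatives at $\beta_3 = 1$; mean absolute
error of $\hat\beta_3$ below 0.05 at $n = 400$, decreasing monotonically
over $n \in \{50, 100, 400\}$; $\ge 95\%$ recovery of all eight planted
transition labels at effect 0.8 with groups of 120; exact influence
percentages and strict thresholding on a planted scan; and byte-identical
output of the CLI chain run twice under one seed. These sizes were chosen as
the smallest at which the asymptotic statements (nominal test size, FDR
control, consistency) are comfortably visible.

Passing them shows the machinery is correct *given the model*: linear
interaction on the transformed scale, Gaussian noise, independent samples.
It does not show that real tumor cohorts satisfy those assumptions — the
generator does not emulate read-level PSI estimation uncertainty,
expression-dependent measurement noise, batch structure, tumor purity, or
correlated targets, and results on real data inherit all of those caveats.

## Known limitations

* The interaction test is OLS-based; heavy-tailed expression noise or strong
  heteroscedasticity will distort its size. Robust or covariate-adjusted
  variants are out of scope.
* `Uncalled` triplets (significant $\beta_3$, no resolvable correlation
  change at `alpha_corr`) are reported but not forced into a category;
  their rate rises as `alpha_corr` falls.
* The mode-of-action step discards the middle 40% of samples by design;
  with small cohorts the per-group correlation tests lose power long before
  the interaction test does.
* Gene identifiers are opaque strings; mapping events to host genes (for
  PPI support) is the caller's responsibility via the PSI file's
  `event_gene` column.
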