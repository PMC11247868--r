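---
title: "Fragment-level cfDNA methylation scoring and signal-origin localization: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-level cfDNA methylation scoring and signal-origin localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

methtrace implements a two-step liquid-biopsy analysis: (1) decide whether a
plasma cfDNA sample carries a tumor-derived methylation signal, and (2) if it
does, localize the cancer signal origin (CSO) among seven common cancer
types. This vignette explains the underlying models, the tunable parameters
and their defaults, what the bundled synthetic-cohort generator does and does
not emulate, and the numerical conventions the implementation commits to.

## Marker unit: methylation-correlated blocks

DNA methyltransferases are processive, so nearby CpGs on the same allele
share methylation state. A methylation-correlated block (MCB) is a maximal
run of CpGs in which every adjacent pair lies less than `max_gap` bp apart
(default 100, strict) and has Pearson correlation of beta values above
`min_r` (default 0.95, strict), with at least `min_cpgs` CpGs (default 3).
`call_mcbs()` chains adjacent pairs left to right; this is the standard
block heuristic and matches a pairwise reading of the criteria (an
all-pairs-within-block criterion would be strictly more conservative).
Correlations use pairwise-complete samples; a pair with fewer than three
complete observations or zero variance cannot demonstrate correlation and
breaks the run. Coordinates are 0-based half-open and strand-collapsed to
the forward-strand C; a block's `end` covers the final CpG dinucleotide.

## Fragment-level quantification

The unit of methylation evidence is the *fragment* - the union of a read
pair's CpG calls. Mates are merged by position; where they disagree the
position is dropped (removing a call is conservative: it never fabricates a
converted state). Fragments with fewer than 3 CpG calls are discarded.
Per sample and MCB we report:

* `coverage` - fragments whose span overlaps the block (this is the weight
  `w_i` in the diagnostic score);
* `n_informative` - fragments covering at least `min_marker_cpgs` (default
  3) of the block's member CpGs;
* `mfc` - informative fragments whose covered member CpGs are *all*
  methylated (the methylated fragment count);
* `mfr = mfc / n_informative` - the methylated fragment ratio, undefined
  when no fragment is informative.

A fragment does not need to cover the whole block to be informative:
requiring all member CpGs would discard most edge-overlapping fragments and
is not implied by "fully methylated status on the block", which we read as
"fully methylated at the member CpGs it covers".

## Diagnostic score

For marker $i$ with baseline mean $\mu_i$ and standard deviation $\sigma_i$
of the logit-transformed MFR across healthy training controls,

$$Z_i = \frac{x_i - \mu_i}{\sigma_i}, \qquad
\text{score} = \frac{-2\sum_i w_i \ln p_i}{\sum_i w_i},$$

where $x_i$ is the sample's logit MFR, $p_i$ the one-sided upper-tail
normal p-value of $Z_i$, and $w_i$ the sample's fragment coverage of
marker $i$ - a coverage-weighted Fisher combination. Numerical
conventions, each of which matters in the zero-inflated regime of healthy
plasma:

* **Logit continuity correction.** $x = \mathrm{logit}\!\big((\text{mfc} +
  0.5)/(n_\text{inf} + 1)\big)$. Healthy samples sit at MFR $= 0$ for most
  markers; an uncorrected logit would be $-\infty$ there. The correction is
  symmetric (MFC $= n/2$ still maps to 0) and finite for all counts.
* **One-sided p-values.** The panel is designed around hypermethylated
  markers; a two-sided conversion would reward hypomethylation the design
  excludes. `z_to_p()` clips to $[10^{-300}, 1]$ so logs stay finite.
* **$\sigma$ floor.** $\sigma_i$ is floored at $10^{-6}$; a marker never
  observed methylated in controls otherwise has zero variance. With a
  floored (or merely small) $\sigma$, a single methylated fragment at such
  a marker produces an enormous $Z$ - this is intended behavior: one
  fully-methylated molecule at a clean background locus *is* strong
  evidence, and the specificity calibration (below) absorbs the occasional
  stray control molecule.
* **Missing markers** (no informative fragments) drop out of both sums;
  the score stays a weighted mean of the observed markers. Samples with no
  usable marker get `NA`, not 0.
* **Weights are per-sample.** $w_i$ is the *tested sample's* coverage of
  marker $i$, not a cohort constant - coverage is a property of the sample.

Under the null ($x_i \sim N(\mu_i, \sigma_i^2)$, unit weights),
$-2\ln p_i \sim \chi^2_2$, so baseline samples score about 2; the test
suite checks this by simulation.

## Threshold calibration

The cutoff is the empirical lower quantile of training-control scores: the
smallest control score such that the fraction of controls at or below it
reaches the specificity target (default 0.98, the 98th percentile). A
sample is positive iff its score is strictly greater, so training
specificity is $\ge$ the target by construction, and with $n$ a multiple of
50 and distinct scores it is exact (343 of 350 controls at or below the
cutoff leaves exactly 2%).

## Marker selection

**Diagnostic markers.** Per cancer type, markers are ranked by plug-in
mutual information (in bits) between the marker's MFC and the
class-vs-healthy label in the training cohort; the union of per-class top-X
lists is the panel, with X chosen to maximize training AUC (smallest X on
ties). MFC values are discretized by equal-frequency binning into
`n_bins = 4` bins computed on average ranks: tied values - the zero-inflated
mass of healthy MFC distributions - always share a bin, while the non-zero
tail is still split. Plain quantile breaks would collapse a mostly-zero
vector into a single bin and zero out MI for exactly the cleanest
low-background markers. Binarization at MFC > 0 is available
(`binarize = TRUE`). All rankings break ties by marker id for
cross-platform determinism.

**CSO markers.** Among training cancer samples called positive at the
calibrated threshold (true positives), markers are ranked by MI for each of
the 21 unordered class pairs; the union of per-pair top-k lists seeds an
AIC-guided backward elimination of an L2-penalized multinomial regression:
repeatedly remove the single marker whose removal most improves AIC, stop
when no removal improves it. We minimize AIC; an elimination that stopped at
*maximum* AIC would retain the worst model and contradict the procedure's
purpose. AIC for a penalized fit is not well defined; we use the common
convention of the unpenalized log-likelihood evaluated at the penalized
estimate with $k = (K-1)(p+1)$ free parameters, and state it here openly.
The elimination runs on 10 stratified 80% subsamples (without replacement)
drawn from one run seed; markers retained in more than 6 of the 10 draws
(i.e. at least 7) are the final CSO set.

Two scale-dependent defaults: `select_cso_candidates()` defaults to the
per-pair top 100 appropriate for panels of thousands of blocks, while
`run_pipeline()` defaults to `cso_top_k = 10` - on a 150-marker desk-scale
panel a top-100 union is the whole panel, and elimination cost grows with
the union size. The ridge strength `l2_strength = 0.05` was chosen by pilot
runs: retention is insensitive to it between 0.02 and 0.3 (4-8 markers
kept) but weaker penalties let genuinely informative markers justify their
12-point AIC cost more easily.

With a few dozen true positives per run, the $2(K-1) = 12$ AIC points a
marker must "pay" are a high bar: a marker discriminating one class with
eight or nine positive samples rarely gains 6 nats of log-likelihood, so
desk-scale eliminations retain far fewer markers (typically 4-8) than the
hundreds retained at real cohort size, where per-marker likelihood gains
scale with $n$. This is the procedure behaving as specified at small $n$,
not a failure of the selection; it caps desk-scale CSO accuracy well below
what the same pipeline reaches on cohort-scale data.

## CSO ensemble

Features are logit-MFR values normalized by training mean and standard
deviation per marker (missing values imputed to the training mean, i.e.
feature 0). The architecture mirrors a generic stacked ensemble: four base
learner families - gradient-boosted trees (xgboost), random forest
(ranger), L2 multinomial regression (glmnet), and a single-hidden-layer
network (nnet) - produce out-of-fold class probabilities under repeated
stratified k-fold bagging (k = 5, 2 repeats); two stackers (multinomial
regression and gradient boosting) consume the out-of-fold probabilities
concatenated with the features; the final probability is a convex
combination of the stackers chosen by greedy forward selection (with
replacement) on out-of-fold log-loss. The no-leakage property - a sample's
stacking input never comes from a base model trained on it - holds by
construction of the fold bookkeeping and is asserted in tests. All
randomness (folds, learners, subsampling) derives from one seed; the same
seed reproduces identical weights and predictions. Class-probability
vectors are renormalized at each layer and sum to 1 within $10^{-9}$.

Ranking ties are broken by alphabetical class order. Top-k accuracy counts
a sample as correct when its true class is among the k highest
probabilities. The hepatopancreatic merge (HPCA) sums the LIHC and PAAD
probabilities into one class; for a sample whose truth is LIHC or PAAD the
merged top-1 can only improve, since the merged class probability dominates
each component.

## Synthetic cohorts

The generator emulates the statistical structure the pipeline assumes,
without any sequencing-level detail:

* **Marker-specific background.** Each marker draws a mean background
  fully-methylated-fragment rate $m_j \sim \mathrm{Beta}(1, 60)$ (mean
  ~1.6%); individuals vary around it as $r_{0,ij} \sim \mathrm{Beta}(m_j
  \kappa, (1-m_j)\kappa)$ with concentration $\kappa = 200$ (about 0.9%
  rate s.d. at the mean background). Background level is a property of the
  locus - that is the premise of fitting a per-marker baseline - and the
  long lower tail of Beta(1, 60) supplies the near-zero-background markers
  that drive single-molecule sensitivity in real panels.
* **Tumor signal.** Each class has a 12-marker hypermethylated signature
  (a quarter of it a pan-cancer core shared by all classes, the rest
  class-specific); cancer samples mix tumor signal at signature markers as
  $r = (1-\theta) r_0 + \theta\, r_\text{tumor}$ with $r_\text{tumor} =
  0.6$ and tumor fraction $\theta$ by stage: 0.004, 0.01, 0.03, 0.08 for
  I-IV - the standard ctDNA dilution model.
* **Counts.** $n_\text{inf} \sim \mathrm{NegBin}(\text{mean } 40,
  \text{size } 5)$ per cell, $\text{MFC} \sim \mathrm{Binom}(n_\text{inf},
  r)$, coverage $= \lceil 1.2\, n_\text{inf} \rceil$.
* **Cohort shape.** Defaults: 150 markers, 200 healthy, 40 samples per
  class allocated 16/20/30/34% to stages I-IV (a late-stage-weighted mix
  typical of symptomatic cohorts, where roughly a third of patients are
  early-stage).

Beta-matrix mode plants correlated CpG blocks via a per-block latent factor
with site noise (s.d. 0.1 over 130 samples, giving adjacent correlations
~0.99 against the 0.95 criterion); block spacing keeps within-block gaps
under and between-block gaps over the 100 bp rule. Fragment mode emits read
pairs that reproduce a marker matrix cell-for-cell: `n_informative`
informative pairs per cell (the non-fully-methylated ones unmethylated at
one random member CpG) plus span-overlapping two-member-CpG pairs to make
up coverage; quantifying them returns the input matrix bit-exactly, which
is the round-trip oracle used in tests.

What the generator does *not* model: sequencing error, incomplete
enzymatic conversion, fragment-length biology, inter-marker correlation
beyond the planted blocks, batch effects, or age/sex structure. Passing
tests therefore demonstrate the pipeline's statistical machinery, not
clinical performance on real plasma.

## Desk-scale power

The default conditions are deliberately not at performance ceiling. At
depth ~40 informative fragments per marker, a stage-I tumor fraction of
0.004 shifts a signature marker's expected MFC by ~0.1 fragments -
essentially undetectable - while stage IV (θ = 0.08) is detected reliably;
held-out AUC lands near 0.82 with overall sensitivity ~30% at 98%
specificity, stage-graded as in real cohorts. Similarly, backward
elimination with a handful of true positives per class retains only a few
CSO markers, capping top-1 CSO accuracy near 0.3-0.5. Both are honest
consequences of the stated cohort size, sequencing depth and tumor
fractions; the test suite asserts the structural properties (calibration,
monotonicity, recovery, determinism, oracle equivalence) at this scale and
records the performance numbers as measured.

## Problem sizes used in checks

The bundled checks run, per invocation: one default cohort (480 samples x
150 markers) through the full two-step pipeline; one null cohort (θ = 0,
~870 samples) for specificity calibration; 200 random beta matrices (≤50
CpGs) and 100 random fragment instances against brute-force oracles; 20
small cohorts for the fragment round trip; and a scoring-only stage-
monotonicity cohort (300 cancer samples per stage). These sizes keep a full
run on one CPU within a coffee break while leaving every property
measurable.
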