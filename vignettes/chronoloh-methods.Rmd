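---
title: "Methods: rhythm calling, dPCR copy number, read-depth LOH and clock-Wnt survival stratification"
author: "chronoloh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythm calling, dPCR copy number, read-depth LOH and clock-Wnt survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoloh)
```

`chronoloh` implements the computational chain that connects a broken
circadian clock to loss of heterozygosity (LOH) at the *Apc* tumor
suppressor and, at population scale, to colorectal-cancer survival. It has
four analysis stages — bioluminescence rhythmicity classification, digital
PCR copy-number estimation, exome read-depth LOH segment detection, and a
clock–Wnt covariance survival stratification — plus seeded synthetic-data
generators so that every stage can be exercised against planted ground
truth without access to patient organoids, mouse whole-exome sequencing or
a TCGA download.

## Rhythm analysis

Organoid reporter recordings are modeled as a damped cosine on a drifting
baseline,

$$y(t) = b + m t + A e^{-d t}\cos\!\big(2\pi (t-\phi)/T\big) + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2).$$

**Detrending.** The baseline drift is removed before any rhythm statistic.
The default subtracts an ordinary least-squares line — the standard choice
for multi-day luminescence records, where drift is dominated by substrate
depletion — with a centered 24 h moving-average subtraction available as
`method = "movavg"` for strongly nonlinear baselines. The two methods
differ only in how much low-frequency power they remove; both leave a
zero-mean oscillation.

**JTK_CYCLE.** Rhythmicity is tested nonparametrically: the detrended
series is rank-correlated (Kendall's S) against cosine reference curves
with a 24 h preset period, at every candidate phase spaced by the sampling
interval. The best $|S|$ is converted to a two-sided p-value under the
exact permutation null, computed from the inversion-count recursion (the
number of permutations of $n$ items with $k$ inversions; a permutation
with $k$ inversions has $S = n(n-1)/2 - 2k$). For $n > 50$ the normal
approximation with variance $n(n-1)(2n+5)/18$ is used. The minimum p over
phase alternatives is Bonferroni-multiplied by the number of alternatives
and capped at 1 — deliberately conservative; published JTK variants differ
in exactly how they combine phase alternatives, and the conservative
choice keeps the type-I error of the downstream call below its nominal
level (verified by simulation in the test suite). Pairs tied in either
vector are dropped from S; a fully tied (constant) trace returns $p = 1$.
An optional period scan (e.g. 20–28 h) is available behind
`period_scan_h`; the default follows the single 24 h preset.

**FFT-NLLS.** Period and amplitude come from a damped-cosine fit
$A e^{-d(t-t_0)}\cos(2\pi(t-\phi)/T) + c$ by Levenberg–Marquardt least
squares, initialized at the dominant discrete-Fourier component inside an
18–34 h band. Residual sums of squares are non-increasing across LM
iterations; convergence is declared at a relative RSS change below
$10^{-10}$ (at most 500 iterations). The reported amplitude is the fitted
envelope at the start of the recording — the convention for FFT-NLLS
reports, since the paper trail for "amplitude" of a damped oscillation is
otherwise ambiguous. The relative amplitude error (RAE) is the half-width
of the amplitude's asymptotic 95% confidence interval divided by the
amplitude; the covariance matrix is computed from a finite-difference
Jacobian at the optimum, which is robust to the occasional exactly
singular curvature matrix returned by the optimizer. If no Fourier
component falls in the band, or the optimizer fails, the fit is flagged
unusable (`period_h = 0`).

A practical note on precision: the asymptotic standard error of the fitted
period for a 72 h hourly recording scales like $\mathrm{SE}(T) \approx
0.77\,\sigma/A$ hours (from the Fisher information of the 5-parameter
model). At amplitude-to-noise 2 this is ≈ 0.39 h, so individual period
estimates scatter by several tenths of an hour even when the rhythm is
detected with overwhelming confidence; period accuracy claims should be
read against this bound.

**Classification.** A trace is rhythmic only if the JTK p-value is
strictly below 0.001 *and* the fitted period lies inside the closed
interval [22, 30] h; otherwise it is nonrhythmic (NR) with the first
failing reason recorded (`p_above_threshold`, `period_short`,
`period_long`). The thresholds are strict as printed: $p = 0.001$ exactly
fails, $T = 22$ and $T = 30$ exactly pass. NR calls carry `NA` period and
amplitude in machine-readable output and the string `"NR"` in report
tables.

**Paired amplitudes.** Tumor organoid amplitudes are normalized to the
matched normal organoid of the same patient; a tumor that is NR but still
has a usable fit contributes its fitted amplitude (flagged `tumor_nr`), so
that a collapsed-but-measurable rhythm is not silently dropped. The
matched ratios are tested against 1 with a two-sided Wilcoxon signed-rank
test: exact by full enumeration of the $2^n$ sign assignments for up to 25
non-zero differences (ties mid-ranked, via a convolution over doubled
ranks), normal approximation with continuity correction and tie-corrected
variance above. With 7 pairs the smallest attainable exact two-sided p is
$2/128 = 0.015625$ — worth remembering when reading starred p-values on
seven matched pairs.

## Digital PCR copy number

A digital PCR plate partitions genomic DNA into ~20,000 sub-reactions;
template molecules land in partitions approximately Poisson, so the mean
template per partition is recovered from the fraction of positive
partitions by the occupancy inversion

$$\hat\lambda = -\ln(1 - \hat p).$$

The 95% CI is the Wilson interval on $\hat p$ pushed through the same
transform (monotone, so the interval maps directly). The copy number of
the target locus relative to an autosomal reference present at
`ref_copies` (default 2, the convention for a control locus stable during
cancer progression) is

$$\widehat{CNV} = \mathrm{ref\_copies}\cdot
  \hat\lambda_{target}/\hat\lambda_{reference},$$

with a CI from first-order propagation of the two channels' relative
half-widths. State labels use configurable thresholds (below 0.3
homozygous loss, below 1.5 heterozygous loss, up to 2.5 diploid, above
gain); the instrument literature reports states only qualitatively, so
these cutoffs are explicit package defaults rather than published values.
Saturated plates (every partition positive) are an error: $\lambda$ is
undefined there and the assay should be rerun at higher dilution.

## Read-depth LOH detection

Input is a matrix of read counts over fixed genomic tiles (200 bp by
default) for replicate samples in two groups (early vs late passage). The
counts are assumed to come from alignments already filtered for mapping
quality ≥ 20 and proper-pair distance ≤ 1000 bp; those filters belong to
the alignment toolchain, and this module treats them as a contract on its
input rather than re-parsing BAMs.

The stage mirrors the standard exome quantification chain: (i) each
sample is scaled so all totals match the largest sample's total
("normalized to the largest data store"); (ii) tiles are quantified as
$\log_2((\mathrm{count} + 1)/\mathrm{length_{kb}})$ — pseudocount 1 keeps
zeros finite, length correction uses the BED interval width; (iii) each
tile is tested for a late-vs-early difference with a moderated t
statistic: the pooled per-tile variance $s^2$ (d residual df) is shrunk
toward a prior $s_0^2$ with prior df $d_0$,

$$\tilde s^2 = \frac{d_0 s_0^2 + d s^2}{d_0 + d},$$

and $t = \Delta/(\tilde s\sqrt{1/n_1 + 1/n_2})$ is referred to
$t_{d_0+d}$. The prior is fit by matching the first two moments of
$\log s^2$ across tiles (digamma/trigamma moments of the log chi-square;
the trigamma equation is inverted by Newton iteration). The two
degenerate limits are exact: $d_0 = 0$ recovers the ordinary pooled t and
$d_0 \to \infty$ a fixed-variance z-like statistic, and the estimated
prior and the resulting statistics agree with the reference
empirical-Bayes implementation in the test suite.

Deleted segments are maximal runs of at least `min_run = 3` consecutive
tiles with $\log_2$ fold change at or below −1 and $p < 0.01$. The p
filter is the published one; the fold-change gate and run length are
package defaults, stated here because a P-filter alone would call
scattered single tiles. Two arithmetic consequences are worth knowing
when configuring the gate: the pseudocount compresses the observable fold
change (a true halving at depth 100 appears as ≈ −0.99, not −1.0), and
largest-store normalization redistributes the lost depth, shifting
unaffected tiles slightly upward — so for heterozygous-level (fold 0.5)
events the gate should sit between 0 and −1 (e.g. −0.5). A complete
deletion (fold 0) is far from any of these margins and is recovered with
exact tile boundaries in essentially every simulation.

## Clock–Wnt covariance and survival

The cohort stage reproduces the population analysis end to end:

1. **Gene filter**: a gene is kept only if it is above zero in strictly
   more than 50% of samples.
2. **Tumor/normal split** by the TCGA barcode sample code (01–09 tumor,
   10–19 normal); anything else is excluded with a warning.
3. **Differential means** per core clock gene: two-sided unequal-variance
   (Welch) t tests, flagged at $p < 0.001$. "Student's t" in methods
   sections almost always means the Welch default of the analysis
   environment, and Welch is the safer choice under unequal group sizes
   (57 normals vs 470 tumors in the motivating cohort).
4. **Biweight midcorrelation** (bicor) between clock and Wnt panel genes:
   with $u_i = (x_i - \mathrm{med}\,x)/(9\,\mathrm{MAD}\,x)$ (MAD
   unscaled, no 1.4826 factor — the biweight convention) and weights
   $a_i = (1-u_i^2)^2\,\mathbf{1}[|u_i|<1]$,
   $$\mathrm{bicor}(x,y) = \frac{\sum_i a_i b_i (x_i-\mathrm{med}\,x)(y_i-\mathrm{med}\,y)}
     {\sqrt{\sum_i [a_i(x_i-\mathrm{med}\,x)]^2}\sqrt{\sum_i [b_i(y_i-\mathrm{med}\,y)]^2}}.$$
   It agrees with Pearson to ~0.02 on clean Gaussian data and moves by
   less than 0.1 under a single gross outlier that shifts Pearson by more
   than 0.3. A zero MAD (more than half the samples identical) falls back
   to Pearson. P-values use the regression t approximation
   $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df; pairs with $p < 0.001$ are
   significant, and the union of genes in at least one significant pair
   feeds the scoring step. An empty union halts the pipeline explicitly —
   with no covarying clock–Wnt genes there is nothing to score.
5. **PC contribution scores**: genes are standardized across tumor
   samples, the sample covariance is eigen-decomposed, and individual
   $i$'s contribution to component $k$ is
   $100\,s_{ik}^2/\sum_j s_{jk}^2$ (percent; sums to 100). Component 1 is
   the default — it is the direction along which coordinated clock–Wnt
   variation dominates — but the component is configurable, since
   contribution-based risk scores in the literature do not always state
   which component they rank on. Individuals are also binned into 10
   contribution quantiles for transparency.
6. **High/low covariance split**: individuals ranked by the absolute
   contribution; the upper half is "high covariance", the lower half
   "low", ties broken by stable sample order, the odd individual going to
   "low". Tumor samples without survival records are excluded (and
   counted) before scoring — which is how a 470-tumor cohort becomes a
   212/202 split.
7. **Survival**: Kaplan-Meier product-limit curves per group and the
   two-group log-rank test (observed vs hypergeometric-expected events at
   each distinct event time, $\chi^2_1$). These standard estimators are
   delegated to the `survival` package; the test suite pins them against
   hand-computed product-limit and 2-vs-2 log-rank oracles.

## Synthetic data: what it emulates and what it does not

All generators are pure functions of their configuration and seed
(byte-identical on repeat) and write the same plain-text formats the
readers consume.

* **Traces** follow the damped-cosine model above. `arrhythmic` forces
  $A = 0$; `abnormal_period` draws the period uniformly from
  $[14,20]\cup[32,40]$ h, outside the circadian gate.
* **dPCR plates** draw each channel's positives as binomial with
  $P(\mathrm{positive}) = 1 - e^{-\lambda}$, target
  $\lambda = \lambda_{ref}\cdot CNV_{true}/\mathrm{ref\_copies}$ — the
  exact occupancy model the estimator inverts, so estimator consistency
  (mean error $O(n^{-1/2})$) is testable.
* **Cohorts** use a single latent Gaussian factor: in normal tissue every
  clock and Wnt gene loads on it with weight `covariance_strength`; in
  tumors each patient draws a binary covariance level (probability 1/2),
  and only high-level patients keep the factor. Survival is exponential
  with hazard $h_0\cdot HR^{\mathbf 1[\text{low level}]}$; censoring hits
  a `censor_rate` fraction of patients uniformly before their event time.
  Defaults (300 patients, 50 matched normals, 12 clock and 30 Wnt genes,
  200 background genes, strength 0.8, HR 2.5, 30% censoring, baseline
  hazard 1/1000 per day, noise SD 1 on a log2 scale with gene means
  $N(8, 1.5)$) are fixed once as a realistic desk-scale cohort. The
  single-factor construction is deliberately the simplest structure that
  makes the covariance statistics recoverable; it does not emulate
  count-level noise, batch structure, correlated background pathways, or
  non-proportional hazards, so passing tests demonstrate method
  correctness, not robustness to everything real cohorts contain.
* **Depth tracks** draw negative-binomial counts with variance
  $\mu + \mu^2/\mathrm{dispersion}$ (dispersion 20 by default — moderate
  exome-tile overdispersion; `Inf` gives Poisson), with the planted
  deletion multiplying the late-group mean by `loh_fold` over a 0-based
  half-open tile range; `loh_fold = 0` yields exact zeros.

Identifiers follow the TCGA convention ("-01" tumor, "-11" normal) so the
barcode split is exercised realistically.

## Numerical and design notes

* Thresholds default to their published values everywhere: rhythm p
  0.001, period gate 22–30 h, correlation alpha 0.001, depth filter 0.01,
  10 contribution quantiles.
* The Kendall null pmf is built by exact convolution in double precision;
  tail sums that include the whole support short-circuit to exactly 1.
* JTK reports the phase of the largest $|S|$; under noise the anti-phase
  candidate can win (the test is two-sided in S), so phase is best
  interpreted modulo half a period.
* The signed-rank enumeration works on doubled mid-ranks (integers even
  under ties), so the exact branch handles tied ratios correctly where
  textbook implementations fall back to approximations.
* Wilson (not Wald) intervals keep dPCR CIs sensible at 0 and near
  saturation; the upper endpoint is clamped one half-partition below 1 so
  the log transform stays finite.
* Degenerate inputs are defined, not accidental: constant traces give
  $p = 1$; zero-variance genes give $p = 1$ when means agree and are
  dropped (with a warning) before PCA; zero-total depth samples and
  zero-length tiles are errors naming the offender.
* Test and simulation sizes (100 plates per CNV state, 1000 white-noise
  traces, 50-seed cohort batches of 300 tumors, 2000 null tiles) were
  chosen so every stochastic check has a 3-standard-error verdict band
  while the whole suite stays interactive.

## Known limitations

* The JTK Bonferroni correction is conservative; its p-values are upper
  bounds, which is the right direction for a 0.001 screening threshold
  but costs some power relative to permutation-calibrated variants.
* Period estimates inherit the $\mathrm{SE}(T)\propto\sigma/A$ floor
  discussed above; at low amplitude-to-noise, period-band accuracy is
  information-limited no matter the fitter.
* The LOH stage detects depth loss only; allele-fraction LOH (copy-neutral
  events) is out of scope, as are variant calling and annotation.
* The cohort model ties survival to a binary latent level; real cohorts
  presumably sit on a continuum, and the median split discards within-half
  ordering by construction.
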