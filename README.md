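# chronoloh

Circadian rhythmicity, *Apc* copy-number loss, and clock–Wnt survival
stratification in colorectal cancer.

Disruption of the circadian clock accelerates intestinal tumorigenesis:
clock-deficient organoids lose the remaining functional *Apc* allele (loss
of heterozygosity, LOH), and in human colorectal tumors the tight
covariance between core clock and Wnt pathway genes breaks down — with the
low-covariance patients showing worse overall survival. `chronoloh` is an
R package for the computational side of that story, aimed at chronobiology
and cancer-genomics analysts. It implements four analysis stages, each
with a seeded synthetic-data generator carrying planted ground truth:

1. **Rhythm analysis** — detrending of bioluminescence reporter traces;
   the JTK_CYCLE rhythmicity test (Kendall's S against phase-shifted 24 h
   cosine references, exact permutation null
   $P(|S| \ge s)$ via the inversion-count recursion, Bonferroni over phase
   alternatives); FFT-NLLS damped-cosine fitting
   $y = A e^{-dt}\cos(2\pi(t-\phi)/T) + c$ for period, amplitude and
   relative amplitude error; strict rhythmic/NR gating (p < 0.001 and
   22 h ≤ T ≤ 30 h); matched tumor/normal amplitude ratios with an exact
   Wilcoxon signed-rank test.
2. **Digital PCR copy number** — Poisson occupancy correction
   $\hat\lambda = -\ln(1-\hat p)$ per channel with Wilson-based CIs and
   $\widehat{CNV} = 2\,\hat\lambda_{target}/\hat\lambda_{ref}$ state
   calls (diploid / het loss / homozygous loss / gain).
3. **Read-depth LOH** — largest-store normalization, length-corrected
   log2 tile quantification, empirical-Bayes moderated t filtering
   (P < 0.01) with a moment-matched variance prior, and contiguous
   deleted-segment calling.
4. **Covariance–survival** — expressed-gene filtering, TCGA barcode
   tumor/normal splitting, per-gene Welch tests, biweight midcorrelation
   (bicor) clock × Wnt networks with significance at P < 0.001,
   principal-component contribution scores
   ($100\,s_i^2/\sum_j s_j^2$ percent), a high/low covariance median
   split, Kaplan-Meier curves and the log-rank test.

## Worked example

Simulate seven-pair-style organoid recordings, run the rhythm pipeline,
call copy number on a simulated heterozygous-loss plate, and stratify a
synthetic cohort:

```r
library(chronoloh)

normals <- generate_traces(trace_config(n_samples = 3, amplitude = 3,
                                        condition = "normal", seed = 101))
tumors  <- generate_traces(trace_config(n_samples = 3, amplitude = 0.5,
                                        damping_per_h = 0.05,
                                        condition = "tumor", seed = 102))
res <- rhythm_pipeline(rbind(normals, tumors))
res$report
#>  sample_id  p_value period_h amplitude    rae  verdict            reason
#>  normal_01 5.89e-24     23.9      2.91 0.0709 rhythmic                ok
#>  normal_02 1.59e-23     24.0      2.85 0.0835 rhythmic                ok
#>  normal_03 2.37e-23     24.0      2.94 0.0726 rhythmic                ok
#>   tumor_01 9.63e-01       NA        NA 0.6824       NR p_above_threshold
#>   tumor_02 3.46e-02       NA        NA 0.5075       NR p_above_threshold
#>   tumor_03 1.00e+00       NA        NA 0.6588       NR p_above_threshold
```

Normal organoids come out rhythmic with ~24 h periods and amplitudes near
the simulated value of 3; the damped, low-amplitude tumor traces fail the
JTK p < 0.001 screen and are reported NR (their high relative amplitude
error says the fitted amplitude is not trustworthy either).

```r
plate <- generate_dpcr_plate(dpcr_config(true_cnv = 1, seed = 7),
                             sample_id = "organoid_line_3")
dpcr_pipeline(plate)
#>        sample_id lam_target lam_ref  cnv ci_lo ci_hi    state
#>  organoid_line_3       0.26   0.501 1.04 0.999  1.07 het_loss
```

One of the two target alleles is gone: the estimated copy number is ~1
("het_loss"), against a reference locus at 0.5 copies/partition.

```r
tk <- generate_depth_tracks(depth_config(loh_start = 40, loh_end = 80,
                                         loh_fold = 0, seed = 3))
loh_pipeline(tk)$segments
#>  start_index end_index chrom start   end mean_log2fc n_significant
#>           40        80 chr18  8000 16000      -6.632            40

b  <- generate_cohort(cohort_config(seed = 42))
cv <- covsurv_pipeline(b)
cv$logrank
#> significant clock-Wnt pairs: 213 (gene union 42)
#> log-rank chi-square = 6.57, p = 0.01039 (high n=150, low n=150)
```

The planted exon-scale deletion is recovered with exact tile boundaries,
and on the synthetic cohort the low clock–Wnt covariance group shows
significantly worse overall survival, as in the motivating human cohort.

A thin command-line wrapper over the same functions lives in
`inst/scripts/chronoloh`
(`chronoloh simulate-cohort --out dir --seed 5`, then
`chronoloh covsurv --expr dir/expression.tsv ...`); every run writes a
`run_report.json` manifest with resolved parameters and output checksums.

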