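# h2scan

Stratified fine-mapping and association analysis of the chr17q21 *MAPT*
H1/H2 inversion haplotype in case cohorts genotyped against **external**
population controls.

The locus segregates as two non-recombining haplotype classes; the rarer H2
class is protective against Parkinson's disease. h2scan implements the full
workflow for characterising such a haplotype when only case genotypes and
published control *allele counts* are available:

* **Synthetic cohort generator** — an Ashkenazi-like PD cohort with an
  inversion-style perfect-LD block (tag SNV + divergent SNVs), planted
  recombination breakpoints, founder-mutation subgroups (GBA1, LRRK2-G2019S,
  dual, SMPD1, non-carriers), a configurable protective odds ratio injected
  by rejection sampling, per-call DP/GQ noise, and age at motor symptom
  onset from a linear model with a sex effect. Every downstream stage runs
  with no external data.
* **Variant QC** — strict DP < 10 / GQ < 30 call masking, call-rate and
  indel filters, region extraction, low-coverage interval scanning.
* **LD fine-mapping** — composite r² scan around a tag SNV,
  haplotype-divergent SNV calling (r² ≥ 0.99), recombinant-segment detection
  in tag homozygotes, and the minimal LD interval (intersection of
  haplotype-consistent segments).
* **Association** — allelic / dominant / recessive odds ratios of case
  genotype counts against control allele counts, with Hardy–Weinberg
  expected control genotype cells, Woolf log-OR confidence intervals, and
  founder-mutation-stratified output:
  OR = (case odds)/(control odds), CI = exp(ln OR ± z·√Σ1/xᵢ).
* **Dual-carrier null** — observed H2 carriage among founder-mutation
  carriers versus the independence expectation f = 1 − (1 − p)², closed form
  or Monte Carlo (100,000 simulated individuals, seeded).
* **Onset model** — OLS of AMSO on dominant H2 carrier status adjusted for
  sex, after excluding severe/compound-het/N370S-homozygous GBA1 carriers.
* **Annotation & QTL filters** — CADD Phred thresholds, candidate-variant
  reports, eQTL (m ≥ 0.9 and p < 5e-4) and sQTL (p < 1e-4) filters, and
  cross-tissue consistency over the 13 GTEx brain tissues.

Everything takes and returns tibbles, chains with the pipe, has
`tidy()`/`glance()` methods for fitted objects and `autoplot()` methods for
scan and association results.

## Worked example

```r
library(h2scan)

ctrl <- control_frequencies(1259, 4912)       # external control allele counts
cfg  <- cohort_config(n_samples = 1200, seed = 42,
                      n_divergent_snvs = 6, n_background_snvs = 0,
                      n_indels = 0, missing_rate = 0, gq_sd = 0, dp_size = 1e6)
ch   <- simulate_cohort(cfg)                  # protective OR 0.75 by default

stratified_association(ch$meta, ctrl, models = c("allelic", "dominant"))
#>   stratum    model n_cases case_af odds_ratio ci_low ci_high  p_value
#> 1     all  allelic    1200   0.230      0.867  0.773   0.972 0.014431
#> 2     all dominant    1200   0.230      0.788  0.685   0.908 0.000927
#> 3    GBA1  allelic     232   0.226      0.849  0.677   1.065 0.155877
#> 4    GBA1 dominant     232   0.226      0.664  0.501   0.880 0.004321
#> 5   LRRK2  allelic     158   0.269      1.068  0.826   1.380 0.617273
#> 6   LRRK2 dominant     158   0.269      1.010  0.731   1.396 0.952314
#> 7      NC  allelic     778   0.226      0.845  0.738   0.967 0.014624
#> 8      NC dominant     778   0.226      0.798  0.677   0.941 0.007150
```

The cohort was generated with a dominant protective OR of 0.75 for H2
carriers: the overall dominant estimate (0.788, CI 0.685–0.908) recovers it,
the allelic estimates are attenuated toward 1 (the injected mechanism is
carrier-level, not allele-level), and the small LRRK2 stratum is noisy — all
as expected.

Dual-carrier deficit test from observed counts (86 H2 carriers among 235
GBA1-mutation carriers) against the Hardy–Weinberg expectation from the
control allele frequency:

```r
dual_carrier_test(86, 235,
                  expected_h2_carrier_freq = hwe_carrier_freq(ctrl$alt_freq))
#>   observed_carriers group_size observed_rate expected_carrier_freq odds_ratio
#> 1                86        235         0.366                0.4469     0.7143
#>   ci_low ci_high      z p_value n_simulated
#> 1 0.5478  0.9314 -2.485 0.01296          NA
```

36.6% of mutation carriers carry H2 where independence predicts 44.7%:
co-carriage is depleted (OR 0.714, p = 0.013).

Onset regression (dominant model, sex-adjusted, confounded GBA1 carriers
excluded):

```r
fit <- fit_amso_regression(amso_exclusion_filter(ch$meta)$meta, "all")
tidy(fit)
#>   stratum term        estimate std_error ci_low ci_high p_value n_used
#> 1 all     (Intercept)   60.8       0.508  59.8   61.8     0       1127
#> 2 all     h2_carrier    -0.802     0.699  -2.17   0.568   0.251   1127
#> 3 all     female        -0.844     0.697  -2.21   0.523   0.226   1127
```

The generator draws onset with no carrier effect, and the fitted carrier
coefficient is correspondingly null.

End-to-end, with VCF/TSV/BED outputs and a JSON manifest:

```r
run_pipeline(list(cohort = list(n_samples = 202), seed = 1), "run/")
```

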