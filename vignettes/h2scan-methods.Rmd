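---
title: "Methods: stratified fine-mapping and association analysis of the MAPT H1/H2 haplotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified fine-mapping and association analysis of the MAPT H1/H2 haplotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h2scan)
```

## The scientific problem

The chr17q21 region containing *MAPT* harbours a ~900 kb inversion that
suppresses recombination between its two orientations, so the locus segregates
as two deeply diverged haplotype classes, H1 and H2. H2 is the rarer class in
European-ancestry populations and is protective against Parkinson's disease
(PD). Because the classes barely recombine, thousands of SNVs are fixed for
different alleles on H1 versus H2 ("haplotype-divergent" SNVs, r² ≈ 1 with any
one of them), and a single well-chosen **tag SNV** proxies the entire
haplotype.

h2scan packages the analysis workflow such a locus invites when a case cohort
is genotyped but no matched control genotypes exist:

1. **QC** of genotype calls (depth/quality masking, call-rate and indel
   filters, low-coverage interval scanning);
2. **LD fine-mapping**: a tag-SNV r² scan, divergent-SNV calling, detection of
   recombinant alleles in tag homozygotes, and the **minimal LD interval**
   (the intersection of haplotype-consistent segments across homozygotes);
3. **association** of case genotype counts against *external* control allele
   counts (e.g. a gnomAD population subset), under allelic, dominant and
   recessive models, stratified by founder-mutation carrier status;
4. a **dual-carrier null**: does the H2 haplotype co-occur with founder
   mutations (GBA1, LRRK2-G2019S) at the rate independence predicts?
5. a **linear model of age at motor symptom onset** (AMSO) on dominant H2
   carrier status, adjusted for sex;
6. **annotation/QTL threshold filters** (CADD, ENCODE cCRE and constrained
   regions; GTEx-style eQTL/sQTL tables with cross-tissue consistency).

Because consented patient-level data of this kind cannot be shared, the
package ships a **synthetic cohort generator** that reproduces the *structure*
the analysis assumes, so every stage runs, and can be validated, without any
external data.

## Statistical models

### Odds ratios against external allele counts

Control information enters as two scalars, the alternate and total allele
counts $(a_c, n_c)$, giving $p = a_c / n_c$. Case genotype counts
$(n_0, n_1, n_2)$ are contrasted as:

* **allelic**: case alternate alleles $n_1 + 2 n_2$ of $2N$ vs $a_c$ of $n_c$;
* **dominant**: case carriers $n_1 + n_2$ vs $n_0$, against Hardy–Weinberg
  *expected* carrier/non-carrier counts among $n_c / 2$ control individuals,
  i.e. cells $\tfrac{n_c}{2}\,(1 - (1-p)^2)$ and $\tfrac{n_c}{2}\,(1-p)^2$;
* **recessive**: case homozygotes $n_2$ vs the rest, against the
  $p^2 / (1 - p^2)$ split.

Control genotype cells are expectations and may be fractional; this is the
only way to run genotype-level models when the reference publishes allele
counts only, and it is exact when the reference population is in
Hardy–Weinberg equilibrium. All inference is the Woolf log-OR normal
approximation: $\mathrm{SE} = \sqrt{\sum 1/x_i}$ over the four cells,
$\mathrm{CI} = \exp(\ln \mathrm{OR} \pm z_{\alpha/2}\mathrm{SE})$, two-sided
$p$ from $z = \ln(\mathrm{OR})/\mathrm{SE}$. No continuity correction is
applied by default; a zero cell is an error naming the cell, and the
Haldane–Anscombe +0.5 correction is opt-in (`haldane = TRUE`).

Strata follow the exclusivity rules of founder-mutation cohorts: the GBA1 and
LRRK2 strata exclude dual-mutation carriers, the non-carrier stratum carries
none of the genotyped mutations, and the overall cohort includes everyone.

### The dual-carrier independence null

Among $n$ founder-mutation carriers, $k$ carry H2. Under independence the
expected carrier fraction is the Hardy–Weinberg transform
$f = 1 - (1 - p)^2$ of the control allele frequency. The test compares the
observed odds $k/(n-k)$ with the expected odds $f/(1-f)$ through the same
log-OR machinery. Two expectation paths exist:

* **closed form** (default): $f$ is treated as exact (infinite-reference
  limit), so only the observed side contributes variance;
* **Monte Carlo**: `simulate_dual_carriers()` draws $n_{sim}$ individuals
  (default 100,000) with independent Bernoulli mutation- and H2-carrier
  states; the simulated carrier counts form the expectation side and
  contribute their own sampling variance, which is what makes the reported
  CI and p-value depend (mildly) on the simulation seed.

The odds ratio itself is identical under both paths up to Monte-Carlo noise;
only the CI width differs. The Monte-Carlo path needs the population
mutation-carrier frequency, which is user input; the package defaults use
literature-typical Ashkenazi founder-mutation carrier rates (GBA1 panel 6.5%,
LRRK2-G2019S 1.8%).

### Minimal LD interval from recombinant homozygotes

Tag homozygotes carry two copies of the tagged haplotype, so every divergent
SNV should show dosage 2 in them. A recombinant allele breaks that run: for
each homozygote the package finds the maximal contiguous run of dosage-2
divergent sites containing the tag and labels the clipped side proximal,
distal, both, or none. The minimal LD interval is the intersection of these
consistent intervals; its endpoints are the outermost divergent SNV positions
consistent in *every* homozygote (not midpoints between sites, so the result
is reproducible from genotypes alone). Adding a homozygote can only shrink
the interval.

r² is the **composite (genotypic) estimator**: squared Pearson correlation of
dosage vectors over samples non-missing at both sites. On phase-certain,
noise-free data it equals haplotype r², and it is what standard LD tools
compute from genotype counts by default; an EM haplotype-frequency estimator
is a possible extension, not implemented. "r² ≈ 1" is operationalised as
r² ≥ 0.99 (configurable): tight enough to exclude background LD, tolerant of
finite-sample rounding.

### Onset regression

AMSO is regressed on an H2 carrier indicator (dosage ≥ 1; the dominant
coding) and a female indicator by OLS, per stratum, with t-based confidence
intervals and p-values — the standard small-sample choice. Samples whose
GBA1 genotype itself shifts onset (severe-class carriers, compound
heterozygotes, N370S homozygotes) are excluded beforehand by
`amso_exclusion_filter()`, which reports per-reason counts and counts
overlapping samples once.

## The synthetic cohort generator

`cohort_config()` fixes the generative conditions; `simulate_cohort()` draws
from them. The defaults encode the cohort structure the analysis assumes:

| parameter | default | meaning |
|---|---|---|
| `n_samples` | 1200 | cases |
| `h2_allele_freq` | 0.256 | H2 frequency (the external control AF) |
| `carrier_freqs` | GBA1 .196, LRRK2 .121, dual .021, SMPD1 .007 | founder-mutation subgroups; remainder non-carriers |
| `h2_protective_or` | 0.75 | injected dominant carrier-vs-expectation OR |
| `amso_mean`, `amso_sd` | 60.5, 11.2 y | onset distribution |
| `beta_sex` | −1.0 y | female onset shift in the generative model |
| `female_frac` | 0.396 | sex composition |
| `n_divergent_snvs` | 60 | perfect-LD block (tag = central site) |
| `recombinant_rate` | 0.01 | per-haplotype breakpoint probability |
| `dp_mean`, `dp_size` | 40, 6 | negative-binomial read depth |
| `gq_mean`, `gq_sd` | 85, 20 | genotype quality, clipped to [0, 99] |
| `missing_rate` | 0.002 | per-call missingness |

Mechanics and the reasoning behind the genuinely open choices:

* **Haplotypes, not genotypes, are the primitive.** Each haplotype gets an
  H1/H2 label; divergent SNVs copy the label, background SNVs and indels draw
  independently at evenly spaced allele frequencies. Variant positions are
  deterministic functions of the configuration, so the panel is identical
  across seeds and only the draws vary.
* **The protective effect is injected by rejection sampling** of cases
  against *carrier* status: carriers are accepted with probability equal to
  the target OR (protective case), which scales the realised carrier odds by
  exactly that factor relative to the Hardy–Weinberg expectation. This is a
  dominant mechanism, matching the dominant protection the association stage
  is designed to detect; an allelic mechanism would be an easy variant but is
  not provided.
* **Recombinant breakpoints are planted at fixed positions** (default: two,
  between the 2nd/3rd divergent sites from either end), so the
  interval-narrowing scenario is reproducible: the recoverable inner block is
  known exactly and parameter-recovery tests can assert equality, not
  proximity.
* **Noise models.** Depth is negative binomial and quality a clipped
  Gaussian; the defaults put ~1% of calls below the DP < 10 / GQ < 30
  thresholds. Note that the strict call-rate-1.0 variant filter then removes
  a fraction $1-(1-f)^n$ of variants — steep in the sample size $n$. This is
  faithful to how such filters behave on real cohorts, and it is why the
  pipeline's default simulated cohort is WGS-scale (202 samples, the size at
  which LD fine-mapping is typically done) rather than the full genotyped
  cohort of 1200, which in this design is analysed at a single TaqMan-typed
  variant and never passes through VCF QC.
* **Independence assumptions.** Founder-mutation subgroup, sex and H2 status
  are drawn independently (the dual-carrier null itself assumes mutation–H2
  independence, so the generator's null matches the test's). GBA1 severity
  classes for the onset exclusion rule (severe 25% / mild 45% / risk 30% of
  carriers, 3% compound heterozygotes, 2% N370S homozygotes) are plausible
  founder-population values chosen once; nothing downstream is sensitive to
  them beyond the count of excluded samples.
* **AMSO** is a linear model with a −1 y female effect and residual SD equal
  to the configured cohort SD; the intercept is derived so the expected
  cohort mean hits `amso_mean`.

**What the generator does *not* emulate** — and therefore what passing tests
do not show about real data: coalescent LD decay (background SNVs are in
linkage *equilibrium* with the block, real flanking variation is not),
population structure and relatedness, genotyping batch effects, depth
heterogeneity along the genome (no planted low-coverage dips; the
low-coverage scanner is validated on constructed tracks), structural variants
and the segmental duplications that make parts of such loci hard to call,
and any mutation–haplotype age structure. Tests on synthetic data validate
the *estimators and their wiring*, not robustness to these real-data
pathologies.

## Numerical and convention choices

* Coordinates are 1-based inclusive everywhere internally, matching printed
  genome-browser spans; conversion to BED's 0-based half-open convention
  happens only in `write_bed()`.
* "Lower than" thresholds are strict: DP 10 / GQ 30 pass. CADD thresholds are
  inclusive ("score of X or higher"), the eQTL m-value threshold is inclusive
  (≥ 0.9) while both QTL p thresholds are strict (<), following the wording
  conventions these filters are usually stated in.
* Multi-allelic VCF records are split into one bi-allelic record per
  alternate at load; dosage counts that alternate only.
* Monomorphic LD partners are reported as excluded (r² undefined), never as
  r² = 0; a monomorphic tag is an error.
* Samples with a missing call at any divergent site are dropped from segment
  detection with a warning — the call-rate-1.0 filter normally guarantees
  completeness upstream.
* A homozygote clipped on both flanks is labelled `both` rather than being
  rejected; double recombinants are unusual but not impossible in user data.
* Degenerate association cells (a zero cell in a small stratum) yield `NA`
  statistics in `stratified_association()` rather than an error, so one thin
  stratum cannot abort a whole run; `odds_ratio_test()` itself still errors,
  naming the cell.
* In the QTL consistency summary, records from interchangeable haplotype-proxy
  variants are collapsed per (gene, tissue, type) to the best p-value before
  counting tissues — a documented choice, since gene-level statements need
  one record per tissue and nothing in the inputs dictates the rule.

## Problem sizes used by the validation suite

The test suite validates statistical behaviour at sizes chosen to make
binomial/Monte-Carlo bounds tight while staying quick: haplotype and subgroup
frequencies at n = 10,000 draws against 3σ binomial bounds; dominant OR
recovery at generating values {0.6, 0.75, 1.0} with 200 replicates of
n = 5,000 (mean recovered OR within 0.03 of truth); planted-breakpoint
interval recovery across 20 seeds at n = 400; onset-model type-I error and
CI coverage over 200 replicates. These are the package's validation
conditions, stated here so they can be scaled up by anyone wanting tighter
bounds.

## Known limitations

* The composite r² estimator equals haplotype r² only under phase certainty;
  at intermediate LD on unphased data the two differ. For divergence calling
  at r² ≈ 1 the distinction is immaterial.
* The closed-form dual-carrier CI treats the expected carrier fraction as
  exact; finite-reference uncertainty enters only through the Monte-Carlo
  path (or an explicit `n_reference_carriers`).
* The external-control design cannot adjust for covariates; there is no
  logistic-regression path, and no penetrance modelling.
* `run_pipeline()` recomputes every enabled stage on each call; there is no
  cached partial-rerun machinery. Runs are deterministic given (config,
  seed), so reruns are exact.
* The interval endpoints are SNV positions; when compared against published
  intervals whose endpoints are rounded extraction bounds, agreement at the
  outermost-SNV level is the most that can be claimed.
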