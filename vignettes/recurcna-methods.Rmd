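---
title: "Methods: copy-number and allelic-ratio analysis of recurrence cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number and allelic-ratio analysis of recurrence cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recurcna)
```

# The problem

Rectal cancer recurs locally in a minority of patients, and preoperative
radiotherapy — effective against local recurrence but with substantial
morbidity — is currently given far more broadly than the population at risk.
A genomic marker separating patients headed for local recurrence from the
rest would allow treatment to be targeted. `recurcna` implements a complete
analysis chain for one candidate marker family: somatic copy-number (CN)
alterations and allelic ratios measured on tumor/normal SNP-array pairs from
a matched cohort of surgically treated patients, grouped as controls without
recurrence (C), local (L), distant (D), and local & distant (LD) recurrences.
The headline biological signal the package is organised around is *retention
of heterozygosity on chromosome 7* in tumors of patients who later develop a
local recurrence, against a control group in which roughly six in ten tumors
carry an imbalanced chromosome-7 gain.

Because the underlying clinical-trial data are not publicly deposited, the
package ships a first-class synthetic-data module that generates every input
the analysis consumes, with known ground truth. All operating
characteristics quoted anywhere in this vignette are computed by the test
suite or by `scripts/acceptance.R`, never transcribed.

# Data model

A **probe map** (`build_probe_map()`) lays out SNP probes over autosomal p/q
arms with 0-based, half-open coordinates. The default desk-scale genome is
22 autosomes with 120 probes per arm (5,280 probes); real array density
(~300k probes) is a configuration choice, not a default, because the test
suite must run in minutes. Chromosome 13 is modeled as acrocentric — all of
its probes sit on 13q — so no meaningless 13p calls can arise.

A tumor's latent state (`simulate_truth_profile()`) is a tiling of each
chromosome by segments with total copies $c_t$ and B-allele copies
$b_t \le c_t$. The derived **allelic class** is the package's central
discrete variable:

* 1 — *retention of heterozygosity*: $b_t = c_t/2$ (balanced),
* 2 — *allelic imbalance*: unequal dosage with both alleles present,
* 3 — *LOH*: one parental allele absent.

The observed assay (`simulate_assay_pair()`) mixes tumor and admixed normal
cells at purity $\rho$: expected CN ratio $(\rho c_t + 2(1-\rho))/2$ and, at
germline-heterozygous probes, expected B-allele fraction (BAF)
$(\rho b + (1-\rho)) / (\rho c_t + 2(1-\rho))$ with the assayed parental
allele randomised per probe. Gaussian noise, a sinusoidal genomic wave in
the CN ratio, and log-normal raw intensities complete the observation
model. Default $\rho = 0.75$: tumor material of this kind is enriched by laser
capture microdissection and macrodissection, which favours high purity,
but no exact figure is available, so 0.75 is a documented package choice.
Default noise (CN ratio SD 0.08, BAF SD 0.04) and wave (amplitude 0.05,
period 30 Mb) are typical of mid-2000s Illumina SNP arrays.

## Group-specific aberration priors

The generators encode the study's effect structure:

* chromosome 7 — L-group tumors retain balanced heterozygosity with
  probability 1; controls (and the D group, which shares control priors so
  that D-vs-C is a true null) carry an imbalanced gain ($3/1$) with
  probability 0.62 and copy-neutral LOH with probability 0.02, retention
  otherwise. These follow the printed per-arm control split
  (36% / 62% / 2%).
* chromosome 13(q) — L retention 0.78; control imbalance 0.60 and
  hemizygous-deletion LOH 0.13, mirroring the printed 13q class table.
* background arms — whole-arm gains (rate 0.08/arm) and losses (0.06/arm)
  plus occasional focal events of 30–80 probes (rate 0.05/arm). These rates
  are deliberately below real colorectal-cancer alteration frequencies so
  that single-run association tests remain interpretable at desk scale.

Zeroing every prior and rate yields a fully diploid heterozygous genome, the
null configuration used by several tests.

## Matched cohorts and survival

`simulate_cohort()` produces the default 112-patient discovery layout
(C 46, L 10, D 41, LD 15). Matching criteria are exact TNM stage, exact
circumferential-resection-margin (CRM) involvement, exact sex, and age at
surgery within 7 years. Because there are fewer controls than recurrent
patients, a control may serve several of them; the assignment itself is a
greedy nearest-age match within the exact-covariate stratum
(`match_controls()`), processed in random order, preferring unused controls.
Controls are generated by age-clustered stratified copying of the recurrent
patients — emulating how a study selects matchable controls from a larger
registry — which guarantees the criteria are satisfiable; infeasible
configurations (for example, too few controls for the occupied strata)
raise a matching-failure error naming the stratum.

Survival endpoints follow the standard definitions: OS (death by any
cause), DSS (death by disease, other deaths censored), LRFP and DRFP (first
local / distant recurrence, death before recurrence censors), all
administratively censored at a 12-year horizon. Event times are exponential
with group-specific hazards (defaults: yearly death rates 0.04/0.12/0.20/
0.25 for C/L/D/LD, recurrence-time hazards 0.35–0.40, censoring hazard
0.03) — the simplest generative model supporting Cox-recovery tests; no
standard generative model exists for such cohorts, so simplicity wins. By construction L/LD
patients have a local recurrence within follow-up and D/LD a distant one,
which is what group membership means.

# The array pipeline

`run_array_pipeline()` chains, per patient:

1. **Mean-log2 QC** — a sample fails when the mean of log2 raw intensities
   is below 4 (the threshold itself passes). Applied to raw intensities —
   the conservative reading, since normalization can mask a dim array.
2. **Genotype calling** on the normal BAF: AA < 0.15, AB in [0.35, 0.65],
   BB > 0.85, otherwise NoCall. Cutpoints are standard array practice and
   exposed in `calling_config()`.
3. **Pair-concordance QC** — at probes homozygous in the normal (robust to
   somatic allelic imbalance), tumor and normal genotype calls must agree
   for at least 90% of probes; swapped samples fall far below this.
4. **Normalization** to the sample mean (so the gain/loss thresholds are
   relative to the genome-wide average, and normalization is idempotent).
5. **De-waving** (below).
6. **Mirrored BAF**: $\mathrm{mBAF} = |\mathrm{BAF} - 0.5| + 0.5$ at
   germline-heterozygous probes, NA elsewhere.
7. **Segmentation** of both signals and **calling** (below).

## De-waving

SNP-array CN ratios carry a smooth genomic "wave" artifact that must be
removed without flattening true segments. `dewave()` alternates two
estimates per chromosome: a piecewise-constant level whose edges are
permutation-tested changepoints with a between-segment mean jump of at
least `min_jump` (default 0.18 — above twice a typical wave amplitude,
below any arm-level event at default purity, so level changes small enough
to be wave are never protected), and a short-span local regression
(`lowess`, span = `span/10` of the chromosome) of the level-subtracted
residual, which is subtracted out. Two passes recover the wave fraction the
level absorbs initially. The design was chosen over a single robust
smoother because iterated outlier down-weighting cannot distinguish a
half-chromosome step from a long-period wave; tying step protection to an
explicit jump threshold can. The acceptance suite verifies both directions:
a pure amplitude-0.1 sinusoid is reduced below 0.02, and a 0.5-step
spanning half a chromosome is preserved within 10%.

## Segmentation

`segment_profile()` is recursive binary segmentation: each candidate split
maximises the pooled two-sample t statistic of the flanking means, and is
accepted when its permutation p-value (null: within-segment permutation of
the values, statistic: maximal |t| over allowed splits) is below
`seg_alpha` = 0.01 with both children at least `min_seg_probes` = 5 probes.
100 permutations per test give the exact resolution needed for the 0.01
gate; permutation batches stop early once enough exceedances accumulate to
make acceptance impossible, which leaves null segments cheap. The CN signal
is segmented over all probes and the mBAF signal over heterozygous probes
(breakpoints mapped back to full probe indices); the union of the two
breakpoint sets defines the segments (`segment_assay_pair()`). This
reproduces the behaviour of classical CBS-style segmenters with a fully
specified, testable algorithm.

## Calling

Per segment (`call_segments()`): CN state is *loss* below 0.92 and *gain*
above 1.08 — the published operating points, relative to the sample mean —
with strict inequalities, so a mean exactly at a threshold stays neutral
(a symmetric-conservative boundary convention, documented here). The allelic class comes from the mean mBAF over
germline-heterozygous probes: retention below 0.60, LOH at or above 0.78,
imbalance between; segments with fewer than 10 heterozygous probes are
uninformative (NA). No numeric class rule is published; the cutpoints were
placed from the purity-mixture arithmetic at the default $\rho = 0.75$: a
3:1 gain has expected mBAF $\approx 0.64$ (imbalance), copy-neutral LOH
$\approx 0.875$ and a hemizygous deletion $\approx 0.80$ (both LOH). The
LOH cut sits at 0.78, not higher, precisely so the hemizygous deletion —
the weakest canonical LOH state at this purity — is still called LOH.

Cohort **frequency profiles** (`frequency_profile()`) count, per probe, the
fraction of a group's patients with a gain, and with a loss restricted to
segments of at least 15 probes (the published reporting filter for losses);
arms are summarised by their maximum probe frequency.

# Association testing

The group-association machinery is a hierarchical, gated sequence of
permutation score tests (`hierarchical_test()`):

* The statistic is $Q = \frac{1}{m}\sum_j (z_j^\top \tilde y)^2$ over
  row-standardised features $z_j$ and the centred binary label
  $\tilde y$ — the score form of a global test of whether a feature set is
  jointly associated with the label. Significance comes from label
  permutations: $p = (1 + \#\{Q_{perm} \ge Q\})/(1 + B)$, seeded and
  deterministic. This form was fixed deliberately instead of an asymptotic
  reference distribution: it is exact at any sample size and free of
  distributional assumptions, at the cost of a resolution floor of
  $1/(B+1)$.
* Features: for the *allelic* analysis, per-probe integer class codes
  (1/2/3) expanded from segment calls (uninformative segments coded 1 — no
  evidence of aberration); for the *CN* analysis, per-probe segment-mean
  ratios.
* Hierarchy and gating: by default the gate follows the published protocol
  — arms are tested when the overall copy-number *or* the overall
  allelic-ratio genome test reaches `alpha` (0.05); `gate = "same"`
  restricts the gate to the tested data type. Arms form one
  Benjamini–Hochberg family per comparison; regions — consecutive 40-probe
  windows within arms passing the adjusted gate — form a second family.
  The window width is a package choice: "smaller underlying segments" has
  no canonical granularity, and fixed windows keep the family structure
  patient-independent.
* Permutation budgets: the genome gate only needs to resolve 0.05, so it
  can run with a few thousand permutations; the arm and region estimates
  feed a BH adjustment over ~43 scopes and therefore default to the
  module's 10,000 permutations (`n_permutations_followup`).

`bh_adjust()` is the BH step-up adjustment (delegating to
`stats::p.adjust`; the test suite checks it against the direct step-up
definition on random vectors).

**Chromosome status** (`chromosome_status()`) is the most abundant allelic
class on the chromosome, weighted by heterozygous-probe count (the
abundance measure is configurable); ties resolve to the higher — more
aberrant — class, a conservative-toward-aberration choice that is
documented rather than silent. Combined chromosome status
(`combine_status()`) is the maximum of the inputs. Group differences in
status composition are tested with `fisher_rxc()`, an exact
Fisher test for r×c tables by full enumeration of tables with the observed
margins (p = total multivariate-hypergeometric probability of tables no
more probable than observed, with a 1e-7 relative tolerance on the
comparison). Enumeration is exponential in principle but instantaneous for
the 2×3 status tables it exists for; the suite checks exact equality
against a brute-force oracle and `stats::fisher.test`.

# Survival models

`fit_marker_model()` wraps `survival::coxph` (Efron ties — the default of
the R survival ecosystem) for one per-patient marker, univariate or
multivariate with the predetermined covariates TNM stage (indicator
contrasts II and III against I), age (continuous years), sex and CRM
involvement, included regardless of significance. Competing events are
handled by censoring, matching the stated endpoint definitions, not by a
Fine–Gray model. Results come back through broom-style `tidy()` /
`glance()` methods.

# qPCR validation arithmetic

The dynamic-array validation chain implements the published arithmetic
exactly: Ct values above 30 and missing wells are set to 30
(`preprocess_ct()`, idempotent); molecules $= 2^{26-\mathrm{Ct}}$
(`ct_to_molecules()`, one molecule at Ct 26); replicate wells are averaged
on the molecule scale (averaging molecules rather than Ct respects the
exponential scale); each channel is divided by
its sample total before the A/B ratio is taken (`sample_allelic_ratio()`),
so a global per-channel efficiency bias cancels — a zero denominator yields
a flagged sentinel of $2^8$. Panel selection (`select_validation_snps()`)
takes the 16 most heterozygous SNPs per region (7p, 7q, 13) with
heterozygosity at least 40% in normals, ties broken by probe id.

Per patient and region, the summary statistic is the mean of the *folded*
ratio $\max(r, 1/r)$ over panel SNPs: raw A/B ratios are allele-label
dependent (a 2:1 imbalance reads 2 or 0.5 depending on which parental
allele the assay's A channel happens to tag); folding makes the summary
symmetric in allele labeling and is the documented default. Groups are compared per region with the Welch two-sample t-test
(`stats::t.test`, checked against the textbook formula).

# Cross-study counting rule

`flag_frequent()` marks an arm alteration frequent within a study when at
least 25% of that study's cases carry it (inclusive boundary, per "at
least"); `common_alterations()` calls an alteration common when at least
40% of the (site-filtered) studies flag it, with per-arm missing fractions
excluded from that arm's denominator only; `site_contrast()` reports arms
whose study fractions differ by strictly more than 20% between sites
(strict, per "difference of >20%" — an exactly-0.20 difference is not
reported). `simulate_study_table()` generates Beta-distributed per-study
fractions to exercise the rule.

# Problem sizes and reproducibility

Every stochastic function takes a `seed` and is byte-reproducible given it;
nested seeds are derived deterministically from the parent seed and a
stream label. The test suite and the acceptance script use the desk-scale
genome (5,280 probes) and the default 112-patient cohort throughout; the
heaviest check — 20 simulated cohorts pushed through the full pipeline and
hierarchy — was sized so the whole suite completes comfortably on a single
CPU. Statistical operating points in the tests (e.g. type-I error within
[0.03, 0.07] at $\alpha = 0.05$ over 1000 replicates; ≥90% probe-level CN
recovery) are properties of the method at the stated sizes, measured, not
asserted.

# What the simulation does and does not show

The generator reproduces the *structure* the analysis assumes: purity
attenuation, genotype-conditional BAF, wave artifact, matched covariates,
group-specific allelic priors, exponential survival. It does not model
FFPE degradation chemistry, probe-specific response, GC-content waves with
genomic autocorrelation, subclonal heterogeneity, or germline CNV — so
green tests demonstrate correctness of the implementation and adequate
power under the stated conditions, not performance on any real cohort.
Reproduction of the original cohort-level tables is out of reach by
construction (the trial data are unreleased); the two printed
overall-status contingency tables are used as fixed inputs to the exact
test, which the acceptance checks reproduce to their printed precision.

# Known limitations

* The permutation global test has a p-value floor of $1/(B+1)$ and, more
  fundamentally, an exact-test floor given by the probability of drawing a
  label permutation as extreme as the observed grouping; with 10-vs-46
  groups and near-binary features this floor is a few times $10^{-4}$,
  which bounds how small adjusted arm-level p-values can get.
* Integer allele-specific copy-number deconvolution (purity/ploidy fitting)
  is explicitly out of scope; calls are threshold-based at a configured
  purity regime.
* The allelic classifier is CN-agnostic: copy-neutral imbalance and
  gain-driven imbalance are the same class 2; distinguishing them would
  need integer allele-specific calls, which are out of scope.
* `fisher_rxc()` enumerates exhaustively and is intended for small tables;
  it will not scale to large r×c problems.
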