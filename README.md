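# recurcna

Genome-wide copy-number and allelic-ratio analysis of tumor recurrence
cohorts, with a first-class simulator for matched tumor/normal SNP-array
studies.

## The problem

Local recurrence of rectal cancer is the event preoperative radiotherapy is
meant to prevent, yet only a small minority of patients are actually at
risk. A tumor-genomic marker of that risk would let treatment be targeted.
One candidate signal is *allelic* rather than copy-number: tumors of
patients who later develop a local recurrence tend to retain balanced
heterozygosity on chromosome 7, while control tumors frequently carry an
imbalanced chromosome-7 gain.

`recurcna` implements the full analysis chain around that question:

* **Simulation** of everything the analysis consumes — probe maps,
  matched four-group cohorts (control C, local L, distant D, local &
  distant LD) with survival endpoints, probe-level tumor/normal assays with
  known ground truth, duplicate-well qPCR Ct plates, and cross-study
  alteration-frequency tables.
* **Array pipeline** — mean-log2 intensity QC, genotype calling,
  tumor/normal concordance QC, normalization to the sample mean, de-waving,
  mirrored-BAF computation, permutation-tested recursive binary
  segmentation of both signals, and per-segment calls: copy-number state
  (loss < 0.92, gain > 1.08 relative to the sample mean) and allelic class
  (1 = retention, 2 = imbalance, 3 = LOH) from mean mirrored BAF.
* **Association** — a permutation score test
  $Q = \tfrac1m \sum_j (z_j^\top \tilde y)^2$ applied hierarchically
  (genome → chromosome arm → region) with Benjamini–Hochberg correction and
  the published gate: arms are tested only when an overall copy-number or
  allelic genome test is significant. Per-chromosome *overall status* (the
  most abundant allelic class, ties to the more aberrant) is compared
  between groups with an exact r×c Fisher test by full enumeration.
* **Survival** — Cox proportional-hazards models (Efron ties) of
  per-patient markers, univariate or with the fixed covariates TNM stage,
  age, sex and CRM involvement.
* **qPCR validation arithmetic** — Ct capping at 30, molecules
  $=2^{26-\mathrm{Ct}}$, channel-normalized allelic ratios, folded
  per-region summaries, Welch two-sample comparisons.
* **Meta-analysis counting rule** — an arm alteration is frequent within a
  study at ≥ 25% of cases and common across studies at ≥ 40% of studies;
  site contrasts use a strict 20% difference.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` / `plot_*()` for the main result
types.

## Worked example

Simulate a discovery-scale study (112 patients, 5,280 probes), run the
pipeline, and test the chromosome-7 status contrast:

```r
library(recurcna)
library(dplyr)

study <- simulate_discovery_study(sim_config(), seed = 1)
pipe  <- run_cohort_pipeline(study$assays, calling_config(), seed = 2)

# per-chromosome overall allelic status, chromosome 7
status7 <- chromosome_status(pipe$segments) |>
  filter(chrom == 7) |>
  select(patient_id, status)
res <- status_group_test(status7, study$cohort, "L-vs-C")
res$table
#>   retention imbalance loh
#> L        10         0   0
#> C        12        34   0
res$p_value
#> [1] 1.816062e-05
```

All ten simulated local-recurrence tumors retain balanced chromosome-7
heterozygosity while most controls are imbalanced; the exact test on the
2×3 status table is strongly significant. The same machinery applied to
the published overall-status table (L: 9/0/0 against C: 19/25/1) gives

```r
fisher_rxc(rbind(c(9, 0, 0), c(19, 25, 1)))
#> [1] 0.0024708
```

i.e. p = 0.0025 at the printed precision. The hierarchical association
test localises the allelic signal to the chromosome-7 arms:

```r
segs <- left_join(pipe$segments, study$cohort[, c("patient_id", "group")],
                  by = "patient_id")
hier <- hierarchical_test(segs, study$cohort, study$probe_map,
                          "L-vs-C", "allelic",
                          n_permutations = 2000, seed = 3)
hier |> filter(level == "arm", p_adjusted < 0.05) |>
  select(scope, statistic, p_value, p_adjusted)
#> # A tibble: 2 × 4
#>   scope statistic  p_value p_adjusted
#>   <chr>     <dbl>    <dbl>      <dbl>
#> 1 7p         152. 0.0001       0.00430
#> 2 7q         152. 0.000200     0.00430
```

`run_demo(out_dir, seed = 1)` chains every stage — simulation, pipeline,
association, status Fisher tests, a multivariate Cox model of
chromosome-7 aberration for the local recurrence-free period, the qPCR
validation round and the cross-study counting rule — and writes all tables
plus a summary report to `out_dir`.

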