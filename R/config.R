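#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators: cohort composition,
#' array geometry, assay noise, group-specific aberration priors and survival
#' hazards. Defaults emulate the discovery conditions the package is designed
#' around: a 112-patient matched rectal-cancer cohort (46 controls, 10 local,
#' 41 distant, 15 local & distant recurrences), tumor purity 0.75 after
#' microdissection, and a chromosome-7 effect in which local-recurrence tumors
#' retain balanced heterozygosity while roughly half the controls carry an
#' imbalanced chromosome-7 gain.
#'
#' @param n_per_group Named integer vector with group sizes for `C` (control),
#'   `L` (local), `D` (distant) and `LD` (local & distant recurrence).
#' @param n_chromosomes Number of autosomes simulated (1..22).
#' @param probes_per_arm SNP probes per chromosome arm. Chromosome 13 is
#'   modeled as acrocentric: its p arm gets zero probes.
#' @param arm_length_bp Physical length of each simulated arm in bp.
#' @param purity Tumor-cell fraction \eqn{\rho} in (0, 1]; attenuates observed
#'   copy-number ratio and B-allele fraction toward diploid values.
#' @param noise_sd_cn,noise_sd_baf Gaussian noise SD of the per-probe
#'   copy-number ratio and B-allele fraction.
#' @param wave_amplitude,wave_period_bp Amplitude and period of the sinusoidal
#'   genomic wave artifact added to the tumor copy-number ratio.
#' @param population_het Expected heterozygosity of simulated SNPs (the mean
#'   of the per-probe Beta-distributed heterozygosity).
#' @param p_chr7_imbalance,p_chr7_loh Named per-group probabilities that
#'   chromosome 7 carries an imbalanced gain (3 total / 1 B copies) or
#'   copy-neutral LOH; the remainder — the retention prior — leaves it
#'   balanced diploid, so zeroing all aberration priors yields a fully
#'   diploid heterozygous genome. Defaults follow the printed per-arm
#'   control split (36% retention / 62% imbalance / 2% LOH) with full
#'   retention in the L group.
#' @param p_chr13_imbalance,p_chr13_loh Same for chromosome 13(q); LOH there
#'   is a hemizygous deletion.
#' @param background_gain_rate,background_loss_rate Per-arm probability of a
#'   whole-arm gain (3/1) or hemizygous loss (1/0) on arms other than 7 and
#'   13q.
#' @param focal_rate Per-arm probability of an additional focal event
#'   (30-80 probes) on background arms.
#' @param os_rate,p_cancer_death,lrfp_rate,drfp_rate Named per-group yearly
#'   exponential hazards of death, probability a death is disease-specific,
#'   and recurrence-time hazards for the groups that have the event.
#' @param censor_rate Yearly hazard of independent loss to follow-up.
#' @param horizon_years Administrative follow-up horizon (years).
#' @param age_mean,age_sd,age_range,p_male,tnm_probs,p_crm Covariate
#'   distributions for simulated patients.
#' @param max_age_gap,age_jitter_sd Matching constraint (maximum tumor/control
#'   age difference, years) and the SD of the control-age jitter.
#' @param intensity_log2_mean Mean of the per-probe log2 raw intensity used
#'   for the mean-log2 quality-control statistic.
#' @param seed Optional integer recorded in the configuration and used as the
#'   default seed by generators that are not given one explicitly.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_per_group = c(C = 46L, L = 10L, D = 41L, LD = 15L),
                       n_chromosomes = 22L,
                       probes_per_arm = 120L,
                       arm_length_bp = 6e7,
                       purity = 0.75,
                       noise_sd_cn = 0.08,
                       noise_sd_baf = 0.04,
                       wave_amplitude = 0.05,
                       wave_period_bp = 3e7,
                       population_het = 0.5,
                       p_chr7_imbalance = c(C = 0.62, L = 0.00, D = 0.62, LD = 0.48),
                       p_chr7_loh = c(C = 0.02, L = 0.00, D = 0.02, LD = 0.02),
                       p_chr13_imbalance = c(C = 0.60, L = 0.11, D = 0.60, LD = 0.45),
                       p_chr13_loh = c(C = 0.13, L = 0.11, D = 0.13, LD = 0.15),
                       background_gain_rate = 0.08,
                       background_loss_rate = 0.06,
                       focal_rate = 0.05,
                       os_rate = c(C = 0.04, L = 0.12, D = 0.20, LD = 0.25),
                       p_cancer_death = c(C = 0.20, L = 0.70, D = 0.80, LD = 0.85),
                       lrfp_rate = 0.35,
                       drfp_rate = 0.40,
                       censor_rate = 0.03,
                       horizon_years = 12,
                       age_mean = 64,
                       age_sd = 12,
                       age_range = c(30, 92),
                       p_male = 0.65,
                       tnm_probs = c(I = 0.10, II = 0.21, III = 0.69),
                       p_crm = 0.27,
                       max_age_gap = 7,
                       age_jitter_sd = 2,
                       intensity_log2_mean = 5,
                       seed = NULL) {
  groups <- c("C", "L", "D", "LD")
  n_per_group <- n_per_group[groups]
  if (anyNA(n_per_group)) {
    stop_invalid("`n_per_group` must name all of C, L, D, LD")
  }
  check_number(purity, "purity", min = 1e-12, max = 1)
  check_number(noise_sd_cn, "noise_sd_cn", min = 0)
  check_number(noise_sd_baf, "noise_sd_baf", min = 0)
  check_number(wave_amplitude, "wave_amplitude", min = 0)
  check_number(probes_per_arm, "probes_per_arm", min = 2, integer = TRUE)
  check_number(n_chromosomes, "n_chromosomes", min = 1, max = 22, integer = TRUE)
  for (nm in c("p_chr7_imbalance", "p_chr7_loh",
               "p_chr13_imbalance", "p_chr13_loh")) {
    v <- get(nm)[groups]
    if (anyNA(v)) stop_invalid(sprintf("`%s` must name all groups", nm))
    if (any(v < 0 | v > 1)) stop_invalid(sprintf("`%s` must lie in [0, 1]", nm))
    assign(nm, v)
  }
  if (any(p_chr7_imbalance + p_chr7_loh > 1 + 1e-12) ||
      any(p_chr13_imbalance + p_chr13_loh > 1 + 1e-12)) {
    stop_invalid("imbalance + LOH priors must not exceed 1 in any group")
  }
  check_prob(background_gain_rate, "background_gain_rate")
  check_prob(background_loss_rate, "background_loss_rate")
  check_prob(focal_rate, "focal_rate")
  check_prob(population_het, "population_het")
  check_number(horizon_years, "horizon_years", min = 0)
  cfg <- list(
    n_per_group = as.integer(n_per_group),
    n_chromosomes = as.integer(n_chromosomes),
    probes_per_arm = as.integer(probes_per_arm),
    arm_length_bp = arm_length_bp,
    purity = purity,
    noise_sd_cn = noise_sd_cn,
    noise_sd_baf = noise_sd_baf,
    wave_amplitude = wave_amplitude,
    wave_period_bp = wave_period_bp,
    population_het = population_het,
    p_chr7_imbalance = p_chr7_imbalance,
    p_chr7_loh = p_chr7_loh,
    p_chr7_retention = 1 - p_chr7_imbalance - p_chr7_loh,
    p_chr13_imbalance = p_chr13_imbalance,
    p_chr13_loh = p_chr13_loh,
    p_chr13_retention = 1 - p_chr13_imbalance - p_chr13_loh,
    background_gain_rate = background_gain_rate,
    background_loss_rate = background_loss_rate,
    focal_rate = focal_rate,
    os_rate = os_rate,
    p_cancer_death = p_cancer_death,
    lrfp_rate = lrfp_rate,
    drfp_rate = drfp_rate,
    censor_rate = censor_rate,
    horizon_years = horizon_years,
    age_mean = age_mean,
    age_sd = age_sd,
    age_range = age_range,
    p_male = p_male,
    tnm_probs = tnm_probs,
    p_crm = p_crm,
    max_age_gap = max_age_gap,
    age_jitter_sd = age_jitter_sd,
    intensity_log2_mean = intensity_log2_mean,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  names(cfg$n_per_group) <- groups
  structure(cfg, class = "sim_config")
}

#' Copy-number and allelic-class calling configuration
#'
#' Thresholds and tuning constants of the array pipeline. The copy-number
#' thresholds (0.92 for losses, 1.08 for gains, relative to the sample mean),
#' the mean-log2 quality-control floor of 4 and the 15-probe loss-reporting
#' filter are the published operating points; the remaining values are design
#' choices documented in the methods vignette and exposed here.
#'
#' @param loss_threshold,gain_threshold Copy-number ratio thresholds (strict
#'   inequalities; a segment mean exactly at a threshold is neutral).
#' @param aa_max,ab_min,ab_max,bb_min B-allele-fraction cutpoints for genotype
#'   calling in the normal sample (AA below `aa_max`, AB inside
#'   `[ab_min, ab_max]`, BB above `bb_min`, otherwise NoCall).
#' @param concordance_min Minimum tumor/normal genotype concordance at
#'   normal-homozygous probes for a pair to pass identity QC.
#' @param mean_log2_min Minimum mean log2 raw intensity for a sample to pass.
#' @param mbaf_imbalance_cut,mbaf_loh_cut Mean mirrored-BAF cutpoints for the
#'   three allelic classes: below the first is retention (1), at or above the
#'   second is LOH (3), between is imbalance (2). The LOH cut is placed so a
#'   hemizygous deletion at the default purity 0.75 (mixture mBAF 0.80) is
#'   called LOH.
#' @param min_het_per_segment Minimum heterozygous probes for a segment to
#'   receive an allelic class.
#' @param seg_alpha Permutation significance level for accepting a split in
#'   the recursive binary segmentation.
#' @param seg_n_perm Permutations per split test.
#' @param min_seg_probes Minimum probes per segment.
#' @param loss_report_min_probes Minimum probes a loss segment must span to
#'   count toward cohort loss frequencies.
#' @param dewave_span Smoother span of the per-chromosome de-waving fit (as a
#'   fraction of probes on the chromosome).
#' @param region_probes Width (in probes) of the fixed windows used as the
#'   region level of the hierarchical test.
#' @param gate_alpha Alpha used to gate each level of the hierarchy (applied
#'   to adjusted p-values below the genome level).
#'
#' @return An object of class `calling_config` (a named list).
#' @export
calling_config <- function(loss_threshold = 0.92,
                           gain_threshold = 1.08,
                           aa_max = 0.15,
                           ab_min = 0.35,
                           ab_max = 0.65,
                           bb_min = 0.85,
                           concordance_min = 0.90,
                           mean_log2_min = 4.0,
                           mbaf_imbalance_cut = 0.60,
                           mbaf_loh_cut = 0.78,
                           min_het_per_segment = 10L,
                           seg_alpha = 0.01,
                           seg_n_perm = 100L,
                           min_seg_probes = 5L,
                           loss_report_min_probes = 15L,
                           dewave_span = 0.5,
                           region_probes = 40L,
                           gate_alpha = 0.05) {
  if (!(loss_threshold < 1 && 1 < gain_threshold)) {
    stop_invalid("need loss_threshold < 1 < gain_threshold")
  }
  if (!(0.5 < mbaf_imbalance_cut && mbaf_imbalance_cut < mbaf_loh_cut &&
        mbaf_loh_cut <= 1)) {
    stop_invalid("need 0.5 < mbaf_imbalance_cut < mbaf_loh_cut <= 1")
  }
  check_prob(concordance_min, "concordance_min")
  check_number(seg_alpha, "seg_alpha", min = 0, max = 1)
  check_number(min_seg_probes, "min_seg_probes", min = 1, integer = TRUE)
  structure(list(
    loss_threshold = loss_threshold,
    gain_threshold = gain_threshold,
    aa_max = aa_max, ab_min = ab_min, ab_max = ab_max, bb_min = bb_min,
    concordance_min = concordance_min,
    mean_log2_min = mean_log2_min,
    mbaf_imbalance_cut = mbaf_imbalance_cut,
    mbaf_loh_cut = mbaf_loh_cut,
    min_het_per_segment = as.integer(min_het_per_segment),
    seg_alpha = seg_alpha,
    seg_n_perm = as.integer(seg_n_perm),
    min_seg_probes = as.integer(min_seg_probes),
    loss_report_min_probes = as.integer(loss_report_min_probes),
    dewave_span = dewave_span,
    region_probes = as.integer(region_probes),
    gate_alpha = gate_alpha
  ), class = "calling_config")
}

#' qPCR validation configuration
#'
#' Constants of the dynamic-array molecule-counting arithmetic: Ct values
#' above 30 (and missing wells) are set to 30, a Ct of 26 corresponds to one
#' DNA molecule, validation SNPs require at least 40% heterozygosity in
#' normals, and 16 SNPs are selected per region (7p, 7q, 13).
#'
#' @param ct_cap Ct ceiling; larger and missing values are set here.
#' @param single_molecule_ct Ct corresponding to one template molecule.
#' @param min_het_fraction Minimum normal-tissue heterozygosity for a SNP to
#'   be eligible for the validation panel.
#' @param panel_size SNPs selected per region.
#' @param regions Region labels of the panel.
#' @param max_ratio Sentinel emitted (with a flag) when the denominator
#'   channel has zero molecules.
#' @return An object of class `qpcr_config` (a named list).
#' @export
qpcr_config <- function(ct_cap = 30,
                        single_molecule_ct = 26,
                        min_het_fraction = 0.40,
                        panel_size = 16L,
                        regions = c("7p", "7q", "13"),
                        max_ratio = 2^8) {
  if (!(ct_cap > single_molecule_ct)) {
    stop_invalid("`ct_cap` must exceed `single_molecule_ct`")
  }
  check_prob(min_het_fraction, "min_het_fraction")
  structure(list(
    ct_cap = ct_cap,
    single_molecule_ct = single_molecule_ct,
    min_het_fraction = min_het_fraction,
    panel_size = as.integer(panel_size),
    regions = regions,
    max_ratio = max_ratio
  ), class = "qpcr_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  cohort:", paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
                         collapse = " "), "\n")
  cat(sprintf("  genome: %d chromosomes x %d probes/arm\n",
              x$n_chromosomes, x$probes_per_arm))
  cat(sprintf("  purity %.2f, cn noise %.3f, baf noise %.3f, wave %.3f\n",
              x$purity, x$noise_sd_cn, x$noise_sd_baf, x$wave_amplitude))
  invisible(x)
}

#' @export
print.calling_config <- function(x, ...) {
  cat("<calling_config>\n")
  cat(sprintf("  CN thresholds: loss < %.2f, gain > %.2f\n",
              x$loss_threshold, x$gain_threshold))
  cat(sprintf("  mBAF classes: retention < %.2f <= imbalance < %.2f <= LOH\n",
              x$mbaf_imbalance_cut, x$mbaf_loh_cut))
  invisible(x)
}
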