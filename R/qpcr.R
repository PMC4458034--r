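#' Select the SNP panel for qPCR validation
#'
#' Ranks SNPs within each target region (7p, 7q, chromosome 13) by their
#' heterozygous fraction in normal tissues and returns the top
#' `config$panel_size` (16) with heterozygosity of at least
#' `config$min_het_fraction` (40%). Ties break deterministically by probe
#' id. Regions with fewer eligible SNPs return all of them with a warning.
#'
#' @param het_table Tibble `probe_id`, `het_fraction` (fraction of normal
#'   samples called AB at the probe).
#' @param probe_map The probe map (supplies `chrom`, `arm`, per-chromosome
#'   index).
#' @param config A [qpcr_config()].
#' @return Tibble `snp_id`, `region`, `chrom`, `idx` (0-based probe index
#'   within the chromosome), `het_fraction`, sorted by region then rank.
#' @export
select_validation_snps <- function(het_table, probe_map,
                                   config = qpcr_config()) {
  pm <- probe_map %>%
    group_by(.data$chrom) %>% mutate(idx = row_number() - 1L) %>% ungroup() %>%
    mutate(region = dplyr::case_when(
      .data$chrom == 7L ~ paste0("7", .data$arm),
      .data$chrom == 13L ~ "13",
      TRUE ~ NA_character_
    ))
  eligible <- het_table %>%
    dplyr::inner_join(pm, by = "probe_id") %>%
    filter(!is.na(.data$region), .data$region %in% config$regions,
           .data$het_fraction >= config$min_het_fraction)
  panel <- eligible %>%
    arrange(.data$region, dplyr::desc(.data$het_fraction), .data$probe_id) %>%
    group_by(.data$region) %>%
    slice(seq_len(min(config$panel_size, n()))) %>%
    ungroup() %>%
    transmute(snp_id = .data$probe_id, region = .data$region,
              chrom = .data$chrom, idx = .data$idx,
              het_fraction = .data$het_fraction)
  short <- setdiff(config$regions,
                   panel %>% count(.data$region) %>%
                     filter(.data$n >= config$panel_size) %>% pull("region"))
  if (length(short) > 0L) {
    warn(sprintf("fewer than %d eligible SNPs in region(s): %s",
                 config$panel_size, paste(short, collapse = ", ")))
  }
  panel
}

#' Preprocess qPCR Ct values
#'
#' Missing wells and Ct values above `config$ct_cap` (30) are set to the
#' cap; everything else passes through unchanged. Idempotent.
#'
#' @param ct Numeric vector of Ct values, possibly with NAs.
#' @param config A [qpcr_config()].
#' @return Numeric vector without NAs, capped at `config$ct_cap`.
#' @export
preprocess_ct <- function(ct, config = qpcr_config()) {
  if (any(ct < 0, na.rm = TRUE)) {
    stop_invalid("Ct values must be non-negative",
                 class = "recurcna_invalid_input")
  }
  pmin(dplyr::coalesce(ct, config$ct_cap), config$ct_cap)
}

#' Convert a Ct value to template molecule count
#'
#' `molecules = 2^(26 - Ct)`: Ct 26 corresponds to one DNA molecule and each
#' cycle halves the implied template amount.
#'
#' @param ct Preprocessed Ct values.
#' @param config A [qpcr_config()].
#' @return Numeric vector of molecule counts.
#' @export
#' @examples
#' ct_to_molecules(c(26, 25, 30))  # 1, 2, 0.0625
ct_to_molecules <- function(ct, config = qpcr_config()) {
  2^(config$single_molecule_ct - ct)
}

#' Channel-normalized per-SNP allelic ratios
#'
#' Each channel's replicate-averaged molecule count is divided by the
#' sample's total molecule amount in that channel (normalizing away global
#' per-channel efficiency differences), then the A/B ratio is taken. A zero
#' B-channel after normalization yields the `config$max_ratio` sentinel with
#' a flag.
#'
#' @param molecules Tibble `sample_id`, `snp_id`, `channel` ("A"/"B"),
#'   `molecules` (replicate-averaged counts).
#' @param config A [qpcr_config()].
#' @return Tibble `sample_id`, `snp_id`, `ratio`, `flag` ("ok" or
#'   "zero_denominator").
#' @export
sample_allelic_ratio <- function(molecules, config = qpcr_config()) {
  norm <- molecules %>%
    group_by(.data$sample_id, .data$channel) %>%
    mutate(total = sum(.data$molecules)) %>%
    ungroup()
  if (any(norm$total <= 0)) {
    stop_invalid("sample channel totals must be positive")
  }
  norm %>%
    mutate(normalized = .data$molecules / .data$total) %>%
    select("sample_id", "snp_id", "channel", "normalized") %>%
    tidyr::pivot_wider(names_from = "channel", values_from = "normalized") %>%
    mutate(
      flag = if_else(.data$B <= 0, "zero_denominator", "ok"),
      ratio = if_else(.data$B <= 0, config$max_ratio, .data$A / .data$B)
    ) %>%
    select("sample_id", "snp_id", "ratio", "flag")
}

#' Aggregate replicate wells to molecule counts
#'
#' Preprocesses Ct values (cap 30, missing to 30), converts to molecules and
#' averages over replicate wells per sample x SNP x channel.
#'
#' @param ct_records Long tibble `sample_id`, `snp_id`, `replicate`,
#'   `channel`, `ct` (see [simulate_ct_plate()]).
#' @param config A [qpcr_config()].
#' @return Tibble `sample_id`, `snp_id`, `channel`, `molecules`.
#' @export
ct_to_sample_molecules <- function(ct_records, config = qpcr_config()) {
  ct_records %>%
    mutate(molecules = ct_to_molecules(preprocess_ct(.data$ct, config),
                                       config)) %>%
    group_by(.data$sample_id, .data$snp_id, .data$channel) %>%
    summarise(molecules = mean(.data$molecules), .groups = "drop")
}

#' Per-region Welch comparison of allelic ratios between groups
#'
#' Summarises each patient and region by the mean folded allelic ratio
#' `max(r, 1/r)` over the region's panel SNPs (symmetric in allele
#' labeling), then compares the two groups of the comparison per region with
#' the Welch two-sample t-test.
#'
#' @param ratios Tibble `sample_id`, `snp_id`, `ratio` (from
#'   [sample_allelic_ratio()]).
#' @param panel Tibble `snp_id`, `region`.
#' @param cohort Tibble `patient_id`, `group`; `sample_id` in `ratios` must
#'   equal `patient_id`.
#' @param comparison `"L-vs-C"`, `"D-vs-C"` or `"LD-vs-C"`.
#' @return Tibble `region`, `comparison`, `t`, `df`, `p_value`, `n_1`,
#'   `n_2`.
#' @export
region_group_comparison <- function(ratios, panel, cohort,
                                    comparison = c("L-vs-C", "D-vs-C",
                                                   "LD-vs-C")) {
  comparison <- match.arg(comparison)
  grp <- sub("-vs-C$", "", comparison)
  per_region <- ratios %>%
    dplyr::inner_join(panel %>% select("snp_id", "region"), by = "snp_id") %>%
    mutate(folded = pmax(.data$ratio, 1 / .data$ratio)) %>%
    group_by(sample_id = .data$sample_id, region = .data$region) %>%
    summarise(summary_ratio = mean(.data$folded), .groups = "drop") %>%
    dplyr::inner_join(cohort %>% select("patient_id", "group"),
                      by = c(sample_id = "patient_id")) %>%
    filter(.data$group %in% c(grp, "C"))
  per_region %>%
    group_by(.data$region) %>%
    dplyr::group_modify(function(df, key) {
      a <- df$summary_ratio[df$group == grp]
      b <- df$summary_ratio[df$group == "C"]
      if (length(a) < 2L || length(b) < 2L) {
        stop_invalid("each compared group needs at least 2 patients")
      }
      if (sd(a) == 0 && sd(b) == 0) {
        return(tibble(comparison = comparison,
                      t = if (mean(a) == mean(b)) 0 else NaN,
                      df = NA_real_,
                      p_value = if (mean(a) == mean(b)) 1 else NaN,
                      n_1 = length(a), n_2 = length(b)))
      }
      tt <- t.test(a, b, var.equal = FALSE)
      tibble(comparison = comparison, t = unname(tt$statistic),
             df = unname(tt$parameter), p_value = tt$p.value,
             n_1 = length(a), n_2 = length(b))
    }) %>%
    ungroup()
}
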