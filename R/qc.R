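#' Mean-log2 intensity quality control
#'
#' A sample fails when the mean of log2 raw probe intensities falls below
#' `config$mean_log2_min` (default 4); the threshold itself passes. Failing
#' samples are flagged for exclusion, never deleted.
#'
#' @param raw_intensities Positive numeric vector of raw probe intensities.
#' @param config A [calling_config()].
#' @return A list with `statistic` (the mean log2 value) and `pass`.
#' @export
#' @examples
#' qc_mean_log2(rep(16, 100))$pass   # mean log2 = 4 -> pass
#' qc_mean_log2(rep(8, 100))$pass    # mean log2 = 3 -> fail
qc_mean_log2 <- function(raw_intensities, config = calling_config()) {
  x <- raw_intensities[!is.na(raw_intensities)]
  if (length(x) == 0L) stop_invalid("no non-missing intensities")
  if (any(x <= 0)) {
    stop_invalid("raw intensities must be positive",
                 class = "recurcna_invalid_input")
  }
  stat <- mean(log2(x))
  list(statistic = stat, pass = stat >= config$mean_log2_min)
}

#' Call germline genotypes from normal-sample BAF
#'
#' AA below `aa_max` (default 0.15), BB above `bb_min` (default 0.85), AB
#' inside `[ab_min, ab_max]` (default \[0.35, 0.65\]); anything else is
#' NoCall. The heterozygous fraction is AB calls over all non-NoCall calls.
#'
#' @param normal_baf Numeric vector in \[0, 1\].
#' @param config A [calling_config()].
#' @return A list with `genotype` (character vector in AA/AB/BB/NoCall) and
#'   `het_fraction`.
#' @export
call_genotypes <- function(normal_baf, config = calling_config()) {
  if (any(normal_baf < 0 | normal_baf > 1, na.rm = TRUE)) {
    stop_invalid("`normal_baf` must lie in [0, 1]")
  }
  g <- dplyr::case_when(
    is.na(normal_baf) ~ "NoCall",
    normal_baf < config$aa_max ~ "AA",
    normal_baf > config$bb_min ~ "BB",
    normal_baf >= config$ab_min & normal_baf <= config$ab_max ~ "AB",
    TRUE ~ "NoCall"
  )
  called <- sum(g != "NoCall")
  list(genotype = g,
       het_fraction = if (called == 0L) NA_real_ else sum(g == "AB") / called)
}

#' Tumor/normal genotype concordance check
#'
#' Sample-identity QC: at probes called homozygous in the normal (robust to
#' somatic allelic imbalance), the tumor genotype must match. A pair fails
#' when concordance drops below `config$concordance_min`.
#'
#' @param tumor_genotypes,normal_genotypes Aligned character vectors of
#'   genotype calls (AA/AB/BB/NoCall).
#' @param config A [calling_config()].
#' @return A list with `concordance`, `n_informative` and `pass`.
#' @export
check_pair_concordance <- function(tumor_genotypes, normal_genotypes,
                                   config = calling_config()) {
  if (length(tumor_genotypes) != length(normal_genotypes)) {
    stop_invalid("genotype vectors must be aligned (equal length)")
  }
  hom <- normal_genotypes %in% c("AA", "BB") & tumor_genotypes != "NoCall"
  n_inf <- sum(hom)
  if (n_inf == 0L) {
    abort("no informative probes for concordance QC",
          class = c("recurcna_indeterminate_qc", "recurcna_error"))
  }
  conc <- mean(tumor_genotypes[hom] == normal_genotypes[hom])
  list(concordance = conc, n_informative = n_inf,
       pass = conc >= config$concordance_min)
}
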