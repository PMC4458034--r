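#' Simulate a matched tumor/normal probe-level SNP-array assay
#'
#' Emits per-probe copy-number ratios and B-allele fractions (BAF) for a
#' normal and a tumor sample of one patient, given the tumor's latent truth
#' profile and tumor purity \eqn{\rho}.
#'
#' The normal sample is diploid: copy-number ratio \eqn{1 + } noise and BAF
#' near 0, 0.5 or 1 according to the germline genotype drawn per probe from
#' `population_het`. The tumor is a purity mixture of tumor and admixed
#' normal cells: expected ratio \eqn{(\rho c_t + (1-\rho)2)/2} plus a
#' sinusoidal genomic wave and noise, and at germline-heterozygous probes
#' expected BAF \eqn{(\rho b + (1-\rho))/(\rho c_t + (1-\rho)2)} where `b`
#' is `b_t` or `c_t - b_t` with equal probability (allele phase is random
#' per probe). Copy-number ratios are clipped at 0 and BAF to [0, 1].
#' Per-probe raw intensities (log-normal around `config$intensity_log2_mean`
#' on the log2 scale) are included for mean-log2 quality control.
#'
#' @param truth Truth profile from [simulate_truth_profile()]; must tile
#'   `probe_map`.
#' @param probe_map Probe map from [build_probe_map()].
#' @param config A [sim_config()]; `purity` must lie in (0, 1].
#' @param seed Optional integer seed.
#' @param patient_id Identifier stored in the output.
#'
#' @return A tibble with one row per probe: `probe_id`, `chrom`, `arm`,
#'   `pos`, `patient_id`, `normal_cn_ratio`, `normal_baf`, `normal_raw`,
#'   `tumor_cn_ratio`, `tumor_baf`, `tumor_raw`, `genotype` (true germline
#'   genotype "AA"/"AB"/"BB"), and the ground truth (`c_t`, `b_t`,
#'   `true_class`) retained for evaluation.
#' @export
simulate_assay_pair <- function(truth, probe_map, config = sim_config(),
                                seed = NULL, patient_id = "pt_001") {
  if (config$purity <= 0 || config$purity > 1) {
    stop_invalid("`purity` must lie in (0, 1]")
  }
  per_probe <- truth_per_probe(truth, probe_map)
  if (anyNA(per_probe$c_t)) {
    stop_invalid("`truth` does not tile `probe_map`")
  }
  seed <- seed %||% config$seed
  with_seed_or_current(seed, {
    n <- nrow(per_probe)
    rho <- config$purity
    u <- runif(n)
    genotype <- if_else(u < per_probe$population_het, "AB",
                        if_else(runif(n) < 0.5, "AA", "BB"))
    germ_b <- unname(c(AA = 0, AB = 0.5, BB = 1)[genotype])

    normal_cn <- pmax(1 + rnorm(n, 0, config$noise_sd_cn), 0)
    normal_baf <- pmin(pmax(germ_b + rnorm(n, 0, config$noise_sd_baf), 0), 1)

    tumor_expected <- (rho * per_probe$c_t + (1 - rho) * 2) / 2
    wave <- if (config$wave_amplitude > 0) {
      config$wave_amplitude * sin(2 * pi * per_probe$pos / config$wave_period_bp)
    } else 0
    tumor_cn <- pmax(tumor_expected + wave + rnorm(n, 0, config$noise_sd_cn), 0)

    # tumor BAF: random phase at heterozygous probes; homozygous probes keep
    # their germline pole (somatic events do not change a homozygous BAF
    # unless the remaining allele is lost, which the mixture still maps to
    # the same pole).
    b_eff <- if_else(runif(n) < 0.5, as.numeric(per_probe$b_t),
                     as.numeric(per_probe$c_t - per_probe$b_t))
    denom <- rho * per_probe$c_t + (1 - rho) * 2
    het_baf <- (rho * b_eff + (1 - rho) * 1) / denom
    hom_b <- (rho * if_else(germ_b == 0, 0, as.numeric(per_probe$c_t)) +
                (1 - rho) * 2 * germ_b) / denom
    tumor_mean_baf <- if_else(genotype == "AB", het_baf, hom_b)
    tumor_baf <- pmin(pmax(tumor_mean_baf + rnorm(n, 0, config$noise_sd_baf),
                           0), 1)

    raw <- function(cn) 2^(config$intensity_log2_mean + rnorm(n, 0, 0.4)) * cn
    per_probe %>%
      transmute(
        probe_id = .data$probe_id, chrom = .data$chrom, arm = .data$arm,
        pos = .data$pos, patient_id = patient_id,
        normal_cn_ratio = normal_cn, normal_baf = normal_baf,
        normal_raw = raw(normal_cn),
        tumor_cn_ratio = tumor_cn, tumor_baf = tumor_baf,
        tumor_raw = raw(tumor_cn),
        genotype = genotype,
        c_t = .data$c_t, b_t = .data$b_t, true_class = .data$true_class
      )
  })
}
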