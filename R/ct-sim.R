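#' Simulate a dynamic-array qPCR Ct plate
#'
#' Emits duplicate-well two-channel (A = VIC, B = FAM) Ct values for a panel
#' of SNP assays across a set of samples, from each sample's latent truth
#' profile. Per well, the number of template molecules for an allele is
#' `input_molecules` times the allele's copy number in the segment covering
#' the SNP, and `Ct = 26 - log2(molecules)` plus Gaussian noise, so one
#' molecule corresponds to Ct 26 and each doubling of input lowers Ct by one
#' cycle. Wells whose Ct exceeds 40 (including zero-molecule wells) are
#' emitted as missing with probability `dropout_prob`, otherwise recorded at
#' the detection limit of 40.
#'
#' @param truth_profiles Named list of truth profiles (one per sample), as
#'   returned by [simulate_truth_profile()].
#' @param snp_panel Tibble with columns `snp_id`, `chrom`, `idx` (0-based
#'   probe index within the chromosome) and `region`, e.g. from
#'   [select_validation_snps()].
#' @param input_molecules Template molecules per allele copy (> 0).
#' @param n_replicates Wells per sample x SNP x channel.
#' @param ct_noise_sd Gaussian Ct noise SD (cycles).
#' @param dropout_prob Probability a `Ct > 40` well is missing.
#' @param seed Optional integer seed.
#'
#' @return A long tibble: `sample_id`, `snp_id`, `region`, `replicate`,
#'   `channel` ("A"/"B"), `ct` (NA when missing).
#' @export
simulate_ct_plate <- function(truth_profiles, snp_panel, input_molecules = 8,
                              n_replicates = 2L, ct_noise_sd = 0.15,
                              dropout_prob = 0.5, seed = NULL) {
  if (nrow(snp_panel) == 0L) stop_invalid("`snp_panel` is empty")
  check_number(input_molecules, "input_molecules", min = 1e-12)
  if (is.null(names(truth_profiles)) || any(names(truth_profiles) == "")) {
    stop_invalid("`truth_profiles` must be a named list of truth tibbles")
  }
  with_seed_or_current(seed, {
    purrr::imap(truth_profiles, function(truth, sid) {
      seg <- snp_panel %>%
        dplyr::left_join(truth, by = dplyr::join_by("chrom", "idx" >= "start",
                                                    "idx" < "end"))
      if (anyNA(seg$c_t)) {
        stop_invalid(sprintf("panel SNPs not covered by truth profile of %s", sid))
      }
      # allele phase is random per sample x SNP: which parental allele the
      # A-channel assays is arbitrary, as on the array
      seg$a_copies <- if_else(runif(nrow(seg)) < 0.5,
                              seg$c_t - seg$b_t, seg$b_t)
      tidyr::expand_grid(
        seg %>% select("snp_id", "region", "c_t", "a_copies"),
        replicate = seq_len(n_replicates),
        channel = c("A", "B")
      ) %>%
        mutate(
          sample_id = sid,
          copies = if_else(.data$channel == "A",
                           .data$a_copies, .data$c_t - .data$a_copies),
          mol = input_molecules * .data$copies,
          ct = 26 - log2(pmax(.data$mol, .Machine$double.xmin)) +
            rnorm(n(), 0, ct_noise_sd),
          ct = if_else(.data$mol == 0, Inf, .data$ct),
          ct = if_else(.data$ct > 40,
                       if_else(runif(n()) < dropout_prob, NA_real_, 40),
                       .data$ct)
        ) %>%
        select("sample_id", "snp_id", "region", "replicate", "channel", "ct")
    }) %>% bind_rows()
  })
}
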