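#' Recovery metrics of the pipeline against simulated ground truth
#'
#' Compares segment calls with the latent truth retained by
#' [simulate_assay_pair()]: the fraction of probes assigned the true
#' copy-number state (loss / neutral / gain from the true total copies), and
#' the fraction of chromosomes assigned the true overall allelic status.
#' The true status is computed with the same definition the estimator uses —
#' the modal allelic class weighted by germline-heterozygous probes, ties to
#' the more aberrant class — so the metric isolates pipeline error from
#' ambiguity in near-tied chromosomes.
#'
#' @param segments Segment calls with `patient_id` (from
#'   [run_cohort_pipeline()] or [run_array_pipeline()]).
#' @param assays Named list of assay tibbles (with their truth columns), or
#'   one long tibble with `patient_id`.
#' @return A tibble with one row per patient: `patient_id`,
#'   `probe_cn_accuracy`, `chrom_class_accuracy`.
#' @export
recovery_metrics <- function(segments, assays) {
  if (is.data.frame(assays)) assays <- split(assays, assays$patient_id)
  purrr::imap(assays, function(a, pid) {
    seg <- segments %>%
      filter(.data$patient_id == pid) %>%
      arrange(.data$chrom, .data$start)
    a <- a %>% arrange(.data$chrom, .data$pos)
    true_state <- dplyr::case_when(a$c_t < 2 ~ "loss", a$c_t > 2 ~ "gain",
                                   TRUE ~ "neutral")
    called_state <- rep(seg$cn_state, seg$n_probes)
    het <- a$genotype == "AB"
    true_status <- a %>%
      mutate(het = het) %>%
      group_by(.data$chrom) %>%
      summarise(truth = modal_class(.data$true_class, as.numeric(.data$het)),
                .groups = "drop")
    called_status <- chromosome_status(seg)
    j <- dplyr::inner_join(true_status, called_status, by = "chrom")
    tibble(
      patient_id = pid,
      probe_cn_accuracy = mean(called_state == true_state),
      chrom_class_accuracy = mean(j$status == j$truth, na.rm = TRUE)
    )
  }) %>% bind_rows()
}
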