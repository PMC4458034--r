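#' Flag frequent alterations within one study
#'
#' A chromosome-arm alteration counts as frequent within a study when at
#' least `case_threshold` (default 25%) of the study's cases carry it; the
#' boundary is inclusive. Missing fractions (studies whose percentages could
#' not be extracted for an arm) yield NA flags.
#'
#' @param studies Long study table: `study_id`, `arm`, `gain_fraction`,
#'   `loss_fraction` (see [simulate_study_table()]).
#' @param case_threshold Fraction of cases required.
#' @param arms Allowed arm labels; unknown arms are an error.
#' @return Input with logical `gain_flag` and `loss_flag` columns.
#' @export
flag_frequent <- function(studies, case_threshold = 0.25,
                          arms = canonical_arms()) {
  unknown <- setdiff(unique(studies$arm), arms)
  if (length(unknown) > 0L) {
    stop_invalid(paste("unknown arm(s):", paste(unknown, collapse = ", ")))
  }
  studies %>%
    mutate(gain_flag = .data$gain_fraction >= case_threshold,
           loss_flag = .data$loss_fraction >= case_threshold)
}

#' Cross-study common-alteration summary
#'
#' The counting rule for "common alterations with high frequency": per arm
#' and direction, the fraction of studies reporting the alteration in at
#' least `case_threshold` (25%) of their cases is computed over the
#' site-filtered studies; an alteration is common when at least
#' `study_threshold` (40%) of studies flag it. Studies with a missing
#' fraction for an arm are excluded from that arm's denominator only.
#'
#' @param studies Long study table (see [flag_frequent()]).
#' @param site_filter Optional site label ("rectum", "colon", "colorectal");
#'   NULL keeps all studies.
#' @param study_threshold Fraction of studies required for a common call.
#' @param case_threshold Within-study case fraction (passed to
#'   [flag_frequent()]).
#' @return Tibble `arm`, `direction` ("gain"/"loss"), `n_studies`,
#'   `fraction`, `common`.
#' @export
common_alterations <- function(studies, site_filter = NULL,
                               study_threshold = 0.40,
                               case_threshold = 0.25) {
  if (!is.null(site_filter)) {
    studies <- studies %>% filter(.data$site == site_filter)
    if (nrow(studies) == 0L) {
      stop_invalid(sprintf("no studies left after site filter '%s'",
                           site_filter))
    }
  }
  flag_frequent(studies, case_threshold,
                arms = unique(c(canonical_arms(), studies$arm))) %>%
    select("study_id", "arm", "gain_flag", "loss_flag") %>%
    tidyr::pivot_longer(c("gain_flag", "loss_flag"),
                        names_to = "direction", values_to = "flag") %>%
    mutate(direction = sub("_flag$", "", .data$direction)) %>%
    filter(!is.na(.data$flag)) %>%
    group_by(.data$arm, .data$direction) %>%
    summarise(n_studies = n(), fraction = mean(.data$flag),
              .groups = "drop") %>%
    mutate(common = .data$fraction >= study_threshold)
}

#' Site contrast of common-alteration fractions
#'
#' Arms whose study fractions differ by strictly more than
#' `delta_threshold` (20%) between two site summaries, with the direction of
#' excess.
#'
#' @param summary_a,summary_b Summaries from [common_alterations()] over the
#'   same arms and directions (e.g. rectum and colon).
#' @param delta_threshold Minimum absolute difference (strict).
#' @param labels Length-2 labels naming the two summaries in the output.
#' @return Tibble `arm`, `direction`, `fraction_a`, `fraction_b`, `delta`,
#'   `excess` (which summary is higher).
#' @export
site_contrast <- function(summary_a, summary_b, delta_threshold = 0.20,
                          labels = c("rectum", "colon")) {
  joined <- summary_a %>%
    select("arm", "direction", fraction_a = "fraction") %>%
    dplyr::full_join(
      summary_b %>% select("arm", "direction", fraction_b = "fraction"),
      by = c("arm", "direction"))
  if (anyNA(joined$fraction_a) || anyNA(joined$fraction_b)) {
    stop_invalid("summaries cover different arm/direction sets")
  }
  joined %>%
    mutate(delta = .data$fraction_a - .data$fraction_b) %>%
    filter(abs(.data$delta) > delta_threshold) %>%
    mutate(excess = if_else(.data$delta > 0, labels[1], labels[2])) %>%
    arrange(.data$direction, .data$arm)
}
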