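#' Canonical chromosome-arm labels
#'
#' The 39 autosomal arms (acrocentric p arms 13p/14p/15p/21p/22p omitted).
#' @return Character vector of arm labels ("1p", "1q", ..., "22q").
#' @export
canonical_arms <- function() {
  acro <- c("13p", "14p", "15p", "21p", "22p")
  arms <- as.vector(t(outer(1:22, c("p", "q"), paste0)))
  setdiff(arms, acro)
}

#' Simulate a literature table of per-arm alteration frequencies
#'
#' Generates one record per published study: a case count and, per chromosome
#' arm, the fraction of that study's cases with a gain and with a loss, drawn
#' from Beta distributions. Feeds the cross-study counting rule in
#' [common_alterations()].
#'
#' @param n_studies Number of studies (>= 1).
#' @param arms Character vector of arm labels.
#' @param n_cases_range Integer range the per-study case count is drawn from.
#' @param gain_beta,loss_beta Length-2 shape parameters of the Beta
#'   distributions for gain and loss fractions.
#' @param site_probs Named probabilities for the study tissue site.
#' @param seed Optional integer seed.
#'
#' @return A long tibble: `study_id`, `n_cases`, `site`, `arm`,
#'   `gain_fraction`, `loss_fraction`.
#' @export
simulate_study_table <- function(n_studies,
                                 arms = canonical_arms(),
                                 n_cases_range = c(6L, 120L),
                                 gain_beta = c(1.2, 3.0),
                                 loss_beta = c(1.2, 3.5),
                                 site_probs = c(rectum = 0.45, colon = 0.25,
                                                colorectal = 0.30),
                                 seed = NULL) {
  check_number(n_studies, "n_studies", min = 1, integer = TRUE)
  if (length(arms) == 0L) stop_invalid("`arms` must be non-empty")
  with_seed_or_current(seed, {
    studies <- tibble(
      study_id = sprintf("study_%02d", seq_len(n_studies)),
      n_cases = sample(seq(n_cases_range[1], n_cases_range[2]), n_studies,
                       replace = TRUE),
      site = sample(names(site_probs), n_studies, TRUE, site_probs)
    )
    tidyr::expand_grid(studies, arm = arms) %>%
      mutate(
        gain_fraction = rbeta(n(), gain_beta[1], gain_beta[2]),
        loss_fraction = rbeta(n(), loss_beta[1], loss_beta[2])
      )
  })
}
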