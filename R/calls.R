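#' Call copy-number state and allelic class per segment
#'
#' Summarises each segment of a preprocessed assay and applies the calling
#' thresholds: copy-number state is `loss` when the segment mean ratio is
#' strictly below `config$loss_threshold` (0.92), `gain` strictly above
#' `config$gain_threshold` (1.08), otherwise `neutral` (a mean exactly at a
#' threshold is neutral). The allelic class comes from the mean mirrored BAF
#' over germline-heterozygous probes: 1 (retention) below
#' `mbaf_imbalance_cut`, 3 (LOH) at or above `mbaf_loh_cut`, 2 (imbalance)
#' between; segments with fewer than `min_het_per_segment` heterozygous
#' probes get NA (uninformative).
#'
#' @param assay Preprocessed per-probe tibble with columns `chrom`, `pos`,
#'   `cn_corrected`, `mbaf`, `het` (see [run_array_pipeline()]), ordered by
#'   chromosome and position.
#' @param breakpoints Tibble with columns `chrom` and `bp` (0-based
#'   half-open within-chromosome probe indices), e.g. from
#'   [segment_assay_pair()].
#' @param config A [calling_config()].
#'
#' @return A tibble of segment calls tiling every chromosome: `chrom`,
#'   `start`, `end` (0-based half-open probe indices), `start_bp`, `end_bp`,
#'   `n_probes`, `n_het`, `mean_cn_ratio`, `mean_mbaf`, `cn_state`,
#'   `allelic_class`.
#' @export
call_segments <- function(assay, breakpoints, config = calling_config()) {
  chrom_idx <- split(seq_len(nrow(assay)), assay$chrom)
  chrom_idx <- chrom_idx[order(as.integer(names(chrom_idx)))]
  bp_by_chrom <- split(breakpoints$bp, factor(breakpoints$chrom,
                                              levels = names(chrom_idx)))
  parts <- purrr::map(names(chrom_idx), function(ch) {
    rows <- chrom_idx[[ch]]
    n <- length(rows)
    if (n == 0L) {
      abort("segment with zero probes", class = c("recurcna_structural_error",
                                                  "recurcna_error"))
    }
    bp <- bp_by_chrom[[ch]]
    bounds <- sort(unique(c(0L, bp[bp > 0 & bp < n], n)))
    s <- head(bounds, -1L); e <- tail(bounds, -1L)
    seg_id <- findInterval(seq_len(n) - 1L, bounds, left.open = FALSE)
    mbaf <- assay$mbaf[rows]
    het <- assay$het[rows] & !is.na(mbaf)
    sums <- rowsum(cbind(het = as.numeric(het),
                         mbaf = ifelse(het, mbaf, 0),
                         cn = assay$cn_corrected[rows],
                         one = 1),
                   seg_id, reorder = TRUE)
    n_het <- as.integer(sums[, "het"])
    pos <- assay$pos[rows]
    list(chrom = rep(as.integer(ch), length(s)), start = s, end = e,
         start_bp = pos[s + 1L], end_bp = pos[e], n_het = n_het,
         mean_mbaf = unname(ifelse(n_het > 0, sums[, "mbaf"] / n_het,
                                   NA_real_)),
         mean_cn = unname(sums[, "cn"] / sums[, "one"]))
  })
  one <- function(f) unlist(purrr::map(parts, f), use.names = FALSE)
  mean_cn <- one("mean_cn"); n_het <- one("n_het")
  mean_mbaf <- one("mean_mbaf")
  s <- one("start"); e <- one("end")
  tibble(
    chrom = one("chrom"), start = s, end = e,
    start_bp = one("start_bp"), end_bp = one("end_bp"),
    n_probes = e - s, n_het = n_het,
    mean_cn_ratio = mean_cn, mean_mbaf = mean_mbaf,
    cn_state = dplyr::case_when(
      mean_cn < config$loss_threshold ~ "loss",
      mean_cn > config$gain_threshold ~ "gain",
      TRUE ~ "neutral"
    ),
    allelic_class = dplyr::case_when(
      n_het < config$min_het_per_segment ~ NA_integer_,
      mean_mbaf >= config$mbaf_loh_cut ~ 3L,
      mean_mbaf >= config$mbaf_imbalance_cut ~ 2L,
      TRUE ~ 1L
    )
  )
}

#' Segment both signals of a preprocessed assay
#'
#' Runs the permutation-tested binary segmentation ([segment_profile()]) on
#' the corrected copy-number ratio (all probes) and on the mirrored BAF
#' (heterozygous probes, breakpoints mapped back to full probe indices) of
#' every chromosome, and returns the union of the two breakpoint sets.
#'
#' @param assay Preprocessed per-probe tibble (see [call_segments()]).
#' @param config A [calling_config()].
#' @param seed Optional integer seed for the permutation tests.
#' @return Tibble with columns `chrom`, `bp`.
#' @export
segment_assay_pair <- function(assay, config = calling_config(), seed = NULL) {
  chrom_idx <- split(seq_len(nrow(assay)), assay$chrom)
  chrom_idx <- chrom_idx[order(as.integer(names(chrom_idx)))]
  with_seed_or_current(seed, {
    purrr::map(names(chrom_idx), function(ch) {
      rows <- chrom_idx[[ch]]
      cn <- assay$cn_corrected[rows]
      pos <- assay$pos[rows]
      mbaf <- assay$mbaf[rows]
      bp_cn <- segment_profile(cn, pos,
                               alpha = config$seg_alpha,
                               min_seg_probes = config$min_seg_probes,
                               n_perm = config$seg_n_perm)
      het_idx <- which(assay$het[rows] & !is.na(mbaf))
      bp_mb <- integer(0)
      if (length(het_idx) >= 2L * config$min_seg_probes) {
        bp_het <- segment_profile(mbaf[het_idx], pos[het_idx],
                                  alpha = config$seg_alpha,
                                  min_seg_probes = config$min_seg_probes,
                                  n_perm = config$seg_n_perm)
        # breakpoint before the b-th het probe -> before that probe overall
        bp_mb <- het_idx[bp_het + 1L] - 1L
      }
      bps <- sort(unique(c(bp_cn, bp_mb)))
      if (length(bps) == 0L) return(NULL)
      tibble(chrom = as.integer(ch), bp = as.integer(bps))
    }) %>% bind_rows() %>%
      (function(df) if (nrow(df) == 0) tibble(chrom = integer(), bp = integer())
       else df)
  })
}

#' Cohort gain/loss frequency profile
#'
#' For one analysis group, computes the fraction of patients altered at each
#' probe — gains from any gain segment, losses only from segments spanning at
#' least `config$loss_report_min_probes` probes (default 15, suppressing
#' unreliable small losses) — and summarises each chromosome arm by its
#' maximum probe frequency.
#'
#' @param cohort_calls Segment calls for several patients: a tibble as from
#'   [call_segments()] with added `patient_id` and `group` columns.
#' @param group Group label to profile ("C", "L", "D" or "LD").
#' @param probe_map The probe map the calls refer to.
#' @param config A [calling_config()].
#' @param level `"arm"` (default) for the per-arm summary, `"probe"` for the
#'   per-probe frequencies.
#'
#' @return At arm level: tibble `arm`, `gain_frequency`, `loss_frequency`,
#'   `n_patients`. At probe level: `probe_id`, `chrom`, `arm`, `pos`,
#'   `gain_frequency`, `loss_frequency`.
#' @export
frequency_profile <- function(cohort_calls, group, probe_map,
                              config = calling_config(),
                              level = c("arm", "probe")) {
  level <- match.arg(level)
  if (!group %in% c("C", "L", "D", "LD")) {
    stop_invalid("unknown group label")
  }
  calls <- cohort_calls %>% filter(.data$group == !!group)
  patients <- unique(calls$patient_id)
  if (length(patients) == 0L) {
    stop_invalid(sprintf("no patients with calls in group %s", group))
  }
  pm <- probe_map %>%
    group_by(.data$chrom) %>% mutate(.idx = row_number() - 1L) %>% ungroup()
  per_probe <- calls %>%
    mutate(loss_ok = .data$cn_state == "loss" &
             .data$n_probes >= config$loss_report_min_probes) %>%
    dplyr::inner_join(pm, by = dplyr::join_by("chrom", "start" <= ".idx",
                                              "end" > ".idx")) %>%
    group_by(.data$probe_id, .data$chrom, .data$arm, .data$pos) %>%
    summarise(
      gain_frequency = sum(.data$cn_state == "gain") / length(patients),
      loss_frequency = sum(.data$loss_ok) / length(patients),
      .groups = "drop"
    ) %>%
    arrange(.data$chrom, .data$pos)
  if (level == "probe") return(per_probe)
  per_probe %>%
    group_by(arm = paste0(.data$chrom, .data$arm)) %>%
    summarise(gain_frequency = max(.data$gain_frequency),
              loss_frequency = max(.data$loss_frequency),
              .groups = "drop") %>%
    mutate(n_patients = length(patients))
}
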