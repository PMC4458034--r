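#' Simulate a latent copy-number/allelic truth profile
#'
#' Draws the true segmental genome of one tumor: per segment a total copy
#' number `c_t` and a B-allele copy number `b_t` (`0 <= b_t <= c_t`).
#' Chromosome 7 and chromosome 13 states follow the group-specific priors in
#' `config` (balanced diploid retention, imbalanced gain 3/1, or LOH —
#' copy-neutral 2/0 on chromosome 7, hemizygous deletion 1/0 on 13); other
#' arms receive whole-arm gains/losses at the background rates plus optional
#' focal events of 30-80 probes. With all priors and rates zero the genome is
#' balanced diploid (2/1) everywhere.
#'
#' @param group Recurrence group label: "C", "L", "D" or "LD".
#' @param probe_map A probe map from [build_probe_map()].
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#'
#' @return A tibble of segments tiling every chromosome of `probe_map`:
#'   `chrom`, `start`, `end` (0-based half-open probe indices within the
#'   chromosome), `c_t`, `b_t`, and `true_class` (1 retention, 2 imbalance,
#'   3 LOH) derived from the allele counts.
#' @export
simulate_truth_profile <- function(group, probe_map, config = sim_config(),
                                   seed = NULL) {
  if (!is.character(group) || length(group) != 1L ||
      !group %in% c("C", "L", "D", "LD")) {
    stop_invalid("`group` must be one of C, L, D, LD")
  }
  seed <- seed %||% config$seed
  with_seed_or_current(seed, {
    chrom_tabs <- probe_map %>% count(.data$chrom, .data$arm)
    segs <- purrr::map(unique(chrom_tabs$chrom), function(ch) {
      arms <- chrom_tabs %>% filter(.data$chrom == ch)
      n_ch <- sum(arms$n)
      if (ch == 7L) {
        state <- draw_chrom_state(config$p_chr7_imbalance[[group]],
                                  config$p_chr7_loh[[group]],
                                  loh_state = c(2L, 0L))
        return(tibble(chrom = ch, start = 0L, end = n_ch,
                      c_t = state[1], b_t = state[2]))
      }
      if (ch == 13L) {
        state <- draw_chrom_state(config$p_chr13_imbalance[[group]],
                                  config$p_chr13_loh[[group]],
                                  loh_state = c(1L, 0L))
        return(tibble(chrom = ch, start = 0L, end = n_ch,
                      c_t = state[1], b_t = state[2]))
      }
      # background arms: whole-arm events, then an optional focal event
      purrr::map(seq_len(nrow(arms)), function(a) {
        n_arm <- arms$n[a]
        lo <- sum(arms$n[seq_len(a - 1L)])
        u <- runif(1)
        if (u < config$background_gain_rate) {
          st <- c(3L, 1L)
        } else if (u < config$background_gain_rate + config$background_loss_rate) {
          st <- c(1L, 0L)
        } else {
          st <- c(2L, 1L)
        }
        out <- tibble(chrom = ch, start = lo, end = lo + n_arm,
                      c_t = st[1], b_t = st[2])
        if (all(st == c(2L, 1L)) && runif(1) < config$focal_rate &&
            n_arm >= 30L) {
          len <- sample(30:min(80L, n_arm), 1L)
          fs <- lo + sample.int(n_arm - len + 1L, 1L) - 1L
          fst <- switch(sample(3L, 1L),
                        c(3L, 1L), c(1L, 0L), c(2L, 0L))
          out <- tibble(
            chrom = ch,
            start = c(lo, fs, fs + len),
            end = c(fs, fs + len, lo + n_arm),
            c_t = c(2L, fst[1], 2L),
            b_t = c(1L, fst[2], 1L)
          ) %>% filter(.data$end > .data$start)
        }
        out
      }) %>% bind_rows()
    }) %>% bind_rows()
    segs %>%
      mutate(start = as.integer(.data$start), end = as.integer(.data$end),
             true_class = allelic_class_of(.data$c_t, .data$b_t))
  })
}

draw_chrom_state <- function(p_imb, p_loh, loh_state) {
  u <- runif(1)
  if (u < p_imb) c(3L, 1L)
  else if (u < p_imb + p_loh) loh_state
  else c(2L, 1L)
}

#' True allelic class of an allele-specific copy-number state
#'
#' Class 1 (retention) when the two allele counts are equal, 3 (LOH) when one
#' allele is absent, 2 (imbalance) otherwise.
#'
#' @param c_t Total copies (non-negative integer vector).
#' @param b_t B-allele copies, `0 <= b_t <= c_t`.
#' @return Integer vector of classes in `{1, 2, 3}`.
#' @export
allelic_class_of <- function(c_t, b_t) {
  if (any(b_t < 0 | b_t > c_t)) stop_invalid("need 0 <= b_t <= c_t")
  dplyr::case_when(
    c_t > 0 & (b_t == 0 | b_t == c_t) ~ 3L,
    2L * b_t == c_t ~ 1L,
    TRUE ~ 2L
  )
}

# Expand a truth profile to per-probe vectors aligned with probe_map.
# Relies on segments tiling each chromosome in order, which lets the
# expansion be a straight rep() instead of an interval join.
truth_per_probe <- function(truth, probe_map) {
  truth <- truth %>% arrange(.data$chrom, .data$start)
  sizes <- table(probe_map$chrom)
  by_chrom <- split(truth, truth$chrom)
  ok <- all(names(by_chrom) %in% names(sizes)) &&
    all(vapply(names(by_chrom), function(ch) {
      seg <- by_chrom[[ch]]
      seg$start[1] == 0L && all(seg$start[-1] == head(seg$end, -1)) &&
        seg$end[nrow(seg)] == sizes[[ch]]
    }, logical(1)))
  if (!ok || length(by_chrom) != length(sizes)) {
    # fall back to the general interval join for partial/unsorted truths
    return(probe_map %>%
      group_by(.data$chrom) %>%
      mutate(.idx0 = row_number() - 1L) %>%
      ungroup() %>%
      dplyr::left_join(truth, by = dplyr::join_by("chrom", ".idx0" >= "start",
                                                  ".idx0" < "end")) %>%
      select(-".idx0"))
  }
  reps <- truth$end - truth$start
  bind_cols(
    probe_map %>% arrange(.data$chrom, .data$pos),
    truth[rep(seq_len(nrow(truth)), reps),
          c("start", "end", "c_t", "b_t", "true_class")]
  )
}
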