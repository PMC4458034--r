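# ggplot2 displays of the main result types.

#' Plot a cohort gain/loss frequency profile
#'
#' Per-probe fraction of patients with gains (up) and losses (down) along
#' the genome, faceted by chromosome.
#'
#' @param probe_frequencies Probe-level output of
#'   [frequency_profile()]`(..., level = "probe")`.
#' @return A ggplot object.
#' @export
plot_frequency_profile <- function(probe_frequencies) {
  df <- probe_frequencies %>%
    mutate(loss_down = -.data$loss_frequency)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos)) +
    ggplot2::geom_area(ggplot2::aes(y = .data$gain_frequency),
                       fill = "firebrick", alpha = 0.7) +
    ggplot2::geom_area(ggplot2::aes(y = .data$loss_down),
                       fill = "steelblue", alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::scale_y_continuous(limits = c(-1, 1),
                                labels = function(v) abs(v)) +
    ggplot2::labs(x = NULL, y = "fraction of patients (gain up, loss down)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(0.1, "lines"))
}

#' Plot one patient's processed copy-number and mBAF profile
#'
#' Corrected copy-number ratio and mirrored BAF along the genome with the
#' called segment means overlaid.
#'
#' @param x A `recurcna_pipeline` result.
#' @param chromosomes Optional subset of chromosomes to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.recurcna_pipeline <- function(x, chromosomes = NULL, ...) {
  a <- x$assay
  s <- x$segments
  if (!is.null(chromosomes)) {
    a <- a %>% filter(.data$chrom %in% chromosomes)
    s <- s %>% filter(.data$chrom %in% chromosomes)
  }
  long <- bind_rows(
    a %>% transmute(.data$chrom, .data$pos, value = .data$cn_corrected,
                    signal = "CN ratio"),
    a %>% filter(.data$het) %>%
      transmute(.data$chrom, .data$pos, value = .data$mbaf, signal = "mBAF")
  )
  seg_long <- bind_rows(
    s %>% transmute(.data$chrom, .data$start_bp, .data$end_bp,
                    value = .data$mean_cn_ratio, signal = "CN ratio"),
    s %>% transmute(.data$chrom, .data$start_bp, .data$end_bp,
                    value = .data$mean_mbaf, signal = "mBAF")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4, colour = "grey40") +
    ggplot2::geom_segment(
      data = seg_long,
      ggplot2::aes(x = .data$start_bp, xend = .data$end_bp,
                   y = .data$value, yend = .data$value),
      colour = "firebrick", linewidth = 0.8) +
    ggplot2::facet_grid(signal ~ chrom, scales = "free",
                        space = "free_x") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = x$qc$patient_id) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot chromosome-status composition per group
#'
#' Stacked proportions of retention / imbalance / LOH status per recurrence
#' group for one chromosome.
#'
#' @param statuses Output of [chromosome_status()].
#' @param cohort Cohort tibble with `patient_id` and `group`.
#' @param chromosome Chromosome to display.
#' @return A ggplot object.
#' @export
plot_status_composition <- function(statuses, cohort, chromosome = 7L) {
  df <- statuses %>%
    filter(.data$chrom == chromosome, !is.na(.data$status)) %>%
    dplyr::inner_join(cohort %>% select("patient_id", "group"),
                      by = "patient_id") %>%
    mutate(status = factor(.data$status, 1:3,
                           c("retention", "imbalance", "LOH")),
           group = factor(.data$group, c("C", "L", "D", "LD")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, fill = .data$status)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::scale_fill_manual(values = c(retention = "#4daf4a",
                                          imbalance = "#ff7f00",
                                          LOH = "#e41a1c")) +
    ggplot2::labs(x = NULL, y = "fraction of patients",
                  title = sprintf("Chromosome %s overall status", chromosome),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
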