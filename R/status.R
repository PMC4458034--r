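#' Overall chromosome status per patient
#'
#' The overall status of a chromosome is the most abundant allelic class
#' (1 = balanced/retention, 2 = imbalanced, 3 = LOH) over the chromosome,
#' weighted by the configured abundance measure (heterozygous probe count by
#' default). Ties resolve to the larger class number (the more aberrant
#' state). Chromosomes whose segments all lack a class get NA.
#'
#' @param segments Segment calls (any number of patients/chromosomes) with
#'   columns `patient_id`, `chrom`, `allelic_class` and the abundance
#'   column.
#' @param abundance_measure Column used as segment weight: `"n_het"`
#'   (default) or `"n_probes"`.
#' @return Tibble `patient_id`, `chrom`, `status` (integer 1/2/3 or NA).
#' @export
chromosome_status <- function(segments, abundance_measure = c("n_het",
                                                              "n_probes")) {
  abundance_measure <- match.arg(abundance_measure)
  segments %>%
    group_by(.data$patient_id, .data$chrom) %>%
    summarise(status = modal_class(.data$allelic_class,
                                   .data[[abundance_measure]]),
              .groups = "drop")
}

modal_class <- function(class, weight) {
  ok <- !is.na(class)
  if (!any(ok)) return(NA_integer_)
  w <- tapply(weight[ok], factor(class[ok], levels = 1:3), sum)
  w[is.na(w)] <- 0
  # which.max picks the first maximum; reverse so ties go to the higher class
  as.integer(4L - which.max(rev(w)))
}

#' Combine overall chromosome statuses
#'
#' For chromosome-combination analyses the combined status is the highest
#' status number of the inputs; NA propagates.
#'
#' @param status_a,status_b Integer statuses in `{1, 2, 3}` (vectorized).
#' @return Integer vector `pmax(status_a, status_b)`.
#' @export
combine_status <- function(status_a, status_b) {
  ok <- function(s) all(s %in% c(1:3, NA))
  if (!ok(status_a) || !ok(status_b)) {
    stop_invalid("statuses must be 1, 2, 3 or NA")
  }
  as.integer(pmax(status_a, status_b))
}

#' Exact Fisher test for an r x c contingency table
#'
#' Full enumeration of all tables sharing the observed margins; the p-value
#' is the total multivariate-hypergeometric probability of tables no more
#' probable than the observed one (with a relative tolerance of 1e-7 on the
#' comparison). Exact and deterministic; intended for the small tables of
#' chromosome-status group comparisons.
#'
#' @param contingency_table Matrix (or table) of non-negative integer counts
#'   with at least 2 rows and 2 columns.
#' @return Exact two-sided p-value.
#' @export
#' @examples
#' fisher_rxc(rbind(c(2, 0), c(0, 2)))  # 1/3
fisher_rxc <- function(contingency_table) {
  x <- as.matrix(contingency_table)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop_invalid("counts must be non-negative integers")
  }
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop_invalid("table must have at least 2 rows and 2 columns")
  }
  n <- sum(x)
  if (n == 0) {
    abort("table total is zero; test undefined",
          class = c("recurcna_undefined_test", "recurcna_error"))
  }
  rs <- rowSums(x); cs <- colSums(x)
  lf <- lgamma(seq_len(n + 1))  # lf[k+1] = log(k!)
  lconst <- sum(lf[rs + 1]) + sum(lf[cs + 1]) - lf[n + 1]
  log_prob <- function(tab) lconst - sum(lf[tab + 1])
  lp_obs <- log_prob(x)
  thresh <- lp_obs + log1p(1e-7)
  total <- 0
  r <- length(rs); cc <- length(cs)
  # depth-first enumeration, filling row by row; the last row is implied
  recurse <- function(row_idx, col_rem) {
    if (row_idx == r) {
      tab_rows[[row_idx]] <<- col_rem
      lp <- lconst - sum(lf[unlist(tab_rows) + 1])
      if (lp <= thresh) total <<- total + exp(lp)
      return(invisible())
    }
    fill_row(row_idx, 1L, integer(cc), rs[row_idx], col_rem)
  }
  tab_rows <- vector("list", r)
  fill_row <- function(row_idx, j, row_acc, rem, col_rem) {
    if (j == cc) {
      if (rem > col_rem[j]) return(invisible())
      row_acc[j] <- rem
      tab_rows[[row_idx]] <<- row_acc
      recurse(row_idx + 1L, col_rem - row_acc)
      return(invisible())
    }
    lo <- max(0L, rem - sum(col_rem[(j + 1L):cc]))
    hi <- min(rem, col_rem[j])
    if (lo > hi) return(invisible())
    for (v in lo:hi) {
      row_acc[j] <- v
      fill_row(row_idx, j + 1L, row_acc, rem - v, col_rem)
    }
  }
  recurse(1L, cs)
  min(total, 1)
}

#' Chromosome-status group comparison
#'
#' Builds the 2 x 3 contingency table of overall chromosome status (columns
#' 1/2/3) for the two groups of a comparison and tests it with
#' [fisher_rxc()]. Patients without a status are excluded with a message.
#'
#' @param statuses Tibble `patient_id`, `status` (e.g. one chromosome from
#'   [chromosome_status()], possibly combined with [combine_status()]).
#' @param cohort Cohort tibble with `patient_id` and `group`.
#' @param comparison `"L-vs-C"`, `"D-vs-C"` or `"LD-vs-C"`.
#' @return A list with `table` (2 x 3 matrix, rows = recurrence group then
#'   control) and `p_value`.
#' @export
status_group_test <- function(statuses, cohort,
                              comparison = c("L-vs-C", "D-vs-C", "LD-vs-C")) {
  comparison <- match.arg(comparison)
  grp <- sub("-vs-C$", "", comparison)
  dat <- statuses %>%
    dplyr::inner_join(cohort %>% select("patient_id", "group"),
                      by = "patient_id") %>%
    filter(.data$group %in% c(grp, "C"))
  if (!all(c(grp, "C") %in% dat$group)) {
    stop_invalid(sprintf("empty group in comparison %s", comparison))
  }
  dropped <- dat %>% filter(is.na(.data$status))
  if (nrow(dropped) > 0L) {
    rlang::inform(sprintf(
      "excluding %d patient(s) without an overall chromosome status: %s",
      nrow(dropped), paste(dropped$patient_id, collapse = ", ")))
    dat <- dat %>% filter(!is.na(.data$status))
  }
  tab <- matrix(0L, 2L, 3L,
                dimnames = list(c(grp, "C"), c("retention", "imbalance",
                                               "loh")))
  counts <- dat %>% count(.data$group, .data$status)
  for (i in seq_len(nrow(counts))) {
    tab[counts$group[i], counts$status[i]] <- counts$n[i]
  }
  list(table = tab, p_value = fisher_rxc(tab))
}
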