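#' Permutation score test for joint group association of a feature set
#'
#' Tests whether a set of features (rows) is jointly associated with a binary
#' group label. Features are row-standardized (zero-variance rows dropped);
#' the statistic is the mean squared score
#' \deqn{Q = \frac{1}{m}\sum_j (z_j^\top \tilde y)^2,}
#' where \eqn{\tilde y} is the centred label vector. Significance comes from
#' a label-permutation null: `p = (1 + #\{Q_perm >= Q\}) / (1 + n_perm)`.
#' When every feature is constant the statistic is 0 by convention
#' (uncentred scores of constant features are orthogonal to \eqn{\tilde y})
#' and p is 1.
#'
#' @param feature_matrix Numeric matrix, features in rows, samples in
#'   columns.
#' @param binary_labels Vector with exactly two distinct values (or 0/1
#'   numeric).
#' @param n_permutations Label permutations.
#' @param seed Optional integer seed.
#'
#' @return One-row tibble: `statistic`, `p_value`, `m` (features used), `n`
#'   (samples), `n_permutations`.
#' @export
global_test <- function(feature_matrix, binary_labels,
                        n_permutations = 1000L, seed = NULL) {
  x <- as.matrix(feature_matrix)
  n <- ncol(x)
  if (length(binary_labels) != n) {
    stop_invalid("`binary_labels` must have one entry per sample (column)")
  }
  lev <- unique(binary_labels)
  if (length(lev) != 2L) {
    stop_invalid("`binary_labels` must contain exactly two classes")
  }
  if (nrow(x) == 0L) {
    abort("no features to test", class = c("recurcna_undefined_test",
                                           "recurcna_error"))
  }
  y <- as.numeric(binary_labels == lev[2])
  yt <- y - mean(y)
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, sd)
  keep <- sdv > 0
  if (!any(keep)) {
    return(tibble(statistic = 0, p_value = 1, m = nrow(x), n = n,
                  n_permutations = as.integer(n_permutations)))
  }
  z <- (x[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  m <- nrow(z)
  q_obs <- mean((z %*% yt)^2)
  with_seed_or_current(seed, {
    perm <- vapply(seq_len(n_permutations), function(i) sample(yt),
                   numeric(n))
    q_perm <- colMeans((z %*% perm)^2)
    p <- (1 + sum(q_perm >= q_obs - 1e-12)) / (1 + n_permutations)
    tibble(statistic = q_obs, p_value = p, m = m, n = n,
           n_permutations = as.integer(n_permutations))
  })
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment:
#' `adjusted_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and
#' order-preserving.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop_invalid("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Build a probes-by-patients feature matrix from segment calls
#'
#' Expands per-segment calls to per-probe features aligned to the probe map:
#' `"allelic"` gives the integer allelic class code (1/2/3) of the covering
#' segment (uninformative segments coded 1, no evidence of aberration);
#' `"cn"` gives the covering segment's mean copy-number ratio.
#'
#' @param segments Segment calls for several patients (with `patient_id`).
#' @param probe_map The probe map the calls refer to.
#' @param what `"allelic"` or `"cn"`.
#' @return A numeric matrix (probes x patients) with `chrom`/`arm` probe
#'   metadata attached as attribute `probe_info`.
#' @export
build_feature_matrix <- function(segments, probe_map,
                                 what = c("allelic", "cn")) {
  what <- match.arg(what)
  pm <- probe_map %>% arrange(.data$chrom, .data$pos)
  segments <- segments %>% arrange(.data$chrom, .data$start)
  by_patient <- split(seq_len(nrow(segments)), segments$patient_id)
  pids <- names(by_patient)
  value <- if (what == "allelic") {
    as.numeric(dplyr::coalesce(segments$allelic_class, 1L))
  } else {
    segments$mean_cn_ratio
  }
  cols <- purrr::map(by_patient, function(rows) {
    v <- rep(value[rows], segments$n_probes[rows])
    if (length(v) != nrow(pm)) {
      stop_invalid(sprintf("segments of %s do not tile the probe map",
                           segments$patient_id[rows[1]]))
    }
    v
  })
  mat <- do.call(cbind, cols)
  dimnames(mat) <- list(pm$probe_id, pids)
  attr(mat, "probe_info") <- pm %>%
    transmute(probe_id = .data$probe_id, chrom = .data$chrom,
              arm = paste0(.data$chrom, .data$arm))
  mat
}

#' Hierarchical genome / arm / region association testing
#'
#' The gated hierarchy: genome-wide [global_test()]s first; only if the
#' genome level is significant at `alpha` are the individual chromosome arms
#' tested (one BH family across arms); for arms significant after
#' adjustment, the underlying regions — consecutive windows of
#' `config$region_probes` probes — are tested (one BH family across all
#' regions of all accepted arms).
#'
#' With `gate = "either"` (the default, matching the published protocol of
#' proceeding when the overall copy-number *or* allelic-ratio test is
#' significant) the genome level comprises both data types and the gate
#' opens when either p-value is below `alpha`; arm and region tests still
#' use the `data` type requested. With `gate = "same"` only the requested
#' data type's genome test gates.
#'
#' @param segments Cohort segment calls (with `patient_id`).
#' @param cohort Cohort tibble with `patient_id` and `group`.
#' @param probe_map The probe map.
#' @param comparison One of `"L-vs-C"`, `"D-vs-C"`, `"LD-vs-C"`.
#' @param data `"allelic"` (per-probe class codes) or `"cn"` (per-probe
#'   copy-number ratios).
#' @param alpha Gate level applied to the genome p-value and to adjusted
#'   p-values at the lower levels.
#' @param n_permutations Permutations for the genome-level gate tests.
#' @param n_permutations_followup Permutations for the arm and region tests,
#'   where the Benjamini-Hochberg adjustment needs finer p-value resolution
#'   than the 0.05 gate; defaults to 10000.
#' @param seed Optional integer seed (per-scope seeds are derived from it).
#' @param config A [calling_config()].
#'
#' @return Tibble of test results: `level` ("genome"/"arm"/"region"),
#'   `scope`, `comparison`, `data`, `statistic`, `p_value`, `p_adjusted`,
#'   `n_permutations`. Lower levels are absent when their gate fails.
#' @export
hierarchical_test <- function(segments, cohort, probe_map,
                              comparison = c("L-vs-C", "D-vs-C", "LD-vs-C"),
                              data = c("allelic", "cn"),
                              gate = c("either", "same"),
                              alpha = 0.05, n_permutations = 1000L,
                              n_permutations_followup = 10000L,
                              seed = NULL, config = calling_config()) {
  comparison <- match.arg(comparison)
  data <- match.arg(data)
  gate <- match.arg(gate)
  grp <- sub("-vs-C$", "", comparison)
  keep <- cohort %>% filter(.data$group %in% c(grp, "C"))
  if (length(unique(keep$group)) < 2L) {
    stop_invalid(sprintf("both groups of %s must be present", comparison))
  }
  gate_types <- if (gate == "either") c("allelic", "cn") else data
  mats <- purrr::map(
    stats::setNames(unique(c(data, gate_types)), unique(c(data, gate_types))),
    function(w) build_feature_matrix(segments, probe_map, what = w))
  info <- attr(mats[[data]], "probe_info")  # subsetting drops attributes
  mats <- purrr::map(mats, function(m) {
    m[, colnames(m) %in% keep$patient_id, drop = FALSE]
  })
  mat <- mats[[data]]
  labels <- keep$group[match(colnames(mat), keep$patient_id)] == grp

  res_row <- function(level, scope, gt, p_adj = NA_real_, dat = data) {
    tibble(level = level, scope = scope, comparison = comparison,
           data = dat, statistic = gt$statistic, p_value = gt$p_value,
           p_adjusted = p_adj, n_permutations = gt$n_permutations)
  }
  genome <- purrr::map(gate_types, function(w) {
    global_test(mats[[w]], labels, n_permutations,
                seed = child_seed(seed, paste0("genome_", w)))
  })
  out <- purrr::map2(genome, gate_types, function(g, w) {
    res_row("genome", "genome", g, g$p_value, dat = w)
  }) %>% bind_rows()
  if (all(purrr::map_dbl(genome, "p_value") >= alpha)) return(out)

  arms <- unique(info$arm)
  arm_res <- purrr::map(arms, function(a) {
    idx <- which(info$arm == a)
    gt <- global_test(mat[idx, , drop = FALSE], labels,
                      n_permutations_followup,
                      seed = child_seed(seed, paste0("arm_", a)))
    res_row("arm", a, gt)
  }) %>% bind_rows() %>%
    mutate(p_adjusted = bh_adjust(.data$p_value))
  out <- bind_rows(out, arm_res)
  sig_arms <- arm_res$scope[arm_res$p_adjusted < config$gate_alpha]
  if (length(sig_arms) == 0L) return(out)

  region_res <- purrr::map(sig_arms, function(a) {
    idx <- which(info$arm == a)
    windows <- split(idx, (seq_along(idx) - 1L) %/% config$region_probes)
    purrr::imap(windows, function(w, wi) {
      gt <- global_test(mat[w, , drop = FALSE], labels,
                        n_permutations_followup,
                        seed = child_seed(seed, paste0("region_", a, "_", wi)))
      res_row("region", sprintf("%s:%s-%s", a, min(w), max(w)), gt)
    }) %>% bind_rows()
  }) %>% bind_rows() %>%
    mutate(p_adjusted = bh_adjust(.data$p_value))
  bind_rows(out, region_res)
}
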