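#' Normalize copy-number ratios to the sample mean
#'
#' Divides by the mean of the non-missing values so the genome-wide mean is
#' exactly 1 — the reference against which the loss/gain thresholds are
#' defined. Idempotent.
#'
#' @param cn_ratios Numeric vector with at least one finite positive value.
#' @return Numeric vector of the same length, mean 1 over non-missing values.
#' @export
normalize_to_sample_mean <- function(cn_ratios) {
  m <- mean(cn_ratios, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) {
    stop_invalid("`cn_ratios` needs at least one finite positive value")
  }
  cn_ratios / m
}

#' Remove long-range genomic waves from a copy-number profile
#'
#' Estimates and subtracts the smooth genomic wave artifact per chromosome
#' while preserving true copy-number segments. Each pass (i) finds candidate
#' changepoints with the permutation-tested binary segmentation, (ii) merges
#' adjacent segments whose mean difference is below `min_jump` — level
#' changes that small are indistinguishable from wave artifact, so only
#' segment edges too large to be wave are protected — and (iii) fits a local
#' regression (span `span/10`) to the level-subtracted residual and
#' subtracts it. Two passes recover the wave fraction initially absorbed by
#' the level. The result is re-normalized to mean 1. Chromosomes with fewer
#' than 10 probes are left uncorrected with a warning.
#'
#' @param cn_ratios Numeric vector of (normalized) copy-number ratios.
#' @param positions Base-pair positions, sorted within each chromosome.
#' @param chrom Chromosome label per probe (a single chromosome when
#'   omitted).
#' @param span Smoothing scale of the wave fit, as a fraction of the
#'   chromosome's probes (the local-regression span is `span/10`).
#' @param min_jump Minimum between-segment mean difference treated as a real
#'   copy-number edge rather than wave (default 0.18: above twice a typical
#'   wave amplitude, below any arm-level event at default purity).
#' @param passes Level/wave refinement passes.
#' @return Corrected ratios, same length, re-normalized to mean 1.
#' @export
dewave <- function(cn_ratios, positions, chrom = NULL, span = 0.5,
                   min_jump = 0.18, passes = 2L) {
  if (is.null(chrom)) chrom <- rep(1L, length(cn_ratios))
  stopifnot(length(positions) == length(cn_ratios),
            length(chrom) == length(cn_ratios))
  out <- cn_ratios
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (is.unsorted(positions[idx])) {
      stop_invalid(sprintf("positions not sorted on chromosome %s", ch),
                   class = "recurcna_invalid_input")
    }
    ok <- idx[!is.na(cn_ratios[idx])]
    if (length(ok) < 10L) {
      warn(sprintf("chromosome %s has < 10 probes; de-waving skipped", ch))
      next
    }
    x <- cn_ratios[ok]
    pos <- positions[ok]
    n <- length(x)
    for (pass in seq_len(passes)) {
      level <- step_level(x, pos, min_jump)
      fit <- lowess(pos, x - level, f = span / 10, iter = 2L)
      trend <- stats::approx(fit$x, fit$y, xout = pos, rule = 2)$y
      x <- x - trend
    }
    out[ok] <- x
  }
  normalize_to_sample_mean(out)
}

# Piecewise-constant level whose edges are changepoints with a mean jump of
# at least `min_jump`; smaller candidate edges are merged away so smooth
# waves cannot masquerade as segment structure.
step_level <- function(x, pos, min_jump) {
  n <- length(x)
  bp <- segment_profile(x, pos, alpha = 0.02, min_seg_probes = 15L,
                        n_perm = 50L, seed = 1L)
  bounds <- c(0L, bp, n)
  repeat {
    s <- head(bounds, -1L); e <- tail(bounds, -1L)
    if (length(s) < 2L) break
    mns <- purrr::map2_dbl(s, e, function(a, b) mean(x[(a + 1):b]))
    d <- abs(diff(mns))
    j <- which.min(d)
    if (d[j] >= min_jump) break
    bounds <- bounds[-(j + 1L)]
  }
  s <- head(bounds, -1L); e <- tail(bounds, -1L)
  unlist(purrr::map2(s, e, function(a, b) rep(mean(x[(a + 1):b]), b - a)))
}

#' Mirrored B-allele fraction
#'
#' Folds the BAF of heterozygous probes about 0.5: `mbaf = |baf - 0.5| + 0.5`,
#' making allelic deviation sign-free (0.5 = balanced, 1 = complete loss of
#' one allele). Probes outside `het_mask` get NA: homozygous probes carry no
#' allelic-ratio information.
#'
#' @param baf Numeric vector in \[0, 1\].
#' @param het_mask Logical vector marking germline-heterozygous (normal AB)
#'   probes.
#' @return Numeric vector in \[0.5, 1\] at het probes, NA elsewhere.
#' @export
mirrored_baf <- function(baf, het_mask) {
  stopifnot(length(baf) == length(het_mask))
  out <- rep(NA_real_, length(baf))
  out[het_mask] <- abs(baf[het_mask] - 0.5) + 0.5
  out
}
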