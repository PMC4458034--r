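#' Segment a genomic signal by permutation-tested recursive binary splitting
#'
#' Recursively splits a per-probe signal (copy-number ratio or mirrored BAF)
#' at the position maximizing the two-sample t-statistic of the flanking
#' means; a split is accepted when its permutation p-value (max-|t| null over
#' within-segment permutations) is below `alpha` and both children hold at
#' least `min_seg_probes` probes.
#'
#' @param values Numeric vector without NAs (subset to informative probes
#'   first).
#' @param positions Sorted numeric positions aligned with `values` (used only
#'   to validate ordering; the statistic is index-based).
#' @param alpha Significance level for accepting a split.
#' @param min_seg_probes Minimum probes per resulting segment.
#' @param n_perm Permutations per split test.
#' @param seed Optional integer seed for the permutation null.
#'
#' @return Sorted integer vector of 0-based half-open breakpoints: value `b`
#'   separates probes `[.., b)` and `[b, ..)`. Empty when no split is
#'   accepted.
#' @export
segment_profile <- function(values, positions = seq_along(values),
                            alpha = 0.01, min_seg_probes = 5L,
                            n_perm = 100L, seed = NULL) {
  if (anyNA(values)) stop_invalid("`values` must not contain NA")
  if (length(positions) != length(values)) {
    stop_invalid("`positions` must align with `values`")
  }
  if (is.unsorted(positions)) {
    stop_invalid("`positions` must be sorted", class = "recurcna_invalid_input")
  }
  min_seg_probes <- as.integer(min_seg_probes)
  with_seed_or_current(seed, {
    bps <- integer(0)
    stack <- list(c(0L, length(values)))  # half-open [lo, hi)
    while (length(stack) > 0L) {
      seg <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      lo <- seg[1]; hi <- seg[2]
      n <- hi - lo
      if (n < 2L * min_seg_probes) next
      v <- values[(lo + 1L):hi]
      obs <- max_split_t(v, min_seg_probes)
      if (is.na(obs$t)) next
      # sequential permutation batches: stop as soon as enough exceedances
      # accumulate to make p < alpha unreachable
      stop_count <- alpha * (1 + n_perm) - 1
      cnt <- 0L; done <- 0L
      while (done < n_perm) {
        b <- min(if (done == 0L) 10L else 30L, n_perm - done)
        perm_max <- perm_max_t(v, min_seg_probes, b)
        cnt <- cnt + sum(perm_max >= obs$t - 1e-12)
        done <- done + b
        if (cnt > stop_count) break
      }
      p <- if (cnt > stop_count) 1 else (1 + cnt) / (1 + n_perm)
      if (p < alpha) {
        b <- lo + obs$k
        bps <- c(bps, b)
        stack <- c(stack, list(c(lo, b)), list(c(b, hi)))
      }
    }
    sort(bps)
  })
}

# Max |t| over allowed splits of v; returns the split (left size k) as well.
# Split t-statistics for all allowed left sizes, vectorized.
split_t_stats <- function(v, min_seg) {
  n <- length(v)
  ks <- seq.int(min_seg, n - min_seg)
  S <- cumsum(v); S2 <- cumsum(v * v)
  tot <- S[n]; tot2 <- S2[n]
  ml <- S[ks] / ks
  mr <- (tot - S[ks]) / (n - ks)
  ssl <- S2[ks] - S[ks]^2 / ks
  ssr <- (tot2 - S2[ks]) - (tot - S[ks])^2 / (n - ks)
  pv <- (ssl + ssr) / pmax(n - 2, 1)
  se <- sqrt(pmax(pv, 1e-12) * (1 / ks + 1 / (n - ks)))
  list(ks = ks, t = abs(ml - mr) / se)
}

max_split_t <- function(v, min_seg) {
  st <- split_t_stats(v, min_seg)
  i <- which.max(st$t)
  if (length(i) == 0L) return(list(t = NA_real_, k = NA_integer_))
  list(t = st$t[i], k = st$ks[i])
}

# Null distribution of the max split statistic under within-segment
# permutation; one max per permutation. Fully vectorized over permutations.
perm_max_t <- function(v, min_seg, n_perm) {
  n <- length(v)
  ks <- seq.int(min_seg, n - min_seg)
  P <- vapply(seq_len(n_perm), function(i) v[sample.int(n)], numeric(n))
  # per-column prefix sums via one flat cumsum + column-offset subtraction
  col_prefix <- function(M) {
    cs <- matrix(cumsum(M), n, n_perm)
    off <- c(0, cs[n, -n_perm])
    sweep(cs[ks, , drop = FALSE], 2L, off)
  }
  Sk <- col_prefix(P)
  S2k <- col_prefix(P * P)
  tot <- sum(v); tot2 <- sum(v * v)
  ml <- Sk / ks
  mr <- (tot - Sk) / (n - ks)
  ssl <- S2k - Sk^2 / ks
  ssr <- (tot2 - S2k) - (tot - Sk)^2 / (n - ks)
  pv <- (ssl + ssr) / max(n - 2, 1)
  se <- sqrt(pmax(pv, 1e-12) * (1 / ks + 1 / (n - ks)))
  suppressWarnings(apply(abs(ml - mr) / se, 2L, max))
}
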