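make_call_assay <- function(cn, mbaf = NULL, het = NULL) {
  n <- length(cn)
  tibble::tibble(
    chrom = 1L, pos = as.numeric(seq_len(n)),
    cn_corrected = cn,
    mbaf = mbaf %||% rep(NA_real_, n),
    het = het %||% !is.na(mbaf %||% rep(NA_real_, n))
  )
}

test_that("copy-number thresholds use strict inequalities", {
  cc <- calling_config()
  for (case in list(list(0.90, "loss"), list(1.10, "gain"),
                    list(1.00, "neutral"), list(0.92, "neutral"),
                    list(1.08, "neutral"))) {
    a <- make_call_assay(rep(case[[1]], 20))
    seg <- call_segments(a, tibble::tibble(chrom = integer(), bp = integer()),
                         cc)
    expect_equal(seg$cn_state, case[[2]])
  }
})

test_that("allelic classes follow the mBAF cutpoints and het minimum", {
  cc <- calling_config()
  mk <- function(mbaf_val, n_het = 20L) {
    mb <- c(rep(mbaf_val, n_het), rep(NA, 20 - min(n_het, 20)))
    a <- make_call_assay(rep(1, 20), mbaf = mb,
                         het = !is.na(mb))
    call_segments(a, tibble::tibble(chrom = integer(), bp = integer()), cc)
  }
  expect_equal(mk(0.50)$allelic_class, 1L)
  expect_equal(mk(0.95)$allelic_class, 3L)
  expect_equal(mk(0.70)$allelic_class, 2L)
  expect_true(is.na(mk(0.95, n_het = 5L)$allelic_class))
})

test_that("allelic class is monotone in mean mBAF", {
  cc <- calling_config()
  classes <- vapply(seq(0.5, 1, by = 0.02), function(m) {
    a <- make_call_assay(rep(1, 30), mbaf = rep(m, 30), het = rep(TRUE, 30))
    call_segments(a, tibble::tibble(chrom = integer(), bp = integer()),
                  cc)$allelic_class
  }, integer(1))
  expect_true(all(diff(classes) >= 0))
})

test_that("breakpoints split segments and stats aggregate correctly", {
  a <- make_call_assay(c(rep(1, 10), rep(1.4, 10)),
                       mbaf = rep(c(0.5, 0.9), each = 10),
                       het = rep(TRUE, 20))
  seg <- call_segments(a, tibble::tibble(chrom = 1L, bp = 10L),
                       calling_config(min_het_per_segment = 5L))
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$mean_cn_ratio, c(1, 1.4))
  expect_equal(seg$cn_state, c("neutral", "gain"))
  expect_equal(seg$allelic_class, c(1L, 3L))
  expect_equal(seg$n_probes, c(10L, 10L))
})

test_that("frequency profile counts gains and filters small losses", {
  pm <- build_probe_map(1, 10, seed = 1)   # 20 probes on chromosome 1
  seg_for <- function(pid, state, n_probes = 20L, group = "C") {
    tibble::tibble(patient_id = pid, group = group, chrom = 1L,
                   start = 0L, end = n_probes,
                   n_probes = n_probes, n_het = 10L,
                   mean_cn_ratio = 1, mean_mbaf = 0.5,
                   cn_state = state, allelic_class = 1L)
  }
  calls <- dplyr::bind_rows(
    seg_for("p1", "gain"), seg_for("p2", "gain"), seg_for("p3", "gain"),
    purrr::map(sprintf("p%d", 4:10), seg_for, state = "neutral"))
  fp <- frequency_profile(calls, "C", pm)
  expect_equal(fp$gain_frequency, c(0.3, 0.3))
  expect_equal(fp$loss_frequency, c(0, 0))
  # a 10-probe loss is below the 15-probe reporting floor
  calls2 <- dplyr::bind_rows(
    dplyr::mutate(seg_for("p1", "loss", 10L),
                  end = 10L),
    dplyr::bind_rows(purrr::map(sprintf("p%d", 2:10), seg_for,
                                state = "neutral")))
  fp2 <- frequency_profile(calls2, "C", pm)
  expect_equal(max(fp2$loss_frequency), 0)
  # but an 18-probe loss counts
  calls3 <- dplyr::bind_rows(
    dplyr::mutate(seg_for("p1", "loss", 18L), end = 18L),
    dplyr::bind_rows(purrr::map(sprintf("p%d", 2:10), seg_for,
                                state = "neutral")))
  fp3 <- frequency_profile(calls3, "C", pm)
  expect_equal(max(fp3$loss_frequency), 0.1)
  expect_error(frequency_profile(calls, "Z", pm),
               class = "recurcna_invalid_argument")
})

test_that("end-to-end recovery meets the design operating point", {
  # one patient per group at default purity/noise on a reduced genome
  pm <- build_probe_map(8, 60, seed = 21)
  cfg <- sim_config(n_chromosomes = 8L, probes_per_arm = 60L)
  accs <- purrr::map(c("C", "L", "D", "LD"), function(g) {
    tr <- simulate_truth_profile(g, pm, cfg, seed = 31 + match(g, c("C", "L", "D", "LD")))
    a <- simulate_assay_pair(tr, pm, cfg, seed = 41 + match(g, c("C", "L", "D", "LD")),
                             patient_id = g)
    res <- run_array_pipeline(a, fast_calling_config(), seed = 51)
    seg <- dplyr::arrange(res$segments, .data$chrom, .data$start)
    tp <- recurcna:::truth_per_probe(tr, pm)
    true_state <- ifelse(tp$c_t < 2, "loss", ifelse(tp$c_t > 2, "gain",
                                                    "neutral"))
    mean(rep(seg$cn_state, seg$n_probes) == true_state)
  })
  expect_gt(mean(unlist(accs)), 0.9)
})
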