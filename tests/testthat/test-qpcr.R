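test_that("Ct preprocessing caps and imputes, and is idempotent", {
  x <- preprocess_ct(c(33, NA, 24.5, 30, 29.9))
  expect_equal(x, c(30, 30, 24.5, 30, 29.9))
  expect_equal(preprocess_ct(x), x)
  expect_error(preprocess_ct(c(20, -1)), class = "recurcna_invalid_input")
})

test_that("molecule counting follows the 2^(26 - Ct) rule", {
  expect_equal(ct_to_molecules(26), 1)
  expect_equal(ct_to_molecules(25), 2)
  expect_equal(ct_to_molecules(30), 0.0625)
  # exact halving per added cycle over a grid, strictly decreasing
  grid <- seq(16, 30, by = 0.5)
  mol <- ct_to_molecules(grid)
  expect_equal(ct_to_molecules(grid + 1) / mol, rep(0.5, length(grid)))
  expect_true(all(diff(mol) < 0))
})

test_that("SNP panel selection enforces the heterozygosity floor and size", {
  pm <- build_probe_map(13, 30, seed = 1)
  het <- tibble::tibble(probe_id = pm$probe_id,
                        het_fraction = rep(c(0.45, 0.45, 0.35),
                                           length.out = nrow(pm)))
  panel <- select_validation_snps(het, pm)
  expect_true(all(panel$het_fraction >= 0.40))
  expect_equal(unname(table(panel$region)[c("7p", "7q", "13")]),
               rep(16L, 3), ignore_attr = TRUE)
  # top-ranked: make 20 eligible with distinct fractions on 7p
  het2 <- het
  i7p <- which(pm$chrom == 7 & pm$arm == "p")
  het2$het_fraction[i7p] <- 0.3
  het2$het_fraction[i7p[1:20]] <- seq(0.60, 0.41, length.out = 20)
  panel2 <- select_validation_snps(het2, pm)
  p7 <- dplyr::filter(panel2, .data$region == "7p")
  expect_equal(nrow(p7), 16L)
  expect_equal(sort(p7$het_fraction, decreasing = TRUE),
               seq(0.60, 0.41, length.out = 20)[1:16], tolerance = 1e-12)
  # degenerate: nothing eligible
  het0 <- dplyr::mutate(het, het_fraction = 0)
  expect_warning(p0 <- select_validation_snps(het0, pm), "fewer than")
  expect_equal(nrow(p0), 0L)
})

test_that("allelic ratios are channel-normalized", {
  mk <- function(a1, b1, a2, b2) {
    tibble::tibble(sample_id = "s1", snp_id = c("x", "x", "y", "y"),
                   channel = c("A", "B", "A", "B"),
                   molecules = c(a1, b1, a2, b2))
  }
  # equal molecules, equal totals -> 1
  r <- sample_allelic_ratio(mk(4, 4, 4, 4))
  expect_equal(r$ratio, c(1, 1))
  # A = 2B at one SNP, mirrored at the other: equal channel totals -> 2
  r2 <- sample_allelic_ratio(mk(8, 4, 4, 8))
  expect_equal(r2$ratio, c(2, 0.5))
  # a global A-channel efficiency bias cancels in the normalization
  r3 <- sample_allelic_ratio(dplyr::mutate(
    mk(8, 4, 4, 8),
    molecules = .data$molecules * ifelse(.data$channel == "A", 2, 1)))
  expect_equal(r3$ratio, r2$ratio)
  # invariance under arbitrary per-channel rescaling
  r4 <- sample_allelic_ratio(dplyr::mutate(
    mk(8, 4, 4, 8),
    molecules = .data$molecules * ifelse(.data$channel == "A", 13.7, 0.3)))
  expect_equal(r4$ratio, r2$ratio)
  # zero denominator -> sentinel with flag
  r5 <- sample_allelic_ratio(mk(4, 0, 4, 4))
  expect_equal(r5$flag[r5$snp_id == "x"], "zero_denominator")
  expect_equal(r5$ratio[r5$snp_id == "x"], 2^8)
})

test_that("simulated Ct plates honour the molecule arithmetic", {
  truth <- list(s1 = flat_truth(40, 2L, 1L, chrom = 7L))
  panel <- tibble::tibble(snp_id = c("a", "b"), chrom = 7L,
                          idx = c(1L, 5L), region = "7p")
  # one molecule per allele, no noise -> Ct exactly 26, A = B
  ct <- simulate_ct_plate(truth, panel, input_molecules = 1,
                          ct_noise_sd = 0, seed = 2)
  expect_true(all(ct$ct == 26))
  # doubling input lowers Ct by one cycle
  ct2 <- simulate_ct_plate(truth, panel, input_molecules = 2,
                           ct_noise_sd = 0, seed = 2)
  expect_true(all(ct2$ct == 25))
  # noisy regression: slope of mean Ct on log2(input) is about -1
  means <- vapply(c(2, 4, 8, 16, 32), function(inp) {
    mean(simulate_ct_plate(truth, panel, input_molecules = inp,
                           ct_noise_sd = 0.15, seed = 5)$ct)
  }, numeric(1))
  slope <- coef(stats::lm(means ~ log2(c(2, 4, 8, 16, 32))))[2]
  expect_lt(abs(slope + 1), 0.1)
  expect_error(simulate_ct_plate(truth, panel[0, ], 1),
               class = "recurcna_invalid_argument")
})

test_that("Welch comparison matches the textbook computation", {
  a <- c(1.1, 1.5, 1.9); b <- c(2.4, 2.8, 3.6)
  ratios <- tibble::tibble(
    sample_id = sprintf("p%d", 1:6), snp_id = "s",
    ratio = c(a, b))
  panel <- tibble::tibble(snp_id = "s", region = "7p")
  cohort <- tibble::tibble(patient_id = sprintf("p%d", 1:6),
                           group = rep(c("L", "C"), each = 3))
  res <- region_group_comparison(ratios, panel, cohort, "L-vs-C")
  # hand computation on the folded summaries (ratios > 1 fold to themselves)
  se <- sqrt(var(a) / 3 + var(b) / 3)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- (var(a) / 3 + var(b) / 3)^2 /
    ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  p_hand <- 2 * stats::pt(-abs(t_hand), df_hand)
  expect_equal(res$t, t_hand, tolerance = 1e-6)
  expect_equal(res$df, df_hand, tolerance = 1e-6)
  expect_equal(res$p_value, p_hand, tolerance = 1e-6)
  # identical groups -> p = 1
  ratios_same <- dplyr::mutate(ratios, ratio = rep(c(1.2, 1.4, 1.6), 2))
  res_same <- region_group_comparison(ratios_same, panel, cohort, "L-vs-C")
  expect_equal(res_same$p_value, 1)
  expect_equal(res_same$t, 0)
})

test_that("folded summaries are symmetric in allele labeling", {
  ratios <- tibble::tibble(sample_id = rep(c("p1", "p2", "p3", "p4"), each = 2),
                           snp_id = rep(c("s1", "s2"), 4),
                           ratio = c(2, 0.5, 0.5, 2, 3, 1 / 3, 1, 1))
  panel <- tibble::tibble(snp_id = c("s1", "s2"), region = "7p")
  cohort <- tibble::tibble(patient_id = sprintf("p%d", 1:4),
                           group = c("L", "L", "C", "C"))
  res <- region_group_comparison(ratios, panel, cohort, "L-vs-C")
  # p1 and p2 have mirrored ratios yet identical folded summaries
  expect_equal(res$n_1, 2L)
  flipped <- dplyr::mutate(ratios, ratio = 1 / .data$ratio)
  res_f <- region_group_comparison(flipped, panel, cohort, "L-vs-C")
  expect_equal(res$t, res_f$t)
})

test_that("group comparison on simulated plates separates balanced L from imbalanced controls", {
  hits <- vapply(1:12, function(s) {
    pm <- build_probe_map(13, 20, seed = s, population_het = 0.6)
    # the scenario under test: retention in L vs imbalanced gain in controls
    # (chromosome-7 LOH zeroed; its near-infinite capped-Ct ratios are a
    # separate regime from this contrast)
    cfg <- sim_config(n_chromosomes = 13L, probes_per_arm = 20L,
                      p_chr7_loh = c(C = 0, L = 0, D = 0, LD = 0))
    groups <- c(rep("L", 12), rep("C", 37))
    ids <- sprintf("v%02d", seq_along(groups))
    truths <- purrr::map(stats::setNames(seq_along(groups), ids), function(i) {
      simulate_truth_profile(groups[i], pm, cfg, seed = s * 1000 + i)
    })
    het <- tibble::tibble(probe_id = pm$probe_id,
                          het_fraction = pm$population_het)
    panel <- suppressWarnings(select_validation_snps(het, pm))
    ct <- simulate_ct_plate(truths, panel, input_molecules = 8,
                            seed = s * 7)
    ratios <- sample_allelic_ratio(ct_to_sample_molecules(ct))
    cohort <- tibble::tibble(patient_id = ids, group = groups)
    res <- region_group_comparison(ratios, panel, cohort, "L-vs-C")
    res$p_value[res$region == "7p"] < 0.10
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
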