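test_that("truth profiles tile the genome and respect group priors", {
  pm <- small_probe_map()
  cfg <- small_sim_config()
  tr <- simulate_truth_profile("C", pm, cfg, seed = 1)
  sizes <- table(pm$chrom)
  for (ch in unique(tr$chrom)) {
    seg <- dplyr::filter(tr, .data$chrom == ch) %>% dplyr::arrange(.data$start)
    expect_equal(seg$start[1], 0L)
    expect_equal(seg$end[nrow(seg)], unname(sizes[as.character(ch)]),
                 ignore_attr = TRUE)
    if (nrow(seg) > 1) expect_equal(seg$start[-1], head(seg$end, -1))
  }
  expect_true(all(tr$b_t >= 0 & tr$b_t <= tr$c_t))
  expect_error(simulate_truth_profile("X", pm, cfg),
               class = "recurcna_invalid_argument")
})

test_that("L-group chromosome 7 is always balanced under full retention prior", {
  pm <- build_probe_map(7, 20, seed = 2)
  cfg <- sim_config(probes_per_arm = 20L, n_chromosomes = 7L)
  for (s in 1:20) {
    tr <- simulate_truth_profile("L", pm, cfg, seed = s)
    chr7 <- dplyr::filter(tr, .data$chrom == 7L)
    expect_true(all(chr7$b_t / chr7$c_t == 0.5))
  }
})

test_that("null configuration yields a diploid heterozygous genome", {
  pm <- small_probe_map()
  cfg <- small_sim_config(
    p_chr7_imbalance = c(C = 0, L = 0, D = 0, LD = 0),
    p_chr7_loh = c(C = 0, L = 0, D = 0, LD = 0),
    p_chr13_imbalance = c(C = 0, L = 0, D = 0, LD = 0),
    p_chr13_loh = c(C = 0, L = 0, D = 0, LD = 0),
    background_gain_rate = 0, background_loss_rate = 0, focal_rate = 0)
  tr <- simulate_truth_profile("C", pm, cfg, seed = 3)
  expect_true(all(tr$c_t == 2L & tr$b_t == 1L))
})

test_that("control chromosome-7 imbalance frequency matches its prior", {
  pm <- build_probe_map(7, 4, seed = 4)
  cfg <- sim_config(probes_per_arm = 4L, n_chromosomes = 7L,
                    p_chr7_imbalance = c(C = 0.5, L = 0, D = 0.5, LD = 0.5),
                    p_chr7_loh = c(C = 0, L = 0, D = 0, LD = 0))
  hits <- vapply(1:500, function(s) {
    tr <- simulate_truth_profile("C", pm, cfg, seed = s)
    any(tr$chrom == 7L & tr$true_class == 2L)
  }, logical(1))
  # 0.5 within a generous binomial band (3 SD ~ 0.067)
  expect_gt(mean(hits), 0.43)
  expect_lt(mean(hits), 0.57)
})

test_that("assay pair reproduces the purity-mixture closed forms at zero noise", {
  pm <- build_probe_map(1, 20, seed = 5, population_het = 0.999)
  # rho = 1, diploid: ratio 1, het BAF 0.5
  cfg1 <- clean_sim_config(purity = 1)
  a1 <- simulate_assay_pair(flat_truth(40), pm, cfg1, seed = 6)
  expect_equal(a1$tumor_cn_ratio, rep(1, 40))
  expect_equal(a1$tumor_baf[a1$genotype == "AB"],
               rep(0.5, sum(a1$genotype == "AB")))
  # rho = 1, hemizygous loss: ratio 0.5, het-origin BAF at a pole
  a2 <- simulate_assay_pair(flat_truth(40, 1L, 0L), pm, cfg1, seed = 7)
  expect_equal(a2$tumor_cn_ratio, rep(0.5, 40))
  expect_true(all(a2$tumor_baf[a2$genotype == "AB"] %in% c(0, 1)))
  # rho = 0.5, 3 copies / 2 B: ratio 1.25, BAF 0.6 (or mirrored 0.4)
  cfg3 <- clean_sim_config(purity = 0.5)
  a3 <- simulate_assay_pair(flat_truth(40, 3L, 2L), pm, cfg3, seed = 8)
  expect_equal(a3$tumor_cn_ratio, rep(1.25, 40))
  expect_true(all(abs(abs(a3$tumor_baf[a3$genotype == "AB"] - 0.5) - 0.1) < 1e-9))
})

test_that("mixture consistency holds on a grid of states and purities", {
  pm <- build_probe_map(1, 10, seed = 9, population_het = 0.999)
  for (rho in c(0.3, 0.75, 1)) {
    cfg <- clean_sim_config(purity = rho)
    for (state in list(c(1, 0), c(2, 1), c(2, 0), c(3, 1), c(4, 2))) {
      a <- simulate_assay_pair(flat_truth(20, state[1], state[2]), pm, cfg,
                               seed = 10)
      exp_ratio <- (rho * state[1] + (1 - rho) * 2) / 2
      expect_equal(a$tumor_cn_ratio, rep(exp_ratio, 20), tolerance = 1e-12)
      het <- a$genotype == "AB"
      exp_baf <- (rho * state[2] + (1 - rho)) /
        (rho * state[1] + (1 - rho) * 2)
      got <- a$tumor_baf[het]
      expect_true(all(abs(got - exp_baf) < 1e-9 |
                        abs((1 - got) - exp_baf) < 1e-9))
    }
  }
})

test_that("assay simulation is deterministic and validates purity", {
  pm <- small_probe_map()
  cfg <- small_sim_config()
  tr <- simulate_truth_profile("C", pm, cfg, seed = 11)
  expect_identical(simulate_assay_pair(tr, pm, cfg, seed = 12),
                   simulate_assay_pair(tr, pm, cfg, seed = 12))
  cfg_bad <- cfg; cfg_bad$purity <- 1.5
  expect_error(simulate_assay_pair(tr, pm, cfg_bad, seed = 12),
               class = "recurcna_invalid_argument")
})

test_that("study table generator covers arms with valid fractions", {
  st <- simulate_study_table(20, seed = 13)
  expect_equal(length(unique(st$study_id)), 20L)
  expect_true(all(st$gain_fraction >= 0 & st$gain_fraction <= 1))
  expect_true(all(st$loss_fraction >= 0 & st$loss_fraction <= 1))
  expect_identical(st, simulate_study_table(20, seed = 13))
  expect_error(simulate_study_table(0), class = "recurcna_invalid_argument")
  expect_error(simulate_study_table(3, arms = character(0)),
               class = "recurcna_invalid_argument")
})
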