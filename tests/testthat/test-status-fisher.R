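test_that("exact Fisher test reproduces the published chromosome-status p-values", {
  chr7 <- rbind(c(9, 0, 0), c(19, 25, 1))
  p7 <- fisher_rxc(chr7)
  expect_equal(signif(p7, 2), 0.0025)
  comb <- rbind(c(7, 1, 1), c(5, 33, 7))
  expect_lte(fisher_rxc(comb), 0.0002)
})

test_that("fisher_rxc equals full enumeration on the 2x2 three-table margin case", {
  expect_equal(fisher_rxc(rbind(c(2, 0), c(0, 2))), 1 / 3, tolerance = 1e-12)
})

test_that("fisher_rxc matches the brute-force oracle and fisher.test", {
  # all 2x2 tables with total <= 10
  for (a in 0:4) for (b in 0:4) for (cc in 0:4) for (d in 0:4) {
    tab <- rbind(c(a, b), c(cc, d))
    if (sum(tab) == 0 || sum(tab) > 10) next
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      expect_equal(fisher_rxc(tab), 1)
      next
    }
    expect_equal(fisher_rxc(tab), fisher_oracle_2xc(tab), tolerance = 1e-12)
    expect_equal(fisher_rxc(tab), stats::fisher.test(tab)$p.value,
                 tolerance = 1e-8)
  }
  # random 2x3 tables with total <= 12
  withr::with_seed(5, {
    for (i in 1:100) {
      tab <- matrix(stats::rmultinom(1, sample(4:12, 1), rep(1 / 6, 6)),
                    nrow = 2)
      expect_equal(fisher_rxc(tab), fisher_oracle_2xc(tab),
                   tolerance = 1e-12)
    }
  })
})

test_that("fisher_rxc validates its input", {
  expect_error(fisher_rxc(rbind(c(1, -1), c(0, 2))),
               class = "recurcna_invalid_argument")
  expect_error(fisher_rxc(rbind(c(0.5, 1), c(0, 2))),
               class = "recurcna_invalid_argument")
  expect_error(fisher_rxc(matrix(1:3, nrow = 1)),
               class = "recurcna_invalid_argument")
  expect_error(fisher_rxc(matrix(0, 2, 2)),
               class = "recurcna_undefined_test")
})

test_that("chromosome status takes the weighted mode with aberrant tie-break", {
  seg <- tibble::tibble(
    patient_id = "p1", chrom = 1L,
    allelic_class = c(1L, 2L), n_het = c(40L, 60L), n_probes = c(50L, 70L))
  expect_equal(chromosome_status(seg)$status, 2L)
  seg_tie <- dplyr::mutate(seg, allelic_class = c(1L, 3L),
                           n_het = c(50L, 50L))
  expect_equal(chromosome_status(seg_tie)$status, 3L)
  seg_u <- dplyr::mutate(seg, allelic_class = c(1L, 1L))
  expect_equal(chromosome_status(seg_u)$status, 1L)
  seg_na <- dplyr::mutate(seg, allelic_class = c(NA_integer_, NA_integer_))
  expect_true(is.na(chromosome_status(seg_na)$status))
  # alternative abundance measure
  seg_w <- tibble::tibble(patient_id = "p", chrom = 2L,
                          allelic_class = c(1L, 3L),
                          n_het = c(10L, 20L), n_probes = c(80L, 20L))
  expect_equal(chromosome_status(seg_w)$status, 3L)
  expect_equal(chromosome_status(seg_w, "n_probes")$status, 1L)
})

test_that("status combination takes the maximum and is commutative", {
  expect_equal(combine_status(1L, 2L), 2L)
  expect_equal(combine_status(3L, 1L), 3L)
  expect_equal(combine_status(1L, 1L), 1L)
  expect_true(is.na(combine_status(NA, 2L)))
  grid <- expand.grid(a = 1:3, b = 1:3)
  expect_equal(combine_status(grid$a, grid$b), combine_status(grid$b, grid$a))
  expect_true(all(combine_status(grid$a, grid$b) >= pmax(grid$a, grid$b)))
  expect_error(combine_status(0L, 2L), class = "recurcna_invalid_argument")
})

test_that("status group test builds the printed-style 2x3 table", {
  statuses <- tibble::tibble(
    patient_id = c(sprintf("l%d", 1:9), sprintf("c%d", 1:45)),
    status = c(rep(1L, 9), rep(1L, 19), rep(2L, 25), rep(3L, 1)))
  cohort <- tibble::tibble(
    patient_id = statuses$patient_id,
    group = c(rep("L", 9), rep("C", 45)))
  res <- status_group_test(statuses, cohort, "L-vs-C")
  expect_equal(unname(res$table), rbind(c(9, 0, 0), c(19, 25, 1)))
  expect_equal(signif(res$p_value, 2), 0.0025)
  # identical distributions give p = 1
  st2 <- tibble::tibble(patient_id = cohort$patient_id,
                        status = rep(c(1L, 2L), 27))
  expect_equal(status_group_test(st2, cohort, "L-vs-C")$p_value, 1)
})

test_that("simulated retention effect yields significant status tests", {
  hits <- vapply(1:20, function(s) {
    pm <- build_probe_map(7, 6, seed = s)
    cfg <- sim_config(n_chromosomes = 7L, probes_per_arm = 6L)
    groups <- c(rep("L", 10), rep("C", 46))
    status <- vapply(seq_along(groups), function(i) {
      tr <- simulate_truth_profile(groups[i], pm, cfg, seed = s * 100 + i)
      ch7 <- dplyr::filter(tr, .data$chrom == 7L)
      ch7$true_class[1]
    }, integer(1))
    statuses <- tibble::tibble(patient_id = sprintf("p%02d", seq_along(groups)),
                               status = status)
    cohort <- tibble::tibble(patient_id = statuses$patient_id, group = groups)
    status_group_test(statuses, cohort, "L-vs-C")$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
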