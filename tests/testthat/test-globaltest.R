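test_that("global test statistic matches its closed form for one feature", {
  withr::with_seed(1, {
    x <- matrix(rnorm(30), nrow = 1)
    y <- rep(c(0, 1), 15)
  })
  gt <- global_test(x, y, n_permutations = 200, seed = 2)
  z <- (x - mean(x)) / sd(x)
  expect_equal(gt$statistic, as.numeric((z %*% (y - mean(y)))^2))
  # monotone in the squared sample correlation with the label
  withr::with_seed(3, noise <- rnorm(30))
  qs <- vapply(c(0, 0.3, 0.7, 1.5), function(b) {
    xi <- matrix(b * y + noise, nrow = 1)
    global_test(xi, y, n_permutations = 10, seed = 4)$statistic
  }, numeric(1))
  cors <- vapply(c(0, 0.3, 0.7, 1.5), function(b) {
    stats::cor(b * y + noise, y)^2
  }, numeric(1))
  expect_equal(order(qs), order(cors))
})

test_that("constant features give a zero statistic and p of one", {
  gt <- global_test(matrix(5, nrow = 3, ncol = 10), rep(c(0, 1), 5),
                    n_permutations = 100, seed = 1)
  expect_equal(gt$statistic, 0)
  expect_equal(gt$p_value, 1)
})

test_that("global test validates its inputs", {
  x <- matrix(rnorm(20), nrow = 2)
  expect_error(global_test(x, rep(1, 10)),
               class = "recurcna_invalid_argument")
  expect_error(global_test(x, c(0, 1)),
               class = "recurcna_invalid_argument")
  expect_error(global_test(x[0, , drop = FALSE], rep(c(0, 1), 5)),
               class = "recurcna_undefined_test")
})

test_that("permutation p-values are valid under the null", {
  # null labels: rejection rate at alpha = 0.05 stays near nominal
  rejections <- vapply(1:300, function(s) {
    withr::with_seed(s + 4000, {
      x <- matrix(rnorm(5 * 24), nrow = 5)
      y <- sample(rep(c(0, 1), 12))
    })
    global_test(x, y, n_permutations = 200, seed = s)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.02)
  expect_lt(mean(rejections), 0.09)
})

test_that("BH adjustment equals the direct step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  withr::with_seed(9, {
    for (i in 1:500) {
      p <- runif(sample(1:20, 1))^sample(1:3, 1)
      expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), class = "recurcna_invalid_argument")
})

test_that("BH adjustment is order preserving", {
  withr::with_seed(10, p <- runif(50))
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj >= p))
})

test_that("hierarchy is gated: no arm results when the genome test fails", {
  d <- processed_small_cohort()
  segs <- dplyr::left_join(d$pipe$segments,
                           d$cohort[, c("patient_id", "group")],
                           by = "patient_id")
  # D-vs-C has no simulated allelic difference beyond sampling noise on
  # two chromosomes dominated by the shared control priors
  res <- hierarchical_test(segs, d$cohort, d$probe_map, "D-vs-C", "cn",
                           n_permutations = 300, seed = 5)
  genome_p <- res$p_value[res$level == "genome"]
  if (all(genome_p >= 0.05)) {
    expect_equal(unique(res$level), "genome")
  } else {
    expect_true(all(c("genome", "arm") %in% res$level))
  }
  # with same-data gating a failed genome test emits nothing below it
  res_same <- hierarchical_test(segs, d$cohort, d$probe_map, "D-vs-C", "cn",
                                gate = "same", n_permutations = 300,
                                seed = 5)
  if (res_same$p_value[1] >= 0.05) {
    expect_equal(unique(res_same$level), "genome")
    expect_equal(nrow(res_same), 1L)
  }
})

test_that("feature matrices expand segments per probe", {
  d <- processed_small_cohort()
  mat <- build_feature_matrix(d$pipe$segments, d$probe_map, "allelic")
  expect_equal(dim(mat), c(nrow(d$probe_map), nrow(d$cohort)))
  expect_true(all(mat %in% 1:3))
  info <- attr(mat, "probe_info")
  expect_equal(info$probe_id, d$probe_map$probe_id)
  matcn <- build_feature_matrix(d$pipe$segments, d$probe_map, "cn")
  expect_true(all(matcn > 0))
})
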