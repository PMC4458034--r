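test_that("within-study flags use the inclusive 25% boundary", {
  st <- tibble::tibble(study_id = "s1", arm = c("8q", "8q", "1p"),
                       gain_fraction = c(0.30, 0.20, 0.25),
                       loss_fraction = c(0.10, 0.26, 0.24))
  fl <- flag_frequent(st)
  expect_equal(fl$gain_flag, c(TRUE, FALSE, TRUE))
  expect_equal(fl$loss_flag, c(FALSE, TRUE, FALSE))
  expect_error(flag_frequent(dplyr::mutate(st, arm = "99z")),
               class = "recurcna_invalid_argument")
})

test_that("cross-study counting reproduces the published-style fractions", {
  mk_studies <- function(n, arm, frac_flagging, site = "rectum") {
    tidyr::expand_grid(study_id = sprintf("s%02d", 1:n), arm = arm) %>%
      dplyr::mutate(site = site,
                    n_cases = 30L,
                    gain_fraction = ifelse(
                      as.integer(sub("s", "", .data$study_id)) <=
                        round(frac_flagging * n), 0.30, 0.10),
                    loss_fraction = 0)
  }
  # 15 of 20 rectal studies flag 7p gain -> fraction 0.75, common
  s1 <- mk_studies(20, "7p", 0.75)
  r1 <- common_alterations(s1, site_filter = "rectum")
  g1 <- dplyr::filter(r1, .data$direction == "gain")
  expect_equal(g1$fraction, 0.75)
  expect_true(g1$common)
  # 11 of 12 colon studies flag 20q gain -> ~0.92, common
  s2 <- mk_studies(12, "20q", 11 / 12, site = "colon")
  g2 <- dplyr::filter(common_alterations(s2, "colon"),
                      .data$direction == "gain")
  expect_equal(g2$fraction, 11 / 12)
  expect_true(g2$common)
  # 3 of 10 -> 0.30, below the 40% rule
  s3 <- mk_studies(10, "18q", 0.3)
  g3 <- dplyr::filter(common_alterations(s3), .data$direction == "gain")
  expect_equal(g3$fraction, 0.3)
  expect_false(g3$common)
  expect_error(common_alterations(s1, site_filter = "colon"),
               class = "recurcna_invalid_argument")
})

test_that("boundary 0.25 case fraction counts as frequent", {
  st <- tibble::tibble(study_id = "s1", site = "rectum", n_cases = 20L,
                       arm = "13q", gain_fraction = 0.25, loss_fraction = 0)
  r <- common_alterations(st)
  expect_equal(dplyr::filter(r, .data$direction == "gain")$fraction, 1)
})

test_that("missing fractions are excluded per arm, not per study", {
  st <- tidyr::expand_grid(study_id = sprintf("s%d", 1:4),
                           arm = c("1p", "2p")) %>%
    dplyr::mutate(site = "rectum", n_cases = 10L,
                  gain_fraction = c(0.3, 0.3, NA, 0.3, 0.3, 0.3, 0.1, 0.3),
                  loss_fraction = 0)
  r <- common_alterations(st)
  g1p <- dplyr::filter(r, .data$arm == "1p", .data$direction == "gain")
  expect_equal(g1p$n_studies, 3L)   # the NA study drops out for 1p only
  g2p <- dplyr::filter(r, .data$arm == "2p", .data$direction == "gain")
  expect_equal(g2p$n_studies, 4L)
})

test_that("site contrast uses a strict 20% difference", {
  mk <- function(f1p, f4q) {
    tibble::tibble(arm = c("1p", "4q"), direction = "loss",
                   n_studies = 20L, fraction = c(f1p, f4q),
                   common = fraction >= 0.4)
  }
  res <- site_contrast(mk(0.55, 0.50), mk(0.30, 0.30))
  expect_equal(res$arm, "1p")       # 4q differs by exactly 0.20: excluded
  expect_equal(res$excess, "rectum")
  # equal and exactly-0.20 differences are not reported
  res2 <- site_contrast(mk(0.50, 0.50), mk(0.50, 0.30))
  expect_equal(nrow(res2), 0L)
  expect_error(site_contrast(mk(0.5, 0.5), mk(0.5, 0.5)[1, ]),
               class = "recurcna_invalid_argument")
})

test_that("threshold monotonicity holds on simulated study tables", {
  st <- simulate_study_table(15, seed = 3)
  loose <- common_alterations(st, case_threshold = 0.20)
  tight <- common_alterations(st, case_threshold = 0.35)
  j <- dplyr::inner_join(loose, tight, by = c("arm", "direction"))
  expect_true(all(j$fraction.y <= j$fraction.x))
  c1 <- common_alterations(st, study_threshold = 0.30)
  c2 <- common_alterations(st, study_threshold = 0.60)
  expect_true(sum(c2$common) <= sum(c1$common))
  expect_true(all(loose$fraction >= 0 & loose$fraction <= 1))
})

test_that("a constant 0.30 gain on 8q flows through to a common call", {
  st <- simulate_study_table(20, seed = 4) %>%
    dplyr::mutate(gain_fraction = ifelse(.data$arm == "8q", 0.30,
                                         .data$gain_fraction * 0.2))
  r <- common_alterations(st)
  g8q <- dplyr::filter(r, .data$arm == "8q", .data$direction == "gain")
  expect_equal(g8q$fraction, 1)
  expect_true(g8q$common)
})
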