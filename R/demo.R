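#' Simulate a complete discovery study
#'
#' One call producing every input of the analysis: probe map, matched cohort
#' with survival, per-patient truth profiles and tumor/normal assays.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; all per-patient seeds derive from it.
#' @return A list with `probe_map`, `cohort`, `truths` (named list) and
#'   `assays` (named list), plus the `config` and `seed` used.
#' @export
simulate_discovery_study <- function(config = sim_config(), seed = 1L) {
  probe_map <- build_probe_map(config$n_chromosomes, config$probes_per_arm,
                               config$arm_length_bp, config$population_het,
                               seed = child_seed(seed, "probes"))
  cohort <- simulate_cohort(config, seed = child_seed(seed, "cohort"))
  truths <- purrr::map(
    setNames(seq_len(nrow(cohort)), cohort$patient_id),
    function(i) simulate_truth_profile(cohort$group[i], probe_map, config,
                                       seed = child_seed(seed, paste0("truth", i))))
  assays <- purrr::imap(truths, function(tr, pid) {
    simulate_assay_pair(tr, probe_map, config,
                        seed = child_seed(seed, paste0("assay", pid)),
                        patient_id = pid)
  })
  list(probe_map = probe_map, cohort = cohort, truths = truths,
       assays = assays, config = config, seed = as.integer(seed))
}

#' Run the end-to-end demonstration workflow
#'
#' Simulates a discovery study, runs the array pipeline on every patient,
#' performs the hierarchical association tests (local and distant recurrence
#' vs control, allelic data), the chromosome-7 / 7+13 status Fisher
#' comparisons, a multivariate Cox model of chromosome-7 aberration for the
#' local recurrence-free period, the qPCR validation arithmetic on a
#' simulated plate, and the cross-study counting rule on a simulated
#' literature table. All tables are written to `out_dir` and a summary
#' report to `out_dir/report.txt`. Fully reproducible from `seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @param calling A [calling_config()].
#' @param seed Integer seed.
#' @param n_permutations Permutations for the association tests.
#' @return Invisibly, a list with the main result objects: `qc`, `segments`,
#'   `association`, `status_tests`, `cox`, `welch`, `meta`, `report_path`.
#' @export
run_demo <- function(out_dir = tempfile("recurcna_demo_"),
                     config = sim_config(), calling = calling_config(),
                     seed = 1L, n_permutations = 1000L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_discovery_study(config, seed)
  write_probe_map(study$probe_map, file.path(out_dir, "probes.tsv"))
  write_cohort(study$cohort, file.path(out_dir, "cohort.csv"))
  write_truth_json(study$truths, file.path(out_dir, "truth.json"))

  pipe <- run_cohort_pipeline(study$assays, calling,
                              seed = child_seed(seed, "pipeline"))
  segs <- pipe$segments %>%
    dplyr::left_join(study$cohort %>% select("patient_id", "group"),
                     by = "patient_id")
  write_segments_bed(pipe$segments, file.path(out_dir, "segments.bed"))
  readr::write_tsv(pipe$qc, file.path(out_dir, "qc.tsv"))

  assoc <- bind_rows(
    hierarchical_test(segs, study$cohort, study$probe_map, "L-vs-C",
                      "allelic", n_permutations = n_permutations,
                      seed = child_seed(seed, "assoc_L"), config = calling),
    hierarchical_test(segs, study$cohort, study$probe_map, "D-vs-C",
                      "allelic", n_permutations = n_permutations,
                      seed = child_seed(seed, "assoc_D"), config = calling)
  )
  readr::write_tsv(assoc, file.path(out_dir, "association.tsv"))

  status <- chromosome_status(pipe$segments)
  readr::write_tsv(status, file.path(out_dir, "status.tsv"))
  st7 <- status %>% filter(.data$chrom == 7L) %>%
    select("patient_id", "status")
  st13 <- status %>% filter(.data$chrom == 13L) %>%
    select("patient_id", status13 = "status")
  status_tests <- list(
    chr7 = status_group_test(st7, study$cohort, "L-vs-C"))
  if (nrow(st13) > 0L) {
    st_comb <- st7 %>%
      dplyr::inner_join(st13, by = "patient_id") %>%
      transmute(patient_id = .data$patient_id,
                status = combine_status(.data$status, .data$status13))
    status_tests$chr7_13 <- status_group_test(st_comb, study$cohort,
                                              "L-vs-C")
  }

  marker <- st7 %>%
    transmute(patient_id = .data$patient_id,
              marker = as.integer(.data$status > 1L))
  cox <- fit_marker_model(
    endpoint_dataset(study$cohort, marker, "LRFP"), mode = "multivariate")
  readr::write_tsv(tidy(cox), file.path(out_dir, "cox_lrfp.tsv"))

  het_table <- purrr::imap(study$assays, function(a, pid) {
    tibble(probe_id = a$probe_id,
           het = call_genotypes(a$normal_baf, calling)$genotype == "AB")
  }) %>% bind_rows() %>%
    group_by(.data$probe_id) %>%
    summarise(het_fraction = mean(.data$het), .groups = "drop")
  panel <- select_validation_snps(het_table, study$probe_map)
  ct <- simulate_ct_plate(study$truths, panel,
                          seed = child_seed(seed, "ct"))
  write_ct_records(ct, file.path(out_dir, "ct.csv"))
  ratios <- sample_allelic_ratio(ct_to_sample_molecules(ct))
  welch <- region_group_comparison(ratios, panel, study$cohort, "L-vs-C")
  readr::write_tsv(welch, file.path(out_dir, "welch.tsv"))

  studies <- simulate_study_table(20, seed = child_seed(seed, "studies"))
  write_study_table(studies, file.path(out_dir, "studies.csv"))
  meta <- common_alterations(studies, site_filter = "rectum")
  readr::write_tsv(meta, file.path(out_dir, "meta_summary.tsv"))

  report_path <- file.path(out_dir, "report.txt")
  writeLines(c(
    sprintf("recurcna %s demo report",
            as.character(utils::packageVersion("recurcna"))),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("config hash: %s", rlang::hash(list(config, calling))),
    "",
    sprintf("patients: %d (QC-excluded: %d)", nrow(pipe$qc),
            sum(pipe$qc$excluded)),
    sprintf("segments called: %d", nrow(pipe$segments)),
    "",
    "chromosome 7 status table (L vs C):",
    utils::capture.output(print(status_tests$chr7$table)),
    sprintf("Fisher exact p = %.4g", status_tests$chr7$p_value),
    "",
    if (!is.null(status_tests$chr7_13)) c(
      "combined chromosome 7 + 13 status table (L vs C):",
      utils::capture.output(print(status_tests$chr7_13$table)),
      sprintf("Fisher exact p = %.4g", status_tests$chr7_13$p_value),
      ""),
    "hierarchical association (allelic, significant arms):",
    utils::capture.output(print(as.data.frame(
      assoc %>% filter(.data$level == "arm",
                       .data$p_adjusted < calling$gate_alpha))))
  ), report_path)
  invisible(list(qc = pipe$qc, segments = segs, association = assoc,
                 status_tests = status_tests, cox = cox, welch = welch,
                 meta = meta, report_path = report_path))
}
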