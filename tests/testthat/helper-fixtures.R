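# Shared fixtures: small genomes and fast configurations so individual tests
# stay quick. Everything is generated in code at test time.

small_probe_map <- function(n_chrom = 2L, probes = 30L, seed = 101L) {
  build_probe_map(n_chromosomes = n_chrom, probes_per_arm = probes,
                  seed = seed)
}

small_sim_config <- function(...) {
  sim_config(n_per_group = c(C = 20L, L = 6L, D = 5L, LD = 3L),
             n_chromosomes = 2L, probes_per_arm = 30L, ...)
}

# noise-free configuration for closed-form mixture checks
clean_sim_config <- function(...) {
  sim_config(noise_sd_cn = 0, noise_sd_baf = 0, wave_amplitude = 0,
             censor_rate = 0, ...)
}

fast_calling_config <- function(...) {
  calling_config(seg_n_perm = 100L, ...)
}

# one-chromosome truth profile helper
flat_truth <- function(n_probes, c_t = 2L, b_t = 1L, chrom = 1L) {
  tibble::tibble(chrom = chrom, start = 0L, end = as.integer(n_probes),
                 c_t = as.integer(c_t), b_t = as.integer(b_t),
                 true_class = allelic_class_of(c_t, b_t))
}

# a small processed cohort reused by association/status tests; memoised so
# several test files can share one computation
processed_small_cohort <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    pm <- small_probe_map(seed = 7)
    cfg <- small_sim_config()
    cohort <- simulate_cohort(cfg, seed = 8)
    truths <- purrr::map(
      stats::setNames(seq_len(nrow(cohort)), cohort$patient_id),
      function(i) simulate_truth_profile(cohort$group[i], pm, cfg, seed = 500 + i))
    assays <- purrr::imap(truths, function(tr, pid) {
      simulate_assay_pair(tr, pm, cfg, seed = 900 + match(pid, names(truths)),
                          patient_id = pid)
    })
    pipe <- run_cohort_pipeline(assays, fast_calling_config(), seed = 42)
    cache <<- list(probe_map = pm, config = cfg, cohort = cohort,
                   truths = truths, assays = assays, pipe = pipe)
    cache
  }
})
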