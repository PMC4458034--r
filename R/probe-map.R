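#' Build a synthetic SNP probe map
#'
#' Lays out SNP probes over `n_chromosomes` autosomes with `probes_per_arm`
#' probes per arm, uniformly jittered over each arm and sorted by position.
#' Coordinates are 0-based. Chromosome 13 is modeled as acrocentric: its p arm
#' receives no probes (all `2 * probes_per_arm` probes go to 13q), matching
#' the biology and avoiding meaningless 13p calls.
#'
#' @param n_chromosomes Number of autosomes (1..22).
#' @param probes_per_arm Probes per chromosome arm (>= 2).
#' @param arm_length_bp Arm length in bp.
#' @param population_het Mean expected heterozygosity; per-probe values are
#'   drawn from Beta distributions centred there.
#' @param seed Optional integer seed; the same seed reproduces the same map.
#'
#' @return A tibble with columns `probe_id`, `chrom` (integer), `arm`
#'   ("p"/"q"), `pos` (0-based bp) and `population_het`, sorted by chromosome
#'   then position; positions are strictly increasing within a chromosome.
#' @export
#' @examples
#' pm <- build_probe_map(n_chromosomes = 2, probes_per_arm = 10, seed = 1)
#' dplyr::count(pm, chrom, arm)
build_probe_map <- function(n_chromosomes = 22L,
                            probes_per_arm = 120L,
                            arm_length_bp = 6e7,
                            population_het = 0.5,
                            seed = NULL) {
  check_number(n_chromosomes, "n_chromosomes", min = 1, max = 22, integer = TRUE)
  check_number(probes_per_arm, "probes_per_arm", min = 2, integer = TRUE)
  check_number(arm_length_bp, "arm_length_bp", min = 1)
  with_seed_or_current(seed, {
    maps <- purrr::map(seq_len(n_chromosomes), function(chrom) {
      per_arm <- c(p = probes_per_arm, q = probes_per_arm)
      if (chrom == 13L) per_arm <- c(p = 0L, q = 2L * probes_per_arm)
      purrr::map2(names(per_arm), per_arm, function(arm, n_arm) {
        if (n_arm == 0L) return(NULL)
        offset <- if (arm == "p") 0 else arm_length_bp
        pos <- offset + sort(sample.int(arm_length_bp, n_arm))
        tibble(
          chrom = as.integer(chrom),
          arm = arm,
          pos = as.numeric(pos - 1),  # 0-based
          population_het = stats::rbeta(n_arm, population_het * 20,
                                        (1 - population_het) * 20)
        )
      }) %>% bind_rows()
    }) %>% bind_rows()
    maps %>%
      arrange(.data$chrom, .data$pos) %>%
      mutate(probe_id = sprintf("snp_%02d_%06d", .data$chrom, row_number()),
             .by = "chrom") %>%
      select("probe_id", "chrom", "arm", "pos", "population_het")
  })
}

# Arm label ("7p", "13q", ...) for each row of a probe map.
arm_label <- function(probe_map) {
  paste0(probe_map$chrom, probe_map$arm)
}
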