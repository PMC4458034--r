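#' Run the per-patient array pipeline
#'
#' Full preprocessing and calling for one matched tumor/normal assay:
#' mean-log2 intensity QC, germline genotype calling, tumor/normal genotype
#' concordance QC, normalization of the tumor copy-number ratio to the
#' sample mean, de-waving, mirrored-BAF computation, joint segmentation of
#' both signals and per-segment copy-number/allelic-class calling. QC
#' failures flag the sample as excluded but the result is still returned.
#'
#' @param assay Per-probe tibble from [simulate_assay_pair()] (or the same
#'   columns read from disk; the truth columns are optional).
#' @param config A [calling_config()].
#' @param seed Optional integer seed (segmentation permutations).
#'
#' @return An object of class `recurcna_pipeline` — a list with
#'   `assay` (the input plus `genotype_call`, `het`, `cn_corrected`,
#'   `mbaf`), `segments` (segment calls, see [call_segments()]), and `qc`
#'   (tibble with `patient_id`, `mean_log2`, `mean_log2_pass`,
#'   `concordance`, `concordance_pass`, `het_fraction`, `excluded`).
#' @export
run_array_pipeline <- function(assay, config = calling_config(), seed = NULL) {
  patient_id <- assay$patient_id[1] %||% NA_character_
  # raw intensities are absent from the long interchange format; the
  # mean-log2 QC is then not assessable and the sample passes by default
  qc_log2 <- if ("tumor_raw" %in% names(assay) &&
                 any(!is.na(assay$tumor_raw))) {
    qc_mean_log2(assay$tumor_raw, config)
  } else {
    list(statistic = NA_real_, pass = TRUE)
  }
  geno <- call_genotypes(assay$normal_baf, config)
  tumor_geno <- call_genotypes(assay$tumor_baf, config)
  conc <- check_pair_concordance(tumor_geno$genotype, geno$genotype, config)
  assay <- assay %>%
    mutate(
      genotype_call = geno$genotype,
      het = geno$genotype == "AB",
      cn_corrected = dewave(normalize_to_sample_mean(.data$tumor_cn_ratio),
                            .data$pos, .data$chrom, span = config$dewave_span),
      mbaf = mirrored_baf(.data$tumor_baf, .data$het)
    )
  breakpoints <- segment_assay_pair(assay, config, seed = seed)
  segments <- call_segments(assay, breakpoints, config) %>%
    mutate(patient_id = patient_id, .before = 1)
  qc <- tibble(
    patient_id = patient_id,
    mean_log2 = qc_log2$statistic,
    mean_log2_pass = qc_log2$pass,
    concordance = conc$concordance,
    concordance_pass = conc$pass,
    het_fraction = geno$het_fraction,
    excluded = !(qc_log2$pass && conc$pass)
  )
  structure(list(assay = assay, segments = segments, qc = qc),
            class = "recurcna_pipeline")
}

#' @export
print.recurcna_pipeline <- function(x, ...) {
  cat(sprintf("<recurcna_pipeline> patient %s: %d segments, %s\n",
              x$qc$patient_id, nrow(x$segments),
              if (x$qc$excluded) "EXCLUDED by QC" else "QC pass"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.recurcna_pipeline <- function(x, ...) x$segments

#' @exportS3Method generics::glance
glance.recurcna_pipeline <- function(x, ...) x$qc

#' Run the array pipeline over a cohort
#'
#' Applies [run_array_pipeline()] to each patient's assay and binds results.
#'
#' @param assays Named list of per-patient assay tibbles, or one long tibble
#'   with a `patient_id` column.
#' @param config A [calling_config()].
#' @param seed Optional integer seed; per-patient seeds are derived from it.
#' @return A list with `segments` (all patients' segment calls) and `qc`
#'   (one row per patient).
#' @export
run_cohort_pipeline <- function(assays, config = calling_config(),
                                seed = NULL) {
  if (is.data.frame(assays)) {
    assays <- split(assays, assays$patient_id)
  }
  res <- purrr::imap(assays, function(a, pid) {
    run_array_pipeline(a, config, seed = child_seed(seed, pid))
  })
  list(
    segments = purrr::map(res, "segments") %>% bind_rows(),
    qc = purrr::map(res, "qc") %>% bind_rows()
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
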