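# Readers and writers for the package's plain-text interchange formats.
# All functions return/accept tibbles; writers create parent directories.

ensure_dir <- function(path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  path
}

#' Read / write a probe map (TSV)
#'
#' Columns: `probe_id`, `chrom`, `arm`, `pos`, `population_het`.
#' @param path File path.
#' @param probe_map Probe map tibble.
#' @return `read_probe_map()` returns the tibble; writers return the path
#'   invisibly.
#' @export
read_probe_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    probe_id = "c", chrom = "i", arm = "c",
                    pos = "d", population_het = "d"))
}

#' @rdname read_probe_map
#' @export
write_probe_map <- function(probe_map, path) {
  readr::write_tsv(probe_map, ensure_dir(path))
  invisible(path)
}

#' Read / write probe-level assay data (long TSV)
#'
#' Long format with one row per sample x probe: `sample_id`, `patient_id`,
#' `tissue` ("tumor"/"normal"), `probe_id`, `cn_ratio`, `baf`.
#' [assay_to_long()] and [assay_from_long()] convert between this format and
#' the wide per-patient tibble of [simulate_assay_pair()].
#'
#' @param path File path.
#' @param assay Wide assay tibble; `long` a long tibble; `probe_map` the
#'   probe map used to restore probe order.
#' @return Tibbles; writers return the path invisibly.
#' @export
read_assay_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_assay_table
#' @export
write_assay_table <- function(assay, path) {
  readr::write_tsv(assay_to_long(assay), ensure_dir(path))
  invisible(path)
}

#' @rdname read_assay_table
#' @export
assay_to_long <- function(assay) {
  bind_rows(
    assay %>% transmute(
      sample_id = paste0(.data$patient_id, "_T"),
      patient_id = .data$patient_id, tissue = "tumor",
      probe_id = .data$probe_id, cn_ratio = .data$tumor_cn_ratio,
      baf = .data$tumor_baf),
    assay %>% transmute(
      sample_id = paste0(.data$patient_id, "_N"),
      patient_id = .data$patient_id, tissue = "normal",
      probe_id = .data$probe_id, cn_ratio = .data$normal_cn_ratio,
      baf = .data$normal_baf)
  )
}

#' @rdname read_assay_table
#' @param long Long assay tibble.
#' @export
assay_from_long <- function(long, probe_map) {
  wide <- long %>%
    tidyr::pivot_wider(id_cols = c("patient_id", "probe_id"),
                       names_from = "tissue",
                       values_from = c("cn_ratio", "baf"))
  probe_map %>%
    dplyr::inner_join(wide, by = "probe_id") %>%
    rename(tumor_cn_ratio = "cn_ratio_tumor",
           normal_cn_ratio = "cn_ratio_normal",
           tumor_baf = "baf_tumor", normal_baf = "baf_normal") %>%
    arrange(.data$patient_id, .data$chrom, .data$pos)
}

#' Read / write a cohort table (CSV)
#'
#' Columns as produced by [simulate_cohort()].
#' @param path File path.
#' @param cohort Cohort tibble.
#' @return Tibble / invisible path.
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, ensure_dir(path))
  invisible(path)
}

#' Read / write qPCR Ct records (CSV; empty ct field = missing)
#' @param path File path.
#' @param ct_records Ct tibble (see [simulate_ct_plate()]).
#' @return Tibble / invisible path.
#' @export
read_ct_records <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(ct = "d", replicate = "i",
                                          .default = "c"))
}

#' @rdname read_ct_records
#' @export
write_ct_records <- function(ct_records, path) {
  readr::write_csv(ct_records, ensure_dir(path), na = "")
  invisible(path)
}

#' Read / write a literature study table (CSV)
#' @param path File path.
#' @param studies Study tibble (see [simulate_study_table()]).
#' @return Tibble / invisible path.
#' @export
read_study_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_study_table
#' @export
write_study_table <- function(studies, path) {
  readr::write_csv(studies, ensure_dir(path))
  invisible(path)
}

#' Read / write segment calls as BED6+5
#'
#' Columns: chrom (`chr`-prefixed), start, end (bp, 0-based half-open),
#' name (patient id), score (`round(100 * mean_cn_ratio)`), strand (`.`),
#' then `n_probes`, `n_het`, `mean_mbaf`, `cn_state`, `allelic_class`.
#' @param path File path.
#' @param segments Segment calls with `patient_id` (see [call_segments()]).
#' @return Tibble / invisible path.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- segments %>%
    transmute(
      chrom = paste0("chr", .data$chrom),
      start = as.integer(.data$start_bp),
      end = as.integer(.data$end_bp) + 1L,
      name = .data$patient_id,
      score = as.integer(round(100 * .data$mean_cn_ratio)),
      strand = ".",
      n_probes = .data$n_probes, n_het = .data$n_het,
      mean_mbaf = .data$mean_mbaf, cn_state = .data$cn_state,
      allelic_class = .data$allelic_class
    )
  readr::write_tsv(bed, ensure_dir(path), col_names = FALSE)
  invisible(path)
}

#' @rdname write_segments_bed
#' @export
read_segments_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                      "score", "strand", "n_probes",
                                      "n_het", "mean_mbaf", "cn_state",
                                      "allelic_class"),
                  show_col_types = FALSE) %>%
    mutate(chrom = as.integer(sub("^chr", "", .data$chrom)),
           patient_id = .data$name,
           mean_cn_ratio = .data$score / 100)
}

#' Write truth profiles to JSON
#' @param truth_profiles Named list of truth tibbles.
#' @param path File path.
#' @return Invisible path.
#' @export
write_truth_json <- function(truth_profiles, path) {
  jsonlite::write_json(truth_profiles, ensure_dir(path), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  purrr::map(jsonlite::read_json(path, simplifyVector = TRUE), as_tibble)
}

#' Validate interchange files against their schemas
#'
#' Schema, range and structural checks for the package's file formats:
#' required columns, value ranges (e.g. BAF in \[0, 1\]), probe-position
#' sortedness, and per-sample segment tiling (no gaps/overlaps). Returns all
#' violations found rather than stopping at the first.
#'
#' @param paths Named character vector; names identify the format among
#'   `probes`, `assay`, `cohort`, `ct`, `studies`, `segments`.
#' @return A tibble `file`, `rule`, `detail`; zero rows when everything is
#'   valid.
#' @export
validate_inputs <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    stop_invalid("`paths` must be named by format")
  }
  viol <- list()
  note <- function(file, rule, detail) {
    viol[[length(viol) + 1L]] <<- tibble(file = file, rule = rule,
                                         detail = detail)
  }
  for (i in seq_along(paths)) {
    kind <- names(paths)[i]; path <- paths[[i]]
    if (!file.exists(path)) {
      abort(sprintf("cannot read %s (%s): no such file", path, kind),
            class = c("recurcna_io_error", "recurcna_error"))
    }
    tab <- switch(kind,
      probes = read_probe_map(path),
      assay = read_assay_table(path),
      cohort = read_cohort(path),
      ct = read_ct_records(path),
      studies = read_study_table(path),
      segments = read_segments_bed(path),
      stop_invalid(sprintf("unknown format '%s'", kind)))
    need <- switch(kind,
      probes = c("probe_id", "chrom", "arm", "pos", "population_het"),
      assay = c("sample_id", "patient_id", "tissue", "probe_id",
                "cn_ratio", "baf"),
      cohort = c("patient_id", "group", "tnm", "crm", "sex", "age",
                 "os_time", "os_event", "lrfp_time", "lrfp_event"),
      ct = c("sample_id", "snp_id", "replicate", "channel", "ct"),
      studies = c("study_id", "n_cases", "arm", "gain_fraction",
                  "loss_fraction"),
      segments = c("chrom", "start", "end", "name"))
    miss <- setdiff(need, names(tab))
    if (length(miss) > 0L) {
      note(path, "columns", paste("missing:", paste(miss, collapse = ", ")))
      next
    }
    if (kind == "probes") {
      bad <- tab %>% group_by(.data$chrom) %>%
        summarise(sorted = !is.unsorted(.data$pos, strictly = TRUE)) %>%
        filter(!.data$sorted)
      if (nrow(bad) > 0L) {
        note(path, "sorted", paste("positions not strictly increasing on",
                                   paste(bad$chrom, collapse = ", ")))
      }
      if (any(tab$population_het < 0 | tab$population_het > 1)) {
        note(path, "range", "population_het outside [0, 1]")
      }
    }
    if (kind == "assay") {
      if (any(tab$baf < 0 | tab$baf > 1, na.rm = TRUE)) {
        note(path, "range", "baf outside [0, 1]")
      }
      if (any(tab$cn_ratio < 0, na.rm = TRUE)) {
        note(path, "range", "negative cn_ratio")
      }
      if (!all(tab$tissue %in% c("tumor", "normal"))) {
        note(path, "domain", "tissue must be tumor|normal")
      }
    }
    if (kind == "cohort") {
      tms <- grep("_time$", names(tab), value = TRUE)
      if (any(unlist(tab[tms]) < 0, na.rm = TRUE)) {
        note(path, "range", "negative endpoint time")
      }
      if (!all(tab$group %in% c("C", "L", "D", "LD"))) {
        note(path, "domain", "group must be C|L|D|LD")
      }
    }
    if (kind == "ct") {
      if (any(tab$ct < 0, na.rm = TRUE)) note(path, "range", "negative ct")
      if (!all(tab$channel %in% c("A", "B"))) {
        note(path, "domain", "channel must be A|B")
      }
    }
    if (kind == "studies") {
      fr <- c(tab$gain_fraction, tab$loss_fraction)
      if (any(fr < 0 | fr > 1, na.rm = TRUE)) {
        note(path, "range", "fractions outside [0, 1]")
      }
    }
    if (kind == "segments") {
      bad <- tab %>%
        arrange(.data$name, .data$chrom, .data$start) %>%
        group_by(.data$name, .data$chrom) %>%
        summarise(overlap = any(.data$start < lag(.data$end),
                                na.rm = TRUE), .groups = "drop") %>%
        filter(.data$overlap)
      if (nrow(bad) > 0L) {
        note(path, "tiling",
             sprintf("overlapping segments for %d sample-chromosome pair(s)",
                     nrow(bad)))
      }
      if (any(tab$end <= tab$start)) note(path, "range", "end <= start")
    }
  }
  if (length(viol) == 0L) {
    tibble(file = character(), rule = character(), detail = character())
  } else {
    bind_rows(viol)
  }
}
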