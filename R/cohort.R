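#' Simulate a matched tumor-recurrence patient cohort
#'
#' Generates patients in four recurrence groups — `C` (no recurrence,
#' controls), `L` (local), `D` (distant) and `LD` (local & distant) — with
#' clinical covariates, a matched control for every recurrent patient, and
#' the four survival endpoints (OS, DSS, LRFP, DRFP).
#'
#' Matching criteria are: TNM stage, circumferential-resection-margin (CRM)
#' involvement and sex matched exactly, and age at surgery within
#' `config$max_age_gap` years (default 7, average difference about 2).
#' Controls are generated by age-clustered stratified copying of the
#' recurrent patients (emulating selection of matchable controls from a
#' registry), and each recurrent patient is then assigned its control by
#' greedy nearest-age matching within the exact-covariate stratum
#' (see [match_controls()]). When controls are fewer than recurrent patients
#' a control may serve several of them.
#'
#' Event times are exponential with group-specific hazards and independent
#' censoring; by group definition every `L`/`LD` patient has a local
#' recurrence and every `D`/`LD` patient a distant recurrence within
#' follow-up, and `C` patients have neither.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed (defaults to `config$seed`).
#'
#' @return A tibble with one row per patient: `patient_id`, `group`, `tnm`
#'   ("I"/"II"/"III"), `crm` (logical), `sex` ("male"/"female"), `age`
#'   (years), `matched_control_id` (NA for controls) and
#'   `os_time`/`os_event`, `dss_time`/`dss_event`, `lrfp_time`/`lrfp_event`,
#'   `drfp_time`/`drfp_event` (years, 0/1 flags).
#' @export
#' @examples
#' co <- simulate_cohort(sim_config(), seed = 1)
#' dplyr::count(co, group)
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  with_seed_or_current(seed, {
    n <- config$n_per_group
    rec_groups <- rep(c("L", "D", "LD"), times = n[c("L", "D", "LD")])
    n_rec <- length(rec_groups)
    rec <- tibble(
      group = rec_groups,
      tnm = sample(names(config$tnm_probs), n_rec, TRUE, config$tnm_probs),
      crm = runif(n_rec) < config$p_crm,
      sex = if_else(runif(n_rec) < config$p_male, "male", "female"),
      age = draw_age(n_rec, config)
    )
    controls <- make_matchable_controls(rec, n[["C"]], config)
    patients <- bind_rows(controls, rec) %>%
      mutate(patient_id = sprintf("pt_%03d", row_number())) %>%
      select("patient_id", dplyr::everything())
    patients <- match_controls(patients, max_age_gap = config$max_age_gap)
    events <- draw_event_times(patients$group, config)
    endpoints <- build_endpoints(events, horizon = config$horizon_years)
    bind_cols(patients, endpoints)
  })
}

draw_age <- function(n, config) {
  pmin(pmax(rnorm(n, config$age_mean, config$age_sd),
            config$age_range[1]), config$age_range[2])
}

# Construct n_controls control patients guaranteed to be matchable to the
# recurrent patients: within each exact-covariate stratum, recurrent ages are
# clustered into runs of diameter <= max_age_gap and each cluster receives at
# least one control near its age midpoint; remaining controls are spread over
# clusters by size.
make_matchable_controls <- function(rec, n_controls, config) {
  gap <- config$max_age_gap
  clusters <- rec %>%
    mutate(.stratum = paste(.data$tnm, .data$crm, .data$sex, sep = "/")) %>%
    group_by(.data$.stratum, .data$tnm, .data$crm, .data$sex) %>%
    dplyr::group_modify(function(df, key) {
      ages <- sort(df$age)
      cl <- integer(length(ages)); cur <- 1L; anchor <- ages[1]
      for (i in seq_along(ages)) {
        if (ages[i] - anchor > gap) { cur <- cur + 1L; anchor <- ages[i] }
        cl[i] <- cur
      }
      tibble(age = ages, cluster = cl)
    }) %>%
    ungroup() %>%
    group_by(.data$.stratum, .data$tnm, .data$crm, .data$sex, .data$cluster) %>%
    summarise(n_members = n(), age_lo = min(.data$age), age_hi = max(.data$age),
              .groups = "drop")
  if (nrow(clusters) > n_controls) {
    worst <- clusters$.stratum[which.max(clusters$n_members)]
    abort(
      sprintf(paste0("matching infeasible: %d age-clustered covariate strata ",
                     "need a control but only %d controls are configured ",
                     "(e.g. stratum %s)"),
             nrow(clusters), n_controls, worst),
      class = c("recurcna_matching_failure", "recurcna_error")
    )
  }
  extra <- n_controls - nrow(clusters)
  alloc <- rep(1L, nrow(clusters))
  if (extra > 0) {
    idx <- sample(rep(seq_len(nrow(clusters)), times = clusters$n_members),
                  extra, replace = TRUE)
    alloc <- alloc + tabulate(idx, nbins = nrow(clusters))
  }
  purrr::map(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    mid <- (cl$age_lo + cl$age_hi) / 2
    # jitter bounded so the control stays within `gap` of every cluster
    # member (small margin guards the floating-point boundary)
    bound <- max(gap - (cl$age_hi - cl$age_lo) / 2 - 1e-6, 0.25)
    jit <- pmin(pmax(rnorm(alloc[i], 0, config$age_jitter_sd), -bound), bound)
    tibble(group = "C", tnm = cl$tnm, crm = cl$crm, sex = cl$sex,
           age = pmin(pmax(mid + jit, config$age_range[1]), config$age_range[2]))
  }) %>% bind_rows()
}

#' Greedy matched-control assignment
#'
#' Assigns each recurrent patient (`group` in L/D/LD) a control (`group` C)
#' matching TNM stage, CRM involvement and sex exactly and age within
#' `max_age_gap` years. Recurrent patients are processed in random order
#' (randomness taken from the current RNG stream); each picks the same-stratum
#' control with the fewest prior uses and, among those, the nearest age — so
#' controls are used uniquely whenever there are enough of them.
#'
#' @param patients Tibble with columns `patient_id`, `group`, `tnm`, `crm`,
#'   `sex`, `age`.
#' @param max_age_gap Maximum allowed age difference in years.
#' @return `patients` with a `matched_control_id` column (NA for controls).
#' @export
match_controls <- function(patients, max_age_gap = 7) {
  needed <- c("patient_id", "group", "tnm", "crm", "sex", "age")
  if (!all(needed %in% names(patients))) {
    stop_invalid(paste("`patients` must have columns",
                       paste(needed, collapse = ", ")))
  }
  stratum <- paste(patients$tnm, patients$crm, patients$sex, sep = "/")
  is_ctrl <- patients$group == "C"
  use_count <- setNames(rep(0L, sum(is_ctrl)), patients$patient_id[is_ctrl])
  match_id <- rep(NA_character_, nrow(patients))
  rec_idx <- sample(which(!is_ctrl))
  for (i in rec_idx) {
    cand <- which(is_ctrl & stratum == stratum[i] &
                    abs(patients$age - patients$age[i]) <= max_age_gap + 1e-9)
    if (length(cand) == 0L) {
      abort(sprintf("matching failure: no eligible control in stratum %s (age %.1f +/- %g)",
                    stratum[i], patients$age[i], max_age_gap),
            class = c("recurcna_matching_failure", "recurcna_error"))
    }
    uses <- use_count[patients$patient_id[cand]]
    cand <- cand[uses == min(uses)]
    best <- cand[which.min(abs(patients$age[cand] - patients$age[i]))]
    match_id[i] <- patients$patient_id[best]
    use_count[match_id[i]] <- use_count[match_id[i]] + 1L
  }
  patients$matched_control_id <- match_id
  patients
}

# Raw event-date draws per patient given group labels. Times in years.
draw_event_times <- function(groups, config) {
  n <- length(groups)
  death_time <- rexp(n, config$os_rate[groups])
  death_cause <- if_else(runif(n) < config$p_cancer_death[groups],
                         "cancer", "other")
  censor_time <- if (config$censor_rate > 0) rexp(n, config$censor_rate)
                 else rep(Inf, n)
  horizon <- config$horizon_years
  obs_end <- pmin(death_time, censor_time, horizon)
  local_rec_time <- rep(NA_real_, n)
  has_local <- groups %in% c("L", "LD")
  local_rec_time[has_local] <- rtrunc_exp(sum(has_local), config$lrfp_rate,
                                          obs_end[has_local])
  distant_rec_time <- rep(NA_real_, n)
  has_dist <- groups %in% c("D", "LD")
  distant_rec_time[has_dist] <- rtrunc_exp(sum(has_dist), config$drfp_rate,
                                           obs_end[has_dist])
  tibble(death_time = if_else(is.finite(death_time), death_time, NA_real_),
         death_cause = death_cause,
         local_rec_time = local_rec_time,
         distant_rec_time = distant_rec_time,
         censor_time = censor_time)
}

# Exponential(rate) truncated to (0, upper]; inverse-CDF sampling.
rtrunc_exp <- function(n, rate, upper) {
  u <- runif(n)
  -log(1 - u * (1 - exp(-rate * upper))) / rate
}
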