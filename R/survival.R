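#' Construct the four survival endpoints from raw event dates
#'
#' Endpoint definitions: OS (overall survival) is time from surgery to death
#' by any cause; DSS (disease-specific survival) to death by the cancer,
#' with other-cause deaths censored at the death time; LRFP (local
#' recurrence-free period) to the first local recurrence, with death before
#' recurrence censoring at death; DRFP analogous for distant recurrence.
#' Everything is administratively censored at `horizon` years.
#'
#' @param events Tibble with one row per patient and columns `death_time`
#'   (NA if alive), `death_cause` ("cancer"/"other"), `local_rec_time`,
#'   `distant_rec_time` (NA if no such recurrence) and `censor_time`
#'   (loss to follow-up, may be `Inf`). Times in years from surgery.
#' @param horizon Follow-up horizon in years (default 12).
#' @return Tibble with `os_time`, `os_event`, `dss_time`, `dss_event`,
#'   `lrfp_time`, `lrfp_event`, `drfp_time`, `drfp_event` (times in years,
#'   events 0/1). DSS events are a subset of OS events by construction.
#' @export
#' @examples
#' build_endpoints(tibble::tibble(
#'   death_time = 3, death_cause = "cancer",
#'   local_rec_time = NA_real_, distant_rec_time = NA_real_,
#'   censor_time = Inf))
build_endpoints <- function(events, horizon = 12) {
  tm <- events[c("death_time", "local_rec_time", "distant_rec_time",
                 "censor_time")]
  if (any(unlist(tm) < 0, na.rm = TRUE)) {
    stop_invalid("event times must be non-negative",
                 class = "recurcna_invalid_input")
  }
  admin <- pmin(dplyr::coalesce(events$censor_time, Inf), horizon)
  death <- dplyr::coalesce(events$death_time, Inf)
  os_time <- pmin(death, admin)
  os_event <- as.integer(death <= admin)
  dss_event <- as.integer(os_event == 1L & events$death_cause == "cancer")
  rec_endpoint <- function(rec) {
    rec <- dplyr::coalesce(rec, Inf)
    stop_at <- pmin(death, admin)
    tibble(time = pmin(rec, stop_at),
           event = as.integer(rec <= stop_at))
  }
  loc <- rec_endpoint(events$local_rec_time)
  dis <- rec_endpoint(events$distant_rec_time)
  tibble(
    os_time = os_time, os_event = os_event,
    dss_time = os_time, dss_event = dss_event,
    lrfp_time = loc$time, lrfp_event = loc$event,
    drfp_time = dis$time, drfp_event = dis$event
  )
}

#' Cox proportional-hazards model for a per-patient marker
#'
#' Fits a Cox model (Efron tie handling) of one endpoint on a per-patient
#' marker, either univariate or multivariate with the predetermined clinical
#' covariates — TNM stage (indicator contrasts II and III vs I), age at
#' surgery (continuous years), sex and CRM involvement — included regardless
#' of significance.
#'
#' @param endpoint_data Tibble with columns `time`, `event`, `marker`, and
#'   (for multivariate mode) `tnm`, `age`, `sex`, `crm`.
#' @param mode `"univariate"` or `"multivariate"`.
#' @param conf_level Confidence level of the hazard-ratio interval.
#' @return An object of class `recurcna_coxfit` wrapping the
#'   [survival::coxph()] fit; `tidy()` gives one row per term with `term`,
#'   `hr`, `ci_low`, `ci_high`, `p_value`; `glance()` gives `n`, `n_events`,
#'   `converged`, `mode`.
#' @export
fit_marker_model <- function(endpoint_data,
                             mode = c("univariate", "multivariate"),
                             conf_level = 0.95) {
  mode <- match.arg(mode)
  needed <- c("time", "event", "marker")
  if (mode == "multivariate") needed <- c(needed, "tnm", "age", "sex", "crm")
  miss <- setdiff(needed, names(endpoint_data))
  if (length(miss) > 0L) {
    stop_invalid(paste("missing columns:", paste(miss, collapse = ", ")))
  }
  if (sum(endpoint_data$event) == 0L) {
    abort("no events in endpoint data; model undefined",
          class = c("recurcna_no_events", "recurcna_error"))
  }
  df <- as.data.frame(endpoint_data)
  if (mode == "multivariate") {
    df$tnm <- factor(df$tnm, levels = c("I", "II", "III"))
    fml <- survival::Surv(time, event) ~ marker + tnm + age + sex + crm
  } else {
    fml <- survival::Surv(time, event) ~ marker
  }
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w))) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    }
  )
  structure(list(fit = fit, mode = mode, conf_level = conf_level,
                 converged = converged),
            class = "recurcna_coxfit")
}

#' @exportS3Method generics::tidy
tidy.recurcna_coxfit <- function(x, ...) {
  s <- summary(x$fit, conf.int = x$conf_level)
  co <- s$coefficients
  ci <- s$conf.int
  tibble(
    term = rownames(co),
    estimate = co[, "coef"],
    hr = co[, "exp(coef)"],
    ci_low = ci[, 3],
    ci_high = ci[, 4],
    p_value = co[, "Pr(>|z|)"]
  )
}

#' @exportS3Method generics::glance
glance.recurcna_coxfit <- function(x, ...) {
  tibble(n = x$fit$n, n_events = x$fit$nevent,
         converged = x$converged, mode = x$mode)
}

#' @export
print.recurcna_coxfit <- function(x, ...) {
  cat(sprintf("<recurcna_coxfit> %s Cox model, %d events / %d patients\n",
              x$mode, x$fit$nevent, x$fit$n))
  print(tidy(x))
  invisible(x)
}

#' Assemble endpoint data for a marker from a cohort table
#'
#' Convenience join of a simulated (or read) cohort with a per-patient
#' marker, selecting one endpoint's time/event pair.
#'
#' @param cohort Cohort tibble (see [simulate_cohort()]).
#' @param marker Tibble `patient_id`, `marker`.
#' @param endpoint One of "OS", "DSS", "LRFP", "DRFP".
#' @return Tibble ready for [fit_marker_model()].
#' @export
endpoint_dataset <- function(cohort, marker,
                             endpoint = c("OS", "DSS", "LRFP", "DRFP")) {
  endpoint <- match.arg(endpoint)
  pre <- c(OS = "os", DSS = "dss", LRFP = "lrfp", DRFP = "drfp")[[endpoint]]
  cohort %>%
    dplyr::inner_join(marker, by = "patient_id") %>%
    mutate(time = .data[[paste0(pre, "_time")]],
           event = .data[[paste0(pre, "_event")]])
}
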