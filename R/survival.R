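#' Derive survival records from a clinical table
#'
#' Dead patients contribute (`days_to_death`, event); alive patients
#' contribute (`days_to_last_follow_up`, censored). Patients with missing
#' vital status, or with a missing or non-positive time for their status,
#' carry no usable time-to-event information and are excluded; the exclusion
#' count is recorded in the `"n_excluded"` attribute and reported via
#' `message()`.
#'
#' @param clinical [clinical_table()] object
#' @return data.frame (`patient_id`, `time` in days > 0, `event` logical)
#'   with attribute `n_excluded`
#' @export
build_survival_records <- function(clinical) {
  stopifnot(inherits(clinical, "cki_clinical"))
  time <- ifelse(clinical$vital_status == "dead",
                 clinical$days_to_death, clinical$days_to_last_follow_up)
  event <- clinical$vital_status == "dead"
  ok <- !is.na(clinical$vital_status) & !is.na(time) & time > 0
  n_excl <- sum(!ok)
  if (n_excl > 0)
    message(sprintf("survival: excluded %d patient(s) without usable vital status/time",
                    n_excl))
  out <- data.frame(patient_id = clinical$patient_id[ok],
                    time = as.numeric(time[ok]), event = event[ok],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excl
  out
}

#' Kaplan-Meier product-limit curve
#'
#' Estimates S(t) = prod over event times t_i <= t of (1 - d_i / n_i).
#' Deaths tied with censorings at the same time are processed first (the
#' standard convention). The curve is reported at observed event times only.
#'
#' @param records survival records ([build_survival_records()] output or any
#'   data.frame with `time` and `event`)
#' @return list of class `cki_km`: `event_times`, `survival` (non-increasing
#'   in \[0, 1\]), `at_risk`, `n_events`
#' @export
km_curve <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop_cki("no survival records")
  sf <- survival::survfit(survival::Surv(records$time, records$event) ~ 1)
  keep <- sf$n.event > 0
  structure(list(event_times = sf$time[keep], survival = sf$surv[keep],
                 at_risk = sf$n.risk[keep], n_events = sf$n.event[keep]),
            class = "cki_km")
}

#' @export
print.cki_km <- function(x, ...) {
  cat(sprintf("<cki_km> %d event times; S(last) = %.3f\n",
              length(x$event_times),
              if (length(x$survival)) x$survival[length(x$survival)] else 1))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank: chi-squared statistic
#' `(sum(O - E))^2 / sum(V)` over shared event times, referred to a
#' chi-square distribution with 1 degree of freedom.
#'
#' @param records_a,records_b survival record data.frames for the two groups
#' @return list with `chi2` and `p_value`
#' @export
logrank_test <- function(records_a, records_b) {
  if (nrow(records_a) == 0 || nrow(records_b) == 0)
    stop_cki("both log-rank groups must be non-empty")
  time <- c(records_a$time, records_b$time)
  event <- c(records_a$event, records_b$event)
  grp <- rep(c(0L, 1L), c(nrow(records_a), nrow(records_b)))
  if (!any(event)) return(list(chi2 = 0, p_value = 1))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Expression-quartile survival component
#'
#' Splits patients at the 25th and 75th percentiles of the gene's
#' expression (linear-interpolation percentiles; ties at the boundary go to
#' the extreme arms), discards the middle half, and compares the two arms
#' with the log-rank test. The component is 1 iff the log-rank p value is
#' below `alpha` *and* the high-expression arm is the worse arm, judged by
#' restricted mean survival up to the shorter arm's maximum follow-up time;
#' otherwise 0. With fewer than `min_patients` usable patients, or fewer
#' than 2 patients per arm, the component is 0 with detail
#' `"insufficient"`.
#'
#' @param expression named numeric vector of per-patient expression
#' @param records survival record data.frame
#' @param alpha significance level (default 0.05)
#' @param quartiles lower/upper percentile split (default c(0.25, 0.75))
#' @param min_patients minimum patients with both expression and survival
#' @return list: `score` (0/1), `p_value`, `chi2`, `n_high`, `n_low`,
#'   `rmst_high`, `rmst_low`, `detail` ("ok", "insufficient",
#'   "not_significant" or "protective")
#' @export
survival_score <- function(expression, records, alpha = 0.05,
                           quartiles = c(0.25, 0.75), min_patients = 8) {
  shared <- intersect(names(expression), records$patient_id)
  out <- list(score = 0, p_value = NA_real_, chi2 = NA_real_,
              n_high = 0L, n_low = 0L, rmst_high = NA_real_,
              rmst_low = NA_real_, detail = "insufficient")
  if (length(shared) < min_patients) return(out)
  expr <- expression[shared]
  rec <- records[match(shared, records$patient_id), , drop = FALSE]
  qs <- stats::quantile(expr, probs = quartiles, type = 7, names = FALSE)
  low <- expr <= qs[1]
  high <- expr >= qs[2]
  out$n_high <- sum(high); out$n_low <- sum(low)
  if (out$n_high < 2 || out$n_low < 2) return(out)
  rec_h <- rec[high, , drop = FALSE]
  rec_l <- rec[low, , drop = FALSE]
  lr <- logrank_test(rec_h, rec_l)
  out$p_value <- lr$p_value; out$chi2 <- lr$chi2
  tau <- min(max(rec_h$time), max(rec_l$time))
  out$rmst_high <- rmst_from_km(rec_h$time, rec_h$event, tau)
  out$rmst_low <- rmst_from_km(rec_l$time, rec_l$event, tau)
  if (lr$p_value >= alpha) {
    out$detail <- "not_significant"
  } else if (out$rmst_high < out$rmst_low) {
    out$score <- 1
    out$detail <- "ok"
  } else {
    out$detail <- "protective"
  }
  out
}
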