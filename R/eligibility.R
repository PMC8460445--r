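#' Apply retrospective-cohort eligibility rules
#'
#' A woman is eligible when she has a first invasive breast cancer without
#' known metastatic disease at least one year before her baseline
#' (ascertainment) age. Exclusions, each logged once per applied rule:
#'
#' * `missing_baseline_age` -- no baseline age available;
#' * `synchronous_cbc` -- contralateral cancer within one year of the first
#'   primary, judged on exact dates (`date_bc1`/`date_cbc`, decimal years)
#'   when present, otherwise on the age difference;
#' * `metastatic_bc1` -- known metastatic first tumor (unknown status is
#'   retained, assumed non-metastatic);
#' * `baseline_within_year` -- first cancer less than one year before
#'   baseline, so the subject can never enter the risk set.
#'
#' @param records Subject records (see [read_phenotypes()]).
#' @return A list: `records` (eligible rows) and `exclusions`
#'   (data.frame `subject_id`, `reason`).
#' @export
apply_eligibility <- function(records) {
  if (!"age_bc1" %in% names(records)) stop("records must carry age_bc1")
  if (any(!is.na(records$age_cbc) & records$age_cbc < records$age_bc1)) {
    stop("data integrity: age_cbc earlier than age_bc1")
  }
  exclusions <- data.frame(subject_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  note <- function(ids, reason) {
    rbind(exclusions, data.frame(subject_id = ids, reason = reason,
                                 stringsAsFactors = FALSE))
  }
  miss_base <- is.na(records$age_baseline)
  if (any(miss_base)) exclusions <- note(records$subject_id[miss_base],
                                         "missing_baseline_age")
  gap <- if (!is.null(records$date_cbc) && !is.null(records$date_bc1)) {
    ifelse(!is.na(records$date_cbc) & !is.na(records$date_bc1),
           records$date_cbc - records$date_bc1,
           records$age_cbc - records$age_bc1)
  } else {
    records$age_cbc - records$age_bc1
  }
  synchronous <- !is.na(gap) & gap < 1
  if (any(synchronous)) exclusions <- note(records$subject_id[synchronous],
                                           "synchronous_cbc")
  metast <- !is.na(records$metastatic_bc1) & records$metastatic_bc1 == "yes"
  if (any(metast)) exclusions <- note(records$subject_id[metast],
                                      "metastatic_bc1")
  late_base <- !miss_base & (records$age_baseline - records$age_bc1 < 1)
  if (any(late_base)) exclusions <- note(records$subject_id[late_base],
                                         "baseline_within_year")
  keep <- !(miss_base | synchronous | metast | late_base)
  list(records = records[keep, , drop = FALSE], exclusions = exclusions)
}

#' Build left-truncated risk intervals
#'
#' Time runs in years since the first breast cancer; every woman enters the
#' risk set at 1.0 year (earlier time is the synchronous-exclusion window).
#' Exit is the qualifying contralateral event time, or the earliest of
#' baseline age, risk-reducing mastectomy and death (plus distant relapse
#' under the sensitivity option), minus the age at first cancer.
#'
#' Event definitions:
#' * `all_cbc` -- any metachronous CBC, invasive or in situ;
#' * `invasive_only` -- in situ CBCs are censored at their diagnosis age;
#' * `er_positive` / `er_negative` -- CBCs of the alternative (or unknown)
#'   ER status are censored at the CBC age.
#'
#' Under `censor_distant_relapse`, women whose relapse precedes the 1-year
#' entry are dropped (reason `relapse_window`); others are additionally
#' censored at relapse. Subjects whose exit does not exceed entry after
#' censoring are dropped with reason `exit_before_entry`. Birth-cohort
#' quartiles (`birth_q`) are computed on the analysis cohort's observed
#' birth-year distribution (linear-interpolation quantiles, recorded in the
#' `"birth_quartiles"` attribute).
#'
#' @param records Eligible subject records (from [apply_eligibility()]),
#'   carrying a standardized PRS column `z`.
#' @param event_definition One of `all_cbc`, `invasive_only`, `er_positive`,
#'   `er_negative`.
#' @param sensitivity `"none"` or `"censor_distant_relapse"`.
#' @return data.frame with `subject_id`, `entry`, `exit`, `event`,
#'   `stratum`, `cluster`, `z`, `age_bc1`, `birth_year`, `birth_q`,
#'   `variant_class`; attribute `"dropped"` logs removed subjects.
#' @export
build_risk_intervals <- function(records,
                                 event_definition = c("all_cbc", "invasive_only",
                                                      "er_positive", "er_negative"),
                                 sensitivity = c("none", "censor_distant_relapse")) {
  event_definition <- match.arg(event_definition)
  sensitivity <- match.arg(sensitivity)
  if (!"z" %in% names(records)) stop("records must carry a standardized PRS column z")
  dropped <- data.frame(subject_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)

  cens_age <- pmin(records$age_baseline,
                   ifelse(is.na(records$age_rrm), Inf, records$age_rrm),
                   ifelse(is.na(records$age_death), Inf, records$age_death))
  if (sensitivity == "censor_distant_relapse") {
    relapse <- records$age_distant_relapse
    early <- !is.na(relapse) & (relapse - records$age_bc1) <= 1
    if (any(early)) {
      dropped <- rbind(dropped, data.frame(
        subject_id = records$subject_id[early], reason = "relapse_window",
        stringsAsFactors = FALSE))
      records <- records[!early, , drop = FALSE]
      cens_age <- cens_age[!early]
      relapse <- relapse[!early]
    }
    cens_age <- pmin(cens_age, ifelse(is.na(relapse), Inf, relapse))
  }

  has_cbc <- !is.na(records$age_cbc)
  qualifies <- has_cbc & switch(
    event_definition,
    all_cbc = TRUE,
    invasive_only = !is.na(records$cbc_invasive) & records$cbc_invasive,
    er_positive = !is.na(records$cbc_er_status) &
      records$cbc_er_status == "positive",
    er_negative = !is.na(records$cbc_er_status) &
      records$cbc_er_status == "negative"
  )
  # Non-qualifying CBCs censor the subject at the CBC age (in situ under
  # invasive_only; alternative/unknown ER under the ER-specific definitions).
  cbc_censor <- has_cbc & !qualifies & event_definition != "all_cbc"
  cens_age <- ifelse(cbc_censor, pmin(cens_age, records$age_cbc), cens_age)

  event <- qualifies & (records$age_cbc <= cens_age)
  exit_age <- ifelse(event, records$age_cbc, cens_age)
  exit <- exit_age - records$age_bc1

  ok <- exit > 1
  if (any(!ok)) {
    dropped <- rbind(dropped, data.frame(
      subject_id = records$subject_id[!ok], reason = "exit_before_entry",
      stringsAsFactors = FALSE))
  }
  records <- records[ok, , drop = FALSE]
  out <- data.frame(
    subject_id = records$subject_id,
    entry = rep(1.0, nrow(records)),
    exit = exit[ok],
    event = as.integer(event[ok]),
    stratum = records$country,
    cluster = records$family_id,
    z = records$z,
    age_bc1 = records$age_bc1,
    birth_year = records$birth_year %||% NA_integer_,
    stringsAsFactors = FALSE
  )
  if (!is.null(records$variant_class)) out$variant_class <- records$variant_class
  if (all(is.na(out$birth_year))) {
    out$birth_q <- factor(rep("Q1", nrow(out)))
    attr(out, "birth_quartiles") <- NULL
  } else {
    qs <- stats::quantile(out$birth_year, c(0.25, 0.5, 0.75), na.rm = TRUE,
                          type = 7)
    br <- unique(c(-Inf, qs, Inf)) # degenerate distributions collapse levels
    out$birth_q <- cut(out$birth_year, br,
                       labels = paste0("Q", seq_len(length(br) - 1)),
                       right = TRUE)
    attr(out, "birth_quartiles") <- qs
  }
  attr(out, "event_definition") <- event_definition
  attr(out, "sensitivity") <- sensitivity
  attr(out, "dropped") <- dropped
  out
}
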