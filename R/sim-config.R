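#' Simulation configuration for a carrier-consortium-style retrospective CBC cohort
#'
#' Bundles the generative truth (per-SD log hazard ratio, age interaction,
#' baseline hazard), the cohort geometry (sample size, family structure,
#' country strata) and the observation process (censoring lags, risk-reducing
#' mastectomy, death, covariate missingness). Defaults reproduce the scale and
#' mix of the BRCA1 carrier series: 6,591 women with a first invasive breast
#' cancer, ~21% of whom develop a metachronous contralateral breast cancer,
#' clustered in families (about 9% of families contribute more than one
#' woman), diagnosed on average at 41.8 years, followed for a median of about
#' 6 years after the 1-year entry.
#'
#' @param n_subjects Number of women.
#' @param n_variants Number of PRS variants in the simulated weight panel.
#' @param target_event_fraction Desired fraction with a CBC event; the
#'   baseline hazard is rescaled so the expected event fraction matches
#'   (set `calibrate_events = FALSE` to use `baseline_hazard` as-is).
#' @param beta_true Generative log hazard ratio per SD of the PRS.
#' @param gamma_true Generative log hazard ratio per year of age at first BC
#'   for the PRS-by-age interaction (hazard multiplier
#'   `exp((beta + gamma * age_bc1) * z)`).
#' @param baseline_hazard A [piecewise_hazard()] for time since first BC, or
#'   a single rate (one piece from the 1-year entry).
#' @param age_bc1_mean,age_bc1_sd Mean/SD (years) of age at first BC, drawn
#'   from a normal truncated to `age_bc1_range`.
#' @param age_bc1_range Support of the age-at-first-BC distribution.
#' @param n_countries Number of country strata.
#' @param country_probs Mixture weights over countries (default: geometric
#'   decay, mimicking a few large and many small contributing studies).
#' @param family_size_probs Probabilities of family sizes 1, 2, 3.
#' @param median_followup Median administrative follow-up (years beyond the
#'   1-year entry) before the baseline-age censoring; exponential lag.
#' @param p_rrm,rrm_mean_lag Probability of bilateral risk-reducing
#'   mastectomy and mean lag (years after entry) of its age.
#' @param p_death,death_mean_lag Same for death before baseline.
#' @param insitu_fraction Fraction of simulated CBCs that are in situ.
#' @param er_fractions Named fractions (`positive`, `negative`, `unknown`) of
#'   CBC ER status.
#' @param missingness_rates Named per-covariate missing fractions applied by
#'   [inject_missingness()].
#' @param calibrate_events Rescale the baseline hazard so the expected event
#'   fraction equals `target_event_fraction`.
#' @param seed Master seed; all stages derive child seeds from it.
#' @return A `cbc_sim_config` list.
#' @export
sim_config <- function(n_subjects = 6591,
                       n_variants = 313,
                       target_event_fraction = 1402 / 6591,
                       beta_true = log(1.12),
                       gamma_true = 0,
                       baseline_hazard = 0.03,
                       age_bc1_mean = 41.8,
                       age_bc1_sd = 10,
                       age_bc1_range = c(18, 85),
                       n_countries = 5,
                       country_probs = NULL,
                       family_size_probs = c(0.906, 0.080, 0.014),
                       median_followup = 6.0,
                       p_rrm = 0.03, rrm_mean_lag = 5,
                       p_death = 0.008, death_mean_lag = 5,
                       insitu_fraction = 0.10,
                       er_fractions = c(positive = 0.07, negative = 0.32,
                                        unknown = 0.61),
                       missingness_rates = c(er_bc1 = 0.56, node_status = 0.55,
                                             tumor_size = 0.59, chemo = 0.68,
                                             family_history = 0.45),
                       calibrate_events = TRUE,
                       seed = 1L) {
  assert_count(n_subjects)
  assert_count(n_variants)
  assert_prop(target_event_fraction)
  if (target_event_fraction <= 0 || target_event_fraction >= 1) {
    stop("target_event_fraction must be in (0, 1)")
  }
  assert_prop(family_size_probs)
  if (abs(sum(family_size_probs) - 1) > 1e-8) {
    stop("family_size_probs must sum to 1")
  }
  assert_prop(missingness_rates)
  assert_count(n_countries)
  if (is.numeric(baseline_hazard) && !inherits(baseline_hazard, "cbc_hazard")) {
    baseline_hazard <- piecewise_hazard(baseline_hazard)
  }
  if (is.null(country_probs)) {
    country_probs <- 0.5^seq_len(n_countries)
  }
  country_probs <- country_probs / sum(country_probs)
  if (abs(sum(er_fractions) - 1) > 1e-8) stop("er_fractions must sum to 1")
  structure(list(
    n_subjects = as.integer(n_subjects), n_variants = as.integer(n_variants),
    target_event_fraction = target_event_fraction,
    beta_true = beta_true, gamma_true = gamma_true,
    baseline_hazard = baseline_hazard,
    age_bc1_mean = age_bc1_mean, age_bc1_sd = age_bc1_sd,
    age_bc1_range = age_bc1_range,
    n_countries = as.integer(n_countries), country_probs = country_probs,
    family_size_probs = family_size_probs,
    median_followup = median_followup,
    p_rrm = p_rrm, rrm_mean_lag = rrm_mean_lag,
    p_death = p_death, death_mean_lag = death_mean_lag,
    insitu_fraction = insitu_fraction, er_fractions = er_fractions,
    missingness_rates = missingness_rates,
    calibrate_events = isTRUE(calibrate_events),
    seed = as.integer(seed)
  ), class = "cbc_sim_config")
}

#' @export
print.cbc_sim_config <- function(x, ...) {
  cat("CBC cohort simulation config\n")
  cat(sprintf("  n = %d subjects, %d variants, target event fraction %.3f\n",
              x$n_subjects, x$n_variants, x$target_event_fraction))
  cat(sprintf("  beta_true = %.4f (HR/SD %.3f), gamma_true = %.5f per year\n",
              x$beta_true, exp(x$beta_true), x$gamma_true))
  cat(sprintf("  age at first BC ~ truncN(%.1f, %.1f) on [%g, %g]\n",
              x$age_bc1_mean, x$age_bc1_sd,
              x$age_bc1_range[1], x$age_bc1_range[2]))
  cat(sprintf("  %d countries, family sizes P(1,2,3) = (%s), seed %d\n",
              x$n_countries, paste(x$family_size_probs, collapse = ", "),
              x$seed))
  invisible(x)
}
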