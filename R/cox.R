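# Association models: country-stratified, family-clustered Cox fits on
# left-truncated intervals, plus the diagnostics that accompany them.

surv_formula <- function(rhs, adjust_birth_cohort, data) {
  terms <- rhs
  if (adjust_birth_cohort && "birth_q" %in% names(data) &&
      nlevels(droplevels(factor(data$birth_q))) > 1) {
    terms <- c(terms, "birth_q")
  }
  terms <- c(terms, "strata(stratum)", "cluster(cluster)")
  stats::as.formula(paste("survival::Surv(entry, exit, event) ~",
                          paste(terms, collapse = " + ")),
                    env = parent.frame())
}

new_coxfit <- function(fit, data, ties) {
  co <- stats::coef(fit)
  robust_se <- stats::setNames(sqrt(diag(fit$var)), names(co))
  naive_se <- stats::setNames(sqrt(diag(fit$naive.var %||% fit$var)),
                              names(co))
  zstat <- co / robust_se
  structure(list(
    coefficients = co,
    robust_se = robust_se,
    naive_se = naive_se,
    hr = exp(co),
    ci95_low = exp(co - 1.96 * robust_se),
    ci95_high = exp(co + 1.96 * robust_se),
    p = 2 * stats::pnorm(-abs(zstat)),
    n_subjects = fit$n,
    n_events = fit$nevent,
    strata_var = "stratum", cluster_var = "cluster",
    ties_method = ties,
    loglik = fit$loglik,
    cox = fit
  ), class = "cbc_coxfit")
}

#' @export
print.cbc_coxfit <- function(x, ...) {
  cat(sprintf("Stratified cluster-robust Cox fit (%d subjects, %d events)\n",
              x$n_subjects, x$n_events))
  tab <- data.frame(
    coef = x$coefficients, robust_se = x$robust_se, HR = x$hr,
    lower95 = x$ci95_low, upper95 = x$ci95_high, p = x$p
  )
  print(round(tab, 4))
  invisible(x)
}

#' Tidy a Cox fit into one row per term
#'
#' @param fit A `cbc_coxfit`.
#' @return data.frame with term, coefficient, robust SE, HR, CI and p.
#' @export
tidy_coxfit <- function(fit) {
  data.frame(
    term = names(fit$coefficients),
    coef = unname(fit$coefficients),
    robust_se = unname(fit$robust_se),
    hr = unname(fit$hr),
    ci95_low = unname(fit$ci95_low),
    ci95_high = unname(fit$ci95_high),
    p = unname(fit$p),
    n_subjects = fit$n_subjects,
    n_events = fit$n_events,
    stringsAsFactors = FALSE
  )
}

#' Fit the continuous-PRS Cox model
#'
#' Cox partial likelihood with delayed entry (left truncation), stratified
#' by country, adjusted for birth-cohort quartiles, with the sandwich
#' variance aggregated over family clusters. Ties use the Efron
#' approximation by default.
#'
#' @param intervals Risk intervals from [build_risk_intervals()].
#' @param adjust_birth_cohort Include the `birth_q` quartile factor.
#' @param ties Tie-handling method passed to [survival::coxph()].
#' @return A `cbc_coxfit`.
#' @export
fit_cox_continuous <- function(intervals, adjust_birth_cohort = TRUE,
                               ties = "efron") {
  if (any(!is.finite(intervals$z))) stop("non-finite z in intervals")
  if (sum(intervals$event) == 0) stop("no events in any stratum")
  f <- surv_formula("z", adjust_birth_cohort, intervals)
  fit <- survival::coxph(f, data = intervals, ties = ties, robust = TRUE, x = TRUE, y = TRUE)
  new_coxfit(fit, intervals, ties)
}

#' PRS percentile bands from the unilateral-case distribution
#'
#' Band edges are the 5/10/20/40/60/80/90/95 percentiles
#' (linear-interpolation quantiles) of the standardized PRS among
#' unilateral breast cancer cases; bands are half-open `[lower, upper)`,
#' with 40-60 the reference.
#'
#' @param z_ubc Standardized PRS of unilateral cases (>= 100 values).
#' @return A `cbc_percentile_bands` object.
#' @export
compute_percentile_bands <- function(z_ubc) {
  z_ubc <- z_ubc[is.finite(z_ubc)]
  if (length(z_ubc) < 100) stop("need at least 100 unilateral cases")
  probs <- c(0.05, 0.10, 0.20, 0.40, 0.60, 0.80, 0.90, 0.95)
  edges <- stats::quantile(z_ubc, probs, type = 7, names = FALSE)
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("too few unique PRS values to form strictly increasing band edges")
  }
  labels <- c("0-5", "5-10", "10-20", "20-40", "40-60", "60-80", "80-90",
              "90-95", "95-100")
  structure(list(edges = edges, probs = probs, labels = labels,
                 reference = "40-60", quantile_type = 7L),
            class = "cbc_percentile_bands")
}

#' Assign standardized PRS values to percentile bands
#'
#' @param bands A [compute_percentile_bands()] object.
#' @param z Standardized PRS values.
#' @return Factor with band labels, reference level `40-60`.
#' @export
assign_bands <- function(bands, z) {
  f <- cut(z, breaks = c(-Inf, bands$edges, Inf), labels = bands$labels,
           right = FALSE)
  stats::relevel(f, ref = bands$reference)
}

#' Fit the categorical-PRS Cox model
#'
#' Indicator coding for the percentile bands with 40-60 omitted, same
#' strata, clustering and adjustment as the continuous fit. Empty bands are
#' reported with `NA` estimates; the fit proceeds on the remaining bands.
#'
#' @param intervals Risk intervals.
#' @param bands Bands from [compute_percentile_bands()].
#' @inheritParams fit_cox_continuous
#' @return A `cbc_coxfit`; `$band_table` maps band labels to estimates
#'   (reference HR fixed at 1).
#' @export
fit_cox_categorical <- function(intervals, bands, adjust_birth_cohort = TRUE,
                                ties = "efron") {
  intervals$prs_band <- assign_bands(bands, intervals$z)
  present <- table(intervals$prs_band) > 0
  intervals$prs_band <- droplevels(intervals$prs_band)
  f <- surv_formula("prs_band", adjust_birth_cohort, intervals)
  fit <- survival::coxph(f, data = intervals, ties = ties, robust = TRUE, x = TRUE, y = TRUE)
  out <- new_coxfit(fit, intervals, ties)
  tab <- data.frame(band = bands$labels, hr = NA_real_, ci95_low = NA_real_,
                    ci95_high = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  tab[tab$band == bands$reference, c("hr", "ci95_low", "ci95_high")] <- 1
  for (b in setdiff(bands$labels, bands$reference)) {
    term <- paste0("prs_band", b)
    if (term %in% names(out$coefficients)) {
      tab[tab$band == b, c("hr", "ci95_low", "ci95_high", "p")] <-
        c(out$hr[[term]], out$ci95_low[[term]], out$ci95_high[[term]],
          out$p[[term]])
    }
  }
  out$band_table <- tab
  out$empty_bands <- names(present)[!present]
  out
}

#' Band hazard ratios predicted from a continuous per-SD effect
#'
#' Under a standard-normal PRS and log-linear hazard `exp(beta * z)`, the
#' expected hazard ratio of band B relative to the reference band is the
#' ratio of truncated-normal expectations
#' `E[exp(beta z) | z in B] / E[exp(beta z) | z in ref]`, computed by
#' numerical quadrature (absolute tolerance 1e-8). This is the "gray line"
#' against which the categorical fit is compared.
#'
#' @param beta Log hazard ratio per SD.
#' @param bands Bands object (theoretical normal quantiles of its
#'   probabilities are used, not the empirical edges).
#' @return data.frame `band`, `hr`.
#' @export
predict_band_hrs <- function(beta, bands) {
  probs <- c(0, bands$probs, 1)
  mean_exp <- function(a, b) {
    stats::integrate(function(x) exp(beta * x + stats::dnorm(x, log = TRUE)),
                     a, b, abs.tol = 1e-8, rel.tol = 1e-10)$value /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  qa <- stats::qnorm(probs[-length(probs)])
  qb <- stats::qnorm(probs[-1])
  e <- mapply(mean_exp, qa, qb)
  ref <- which(bands$labels == bands$reference)
  data.frame(band = bands$labels, hr = e / e[ref], stringsAsFactors = FALSE)
}

age_group_of <- function(age) {
  cut(age, c(-Inf, 40, 50, Inf), labels = c("<40", "40-50", ">=50"),
      right = FALSE)
}

#' PRS-by-age interaction and age-group fits
#'
#' The interaction model contains the PRS and its product with the
#' (uncentered) age at first breast cancer, so the main effect is the HR
#' per SD at age zero and the interaction the HR-per-SD multiplier per year
#' of age. Group fits refit the continuous model on the `<40`, `[40,50)`
#' and `>=50` subsets (age 40 belongs to 40-50; age 50 to >=50). Empty
#' groups are skipped and listed in `$skipped_groups`.
#'
#' @param intervals Risk intervals carrying `age_bc1`.
#' @inheritParams fit_cox_continuous
#' @return List with `interaction` (`cbc_coxfit`) and `by_age_group`
#'   (named list of `cbc_coxfit`).
#' @export
fit_interaction_and_age_groups <- function(intervals,
                                           adjust_birth_cohort = TRUE,
                                           ties = "efron") {
  if (any(is.na(intervals$age_bc1))) stop("age_bc1 required for all subjects")
  f <- surv_formula(c("z", "z:age_bc1"), adjust_birth_cohort, intervals)
  inter <- new_coxfit(
    survival::coxph(f, data = intervals, ties = ties, robust = TRUE, x = TRUE, y = TRUE),
    intervals, ties)
  groups <- split(intervals, age_group_of(intervals$age_bc1))
  fits <- list()
  skipped <- character(0)
  for (g in names(groups)) {
    sub <- groups[[g]]
    if (nrow(sub) == 0 || sum(sub$event) == 0) {
      skipped <- c(skipped, g)
      next
    }
    fits[[g]] <- fit_cox_continuous(sub, adjust_birth_cohort, ties)
  }
  list(interaction = inter, by_age_group = fits, skipped_groups = skipped)
}

#' Continuous fit within pathogenic-variant classes
#'
#' Subset refits keyed on the `variant_class` column (class I: unstable or
#' no protein; class II: stable mutant protein).
#'
#' @param intervals Risk intervals with `variant_class`.
#' @param classes Classes to fit.
#' @inheritParams fit_cox_continuous
#' @return Named list of `cbc_coxfit`.
#' @export
fit_variant_class <- function(intervals, classes = c("I", "II"),
                              adjust_birth_cohort = TRUE, ties = "efron") {
  if (is.null(intervals$variant_class)) stop("variant_class column required")
  fits <- list()
  for (cl in classes) {
    sub <- intervals[intervals$variant_class %in% cl, , drop = FALSE]
    if (nrow(sub) && sum(sub$event) > 0) {
      fits[[cl]] <- fit_cox_continuous(sub, adjust_birth_cohort, ties)
    }
  }
  fits
}

#' Proportional-hazards check via Schoenfeld residuals
#'
#' Score test of zero correlation between the scaled Schoenfeld residuals
#' of the PRS term and Kaplan-Meier-transformed time
#' ([survival::cox.zph()] with `transform = "km"`).
#'
#' @param fit A `cbc_coxfit` from [fit_cox_continuous()].
#' @param term Model term to test (default the PRS).
#' @return p-value of the PH test for `term`.
#' @export
schoenfeld_ph_test <- function(fit, term = "z") {
  stopifnot(inherits(fit, "cbc_coxfit"))
  if (fit$n_events < 10) stop("fewer than 10 events: PH test refused")
  zp <- survival::cox.zph(fit$cox, transform = "km")
  tab <- zp$table
  if (!term %in% rownames(tab)) stop("term not in fit: ", term)
  unname(tab[term, "p"])
}

#' Restricted cubic spline basis (truncated-power form)
#'
#' Harrell's restricted cubic spline: cubic between the knots, linear in
#' both tails. With k knots the basis has k-1 columns, the first being the
#' identity.
#'
#' @param x Numeric vector.
#' @param knots Increasing knot locations (>= 3).
#' @return Matrix with `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 3) stop("need at least 3 knots")
  if (is.unsorted(knots, strictly = TRUE)) stop("knots must be increasing")
  pos3 <- function(u) pmax(u, 0)^3
  kk <- knots
  out <- matrix(0, length(x), k - 1)
  out[, 1] <- x
  denom <- (kk[k] - kk[1])^2
  for (j in seq_len(k - 2)) {
    out[, j + 1] <- (pos3(x - kk[j]) -
      pos3(x - kk[k - 1]) * (kk[k] - kk[j]) / (kk[k] - kk[k - 1]) +
      pos3(x - kk[k]) * (kk[k - 1] - kk[j]) / (kk[k] - kk[k - 1])) / denom
  }
  colnames(out) <- c("linear", paste0("nonlin", seq_len(k - 2)))
  out
}

#' Linearity check via restricted cubic splines
#'
#' Likelihood-ratio test of the nonlinear spline terms beyond the linear
#' PRS effect, knots at the 10/50/90 percentiles of the standardized PRS.
#' The LRT uses the unclustered partial likelihood (a likelihood ratio has
#' no sandwich analogue); strata and adjustment match the main model.
#'
#' @param intervals Risk intervals.
#' @inheritParams fit_cox_continuous
#' @return p-value for nonlinearity (1 df with 3 knots).
#' @export
rcs_linearity_check <- function(intervals, adjust_birth_cohort = TRUE,
                                ties = "efron") {
  knots <- stats::quantile(intervals$z, c(0.1, 0.5, 0.9), type = 7,
                           names = FALSE)
  if (is.unsorted(knots, strictly = TRUE)) {
    stop("degenerate PRS distribution: spline knots not distinct")
  }
  B <- rcs_basis(intervals$z, knots)
  d <- intervals
  d$z_nl <- B[, -1, drop = FALSE]
  rhs_lin <- "z"
  rhs_spl <- c("z", "z_nl")
  strip_cluster <- function(rhs) {
    trm <- rhs
    if (adjust_birth_cohort && "birth_q" %in% names(d) &&
        nlevels(droplevels(factor(d$birth_q))) > 1) trm <- c(trm, "birth_q")
    stats::as.formula(paste("survival::Surv(entry, exit, event) ~",
                            paste(c(trm, "strata(stratum)"), collapse = " + ")))
  }
  f0 <- survival::coxph(strip_cluster(rhs_lin), data = d, ties = ties)
  f1 <- survival::coxph(strip_cluster(rhs_spl), data = d, ties = ties)
  lrt <- 2 * (f1$loglik[2] - f0$loglik[2])
  df <- length(stats::coef(f1)) - length(stats::coef(f0))
  stats::pchisq(lrt, df, lower.tail = FALSE)
}

#' Harrell's C-index, stratified and cluster-bootstrapped
#'
#' Concordance between the risk score and event ordering, counting pairs
#' within country strata only and honoring delayed entry (pairs are
#' comparable only where risk sets overlap); computed by
#' [survival::concordance()] with `reverse = TRUE` so higher scores mean
#' earlier failure. The confidence interval is a percentile bootstrap
#' resampling whole family clusters.
#'
#' @param intervals Risk intervals.
#' @param score Risk score per row (default the standardized PRS; pass the
#'   full linear predictor to evaluate the adjusted model instead).
#' @param nboot Bootstrap resamples for the CI (0 skips the CI).
#' @param seed Seed for the bootstrap.
#' @return List `c`, `ci95`, `stratified_by`, `n_pairs`.
#' @export
harrell_c <- function(intervals, score = NULL, nboot = 1000, seed = 1L) {
  d <- intervals
  d$.score <- score %||% d$z
  cfit <- survival::concordance(
    survival::Surv(entry, exit, event) ~ .score + strata(stratum),
    data = d, reverse = TRUE)
  cnt <- cfit$count
  if (is.matrix(cnt)) cnt <- colSums(cnt)
  npairs <- sum(cnt[c("concordant", "discordant", "tied.x")])
  if (npairs == 0) stop("no comparable pairs")
  ci <- c(NA_real_, NA_real_)
  if (nboot > 0) {
    set.seed(seed)
    fams <- split(seq_len(nrow(d)), d$cluster)
    cs <- vapply(seq_len(nboot), function(i) {
      pick <- sample(length(fams), replace = TRUE)
      db <- d[unlist(fams[pick]), , drop = FALSE]
      survival::concordance(
        survival::Surv(entry, exit, event) ~ .score + strata(stratum),
        data = db, reverse = TRUE)$concordance
    }, numeric(1))
    ci <- stats::quantile(cs, c(0.025, 0.975), names = FALSE)
  }
  list(c = unname(cfit$concordance), ci95 = ci, stratified_by = "stratum",
       n_pairs = unname(npairs))
}

#' Kaplan-Meier cumulative risk with delayed entry
#'
#' Product-limit estimator on the left-truncated intervals; cumulative risk
#' is `1 - S(horizon)` with the Greenwood log-scale confidence interval.
#'
#' @param intervals Risk intervals.
#' @param horizon Years since first BC.
#' @return List `risk`, `ci95`, `surv`, `n_events_by_horizon`.
#' @export
km_cumulative_risk <- function(intervals, horizon) {
  sf <- survival::survfit(survival::Surv(entry, exit, event) ~ 1,
                          data = intervals, conf.type = "log")
  s <- summary(sf, times = horizon, extend = TRUE)
  risk <- 1 - s$surv
  ci <- c(1 - s$upper, 1 - s$lower)
  if (sum(intervals$event & intervals$exit <= horizon) == 0) {
    risk <- 0
    ci <- c(0, 0)
  }
  list(risk = risk, ci95 = ci, surv = s$surv,
       n_events_by_horizon = sum(intervals$event & intervals$exit <= horizon))
}
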