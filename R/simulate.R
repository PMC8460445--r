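#' Generate a synthetic variant weight panel
#'
#' Stand-in for a published PRS weight table: effect-allele frequencies drawn
#' uniformly on (0.01, 0.5) and per-allele log-odds weights drawn normal,
#' then rescaled so the raw-score variance under linkage equilibrium,
#' `sum(2 p (1 - p) w^2)`, equals `variance_target` exactly. The three PRS
#' flavors (overall, ER-positive, ER-negative) share variants; the ER
#' flavors are correlated reweightings of the overall weights, each rescaled
#' to the same variance target.
#'
#' @param n_variants Number of variants (>= 1).
#' @param seed Integer seed; the same seed reproduces the panel exactly.
#' @param variance_target Target raw-score variance under independence.
#' @return A `data.frame` with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `weight_overall`,
#'   `weight_erpos`, `weight_erneg`.
#' @export
generate_variant_panel <- function(n_variants, seed = 1L,
                                   variance_target = 1.0) {
  assert_count(n_variants, "n_variants")
  set.seed(seed)
  p <- stats::runif(n_variants, 0.01, 0.5)
  rescale <- function(w) w * sqrt(variance_target / sum(2 * p * (1 - p) * w^2))
  w0 <- rescale(stats::rnorm(n_variants))
  # ER flavors: correlated perturbations of the overall weights (r ~ 0.9)
  s0 <- if (n_variants > 1) stats::sd(w0) else abs(w0)
  wp <- rescale(0.9 * w0 + sqrt(1 - 0.9^2) * stats::rnorm(n_variants, sd = s0))
  wn <- rescale(0.9 * w0 + sqrt(1 - 0.9^2) * stats::rnorm(n_variants, sd = s0))
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, n_variants, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), "")
  data.frame(
    variant_id = sprintf("v%04d", seq_len(n_variants)),
    chrom = as.character(sample(1:22, n_variants, replace = TRUE)),
    pos = sort(sample.int(5e7, n_variants)),
    effect_allele = ea, other_allele = unname(oa),
    eaf = p,
    weight_overall = w0, weight_erpos = wp, weight_erneg = wn,
    stringsAsFactors = FALSE
  )
}

#' Validate a variant weight panel
#'
#' @param panel A panel data.frame as from [generate_variant_panel()] or
#'   [read_weight_panel()].
#' @return The panel, invisibly; errors on violations.
#' @export
validate_panel <- function(panel) {
  need <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "weight_overall", "weight_erpos", "weight_erneg")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel missing columns: ", paste(miss, collapse = ", "))
  if (nrow(panel) < 1) stop("panel is empty")
  if (anyDuplicated(panel$variant_id)) stop("duplicate variant ids in panel")
  if (any(panel$effect_allele == panel$other_allele)) {
    stop("effect and other allele must differ")
  }
  if (any(panel$eaf <= 0 | panel$eaf >= 1)) stop("eaf must be inside (0, 1)")
  w <- as.matrix(panel[c("weight_overall", "weight_erpos", "weight_erneg")])
  if (any(!is.finite(w))) stop("weights must be finite")
  invisible(panel)
}

#' Generate family-clustered genotype dosages
#'
#' Founders (single-member families and the simulated parents of larger
#' families) are drawn under Hardy-Weinberg equilibrium at the panel's
#' effect-allele frequencies; members of multi-member families are full
#' siblings produced by Mendelian transmission from two simulated parents,
#' so within-family genotype correlation is genuinely positive (expected
#' r = 0.5 for sib pairs per variant). Dosages are allele counts {0, 1, 2}
#' unless `fractional_noise_sd > 0`, which adds truncated noise emulating
#' imputed expected counts.
#'
#' @param panel Variant weight panel.
#' @param n_subjects Number of subjects.
#' @param family_size_probs Probabilities of family sizes 1, 2, 3.
#' @param seed Integer seed.
#' @param fractional_noise_sd SD of optional dosage noise (clamped to [0,2]).
#' @return A list with `dosages` (subject x variant matrix, dimnames set)
#'   and `families` (data.frame `subject_id`, `family_id`).
#' @export
generate_families_genotypes <- function(panel, n_subjects,
                                        family_size_probs = c(0.906, 0.080, 0.014),
                                        seed = 1L,
                                        fractional_noise_sd = 0) {
  validate_panel(panel)
  assert_count(n_subjects, "n_subjects")
  set.seed(seed)
  # Draw family sizes until the cohort is filled; trim the last family.
  sizes <- integer(0)
  while (sum(sizes) < n_subjects) {
    k <- max(16L, ceiling((n_subjects - sum(sizes)) / mean(1:3)))
    sizes <- c(sizes, sample(1:3, k, replace = TRUE, prob = family_size_probs))
  }
  ncum <- cumsum(sizes)
  nfam <- which(ncum >= n_subjects)[1]
  sizes <- sizes[seq_len(nfam)]
  sizes[nfam] <- sizes[nfam] - (ncum[nfam] - n_subjects)
  sizes <- sizes[sizes > 0]
  nfam <- length(sizes)

  m <- nrow(panel)
  p <- panel$eaf
  # Parent dosage matrices for every family (HWE); singletons reuse parent 1's
  # own HWE draw directly as the founder genotype.
  Gm <- matrix(stats::rbinom(nfam * m, 2, rep(p, each = nfam)), nfam, m)
  Gp <- matrix(stats::rbinom(nfam * m, 2, rep(p, each = nfam)), nfam, m)
  fam_of <- rep(seq_len(nfam), sizes)
  single <- sizes[fam_of] == 1L
  n <- length(fam_of)
  G <- matrix(0L, n, m)
  if (any(single)) G[single, ] <- Gm[fam_of[single], , drop = FALSE]
  if (any(!single)) {
    idx <- fam_of[!single]
    pm <- Gm[idx, , drop = FALSE] / 2
    pp <- Gp[idx, , drop = FALSE] / 2
    G[!single, ] <- matrix(stats::rbinom(length(pm), 1, pm), nrow(pm), m) +
      matrix(stats::rbinom(length(pp), 1, pp), nrow(pp), m)
  }
  G <- G * 1.0
  if (fractional_noise_sd > 0) {
    G <- pmin(2, pmax(0, G + stats::rnorm(length(G), 0, fractional_noise_sd)))
  }
  subject_id <- sprintf("s%06d", seq_len(n))
  dimnames(G) <- list(subject_id, panel$variant_id)
  list(
    dosages = G,
    families = data.frame(subject_id = subject_id,
                          family_id = sprintf("f%05d", fam_of),
                          stringsAsFactors = FALSE)
  )
}

#' Generate a study-like cohort of subject records
#'
#' Attaches demographics, country strata, first-tumor covariates and the
#' censoring machinery to a set of subjects with known standardized PRS, then
#' simulates contralateral events via [simulate_cbc_events()].
#'
#' @param config A [sim_config()].
#' @param z Standardized PRS per subject (finite).
#' @param families Optional data.frame (`subject_id`, `family_id`) as from
#'   [generate_families_genotypes()]; defaults to singleton families.
#' @param simulate_events Attach event/censoring outcomes (default TRUE).
#' @return A `data.frame` of subject records (one row per woman).
#' @export
generate_cohort <- function(config, z, families = NULL,
                            simulate_events = TRUE) {
  stopifnot(inherits(config, "cbc_sim_config"))
  if (any(!is.finite(z))) stop("z must be finite for all subjects")
  n <- length(z)
  set.seed(derive_seed(config$seed, "cohort"))
  if (is.null(families)) {
    families <- data.frame(subject_id = sprintf("s%06d", seq_len(n)),
                           family_id = sprintf("f%05d", seq_len(n)),
                           stringsAsFactors = FALSE)
  }
  if (nrow(families) != n) stop("families must have one row per subject")
  age_bc1 <- rtruncnorm(n, config$age_bc1_mean, config$age_bc1_sd,
                        config$age_bc1_range[1], config$age_bc1_range[2])
  country <- sprintf("C%02d", sample.int(config$n_countries, n, replace = TRUE,
                                         prob = config$country_probs))
  diag_year <- stats::runif(n, 1990, 2015)
  birth_year <- round(diag_year - age_bc1)
  # Administrative censoring: baseline age is ascertainment, at least one
  # year after the first BC, median lag ~ median_followup beyond entry.
  fu_lag <- stats::rexp(n, rate = log(2) / config$median_followup)
  age_baseline <- age_bc1 + 1 + fu_lag
  has_rrm <- stats::runif(n) < config$p_rrm
  age_rrm <- ifelse(has_rrm,
                    age_bc1 + 1 + stats::rexp(n, 1 / config$rrm_mean_lag),
                    NA_real_)
  has_death <- stats::runif(n) < config$p_death
  age_death <- ifelse(has_death,
                      age_bc1 + 1 + stats::rexp(n, 1 / config$death_mean_lag),
                      NA_real_)
  rec <- data.frame(
    subject_id = families$subject_id,
    family_id = families$family_id,
    country = country,
    birth_year = birth_year,
    age_bc1 = age_bc1,
    age_baseline = age_baseline,
    age_rrm = age_rrm,
    age_death = age_death,
    age_distant_relapse = NA_real_,
    metastatic_bc1 = sample(c("no", "unknown"), n, TRUE, prob = c(0.3, 0.7)),
    family_history = sample(c("0", "1", ">=2"), n, TRUE,
                            prob = c(0.25, 0.33, 0.42)),
    er_bc1 = sample(c("positive", "negative"), n, TRUE, prob = c(0.25, 0.75)),
    node_status = sample(c("positive", "negative"), n, TRUE,
                         prob = c(0.35, 0.65)),
    tumor_size = sample(c("T1", "T2", "T3", "T4"), n, TRUE,
                        prob = c(0.60, 0.35, 0.04, 0.01)),
    chemo = sample(c("yes", "no"), n, TRUE, prob = c(0.65, 0.35)),
    hormone_therapy = sample(c("yes", "no"), n, TRUE, prob = c(0.35, 0.65)),
    trastuzumab = sample(c("yes", "no"), n, TRUE, prob = c(0.02, 0.98)),
    radiotherapy = sample(c("yes", "no"), n, TRUE, prob = c(0.67, 0.33)),
    variant_class = sample(c("I", "II", "III"), n, TRUE,
                           prob = c(0.65, 0.26, 0.09)),
    z = z,
    stringsAsFactors = FALSE
  )
  if (simulate_events) rec <- simulate_cbc_events(rec, z, config)
  rec
}

#' Simulate contralateral breast cancer events and censoring
#'
#' Event times (years since first BC, entry at 1) follow the piecewise
#' exponential model with hazard
#' `lambda_b(t) * exp((beta_true + gamma_true * age_bc1) * z)`,
#' drawn by inversion of the cumulative hazard. Censoring is the earliest of
#' baseline age, risk-reducing mastectomy and death. When
#' `config$calibrate_events` is TRUE the baseline hazard is rescaled so the
#' expected event fraction (given the realized linear predictors and censor
#' times) equals `config$target_event_fraction`. A configurable fraction of
#' events is labeled in situ, and ER status assigned by `er_fractions`.
#'
#' @param records Cohort records from [generate_cohort()] (censoring ages
#'   already attached).
#' @param z Standardized PRS per subject.
#' @param config A [sim_config()].
#' @return `records` with `age_cbc`, `cbc_invasive`, `cbc_er_status` filled.
#' @export
simulate_cbc_events <- function(records, z, config) {
  stopifnot(inherits(config, "cbc_sim_config"))
  n <- nrow(records)
  set.seed(derive_seed(config$seed, "events"))
  eta <- (config$beta_true + config$gamma_true * records$age_bc1) * z
  if (any(abs(eta) > 30)) {
    stop("linear predictor overflow: |(beta + gamma * age) * z| > 30")
  }
  cens <- pmin(records$age_baseline,
               ifelse(is.na(records$age_rrm), Inf, records$age_rrm),
               ifelse(is.na(records$age_death), Inf, records$age_death)) -
    records$age_bc1
  hz <- config$baseline_hazard
  if (config$calibrate_events) {
    H <- cum_hazard(hz, cens)
    expected_frac <- function(ls) mean(1 - exp(-exp(ls) * H * exp(eta)))
    if (expected_frac(log(1e4)) < config$target_event_fraction) {
      stop("cannot reach target event fraction under this censoring")
    }
    ls <- stats::uniroot(function(s) expected_frac(s) - config$target_event_fraction,
                         c(log(1e-6), log(1e4)), tol = 1e-10)$root
    hz <- scale_hazard(hz, exp(ls))
  }
  E <- stats::rexp(n)
  T <- inv_cum_hazard(hz, E / exp(eta))
  event <- T <= cens
  records$age_cbc <- ifelse(event, records$age_bc1 + T, NA_real_)
  records$cbc_invasive <- ifelse(event,
                                 stats::runif(n) >= config$insitu_fraction, NA)
  er <- rep(NA_character_, n)
  er[event] <- sample(names(config$er_fractions), sum(event), TRUE,
                      prob = config$er_fractions)
  records$cbc_er_status <- er
  attr(records, "calibrated_hazard") <- hz
  records
}

#' Inject covariate missingness
#'
#' Sets covariate entries to `NA` at the configured rates, either completely
#' at random (MCAR) or with country-dependent rates (MAR-on-country, which
#' shifts the missingness log-odds by country while keeping roughly the
#' marginal rate). The original values are retained in the `"truth"`
#' attribute for recovery tests.
#'
#' @param records Cohort records.
#' @param rates Named vector: covariate column -> missing proportion.
#' @param mechanism `"MCAR"` or `"MAR-on-country"`.
#' @param seed Integer seed.
#' @return `records` with `NA`s injected; `attr(., "truth")` holds the
#'   original columns.
#' @export
inject_missingness <- function(records, rates, mechanism = c("MCAR", "MAR-on-country"),
                               seed = 1L) {
  mechanism <- match.arg(mechanism)
  assert_prop(rates, "rates")
  bad <- setdiff(names(rates), names(records))
  if (length(bad)) stop("unknown covariates: ", paste(bad, collapse = ", "))
  set.seed(seed)
  truth <- records[names(rates)]
  n <- nrow(records)
  if (mechanism == "MAR-on-country") {
    cidx <- as.integer(factor(records$country))
    shift <- scale(cidx)[, 1] * 0.5
  } else {
    shift <- 0
  }
  for (v in names(rates)) {
    r <- rates[[v]]
    pm <- if (r <= 0) rep(0, n) else if (r >= 1) rep(1, n) else {
      stats::plogis(stats::qlogis(r) + shift)
    }
    records[[v]][stats::runif(n) < pm] <- NA
  }
  attr(records, "truth") <- truth
  records
}

#' Simulate a full study: panel, genotypes, PRS, cohort, events
#'
#' Composes the simulator stages into one reproducible draw: a variance-1
#' weight panel, family-structured genotypes, PRS scoring and
#' standardization (internal centering, unit reference SD), demographics and
#' event simulation. This is the generative surface used for
#' parameter-recovery validation.
#'
#' @param config A [sim_config()].
#' @param flavor PRS flavor used for the generative effect.
#' @param missingness Apply `config$missingness_rates` (default FALSE; the
#'   association pipeline applies it explicitly when exercising imputation).
#' @return A list: `records`, `panel`, `dosages`, `families`, `prs`
#'   (the standardized scores), and `truth` (the generative parameters).
#' @export
simulate_cbc_study <- function(config, flavor = "er_negative",
                               missingness = FALSE) {
  stopifnot(inherits(config, "cbc_sim_config"))
  panel <- generate_variant_panel(config$n_variants,
                                  seed = derive_seed(config$seed, "panel"))
  gen <- generate_families_genotypes(panel, config$n_subjects,
                                     config$family_size_probs,
                                     seed = derive_seed(config$seed, "genotypes"))
  raw <- compute_prs(gen$dosages, panel, flavor = flavor)
  prs <- standardize_prs(raw, standardization_spec(scale = 1.0), flavor = flavor)
  records <- generate_cohort(config, prs$z, gen$families)
  if (missingness) {
    records <- inject_missingness(records, config$missingness_rates,
                                  seed = derive_seed(config$seed, "missingness"))
  }
  list(records = records, panel = panel, dosages = gen$dosages,
       families = gen$families, prs = prs,
       truth = list(beta_true = config$beta_true,
                    gamma_true = config$gamma_true,
                    target_event_fraction = config$target_event_fraction,
                    seed = config$seed))
}
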