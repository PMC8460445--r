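# Shared fixtures: tiny hand-built panels and a fast interval simulator that
# bypasses the genotype stage (exponential event times, optional censoring).

hand_panel <- function() {
  data.frame(
    variant_id = c("v1", "v2", "v3"),
    chrom = c("1", "2", "3"), pos = c(100L, 200L, 300L),
    effect_allele = c("A", "C", "G"), other_allele = c("G", "T", "A"),
    eaf = c(0.2, 0.3, 0.4),
    weight_overall = c(0.1, -0.2, 0.3),
    weight_erpos = c(0.1, -0.2, 0.3),
    weight_erneg = c(0.1, -0.2, 0.3),
    stringsAsFactors = FALSE
  )
}

# Left-truncated intervals from an exponential proportional-hazards model:
# hazard lambda0 * exp(beta * z) from the 1-year entry onward.
sim_intervals <- function(n, beta, lambda0 = 0.05, median_fu = 6,
                          n_strata = 1, seed = 1, censor = TRUE,
                          age_mean = 42, age_sd = 8, pair_families = FALSE) {
  set.seed(seed)
  z <- stats::rnorm(n)
  T <- 1 + stats::rexp(n) / (lambda0 * exp(beta * z))
  cens <- if (censor) 1 + stats::rexp(n, log(2) / median_fu) else rep(Inf, n)
  cluster <- if (pair_families) {
    sprintf("f%05d", rep(seq_len(ceiling(n / 2)), each = 2)[seq_len(n)])
  } else {
    sprintf("f%05d", seq_len(n))
  }
  data.frame(
    subject_id = sprintf("s%06d", seq_len(n)),
    entry = 1, exit = pmin(T, cens), event = as.integer(T <= cens),
    stratum = sprintf("C%02d", sample.int(n_strata, n, replace = TRUE)),
    cluster = cluster,
    z = z,
    age_bc1 = round(stats::rnorm(n, age_mean, age_sd)),
    birth_year = sample(1930:1975, n, replace = TRUE),
    birth_q = factor(sample(paste0("Q", 1:4), n, replace = TRUE)),
    variant_class = sample(c("I", "II"), n, replace = TRUE, prob = c(.7, .3)),
    stringsAsFactors = FALSE
  )
}

# Minimal eligible subject records for the eligibility tests.
base_record <- function(subject_id = "s1", age_bc1 = 40, age_baseline = 50,
                        age_cbc = NA, cbc_invasive = NA,
                        cbc_er_status = NA_character_,
                        metastatic_bc1 = "no", age_rrm = NA, age_death = NA,
                        age_distant_relapse = NA, z = 0) {
  data.frame(subject_id = subject_id, family_id = paste0("f", subject_id),
             country = "C01", birth_year = 1960L,
             age_bc1 = age_bc1, age_baseline = age_baseline,
             age_cbc = age_cbc, cbc_invasive = cbc_invasive,
             cbc_er_status = cbc_er_status, metastatic_bc1 = metastatic_bc1,
             age_rrm = age_rrm, age_death = age_death,
             age_distant_relapse = age_distant_relapse, z = z,
             stringsAsFactors = FALSE)
}

# Closed-form concordance of an exponential proportional-hazards model with
# standard-normal score and log HR per SD beta: for an uncensored pair the
# lower-hazard subject outlives the other with probability
# 1 / (1 + exp(-beta |z1 - z2|)); z1 - z2 ~ N(0, 2).
concordance_oracle <- function(beta) {
  stats::integrate(function(d) stats::plogis(beta * abs(d)) *
                     stats::dnorm(d, 0, sqrt(2)),
                   -Inf, Inf, rel.tol = 1e-10)$value
}

# Truncated-normal mean on [a, b].
truncnorm_mean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd; be <- (b - mu) / sd
  mu + sd * (stats::dnorm(al) - stats::dnorm(be)) /
    (stats::pnorm(be) - stats::pnorm(al))
}
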