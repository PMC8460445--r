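test_that("a permuted PRS shows no association", {
  iv <- sim_intervals(2000, beta = log(1.5), n_strata = 3, seed = 5)
  set.seed(6)
  iv$z <- sample(iv$z)
  fit <- fit_cox_continuous(iv)
  expect_lt(abs(fit$coefficients[["z"]]), 3 * fit$robust_se[["z"]])
})

test_that("the continuous fit recovers a generative per-SD effect", {
  beta <- log(1.5)
  est <- vapply(1:5, function(r) {
    iv <- sim_intervals(4000, beta = beta, n_strata = 3, seed = 100 + r)
    fit_cox_continuous(iv)$coefficients[["z"]]
  }, numeric(1))
  mc_se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - beta), 3 * mc_se + 1e-3)
})

test_that("record duplication leaves the clustered fit invariant", {
  # Duplicating every record within its family: identical point estimate,
  # identical cluster-robust SE, naive SE shrinks by 1/sqrt(2) (Breslow
  # ties keep the partial likelihood exactly proportional).
  iv <- sim_intervals(1500, beta = log(1.3), n_strata = 2, seed = 9)
  f1 <- fit_cox_continuous(iv, ties = "breslow")
  f2 <- fit_cox_continuous(rbind(iv, iv), ties = "breslow")
  expect_equal(f2$coefficients[["z"]], f1$coefficients[["z"]],
               tolerance = 1e-6)
  expect_equal(f2$robust_se[["z"]], f1$robust_se[["z"]], tolerance = 1e-4)
  expect_equal(f2$naive_se[["z"]] / f1$naive_se[["z"]], 1 / sqrt(2),
               tolerance = 1e-3)
})

test_that("relabeling countries does not move the estimate", {
  iv <- sim_intervals(2000, beta = log(1.4), n_strata = 4, seed = 11)
  f1 <- fit_cox_continuous(iv)
  iv2 <- iv
  iv2$stratum <- chartr("1234", "4321", iv2$stratum)
  f2 <- fit_cox_continuous(iv2)
  expect_equal(f2$coefficients[["z"]], f1$coefficients[["z"]],
               tolerance = 1e-10)
})

test_that("fit errors are raised for degenerate inputs", {
  iv <- sim_intervals(100, beta = 0, seed = 2)
  iv$event <- 0L
  expect_error(fit_cox_continuous(iv), "no events")
  iv2 <- sim_intervals(100, beta = 0, seed = 2)
  iv2$z[1] <- NA
  expect_error(fit_cox_continuous(iv2), "non-finite")
})

test_that("percentile bands follow the unilateral-case distribution", {
  b <- compute_percentile_bands(1:100 + 0)
  expect_equal(as.character(assign_bands(b, 50.5)), "40-60")
  expect_equal(as.character(assign_bands(b, 99.9)), "95-100")
  expect_equal(levels(assign_bands(b, 1))[1], "40-60")

  # far-above-all-edges cases all land in the top band
  expect_true(all(assign_bands(b, c(200, 300)) == "95-100"))

  # large-sample edges match the normal quantiles
  set.seed(3)
  bn <- compute_percentile_bands(rnorm(2e5))
  expect_equal(bn$edges, qnorm(bn$probs), tolerance = 0.02)

  expect_error(compute_percentile_bands(rnorm(50)), "at least 100")
  expect_error(compute_percentile_bands(rep(1:4, 50)), "unique")
})

test_that("predicted band HRs match the truncated-normal closed form", {
  b <- compute_percentile_bands(rnorm(200))
  expect_equal(predict_band_hrs(0, b)$hr, rep(1, 9))

  # closed form: E[e^{bz} | a<z<b] = e^{b^2/2} (Phi(b-beta)-Phi(a-beta)) /
  # (Phi(b)-Phi(a))
  oracle <- function(beta) {
    probs <- c(0, b$probs, 1)
    qa <- qnorm(probs[-length(probs)]); qb <- qnorm(probs[-1])
    e <- exp(beta^2 / 2) * (pnorm(qb - beta) - pnorm(qa - beta)) /
      (pnorm(qb) - pnorm(qa))
    e / e[5]
  }
  for (beta in c(log(1.12), log(1.5), -0.3)) {
    expect_equal(predict_band_hrs(beta, b)$hr, oracle(beta),
                 tolerance = 1e-7)
  }
  # the top band at the BRCA1-scale effect
  expect_equal(predict_band_hrs(log(1.12), b)$hr[9], 1.26, tolerance = 0.005)
  # reflection symmetry: bottom band at beta equals top band at -beta
  # (z -> -z maps the 0-5 band onto 95-100 and fixes the 40-60 reference)
  expect_equal(predict_band_hrs(log(1.3), b)$hr[1],
               predict_band_hrs(-log(1.3), b)$hr[9], tolerance = 1e-7)
})

test_that("categorical fits are null when the effect is null", {
  iv <- sim_intervals(6000, beta = 0, seed = 21)
  bands <- compute_percentile_bands(iv$z[iv$event == 0])
  fit <- fit_cox_categorical(iv, bands)
  tab <- fit$band_table
  expect_equal(tab$hr[tab$band == "40-60"], 1)
  off <- tab[tab$band != "40-60", ]
  expect_true(all(off$ci95_low < 1.35 & off$ci95_high > 0.75))
})

test_that("interaction and age-group conventions are honored", {
  expect_equal(as.character(cbcprs:::age_group_of(c(39.9, 40, 49.9, 50, 60))),
               c("<40", "40-50", "40-50", ">=50", ">=50"))

  iv <- sim_intervals(3000, beta = log(1.3), seed = 31)
  res <- fit_interaction_and_age_groups(iv)
  expect_true("z:age_bc1" %in% names(res$interaction$coefficients))
  # gamma_true = 0: interaction HR per year ~ 1
  gam <- res$interaction$coefficients[["z:age_bc1"]]
  expect_lt(abs(gam), 3 * res$interaction$robust_se[["z:age_bc1"]])
  expect_setequal(names(res$by_age_group), c("<40", "40-50", ">=50"))

  # empty group skipped with a log entry
  young <- iv[iv$age_bc1 < 40, ]
  res2 <- fit_interaction_and_age_groups(young)
  expect_true(all(c("40-50", ">=50") %in% res2$skipped_groups))
})

test_that("an age-dependent PRS effect orders the per-group estimates", {
  # generative gamma < 0: per-SD effect declines with age at first BC
  set.seed(41)
  n <- 12000
  z <- rnorm(n)
  age <- round(runif(n, 25, 65))
  beta_a <- 0.5 - 0.012 * age
  T <- 1 + rexp(n) / (0.05 * exp(beta_a * z))
  cens <- 1 + rexp(n, log(2) / 8)
  iv <- data.frame(subject_id = as.character(1:n), entry = 1,
                   exit = pmin(T, cens), event = as.integer(T <= cens),
                   stratum = "C01", cluster = as.character(1:n), z = z,
                   age_bc1 = age, birth_year = 1950L,
                   birth_q = factor("Q1"), stringsAsFactors = FALSE)
  res <- fit_interaction_and_age_groups(iv, adjust_birth_cohort = FALSE)
  hrs <- vapply(res$by_age_group, function(f) f$hr[["z"]], numeric(1))
  expect_gt(hrs[["<40"]], hrs[["40-50"]])
  expect_gt(hrs[["40-50"]], hrs[[">=50"]])
  expect_lt(res$interaction$coefficients[["z:age_bc1"]], 0)
})

test_that("variant-class subgroup fits key on the class column", {
  iv <- sim_intervals(3000, beta = log(1.4), seed = 51)
  fits <- fit_variant_class(iv)
  expect_setequal(names(fits), c("I", "II"))
  expect_equal(fits$I$n_subjects + fits$II$n_subjects, nrow(iv))
})

test_that("the Schoenfeld test is calibrated and has power", {
  # null: proportional hazards hold; p-values ~ uniform over replicates
  ps <- vapply(1:200, function(r) {
    iv <- sim_intervals(300, beta = 0.4, seed = 1000 + r)
    schoenfeld_ph_test(fit_cox_continuous(iv, adjust_birth_cohort = FALSE))
  }, numeric(1))
  expect_true(all(ps >= 0 & ps <= 1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  # power: an effect that reverses over follow-up is detected
  set.seed(77)
  n <- 5000
  z <- rnorm(n)
  r1 <- 0.15 * exp(1.0 * z)   # strong positive effect on [1, 3)
  r2 <- 0.15 * exp(-1.0 * z)  # reversed after t = 3
  E <- rexp(n)
  T <- ifelse(E < r1 * 2, 1 + E / r1, 3 + (E - r1 * 2) / r2)
  cens <- 1 + rexp(n, log(2) / 8)
  iv <- data.frame(subject_id = as.character(1:n), entry = 1,
                   exit = pmin(T, cens), event = as.integer(T <= cens),
                   stratum = "C01", cluster = as.character(1:n), z = z,
                   age_bc1 = 42, birth_year = 1950L, birth_q = factor("Q1"),
                   stringsAsFactors = FALSE)
  p <- schoenfeld_ph_test(fit_cox_continuous(iv, adjust_birth_cohort = FALSE))
  expect_lt(p, 0.01)

  tiny <- sim_intervals(30, beta = 0, lambda0 = 0.005, seed = 3)
  tiny_fit <- suppressWarnings(fit_cox_continuous(tiny))
  expect_error(schoenfeld_ph_test(tiny_fit), "refused")
})

test_that("the spline basis is restricted-cubic and the LRT calibrated", {
  knots <- c(-1, 0, 1.5)
  x <- seq(-4, 4, by = 0.01)
  B <- rcs_basis(x, knots)
  expect_equal(ncol(B), 2)
  expect_equal(B[, 1], x)
  # linear tails: second differences vanish outside the boundary knots
  nl <- B[, 2]
  d2 <- diff(diff(nl))
  expect_lt(max(abs(d2[x[-c(1, length(x))] < knots[1]])), 1e-10)
  expect_lt(max(abs(d2[x[-c(1, length(x))] > knots[3] + 0.02])), 1e-10)
  # continuity across knots
  expect_lt(max(abs(diff(nl))), 0.15)

  # null calibration of the nonlinearity p-value
  ps <- vapply(1:200, function(r) {
    iv <- sim_intervals(300, beta = 0.3, seed = 2000 + r)
    rcs_linearity_check(iv, adjust_birth_cohort = FALSE)
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  # power against a quadratic log-hazard
  set.seed(91)
  n <- 4000
  z <- rnorm(n)
  T <- 1 + rexp(n) / (0.05 * exp(0.3 * z^2))
  cens <- 1 + rexp(n, log(2) / 8)
  iv <- data.frame(subject_id = as.character(1:n), entry = 1,
                   exit = pmin(T, cens), event = as.integer(T <= cens),
                   stratum = "C01", cluster = as.character(1:n), z = z,
                   age_bc1 = 42, birth_year = 1950L, birth_q = factor("Q1"),
                   stringsAsFactors = FALSE)
  expect_lt(rcs_linearity_check(iv, adjust_birth_cohort = FALSE), 0.01)
})

test_that("concordance behaves at the random and perfect extremes", {
  iv <- sim_intervals(3000, beta = 0, seed = 61)
  c0 <- harrell_c(iv, nboot = 0)
  expect_lt(abs(c0$c - 0.5), 0.03)

  # perfect score: risk = -event time, uncensored, one stratum
  ivp <- sim_intervals(500, beta = 0, censor = FALSE, seed = 62)
  cp <- harrell_c(ivp, score = -ivp$exit, nboot = 0)
  expect_equal(cp$c, 1)

  # cluster-bootstrap CI brackets the point estimate
  iv2 <- sim_intervals(800, beta = log(1.5), seed = 63, pair_families = TRUE)
  cc <- harrell_c(iv2, nboot = 50, seed = 5)
  expect_true(cc$ci95[1] <= cc$c && cc$c <= cc$ci95[2])
})

test_that("Kaplan-Meier risk reproduces the hand product-limit example", {
  # entries at 1; events at 3 and 5; censored at 4 and 6:
  # S(3) = 3/4, S(5) = 3/4 * 1/2 = 3/8, risk = 0.625
  iv <- data.frame(subject_id = as.character(1:4), entry = 1,
                   exit = c(3, 4, 5, 6), event = c(1L, 0L, 1L, 0L),
                   stratum = "C01", cluster = as.character(1:4), z = 0)
  km <- km_cumulative_risk(iv, 6)
  expect_equal(km$risk, 0.625)
  expect_equal(km$surv, 0.375)

  # no events: risk 0
  iv0 <- transform(iv, event = 0L)
  expect_equal(km_cumulative_risk(iv0, 6)$risk, 0)

  # uncensored: matches the empirical CDF
  ivu <- sim_intervals(400, beta = 0, censor = FALSE, seed = 64)
  km5 <- km_cumulative_risk(ivu, 5)
  expect_equal(km5$risk, mean(ivu$exit <= 5), tolerance = 1e-10)
})
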