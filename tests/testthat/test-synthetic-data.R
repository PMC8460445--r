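test_that("variant panel hits its variance target and is reproducible", {
  expect_error(generate_variant_panel(0), "integer >= 1")

  p1 <- generate_variant_panel(1, seed = 7)
  expect_equal(nrow(p1), 1)
  expect_gt(p1$eaf, 0.01)
  expect_lt(p1$eaf, 0.5)

  expect_identical(generate_variant_panel(50, seed = 3),
                   generate_variant_panel(50, seed = 3))

  panel <- generate_variant_panel(313, seed = 11, variance_target = 1.0)
  for (w in c("weight_overall", "weight_erpos", "weight_erneg")) {
    v <- sum(2 * panel$eaf * (1 - panel$eaf) * panel[[w]]^2)
    expect_equal(v, 1.0, tolerance = 1e-9)
  }
  expect_silent(validate_panel(panel))
})

test_that("founder genotypes follow Hardy-Weinberg and the panel frequency", {
  panel <- generate_variant_panel(2, seed = 5)
  panel$eaf <- c(0.01, 0.3)
  n <- 20000
  gen <- generate_families_genotypes(panel, n, family_size_probs = c(1, 0, 0),
                                     seed = 9)
  # empirical allele frequency within 3 binomial SEs
  for (j in 1:2) {
    p <- panel$eaf[j]
    se <- sqrt(p * (1 - p) / (2 * n))
    expect_lt(abs(mean(gen$dosages[, j]) / 2 - p), 3 * se)
  }
  # genotype class frequencies match (q^2, 2pq, p^2) within 3 SEs
  p <- panel$eaf[2]
  probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  counts <- tabulate(gen$dosages[, 2] + 1, 3)
  for (k in 1:3) {
    se <- sqrt(probs[k] * (1 - probs[k]) / n)
    expect_lt(abs(counts[k] / n - probs[k]), 3 * se)
  }
  # singleton families: no relatedness structure
  expect_equal(anyDuplicated(gen$families$family_id), 0L)
})

test_that("full-sib pairs show the kinship-expected genotype correlation", {
  panel <- generate_variant_panel(1, seed = 2)
  panel$eaf <- 0.3
  n <- 12000 # 6,000 sib pairs
  gen <- generate_families_genotypes(panel, n, family_size_probs = c(0, 1, 0),
                                     seed = 4)
  fam <- gen$families$family_id
  sizes <- table(fam)
  pairs <- names(sizes)[sizes == 2]
  d <- gen$dosages[, 1]
  i1 <- match(pairs, fam) # family members are stored consecutively
  stopifnot(all(fam[i1 + 1] == pairs))
  r <- stats::cor(d[i1], d[i1 + 1])
  expect_lt(abs(r - 0.5), 3 / sqrt(length(pairs)))
  expect_error(generate_families_genotypes(panel[0, ], 10), "empty")
})

test_that("cohort ages match the truncated-normal target", {
  cfg <- sim_config(n_subjects = 20000, n_variants = 5, seed = 21)
  rec <- generate_cohort(cfg, z = rnorm(20000), simulate_events = FALSE)
  mu <- truncnorm_mean(41.8, 10, 18, 85)
  expect_lt(abs(mean(rec$age_bc1) - mu), 3 * 10 / sqrt(20000))
  expect_true(all(rec$age_bc1 >= 18 & rec$age_bc1 <= 85))
  expect_true(all(rec$age_baseline > rec$age_bc1 + 1))
  # birth years consistent with the age ranges
  expect_true(all(rec$birth_year >= 1990 - 86 & rec$birth_year <= 2015 - 17))

  cfg0 <- sim_config(n_subjects = 50, n_variants = 5, age_bc1_sd = 0, seed = 3)
  rec0 <- generate_cohort(cfg0, z = rnorm(50), simulate_events = FALSE)
  expect_true(all(rec0$age_bc1 == 41.8))

  cfg1 <- sim_config(n_subjects = 200, n_variants = 5, n_countries = 1,
                     seed = 3)
  rec1 <- generate_cohort(cfg1, z = rnorm(200), simulate_events = FALSE)
  expect_equal(length(unique(rec1$country)), 1L)
})

test_that("event simulation matches the closed-form exponential fraction", {
  # beta = gamma = 0, constant hazard, administrative horizon T = 11:
  # event fraction = 1 - exp(-lambda * (T - 1))
  n <- 20000
  lambda <- 0.03
  cfg <- sim_config(n_subjects = n, n_variants = 5, beta_true = 0,
                    baseline_hazard = lambda, calibrate_events = FALSE,
                    p_rrm = 0, p_death = 0, seed = 31)
  rec <- generate_cohort(cfg, z = rnorm(n), simulate_events = FALSE)
  rec$age_baseline <- rec$age_bc1 + 11
  rec <- simulate_cbc_events(rec, rec$z, cfg)
  frac <- mean(!is.na(rec$age_cbc))
  expected <- 1 - exp(-lambda * 10)
  expect_lt(abs(frac - expected),
            3 * sqrt(expected * (1 - expected) / n))
  expect_true(all(rec$age_cbc[!is.na(rec$age_cbc)] > rec$age_bc1[!is.na(rec$age_cbc)] + 1))

  # censoring exactly at entry leaves no one at risk
  rec2 <- generate_cohort(cfg, z = rnorm(n), simulate_events = FALSE)
  rec2$age_baseline <- rec2$age_bc1 + 1
  rec2 <- simulate_cbc_events(rec2, rec2$z, cfg)
  expect_equal(sum(!is.na(rec2$age_cbc)), 0L)
})

test_that("event-fraction calibration hits the configured target", {
  n <- 10000
  cfg <- sim_config(n_subjects = n, n_variants = 5,
                    target_event_fraction = 0.213, seed = 17)
  rec <- generate_cohort(cfg, z = rnorm(n))
  frac <- mean(!is.na(rec$age_cbc))
  expect_lt(abs(frac - 0.213), 3 * sqrt(0.213 * 0.787 / n))
})

test_that("linear-predictor overflow is guarded", {
  cfg <- sim_config(n_subjects = 10, n_variants = 5, beta_true = 5,
                    gamma_true = 1, seed = 1)
  rec <- generate_cohort(cfg, z = rep(2, 10), simulate_events = FALSE)
  expect_error(simulate_cbc_events(rec, rep(2, 10), cfg), "overflow")
})

test_that("missingness injection respects rates and keeps the truth channel", {
  cfg <- sim_config(n_subjects = 5189, n_variants = 5, seed = 12)
  rec <- generate_cohort(cfg, z = rnorm(5189), simulate_events = FALSE)

  r0 <- inject_missingness(rec, c(er_bc1 = 0), seed = 1)
  expect_identical(r0$er_bc1, rec$er_bc1)
  r1 <- inject_missingness(rec, c(er_bc1 = 1), seed = 1)
  expect_true(all(is.na(r1$er_bc1)))

  # the magnitude seen for ER status of the first tumor: 56% of 5,189
  r <- inject_missingness(rec, c(er_bc1 = 0.56), seed = 2)
  expect_lt(abs(mean(is.na(r$er_bc1)) - 0.56), 0.02)
  expect_identical(attr(r, "truth")$er_bc1, rec$er_bc1)

  expect_error(inject_missingness(rec, c(er_bc1 = 1.2)), "proportion")
  expect_error(inject_missingness(rec, c(nope = 0.5)), "unknown covariates")

  # MAR-on-country: overall rate near target, but rate varies by country
  rmar <- inject_missingness(rec, c(er_bc1 = 0.5), mechanism = "MAR-on-country",
                             seed = 3)
  by_country <- tapply(is.na(rmar$er_bc1), rec$country, mean)
  expect_gt(max(by_country) - min(by_country), 0.05)
})

test_that("the full simulated study is seed-deterministic", {
  cfg <- sim_config(n_subjects = 300, n_variants = 20, seed = 99)
  s1 <- simulate_cbc_study(cfg)
  s2 <- simulate_cbc_study(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$dosages, s2$dosages)
  s3 <- simulate_cbc_study(sim_config(n_subjects = 300, n_variants = 20,
                                      seed = 100))
  expect_false(identical(s1$records$age_cbc, s3$records$age_cbc))
})

test_that("raw PRS variance on simulated genotypes matches the panel formula", {
  panel <- generate_variant_panel(100, seed = 8, variance_target = 1.0)
  gen <- generate_families_genotypes(panel, 10000, seed = 8)
  raw <- compute_prs(gen$dosages, panel, flavor = "overall")
  expect_gt(stats::sd(raw$raw), 0.9)
  expect_lt(stats::sd(raw$raw), 1.1)
})
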