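# Orchestration: YAML config, end-to-end association runs, risk-curve runs,
# and the simulate-to-files entry point.

#' Read and validate a run configuration (YAML)
#'
#' Recognized fields: `weights`, `genotypes` (CSV or VCF), `phenotypes`,
#' `schedule` (paths); `prs_flavor`, `event_definition`, `sensitivity`,
#' `models` (subset of continuous/categorical/interaction/age-groups/
#' variant-class), `reference_sd`, `m_imputations`, `impute`, `seed`,
#' `out_dir`; risk-curve fields `beta`, `gamma`, `ages`, `percentiles`.
#'
#' @param path YAML file path, or a list already in memory.
#' @param require_paths Check that referenced input paths exist.
#' @return A validated `cbc_run_config` list.
#' @export
read_run_config <- function(path, require_paths = TRUE) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(prs_flavor = "overall", event_definition = "all_cbc",
                   sensitivity = "none", models = c("continuous"),
                   reference_sd = NULL, m_imputations = 10, impute = FALSE,
                   seed = 1L, out_dir = ".",
                   percentiles = c(5, 25, 50, 75, 95), ages = c(35, 45, 55),
                   gamma = 0)
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  ok_models <- c("continuous", "categorical", "interaction", "age-groups",
                 "variant-class")
  bad <- setdiff(cfg$models, ok_models)
  if (length(bad)) stop("unknown models: ", paste(bad, collapse = ", "))
  cfg$event_definition <- match.arg(cfg$event_definition,
                                    c("all_cbc", "invasive_only",
                                      "er_positive", "er_negative"))
  cfg$sensitivity <- match.arg(cfg$sensitivity,
                               c("none", "censor_distant_relapse"))
  cfg$prs_flavor <- match.arg(cfg$prs_flavor,
                              c("overall", "er_positive", "er_negative"))
  if (require_paths) {
    for (k in c("weights", "genotypes", "phenotypes", "schedule")) {
      if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]])) {
        stop("config path does not exist: ", k, " = ", cfg[[k]])
      }
    }
  }
  structure(cfg, class = "cbc_run_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

load_scored_records <- function(cfg) {
  if (is.null(cfg$weights) || is.null(cfg$genotypes) || is.null(cfg$phenotypes)) {
    stop("config must provide weights, genotypes and phenotypes paths")
  }
  if (is.null(cfg$reference_sd)) {
    stop("config must provide reference_sd (the external reference SD)")
  }
  panel <- read_weight_panel(cfg$weights)
  dosages <- if (grepl("\\.vcf(\\.gz)?$", cfg$genotypes)) {
    src <- read_dosage_vcf(cfg$genotypes)
    align_dosages(panel, src)
  } else {
    read_dosage_csv(cfg$genotypes)
  }
  records <- read_phenotypes(cfg$phenotypes)
  raw <- compute_prs(dosages, panel, flavor = cfg$prs_flavor)
  prs <- standardize_prs(raw, standardization_spec(scale = cfg$reference_sd),
                         flavor = cfg$prs_flavor)
  records$z <- prs$z[match(records$subject_id, prs$subject_id)]
  if (any(is.na(records$z))) stop("subjects without PRS: ",
                                  sum(is.na(records$z)))
  records
}

fit_models <- function(intervals, models) {
  res <- list()
  if ("continuous" %in% models) {
    res$continuous <- fit_cox_continuous(intervals)
  }
  if ("categorical" %in% models) {
    bands <- compute_percentile_bands(intervals$z[intervals$event == 0])
    res$categorical <- fit_cox_categorical(intervals, bands)
    res$bands <- bands
  }
  if ("interaction" %in% models || "age-groups" %in% models) {
    ia <- fit_interaction_and_age_groups(intervals)
    if ("interaction" %in% models) res$interaction <- ia$interaction
    if ("age-groups" %in% models) res$by_age_group <- ia$by_age_group
  }
  if ("variant-class" %in% models && "variant_class" %in% names(intervals)) {
    res$by_variant_class <- fit_variant_class(intervals)
  }
  res
}

#' Run the association pipeline end to end
#'
#' score -> eligibility -> intervals -> (impute) -> fits -> diagnostics.
#' Writes a results JSON, a Table-2-shaped CSV, the exclusion log and a run
#' manifest (config hash, seed, counts) to `out_dir`, and returns the
#' results invisibly.
#'
#' @param config A `cbc_run_config` (or path/list accepted by
#'   [read_run_config()]).
#' @param records Optional pre-scored records (bypasses file loading; used
#'   by simulation-driven runs).
#' @param write Write output files to `config$out_dir`.
#' @return List with `intervals`, `exclusions`, `fits`, `diagnostics`,
#'   `manifest`.
#' @export
run_association <- function(config, records = NULL, write = TRUE) {
  cfg <- if (inherits(config, "cbc_run_config")) config else
    read_run_config(config, require_paths = is.null(records))
  set.seed(cfg$seed)
  if (is.null(records)) records <- load_scored_records(cfg)

  elig <- apply_eligibility(records)
  intervals <- build_risk_intervals(elig$records, cfg$event_definition,
                                    cfg$sensitivity)
  fits <- if (isTRUE(cfg$impute)) {
    idata <- elig$records
    iv0 <- intervals
    idata <- idata[idata$subject_id %in% iv0$subject_id, , drop = FALSE]
    idata$event <- iv0$event[match(idata$subject_id, iv0$subject_id)]
    idata$log_time <- log(iv0$exit[match(idata$subject_id, iv0$subject_id)])
    imp <- mice_impute(idata, m = cfg$m_imputations,
                       seed = derive_seed(cfg$seed, "impute"))
    per_fit <- lapply(imp$completed, function(d) {
      iv <- build_risk_intervals(d, cfg$event_definition, cfg$sensitivity)
      fit_cox_continuous(iv)
    })
    list(continuous = per_fit[[1]], pooled = pool_estimates(per_fit),
         imputation = imp)
  } else {
    fit_models(intervals, cfg$models)
  }

  diagnostics <- list()
  if (!is.null(fits$continuous)) {
    diagnostics$ph_p <- tryCatch(schoenfeld_ph_test(fits$continuous),
                                 error = function(e) NA_real_)
    diagnostics$nonlinearity_p <- tryCatch(rcs_linearity_check(intervals),
                                           error = function(e) NA_real_)
    diagnostics$c_index <- harrell_c(intervals, nboot = 0)
    diagnostics$km10 <- km_cumulative_risk(intervals, 10)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("cbcprs")),
    config_hash = config_hash(cfg), seed = cfg$seed,
    n_input = nrow(records), n_excluded = nrow(elig$exclusions),
    n_analyzed = nrow(intervals), n_events = sum(intervals$event),
    event_definition = cfg$event_definition, sensitivity = cfg$sensitivity
  )
  res <- list(intervals = intervals, exclusions = elig$exclusions,
              fits = fits, diagnostics = diagnostics, manifest = manifest)
  if (write) write_association_outputs(res, cfg)
  invisible(res)
}

write_association_outputs <- function(res, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  to_json <- function(x) {
    if (inherits(x, "cbc_coxfit")) return(tidy_coxfit(x))
    if (inherits(x, "cbc_pooled_fit")) {
      return(data.frame(term = names(x$coefficients),
                        coef = unname(x$coefficients), hr = unname(x$hr),
                        total_se = unname(x$total_se)))
    }
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, to_json))
    x
  }
  keep <- setdiff(names(res$fits), c("imputation", "bands"))
  jsonlite::write_json(
    list(fits = to_json(res$fits[keep]),
         diagnostics = res$diagnostics, manifest = res$manifest),
    out("results.json"), auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(res$exclusions, out("exclusions.csv"), row.names = FALSE)
  tabs <- list()
  if (!is.null(res$fits$continuous)) {
    tabs$continuous <- cbind(analysis = "continuous",
                             tidy_coxfit(res$fits$continuous))
  }
  if (!is.null(res$fits$categorical)) {
    bt <- res$fits$categorical$band_table
    tabs$categorical <- data.frame(analysis = "categorical", term = bt$band,
                                   coef = log(bt$hr), robust_se = NA,
                                   hr = bt$hr, ci95_low = bt$ci95_low,
                                   ci95_high = bt$ci95_high, p = bt$p,
                                   n_subjects = NA, n_events = NA)
  }
  if (length(tabs)) {
    utils::write.csv(do.call(rbind, tabs), out("table2.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(res$manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cfg$out_dir)
}

#' Run the absolute-risk calculator over age groups and percentiles
#'
#' Uses fitted parameters from an association run when supplied, otherwise
#' the explicit `beta`/`gamma` in the config. For each age group in the
#' schedule, evaluates the effective per-SD effect at the configured
#' representative age, constrains the baseline hazard and emits percentile
#' curves plus the conservation-check deviation.
#'
#' @param config A `cbc_run_config` (needs `schedule`, `beta` or a fit,
#'   `gamma`, `ages`, `percentiles`).
#' @param fit Optional `cbc_coxfit` whose `z` coefficient (and
#'   `z:age_bc1`, when present) supply beta and gamma.
#' @param write Write `curves.csv` and `conservation.json` to `out_dir`.
#' @return List with `curves` (data.frame) and `conservation` (named
#'   deviations per age group).
#' @export
run_risk_curves <- function(config, fit = NULL, write = TRUE) {
  cfg <- if (inherits(config, "cbc_run_config")) config else
    read_run_config(config)
  if (is.null(cfg$schedule)) stop("config must provide an incidence schedule")
  schedule <- if (is.data.frame(cfg$schedule)) cfg$schedule else
    read_incidence_schedule(cfg$schedule)
  if (!is.null(fit)) {
    beta <- unname(fit$coefficients["z"])
    gamma <- if ("z:age_bc1" %in% names(fit$coefficients)) {
      unname(fit$coefficients["z:age_bc1"])
    } else cfg$gamma
  } else {
    if (is.null(cfg$beta)) stop("provide a fit or an explicit beta")
    beta <- cfg$beta
    gamma <- cfg$gamma
  }
  groups <- unique(schedule$age_group)
  ages <- cfg$ages
  if (length(ages) == 1) ages <- rep(ages, length(groups))
  if (length(ages) != length(groups)) {
    stop("ages must match the schedule's age groups")
  }
  curves <- list()
  conservation <- numeric(0)
  for (i in seq_along(groups)) {
    sub <- schedule[schedule$age_group == groups[i], , drop = FALSE]
    be <- effective_beta(beta, gamma, ages[i])
    bl <- constrain_baseline(sub, be)
    cc <- percentile_risk_curves(bl, cfg$percentiles)
    cc$age_group <- groups[i]
    curves[[i]] <- cc
    conservation[groups[i]] <- marginal_conservation_check(bl)
  }
  curves <- do.call(rbind, curves)
  if (write) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(curves[c("age_group", "percentile", "t", "cum_risk")],
                     file.path(cfg$out_dir, "curves.csv"), row.names = FALSE)
    jsonlite::write_json(as.list(conservation),
                         file.path(cfg$out_dir, "conservation.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(curves = curves, conservation = conservation)
}

#' Simulate a study and write its files
#'
#' Emits the weight TSV, the dosage CSV (and optionally a minimal VCF with
#' a `DS` FORMAT field), the phenotype CSV and a truth JSON carrying the
#' generative parameters.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param vcf Also write the dosage VCF.
#' @return `out_dir`, invisibly; files `weights.tsv`, `dosages.csv`,
#'   (`dosages.vcf`), `phenotypes.csv`, `truth.json`.
#' @export
run_simulation <- function(config, out_dir, vcf = FALSE) {
  sim <- simulate_cbc_study(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_weight_panel(sim$panel, file.path(out_dir, "weights.tsv"))
  write_dosage_csv(sim$dosages, file.path(out_dir, "dosages.csv"))
  if (vcf) write_dosage_vcf(sim$dosages, sim$panel,
                            file.path(out_dir, "dosages.vcf"))
  utils::write.csv(sim$records, file.path(out_dir, "phenotypes.csv"),
                   row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
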