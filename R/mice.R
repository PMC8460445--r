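# Chained-equation imputation and estimate pooling.

draw_coefs <- function(fit) {
  co <- stats::coef(fit)
  V <- stats::vcov(fit)
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(co)
  co + drop(t(L) %*% stats::rnorm(length(co)))
}

impute_one <- function(y, X, miss) {
  obs <- !miss
  df <- data.frame(.y = y, X, stringsAsFactors = FALSE)
  if (is.numeric(y)) {
    # Linear model + predictive-mean matching (5 donors)
    fit <- stats::lm(.y ~ ., data = df[obs, , drop = FALSE])
    bs <- draw_coefs(fit)
    mm <- stats::model.matrix(stats::delete.response(stats::terms(fit)),
                              data = df)
    pred <- drop(mm %*% bs)
    yhat_obs <- pred[obs]
    yobs <- y[obs]
    sapply(pred[miss], function(ph) {
      d <- abs(yhat_obs - ph)
      donors <- order(d)[seq_len(min(5, length(d)))]
      yobs[sample(donors, 1)]
    })
  } else {
    f <- droplevels(factor(y[obs]))
    if (nlevels(f) < 2) return(rep(levels(f)[1], sum(miss)))
    if (nlevels(f) == 2) {
      fit <- stats::glm(.y ~ ., data = transform(df, .y = factor(.y))[obs, ],
                        family = stats::binomial())
      bs <- draw_coefs(fit)
      mm <- stats::model.matrix(stats::delete.response(stats::terms(fit)),
                                data = df)
      p1 <- stats::plogis(drop(mm %*% bs))[miss]
      lv <- levels(f)
      ifelse(stats::runif(sum(miss)) < p1, lv[2], lv[1])
    } else {
      # Ordered categorical: proportional-odds model
      dfo <- df
      dfo$.y <- factor(dfo$.y, levels = levels(f), ordered = TRUE)
      fit <- suppressWarnings(
        MASS::polr(.y ~ ., data = dfo[obs, , drop = FALSE], Hess = TRUE))
      pr <- stats::predict(fit, newdata = dfo[miss, , drop = FALSE],
                           type = "probs")
      if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1)
      apply(pr, 1, function(p) sample(levels(f), 1, prob = p))
    }
  }
}

#' Multiple imputation by chained equations
#'
#' Imputes the covariates with missing values by iterated conditional
#' models, visiting variables in order of ascending missing fraction
#' (least missing first). Per-variable models: logistic for binary,
#' proportional-odds for categorical with 3+ levels, linear regression with
#' predictive-mean matching for continuous. The event indicator and
#' log follow-up time (columns `event` and `log_time` when present, plus
#' any fully observed covariates and `z`) enter every imputation model.
#'
#' @param data data.frame including the variables to impute; character
#'   columns are treated as categorical.
#' @param vars Variables to impute (default: all columns with any `NA`).
#' @param m Number of completed datasets (>= 2; 10 is the convention).
#' @param maxit Chained-equation iterations per dataset.
#' @param seed Integer seed; the full impute chain is deterministic.
#' @return A `cbc_imputation_set`: list with `completed` (list of m
#'   data.frames with no missing values in `vars`), `m`, `visit_order`,
#'   `seed`.
#' @export
mice_impute <- function(data, vars = NULL, m = 10, maxit = 10, seed = 1L) {
  if (m < 2) stop("m must be >= 2")
  miss_frac <- vapply(data, function(x) mean(is.na(x)), numeric(1))
  vars <- vars %||% names(miss_frac)[miss_frac > 0]
  if (!length(vars)) {
    return(structure(list(completed = rep(list(data), m), m = m,
                          visit_order = character(0), seed = seed),
                     class = "cbc_imputation_set"))
  }
  full_missing <- vars[miss_frac[vars] >= 1]
  if (length(full_missing)) {
    stop("variable 100% missing: ", paste(full_missing, collapse = ", "))
  }
  if (!any(miss_frac == 0)) stop("need at least one fully observed variable")
  visit <- vars[order(miss_frac[vars])]
  predictors <- setdiff(names(data)[miss_frac == 0],
                        c("subject_id", "family_id", "cluster", "stratum"))
  set.seed(seed)
  completed <- vector("list", m)
  for (i in seq_len(m)) {
    d <- data
    miss <- lapply(vars, function(v) is.na(data[[v]]))
    names(miss) <- vars
    # Initial fill: sample from the observed margins
    for (v in vars) {
      obs <- d[[v]][!miss[[v]]]
      d[[v]][miss[[v]]] <- sample(obs, sum(miss[[v]]), replace = TRUE)
    }
    for (it in seq_len(maxit)) {
      for (v in visit) {
        rhs <- unique(c(setdiff(visit, v), predictors))
        X <- d[rhs]
        X[] <- lapply(X, function(x) if (is.character(x)) factor(x) else x)
        d[[v]][miss[[v]]] <- impute_one(data[[v]], X, miss[[v]])
      }
    }
    completed[[i]] <- d
  }
  structure(list(completed = completed, m = m, visit_order = visit,
                 seed = seed),
            class = "cbc_imputation_set")
}

#' Pool per-imputation Cox estimates
#'
#' The pooled coefficient is the arithmetic mean of the per-imputation
#' coefficients. The Rubin total variance, within + (1 + 1/m) * between, is
#' also computed and drives the pooled confidence intervals reported here
#' (the mean-of-estimates rule alone gives no interval).
#'
#' @param fits List of `cbc_coxfit` objects with identical model terms.
#' @return A list of class `cbc_pooled_fit`: `coefficients`, `hr`,
#'   `within_var`, `between_var`, `total_se`, `ci95_low`, `ci95_high`, `p`,
#'   `m`.
#' @export
pool_estimates <- function(fits) {
  if (!length(fits)) stop("no fits to pool")
  terms <- names(fits[[1]]$coefficients)
  for (f in fits) {
    if (!identical(names(f$coefficients), terms)) {
      stop("model terms differ across imputations")
    }
  }
  m <- length(fits)
  co <- sapply(fits, function(f) f$coefficients)
  se <- sapply(fits, function(f) f$robust_se)
  if (is.null(dim(co))) {
    co <- matrix(co, nrow = 1, dimnames = list(terms))
    se <- matrix(se, nrow = 1, dimnames = list(terms))
  }
  pooled <- rowMeans(co)
  within <- rowMeans(se^2)
  between <- if (m > 1) apply(co, 1, stats::var) else rep(0, length(terms))
  total <- within + (1 + 1 / m) * between
  tse <- sqrt(total)
  structure(list(
    coefficients = pooled, hr = exp(pooled),
    within_var = within, between_var = between, total_se = tse,
    ci95_low = exp(pooled - 1.96 * tse),
    ci95_high = exp(pooled + 1.96 * tse),
    p = 2 * stats::pnorm(-abs(pooled / tse)),
    m = m
  ), class = "cbc_pooled_fit")
}

#' @export
print.cbc_pooled_fit <- function(x, ...) {
  cat(sprintf("Pooled Cox estimates over %d imputations\n", x$m))
  print(round(data.frame(coef = x$coefficients, HR = x$hr,
                         total_se = x$total_se, lower95 = x$ci95_low,
                         upper95 = x$ci95_high, p = x$p), 4))
  invisible(x)
}
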