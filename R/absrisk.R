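# Constrained-incidence calculator: solve the baseline CBC hazard so that
# the PRS-density-averaged incidence reproduces an external marginal
# schedule, then emit percentile-specific absolute risk curves.

validate_schedule <- function(schedule) {
  if (!all(c("t", "rate") %in% names(schedule))) {
    stop("schedule needs columns t and rate")
  }
  if (any(schedule$rate < 0)) stop("negative marginal incidence rate")
  dt <- diff(schedule$t)
  if (any(dt <= 0)) stop("schedule grid must be strictly increasing")
  if (length(dt) && max(abs(dt - dt[1])) > 1e-8) {
    stop("schedule grid must have a uniform step")
  }
  invisible(schedule)
}

#' Constant marginal incidence schedule
#'
#' Convenience constructor: a constant hazard whose cumulative risk at
#' `horizon` equals `cum_risk`, on a uniform grid of step `dt` starting at
#' the schedule origin (time of first breast cancer).
#'
#' @param cum_risk Target cumulative risk at `horizon` (in (0, 1)).
#' @param horizon Horizon in years.
#' @param dt Grid step in years.
#' @param age_group Optional label.
#' @return data.frame `age_group`, `t`, `rate`; the grid point `t` carries
#'   the rate on `[t, t + dt)`.
#' @export
constant_incidence_schedule <- function(cum_risk, horizon = 20, dt = 0.1,
                                        age_group = "all") {
  if (cum_risk <= 0 || cum_risk >= 1) stop("cum_risk must be in (0, 1)")
  rate <- -log(1 - cum_risk) / min(horizon, horizon)
  rate <- -log(1 - cum_risk) / horizon
  t <- seq(0, horizon - dt, by = dt)
  validate_schedule(data.frame(age_group = age_group, t = t, rate = rate,
                               stringsAsFactors = FALSE))
}

#' Standard-normal percentile nodes
#'
#' @param n Number of nodes.
#' @return List `z` (normal quantiles at the midpoints (k - 0.5)/n) and `w`
#'   (equal weights summing to 1).
#' @export
percentile_nodes <- function(n = 99) {
  list(z = stats::qnorm((seq_len(n) - 0.5) / n), w = rep(1 / n, n))
}

#' Gauss-Hermite nodes on the standard normal
#'
#' Accuracy cross-check for the percentile node scheme.
#'
#' @param n Number of nodes.
#' @return List `z`, `w` with `sum(w) = 1`.
#' @export
gauss_hermite_nodes <- function(n = 40) {
  # Golub-Welsch on the Hermite Jacobi matrix, rescaled to N(0,1)
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(z = sqrt(2) * e$values, w = e$vectors[1, ]^2)
}

#' Effective per-SD log hazard ratio at a given age at first cancer
#'
#' With a PRS-by-age interaction, the per-SD effect at age `a` is
#' `beta + gamma * a` (age uncentered; pass `age_bc1 - center` to apply a
#' centering offset).
#'
#' @param beta Log HR per SD (main effect).
#' @param gamma Log HR per SD per year of age at first BC.
#' @param age_bc1 Age at first breast cancer (years).
#' @return `beta + gamma * age_bc1`.
#' @export
effective_beta <- function(beta, gamma, age_bc1) {
  stopifnot(is.finite(beta), is.finite(gamma), all(is.finite(age_bc1)))
  beta + gamma * age_bc1
}

#' Constrain the baseline hazard to a marginal incidence schedule
#'
#' Forward recursion over the schedule grid: at each step the baseline
#' hazard is the marginal rate deflated by the risk-weighted composition of
#' the surviving cohort,
#' `lambda0(t) = lambda_m(t) * sum_k w_k S_k(t) / sum_k w_k S_k(t) exp(beta_eff z_k)`,
#' followed by the node-specific survival update
#' `S_k(t + dt) = S_k(t) * exp(-lambda0(t) exp(beta_eff z_k) dt)` with
#' `S_k(0) = 1`. In the continuous-time limit the density-weighted survival
#' equals the marginal survival exactly; at step `dt` the discrepancy is
#' first order in `dt`.
#'
#' @param schedule data.frame with uniform grid `t` and marginal `rate`
#'   (per year); rows apply on `[t, t + dt)`.
#' @param beta_eff Effective log HR per SD (see [effective_beta()]).
#' @param nodes PRS nodes as from [percentile_nodes()].
#' @return A `cbc_constrained_baseline`: `t`, `dt`, `lambda0`, `beta_eff`,
#'   `nodes`, `S` (node survival at the grid ends), `lambda_m`.
#' @export
constrain_baseline <- function(schedule, beta_eff, nodes = percentile_nodes(99)) {
  validate_schedule(schedule)
  if (abs(sum(nodes$w) - 1) > 1e-8) stop("node weights must sum to 1")
  t <- schedule$t
  dt <- if (length(t) > 1) t[2] - t[1] else 1
  rel <- exp(beta_eff * nodes$z)
  K <- length(rel)
  S <- rep(1, K)
  lambda0 <- numeric(length(t))
  Smat <- matrix(NA_real_, length(t), K)
  for (i in seq_along(t)) {
    num <- sum(nodes$w * S)
    den <- sum(nodes$w * S * rel)
    if (den <= 0 || num <= 0) stop("cohort exhausted: all node survival zero")
    lambda0[i] <- schedule$rate[i] * num / den
    S <- S * exp(-lambda0[i] * rel * dt)
    Smat[i, ] <- S
  }
  structure(list(t = t, dt = dt, lambda0 = lambda0, beta_eff = beta_eff,
                 nodes = nodes, S = Smat, lambda_m = schedule$rate),
            class = "cbc_constrained_baseline")
}

#' Cumulative risk curves at PRS percentiles
#'
#' For percentile p, `z_p` is the standard-normal quantile and
#' `F(t | z_p) = 1 - exp(-sum_{u <= t} lambda0(u) exp(beta_eff z_p) dt)`.
#'
#' @param baseline A [constrain_baseline()] result.
#' @param percentiles Percentiles in (0, 100).
#' @return data.frame `percentile`, `z`, `t` (interval end times),
#'   `cum_risk`.
#' @export
percentile_risk_curves <- function(baseline, percentiles = c(5, 25, 50, 75, 95)) {
  if (any(percentiles <= 0 | percentiles >= 100)) {
    stop("percentiles must be inside (0, 100)")
  }
  zp <- stats::qnorm(percentiles / 100)
  tend <- baseline$t + baseline$dt
  H0 <- cumsum(baseline$lambda0 * baseline$dt)
  out <- do.call(rbind, lapply(seq_along(zp), function(i) {
    data.frame(percentile = percentiles[i], z = zp[i], t = tend,
               cum_risk = 1 - exp(-H0 * exp(baseline$beta_eff * zp[i])))
  }))
  rownames(out) <- NULL
  out
}

#' Conservation check of the constrained baseline
#'
#' Maximum absolute deviation over the grid between the density-weighted
#' average of node-specific cumulative risks and the marginal cumulative
#' risk implied by the schedule. Shrinks at first order in the grid step.
#'
#' @param baseline A [constrain_baseline()] result.
#' @return Maximum absolute deviation (a risk, on [0, 1]).
#' @export
marginal_conservation_check <- function(baseline) {
  Fbar <- 1 - drop(baseline$S %*% baseline$nodes$w)
  Fm <- 1 - exp(-cumsum(baseline$lambda_m * baseline$dt))
  max(abs(Fbar - Fm))
}

#' Density-weighted average cumulative risk at a horizon
#'
#' The testable face of the constraint: the node-weight average of the
#' node-specific cumulative risks at `horizon`, which should equal the
#' marginal cumulative risk of the input schedule.
#'
#' @param baseline A [constrain_baseline()] result.
#' @param horizon Years since first BC (must be a grid end point).
#' @return Average cumulative risk in [0, 1].
#' @export
average_cumulative_risk <- function(baseline, horizon) {
  tend <- baseline$t + baseline$dt
  i <- which.min(abs(tend - horizon))
  if (abs(tend[i] - horizon) > baseline$dt / 2 + 1e-9) {
    stop("horizon not on the schedule grid")
  }
  1 - sum(baseline$nodes$w * baseline$S[i, ])
}
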