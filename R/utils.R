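# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' One master seed drives a run; each stage draws from its own deterministic
#' child seed so that changing one stage's sampling does not perturb another.
#'
#' @param seed Master seed (integer).
#' @param stage Stage label, one of the known stage names, or an integer index.
#' @return An integer seed in `[0, 2^31 - 20)`.
#' @export
derive_seed <- function(seed, stage) {
  offsets <- c(
    panel = 101, genotypes = 211, cohort = 307, events = 401,
    missingness = 503, impute = 601, bootstrap = 701, replicate = 809
  )
  off <- if (is.character(stage)) {
    if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
    offsets[[stage]]
  } else {
    as.numeric(stage)
  }
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483629)
}

assert_prop <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(name, " must be a proportion in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name = deparse(substitute(x)), min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(name, " must be an integer >= ", min, call. = FALSE)
  }
  invisible(as.integer(x))
}

# Truncated normal sampler by inverse-CDF; degenerate sd = 0 returns the mean.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}
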