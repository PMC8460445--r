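#' Piecewise-constant hazard on the time-since-first-cancer scale
#'
#' The simulator's event clock runs in years since the first breast cancer,
#' with delayed entry at 1 year (the synchronous-exclusion window contributes
#' no risk). A hazard is a step function: `rates[i]` applies on
#' `[breaks[i], breaks[i+1])`, the last piece extending to infinity.
#'
#' @param rates Positive hazard rates per year, one per piece.
#' @param breaks Increasing piece start times (years since first BC);
#'   defaults to a single piece starting at the 1-year entry.
#' @return An object of class `cbc_hazard`.
#' @export
piecewise_hazard <- function(rates, breaks = 1) {
  if (length(rates) != length(breaks)) stop("rates and breaks must align")
  if (any(!is.finite(rates)) || any(rates <= 0)) stop("hazard rates must be > 0")
  if (is.unsorted(breaks, strictly = TRUE)) stop("breaks must be increasing")
  structure(list(rates = as.numeric(rates), breaks = as.numeric(breaks)),
            class = "cbc_hazard")
}

#' Cumulative hazard of a piecewise-constant hazard
#'
#' @param hz A [piecewise_hazard()] object.
#' @param t Times (years since first BC); values before the first break
#'   accumulate no hazard.
#' @return Cumulative hazard at each `t`.
#' @export
cum_hazard <- function(hz, t) {
  ends <- c(hz$breaks[-1], Inf)
  H <- numeric(length(t))
  for (i in seq_along(hz$rates)) {
    H <- H + hz$rates[i] * pmax(0, pmin(t, ends[i]) - hz$breaks[i])
  }
  H
}

# Inverse of cum_hazard: smallest t with H(t) = H. H beyond the last finite
# piece maps into the unbounded final piece.
inv_cum_hazard <- function(hz, H) {
  ends <- c(hz$breaks[-1], Inf)
  cumH <- cumsum(hz$rates * (ends - hz$breaks)) # last entry Inf
  piece <- findInterval(H, c(0, cumH[-length(cumH)]), rightmost.closed = FALSE)
  piece <- pmax(piece, 1L)
  base <- c(0, cumH)[piece]
  hz$breaks[piece] + (H - base) / hz$rates[piece]
}

# Scale every rate by s (used by event-fraction calibration).
scale_hazard <- function(hz, s) piecewise_hazard(hz$rates * s, hz$breaks)
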