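#' Closed-form solution of the logistic growth equation
#'
#' Solves dN/dt = r N (1 - N/K) exactly:
#' \code{N(t) = K n0 e^{rt} / (K + n0 (e^{rt} - 1))}, evaluated in the
#' numerically stable form \code{n0 K / (n0 + (K - n0) e^{-rt})} so large
#' \code{r t} cannot overflow. \code{n0 = 0} is the absorbing state and
#' returns 0.
#'
#' @param n0 initial abundance, cells; non-negative.
#' @param r growth rate, 1/hr; positive.
#' @param K carrying capacity, cells; positive.
#' @param t elapsed time, hours; non-negative. Vectorized over \code{t}
#'   (and over \code{n0} if \code{t} is scalar).
#' @return abundance at time t, cells.
#' @examples
#' logistic_solution(100, 0.6, 10^3.2, 6)
#' logistic_solution(10^3.2, 0.6, 10^3.2, 10)  # fixed point: stays at K
#' @export
logistic_solution <- function(n0, r, K, t) {
  if (!all(is.finite(n0)) || !all(is.finite(r)) || !all(is.finite(K)) ||
      !all(is.finite(t))) {
    stop("non-finite inputs to logistic_solution()")
  }
  if (any(n0 < 0)) stop("'n0' must be non-negative")
  if (any(r <= 0)) stop("'r' must be positive")
  if (any(K <= 0)) stop("'K' must be positive")
  if (any(t < 0)) stop("'t' must be non-negative")
  .logistic(n0, r, K, t)
}

# unchecked core, used in simulator inner loops; handles n0 = 0 exactly
.logistic <- function(n0, r, K, t) {
  n0 * K / (n0 + (K - n0) * exp(-r * t))
}
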