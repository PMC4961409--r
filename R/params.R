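#' Parameters of the stochastic collapse-logistic model
#'
#' Bundles the full parameterization of the model: deterministic logistic
#' growth with intrinsic rate \code{r} and carrying capacity \code{K},
#' punctuated by collapse events that arrive as a homogeneous Poisson process
#' with rate \code{p_c} and multiply the population by a fraction
#' \code{f = 10^x}, where \code{x} is either fixed at \code{mu_logf}
#' (\code{sigma_logf = 0}) or drawn from a Normal(\code{mu_logf},
#' \code{sigma_logf}) truncated so that \code{f <= 1}. Populations falling
#' below \code{extinction_threshold} are set to zero and absorbed (organisms
#' are discrete; without absorption the logistic always recovers and cannot
#' produce the host-to-host variance seen in plating ensembles). Optional
#' host-to-host variability in the carrying capacity is modeled by drawing a
#' per-trajectory \code{K} from a log10-normal with SD \code{sigma_logK}
#' decades.
#'
#' The defaults are the challenge-condition estimates for \emph{Aeromonas}
#' under \emph{Vibrio} invasion in the larval zebrafish gut: plating-derived
#' growth rate 0.6/hr, fitted carrying capacity \code{10^3.2} cells, imaging-
#' derived collapse rate 0.07/hr and mean collapse magnitude
#' \code{log10(f) = -1.9}.
#'
#' @param r intrinsic growth rate, 1/hr; must be positive.
#' @param K carrying capacity, cells; at least 1.
#' @param p_c collapse probability per unit time, 1/hr; non-negative.
#' @param mu_logf mean of log10 collapse fraction f, decades; non-positive.
#' @param sigma_logf SD of log10(f), decades; 0 gives a fixed f.
#' @param sigma_logK SD of per-host log10 carrying capacity, decades; 0
#'   disables host-to-host K variability.
#' @param extinction_threshold abundance below which the population is set to
#'   0 and absorbed, cells.
#'
#' @return An object of class \code{collapse_params}: a named list of the
#'   validated parameters.
#' @seealso [compute_z()], [simulate_trajectory()], [simulate_ensemble()]
#' @examples
#' p <- collapse_params(r = 0.6, K = 10^3.2, p_c = 0.07, mu_logf = -1.9)
#' p
#' compute_z(p$p_c, p$mu_logf)
#' @export
collapse_params <- function(r = 0.6, K = 10^3.2, p_c = 0.07, mu_logf = -1.9,
                            sigma_logf = 0, sigma_logK = 0,
                            extinction_threshold = 1) {
  vals <- list(r = r, K = K, p_c = p_c, mu_logf = mu_logf,
               sigma_logf = sigma_logf, sigma_logK = sigma_logK,
               extinction_threshold = extinction_threshold)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("'", nm, "' must be a single finite number")
    }
  }
  if (r <= 0) stop("'r' must be positive")
  if (K < 1) stop("'K' must be at least 1")
  if (p_c < 0) stop("'p_c' must be non-negative")
  if (mu_logf > 0) stop("'mu_logf' must be <= 0 (f cannot exceed 1)")
  if (sigma_logf < 0 || sigma_logK < 0) {
    stop("'sigma_logf' and 'sigma_logK' must be non-negative")
  }
  if (extinction_threshold < 0) stop("'extinction_threshold' must be >= 0")
  structure(vals, class = "collapse_params")
}

#' @export
print.collapse_params <- function(x, ...) {
  cat("Stochastic collapse-logistic model parameters\n")
  cat(sprintf("  growth rate r            : %.4g /hr\n", x$r))
  cat(sprintf("  carrying capacity K      : %.4g cells (log10 K = %.3g)\n",
              x$K, log10(x$K)))
  if (x$sigma_logK > 0) {
    cat(sprintf("  per-host SD of log10 K   : %.3g decades\n", x$sigma_logK))
  }
  cat(sprintf("  collapse rate p_c        : %.4g /hr\n", x$p_c))
  if (x$sigma_logf > 0) {
    cat(sprintf("  log10 f ~ Normal(%.3g, %.3g), truncated at f <= 1\n",
                x$mu_logf, x$sigma_logf))
  } else {
    cat(sprintf("  collapse fraction f      : %.4g (log10 f = %.3g)\n",
                10^x$mu_logf, x$mu_logf))
  }
  cat(sprintf("  extinction threshold     : %.4g cells\n",
              x$extinction_threshold))
  cat(sprintf("  collapse intensity z     : %.4g /hr\n",
              compute_z(x$p_c, x$mu_logf)))
  invisible(x)
}

#' Collapse intensity z
#'
#' The endpoint statistics of the collapse-logistic model depend on the
#' collapse rate \code{p_c} and magnitude \code{f} only through the combined
#' intensity \code{z = -p_c * log10(f)} (decades lost per hour to collapses),
#' so \code{(p_c, f)} pairs sharing \code{z} are statistically equivalent at
#' matched \code{(r, K)}.
#'
#' @param p_c collapse probability per unit time, 1/hr; non-negative.
#' @param mean_log10_f mean of log10 collapse fraction, decades; non-positive.
#' @return z in 1/hr, unrounded.
#' @examples
#' compute_z(0.07, -1.9)  # 0.133, i.e. 0.13 to two decimals
#' @export
compute_z <- function(p_c, mean_log10_f) {
  if (!is.numeric(p_c) || !is.numeric(mean_log10_f)) {
    stop("'p_c' and 'mean_log10_f' must be numeric")
  }
  if (any(!is.finite(p_c)) || any(!is.finite(mean_log10_f))) {
    stop("non-finite inputs to compute_z()")
  }
  if (any(p_c < 0)) stop("'p_c' must be non-negative")
  if (any(mean_log10_f > 0)) {
    stop("'mean_log10_f' must be <= 0 (a collapse cannot increase abundance)")
  }
  -p_c * mean_log10_f
}
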