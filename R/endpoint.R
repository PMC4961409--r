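#' Terminal abundance ensemble (plating-style data)
#'
#' Container for terminal abundances across hosts from a dissection-and-
#' plating experiment (or a simulated analogue), together with the censoring
#' metadata of the assay: the limit of detection (\code{lod}, default 5
#' CFU/gut) and the limit of quantification (\code{loq}, default 100
#' CFU/gut). Samples with zero countable colonies are recorded as 0 and are
#' only replaced by \code{lod} inside [endpoint_stats()], mirroring the order
#' of operations of the plating protocol.
#'
#' @param abundances CFU per gut, non-negative.
#' @param host_ids optional identifiers (defaults to \code{host1, host2, ...}).
#' @param condition experimental condition label.
#' @param t_final hours since inoculation or challenge at which the guts were
#'   harvested.
#' @param lod,loq limits of detection / quantification, CFU.
#' @return an object of class \code{endpoint_ensemble}.
#' @export
endpoint_ensemble <- function(abundances, host_ids = NULL, condition = "",
                              t_final = NA_real_, lod = 5, loq = 100) {
  if (!is.numeric(abundances) || length(abundances) < 1) {
    stop("'abundances' must be a non-empty numeric vector")
  }
  if (any(!is.finite(abundances)) || any(abundances < 0)) {
    stop("'abundances' must be finite and non-negative")
  }
  if (lod > loq) stop("'lod' must not exceed 'loq'")
  if (is.null(host_ids)) host_ids <- paste0("host", seq_along(abundances))
  if (length(host_ids) != length(abundances)) {
    stop("'host_ids' and 'abundances' lengths differ")
  }
  structure(list(host_ids = as.character(host_ids),
                 abundances = as.numeric(abundances),
                 condition = condition, t_final = t_final,
                 lod = lod, loq = loq),
            class = "endpoint_ensemble")
}

#' @export
print.endpoint_ensemble <- function(x, ...) {
  cat(sprintf("endpoint_ensemble: %d hosts%s%s (lod %g, loq %g)\n",
              length(x$abundances),
              if (nzchar(x$condition)) paste0(", condition '", x$condition, "'") else "",
              if (is.finite(x$t_final)) sprintf(", t = %g hr", x$t_final) else "",
              x$lod, x$loq))
  if (length(x$abundances) >= 2) {
    s <- endpoint_stats(x)
    cat(sprintf("  mean(log10(N+1)) = %.3g, SD = %.3g (censored at lod)\n",
                s$mean_log, s$sd_log))
  }
  invisible(x)
}

#' Censored endpoint statistics
#'
#' Replaces abundances below the limit of detection by \code{lod} (plating
#' zeros are set to the LOD before statistics) and returns the mean and
#' sample standard deviation (n-1 denominator) of \code{log10(abundance + 1)}
#' -- the summary statistics through which the model is compared with plating
#' ensembles.
#'
#' @param ensemble an [endpoint_ensemble()] with at least 2 hosts.
#' @return list with \code{mean_log}, \code{sd_log} (decades) and \code{n}.
#' @examples
#' e <- endpoint_ensemble(c(0, 10000), lod = 5)
#' endpoint_stats(e)  # mean of log10(6) and log10(10001), about 2.389
#' @export
endpoint_stats <- function(ensemble) {
  stopifnot(inherits(ensemble, "endpoint_ensemble"))
  x <- ensemble$abundances
  if (length(x) < 2) stop("at least 2 hosts are required")
  lx <- log10(pmax(x, ensemble$lod) + 1)
  list(mean_log = mean(lx), sd_log = stats::sd(lx), n = length(lx))
}
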