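#' One host-by-species abundance time series
#'
#' Imaging-derived abundance trajectory for one bacterial species in one host,
#' sampled at discrete times (typically every 20 min over 12-15 hr). Times
#' removed by quality control may be listed in \code{excluded_times}; they are
#' dropped from the series but remembered so observation time can discount
#' long gaps.
#'
#' @param host_id host identifier.
#' @param species species label.
#' @param times hours, strictly increasing.
#' @param abundance cells, non-negative, same length as \code{times}.
#' @param excluded_times optional times removed by QC (subset of the original
#'   grid; they must not appear in \code{times}).
#' @return object of class \code{abundance_series}.
#' @export
abundance_series <- function(host_id, species, times, abundance,
                             excluded_times = NULL) {
  times <- as.numeric(times)
  abundance <- as.numeric(abundance)
  if (length(times) != length(abundance)) {
    stop("'times' and 'abundance' lengths differ")
  }
  if (length(times) > 0 && (any(!is.finite(times)) || is.unsorted(times, strictly = TRUE))) {
    stop("'times' must be finite, strictly increasing and free of duplicates")
  }
  if (any(!is.finite(abundance)) || any(abundance < 0)) {
    stop("'abundance' must be finite and non-negative")
  }
  if (!is.null(excluded_times) && any(excluded_times %in% times)) {
    stop("'excluded_times' must not overlap retained 'times'")
  }
  structure(list(host_id = as.character(host_id),
                 species = as.character(species),
                 times = times, abundance = abundance,
                 excluded_times = excluded_times),
            class = "abundance_series")
}

#' @export
print.abundance_series <- function(x, ...) {
  cat(sprintf("abundance_series %s/%s: %d points, %.3g-%.3g hr\n",
              x$host_id, x$species, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.abundance_series <- function(x, ...) {
  data.frame(host_id = x$host_id, species = x$species, time_hr = x$times,
             abundance = x$abundance, stringsAsFactors = FALSE)
}

#' Detect population collapse events in a time series
#'
#' A collapse is a decrease in population by at least \code{drop_factor}
#' (default 10) within \code{window_hr} (default 1 hr); candidates whose
#' pre-collapse population is below \code{min_pre} (default 100 cells) are
#' discarded, since small populations cannot yield reliable ratios. All
#' ordered point pairs within the window are scanned; overlapping triggering
#' pairs describing one monotone decline are merged into a single event whose
#' \code{n_before} is the local maximum preceding the drop and \code{n_after}
#' the local minimum terminating it, so discrete purge episodes are counted
#' once rather than once per pair.
#'
#' A drop to zero abundance is kept as an event; its \code{f} is recorded as
#' \code{(n_after + 1) / n_before} and flagged in the \code{zero_after}
#' column so log statistics stay finite.
#'
#' @param series an [abundance_series()] (or a data frame with columns
#'   \code{time_hr} and \code{abundance}).
#' @param drop_factor minimum fold-decrease defining a collapse; > 1.
#' @param window_hr time window within which the drop must occur, hours.
#' @param min_pre minimum pre-collapse population, cells.
#' @return data frame of class \code{collapse_events} with columns
#'   \code{host_id}, \code{time} (time of the post-collapse minimum, hr),
#'   \code{t_before}, \code{t_after}, \code{n_before}, \code{n_after},
#'   \code{f}, \code{zero_after}; zero rows if no collapse is found.
#' @examples
#' s <- abundance_series("f1", "aeromonas",
#'                       times = c(0, 1/3, 2/3),
#'                       abundance = c(1000, 50, 55))
#' detect_collapses(s)
#' @export
detect_collapses <- function(series, drop_factor = 10, window_hr = 1,
                             min_pre = 100) {
  if (is.data.frame(series)) {
    series <- abundance_series(
      host_id = if ("host_id" %in% names(series)) series$host_id[1] else "series",
      species = if ("species" %in% names(series)) series$species[1] else "",
      times = series$time_hr, abundance = series$abundance)
  }
  stopifnot(inherits(series, "abundance_series"))
  if (drop_factor <= 1) stop("'drop_factor' must exceed 1")
  if (window_hr <= 0) stop("'window_hr' must be positive")
  tt <- series$times
  nn <- series$abundance
  n <- length(tt)
  empty <- data.frame(host_id = character(0), time = numeric(0),
                      t_before = numeric(0), t_after = numeric(0),
                      n_before = numeric(0), n_after = numeric(0),
                      f = numeric(0), zero_after = logical(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("collapse_events", "data.frame")
  if (n < 2 || all(nn == 0)) return(empty)

  tol <- 1e-9
  cand_i <- integer(0)
  cand_j <- integer(0)
  for (i in seq_len(n - 1)) {
    if (nn[i] < min_pre) next
    j <- which(tt > tt[i] & tt <= tt[i] + window_hr + tol &
                 nn <= nn[i] / drop_factor)
    j <- j[j > i]
    if (length(j)) {
      cand_i <- c(cand_i, rep(i, length(j)))
      cand_j <- c(cand_j, j)
    }
  }
  if (!length(cand_i)) return(empty)

  # merge overlapping index intervals [i, j] into maximal runs
  ord <- order(cand_i, cand_j)
  cand_i <- cand_i[ord]; cand_j <- cand_j[ord]
  merged_a <- cand_i[1]; merged_b <- cand_j[1]
  starts <- integer(0); ends <- integer(0)
  if (length(cand_i) > 1) {
    for (k in 2:length(cand_i)) {
      if (cand_i[k] <= merged_b) {
        merged_b <- max(merged_b, cand_j[k])
      } else {
        starts <- c(starts, merged_a); ends <- c(ends, merged_b)
        merged_a <- cand_i[k]; merged_b <- cand_j[k]
      }
    }
  }
  starts <- c(starts, merged_a); ends <- c(ends, merged_b)

  out <- lapply(seq_along(starts), function(k) {
    a <- starts[k]; b <- ends[k]
    jmin <- a - 1L + which.min(nn[a:b])
    imax <- a - 1L + which.max(nn[a:jmin])
    n_before <- nn[imax]; n_after <- nn[jmin]
    zero <- n_after == 0
    data.frame(host_id = series$host_id, time = tt[jmin],
               t_before = tt[imax], t_after = tt[jmin],
               n_before = n_before,
               n_after = n_after,
               f = if (zero) (n_after + 1) / n_before else n_after / n_before,
               zero_after = zero, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$time), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("collapse_events", "data.frame")
  res
}

#' Total usable observation time of a set of series
#'
#' Sum over series of the observed span, counting only gaps between
#' consecutive usable points that do not exceed \code{max_gap_hr} (default
#' 1 hr, the collapse-detection window): collapses inside longer QC gaps are
#' undetectable, so that time does not contribute to the Poisson exposure.
#'
#' @param series_list a list of [abundance_series()] (a single series is
#'   accepted).
#' @param max_gap_hr longest between-point gap counted as observed, hours.
#' @return total observation time, hours.
#' @export
observation_time <- function(series_list, max_gap_hr = 1) {
  if (inherits(series_list, "abundance_series")) series_list <- list(series_list)
  tol <- 1e-9
  sum(vapply(series_list, function(s) {
    d <- diff(s$times)
    sum(d[d <= max_gap_hr + tol])
  }, numeric(1)))
}

#' Poisson collapse statistics from detected events
#'
#' Estimates the collapse probability per unit time as the total number of
#' collapses across all hosts divided by the total observation time,
#' \code{p_c_hat = n / T}, with Poisson standard error \code{sqrt(n) / T}.
#' With zero events the estimate is 0 and a one-sided 95 percent upper bound
#' \code{3 / T} (the "rule of three") is reported instead of a standard
#' error. The magnitude summary is the mean, SD and standard error of
#' \code{log10(f)} over events.
#'
#' @param events a \code{collapse_events} data frame (possibly from several
#'   hosts, row-bound), or an empty one.
#' @param total_time total observation time across hosts, hours; see
#'   [observation_time()].
#' @return object of class \code{collapse_statistics}: list with
#'   \code{n_events}, \code{total_observation_time}, \code{p_c_hat},
#'   \code{p_c_se}, \code{p_c_upper95} (only meaningful when
#'   \code{n_events = 0}), \code{mean_log10_f}, \code{sd_log10_f},
#'   \code{se_log10_f}.
#' @examples
#' ev <- data.frame(f = 10^c(-1.5, -2.5))
#' collapse_statistics(ev, total_time = 28)
#' @export
collapse_statistics <- function(events, total_time) {
  if (!is.finite(total_time) || total_time <= 0) {
    stop("'total_time' must be positive")
  }
  n <- if (is.null(events)) 0L else nrow(events)
  if (n > 0) {
    lf <- log10(events$f)
    structure(list(n_events = n, total_observation_time = total_time,
                   p_c_hat = n / total_time,
                   p_c_se = sqrt(n) / total_time,
                   p_c_upper95 = NA_real_,
                   mean_log10_f = mean(lf),
                   sd_log10_f = if (n > 1) stats::sd(lf) else NA_real_,
                   se_log10_f = if (n > 1) stats::sd(lf) / sqrt(n) else NA_real_),
              class = "collapse_statistics")
  } else {
    structure(list(n_events = 0L, total_observation_time = total_time,
                   p_c_hat = 0, p_c_se = NA_real_,
                   p_c_upper95 = 3 / total_time,
                   mean_log10_f = NA_real_, sd_log10_f = NA_real_,
                   se_log10_f = NA_real_),
              class = "collapse_statistics")
  }
}

#' @export
print.collapse_statistics <- function(x, ...) {
  cat(sprintf("collapse_statistics: %d event(s) in %.3g hr of observation\n",
              x$n_events, x$total_observation_time))
  if (x$n_events > 0) {
    cat(sprintf("  p_c = %.3g +/- %.3g /hr (Poisson)\n", x$p_c_hat, x$p_c_se))
    cat(sprintf("  log10(f): mean %.3g, SD %.3g, SE %.3g\n",
                x$mean_log10_f, x$sd_log10_f, x$se_log10_f))
    cat(sprintf("  implied z = %.3g /hr\n",
                compute_z(x$p_c_hat, min(x$mean_log10_f, 0))))
  } else {
    cat(sprintf("  p_c = 0, one-sided 95%% upper bound %.3g /hr\n",
                x$p_c_upper95))
  }
  invisible(x)
}

#' Log-linear growth-rate estimate over a time window
#'
#' Ordinary least-squares slope of \code{ln(abundance)} against time over
#' \code{[t_start, t_end]}. Zero-abundance points cannot enter the log fit
#' and are excluded (their count is reported).
#'
#' @param series an [abundance_series()].
#' @param t_start,t_end window bounds, hours (inclusive); default the full
#'   series.
#' @return list with \code{rate} (1/hr), \code{se}, \code{n_used},
#'   \code{n_excluded}, \code{window}.
#' @examples
#' tt <- seq(0, 5, by = 1/3)
#' s <- abundance_series("f1", "vibrio", tt, 50 * exp(0.8 * tt))
#' estimate_growth_rate(s)$rate  # 0.8
#' @export
estimate_growth_rate <- function(series, t_start = -Inf, t_end = Inf) {
  stopifnot(inherits(series, "abundance_series"))
  sel <- series$times >= t_start & series$times <= t_end
  tt <- series$times[sel]
  nn <- series$abundance[sel]
  pos <- nn > 0
  if (sum(pos) < 3) {
    stop(sprintf("fewer than 3 positive-abundance points in window [%g, %g]",
                 t_start, t_end))
  }
  fit <- stats::lm(log(nn[pos]) ~ tt[pos])
  co <- summary(fit)$coefficients
  list(rate = unname(co[2, 1]),
       se = unname(co[2, 2]),
       n_used = sum(pos), n_excluded = sum(!pos),
       window = c(t_start, t_end))
}

#' Companion-species response across collapse intervals
#'
#' For each detected collapse of a focal species, computes the companion
#' species' abundance ratio across the same interval (companion abundance at
#' the sampled point nearest the post-collapse time divided by that nearest
#' the pre-collapse time). Ratios near one indicate the companion is
#' unaffected by the perturbation that collapses the focal species.
#'
#' @param focal_events a \code{collapse_events} data frame from
#'   [detect_collapses()].
#' @param companion an [abundance_series()] for the companion species in the
#'   same host; must cover each event's times (events outside its range are
#'   skipped with a warning).
#' @return data frame with columns \code{f_focal} and \code{ratio_companion}.
#' @export
companion_response <- function(focal_events, companion) {
  stopifnot(inherits(companion, "abundance_series"))
  if (nrow(focal_events) == 0) {
    return(data.frame(f_focal = numeric(0), ratio_companion = numeric(0)))
  }
  tt <- companion$times
  nn <- companion$abundance
  lo <- min(tt); hi <- max(tt)
  keep <- focal_events$t_before >= lo & focal_events$t_after <= hi
  if (any(!keep)) {
    warning(sum(!keep), " event(s) outside the companion series' time range were skipped")
  }
  ev <- focal_events[keep, , drop = FALSE]
  nearest <- function(t0) nn[which.min(abs(tt - t0))]
  ratio <- vapply(seq_len(nrow(ev)), function(k) {
    before <- nearest(ev$t_before[k])
    after <- nearest(ev$t_after[k])
    if (before == 0) NA_real_ else after / before
  }, numeric(1))
  data.frame(f_focal = ev$f, ratio_companion = ratio)
}
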