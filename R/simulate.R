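#' Simulate one trajectory of the collapse-logistic model
#'
#' Exact event-driven simulation: collapse times are drawn as a homogeneous
#' Poisson process with rate \code{p_c} (exponential inter-event waits), the
#' closed-form logistic solution carries the population between events with no
#' time-stepping error, and each event multiplies the abundance by a fraction
#' \code{f} (fixed at \code{10^mu_logf}, or drawn as \code{10^x} with
#' \code{x ~ Normal(mu_logf, sigma_logf)} truncated at \code{x <= 0} via the
#' inverse-CDF method). Abundance below \code{extinction_threshold} is set to
#' zero and absorbed. If \code{sigma_logK > 0} the trajectory's carrying
#' capacity is drawn once as \code{10^Normal(log10 K, sigma_logK)}. There is
#' no refractory period: collapses may interrupt recovery.
#'
#' @param params a [collapse_params()] object.
#' @param n0 initial abundance, cells.
#' @param horizon simulated duration, hours.
#' @param output_dt spacing of the output grid, hours; must not exceed
#'   \code{horizon}.
#' @param seed optional integer seed; a fixed seed makes the trajectory
#'   reproducible.
#' @param host_id identifier attached to the trajectory and its events.
#' @return An object of class \code{collapse_trajectory}: list with
#'   \code{times} (hours), \code{abundance} (cells, on the output grid),
#'   \code{events} (data frame: host_id, time, n_before, n_after, f, as
#'   realized, i.e. after any extinction absorption), \code{params},
#'   \code{K_realized}, \code{host_id} and \code{seed}.
#' @examples
#' p <- collapse_params(p_c = 0.07, mu_logf = -1.9)
#' tr <- simulate_trajectory(p, n0 = 1e4, horizon = 14, output_dt = 1/3,
#'                           seed = 11)
#' nrow(tr$events)
#' @export
simulate_trajectory <- function(params, n0, horizon, output_dt, seed = NULL,
                                host_id = "sim") {
  stopifnot(inherits(params, "collapse_params"))
  if (!is.finite(n0) || n0 < 0) stop("'n0' must be finite and non-negative")
  if (!is.finite(horizon) || horizon <= 0) stop("'horizon' must be positive")
  if (!is.finite(output_dt) || output_dt <= 0) {
    stop("'output_dt' must be positive")
  }
  if (output_dt > horizon) stop("'output_dt' must not exceed 'horizon'")
  if (!is.null(seed)) set.seed(seed)

  times_out <- seq(0, horizon, by = output_dt)
  n_out <- length(times_out)
  abundance <- numeric(n_out)

  K_i <- if (params$sigma_logK > 0) {
    10^stats::rnorm(1, log10(params$K), params$sigma_logK)
  } else {
    params$K
  }
  r <- params$r
  ext <- params$extinction_threshold

  N <- n0
  if (N < ext) N <- 0
  t_cur <- 0
  p <- 1L
  ev_time <- ev_before <- ev_after <- ev_f <- numeric(0)

  repeat {
    t_next <- if (params$p_c > 0 && N > 0) {
      t_cur + stats::rexp(1, params$p_c)
    } else {
      Inf
    }
    # emit output points strictly before the next event (or through horizon)
    while (p <= n_out && times_out[p] < t_next) {
      abundance[p] <- .logistic(N, r, K_i, times_out[p] - t_cur)
      p <- p + 1L
    }
    if (t_next > horizon) break
    n_before <- .logistic(N, r, K_i, t_next - t_cur)
    f <- .draw_f(params$mu_logf, params$sigma_logf)
    N <- n_before * f
    if (N < ext) N <- 0
    ev_time <- c(ev_time, t_next)
    ev_before <- c(ev_before, n_before)
    ev_after <- c(ev_after, N)
    ev_f <- c(ev_f, if (n_before > 0) N / n_before else 0)
    t_cur <- t_next
  }

  events <- data.frame(host_id = rep(host_id, length(ev_time)),
                       time = ev_time, n_before = ev_before,
                       n_after = ev_after, f = ev_f,
                       stringsAsFactors = FALSE)
  structure(list(host_id = host_id, times = times_out, abundance = abundance,
                 events = events, params = params, K_realized = K_i,
                 seed = seed),
            class = "collapse_trajectory")
}

# one collapse fraction f = 10^x; truncation x <= 0 done by inverse CDF so no
# rejection loop is needed
.draw_f <- function(mu_logf, sigma_logf) {
  if (sigma_logf <= 0) return(10^mu_logf)
  u <- stats::runif(1) * stats::pnorm(0, mu_logf, sigma_logf)
  10^stats::qnorm(u, mu_logf, sigma_logf)
}

#' @export
print.collapse_trajectory <- function(x, ...) {
  cat(sprintf("collapse_trajectory '%s': %d output points over %.3g hr, %d collapse event(s)\n",
              x$host_id, length(x$times), max(x$times), nrow(x$events)))
  cat(sprintf("  final abundance %.4g cells (K realized %.4g)\n",
              x$abundance[length(x$abundance)], x$K_realized))
  invisible(x)
}

#' @export
plot.collapse_trajectory <- function(x, log = "y", ...) {
  graphics::plot(x$times, pmax(x$abundance, 0.5), type = "l", log = log,
                 xlab = "time (hr)", ylab = "abundance (cells)",
                 main = x$host_id, ...)
  if (nrow(x$events) > 0) {
    graphics::abline(v = x$events$time, col = "grey60", lty = 3)
  }
  invisible(x)
}

#' @export
as.data.frame.collapse_trajectory <- function(x, ..., species = "sim") {
  data.frame(host_id = x$host_id, species = species, time_hr = x$times,
             abundance = x$abundance, stringsAsFactors = FALSE)
}

#' Simulate an ensemble of hosts and return terminal abundances
#'
#' Runs \code{n_hosts} independent trajectories and collects their abundances
#' at \code{horizon} into an [endpoint_ensemble()], the simulated analogue of
#' a dissection-and-plating experiment. Per-host seeds are derived from
#' \code{seed} by an arithmetic split (\code{(seed + 104729 * i) mod 2^31-1}),
#' so host \code{i}'s trajectory does not depend on \code{n_hosts}: enlarging
#' the ensemble leaves shared indices unchanged.
#'
#' @param params a [collapse_params()] object.
#' @param n0 initial abundance per host, cells.
#' @param horizon time of the terminal observation, hours.
#' @param n_hosts number of independent hosts.
#' @param seed integer seed for the ensemble.
#' @param condition label stored on the ensemble.
#' @param lod,loq detection/quantification limits recorded on the ensemble
#'   (used downstream by [endpoint_stats()]).
#' @return an [endpoint_ensemble()] of \code{n_hosts} terminal abundances
#'   (uncensored, as simulated).
#' @examples
#' p <- collapse_params(p_c = 0, mu_logf = 0)
#' e <- simulate_ensemble(p, n0 = 10^3.2, horizon = 24, n_hosts = 5, seed = 1)
#' e$abundances  # all at K
#' @export
simulate_ensemble <- function(params, n0, horizon, n_hosts, seed = 1L,
                              condition = "simulated", lod = 5, loq = 100) {
  stopifnot(inherits(params, "collapse_params"))
  if (n_hosts < 1) stop("'n_hosts' must be at least 1")
  ab <- numeric(n_hosts)
  for (i in seq_len(n_hosts)) {
    tr <- simulate_trajectory(params, n0 = n0, horizon = horizon,
                              output_dt = horizon, seed = split_seed(seed, i),
                              host_id = paste0("host", i))
    ab[i] <- tr$abundance[length(tr$abundance)]
  }
  endpoint_ensemble(ab, host_ids = paste0("host", seq_len(n_hosts)),
                    condition = condition, t_final = horizon,
                    lod = lod, loq = loq)
}

#' Derive a per-host substream seed
#'
#' Deterministic, order-independent arithmetic split of a base seed:
#' \code{(seed + 104729 * i) mod (2^31 - 1)}, mapped away from 0. Used by all
#' ensemble-level generators so that per-host results are reproducible and
#' independent of how many hosts are requested.
#'
#' @param seed base integer seed.
#' @param i host index (1-based).
#' @return an integer seed.
#' @export
split_seed <- function(seed, i) {
  s <- (as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483647
  as.integer(s + 1)
}
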