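#' Fit carrying capacity and collapse intensity to an endpoint ensemble
#'
#' Simulation-based grid search for the two parameters that govern endpoint
#' abundance statistics of the collapse-logistic model: the carrying capacity
#' \code{K} (searched on a log10 grid) and the collapse intensity
#' \code{z = -p_c * log10(f)}. For each grid point, \code{n_sim} trajectories
#' are simulated to the ensemble's terminal time, censored at the ensemble's
#' limit of detection exactly as [endpoint_stats()] censors the data, and the
#' (weighted) Euclidean distance between simulated and observed
#' \code{(mean, SD)} of \code{log10(N+1)} is minimized.
#'
#' Because endpoint statistics depend on \code{(p_c, f)} only through
#' \code{z}, the search uses a fixed-f parameterization: \code{p_c} is held
#' at a declared default (0.07/hr) and \code{mu_logf = -z / p_c}. Common
#' random numbers (one set of Poisson event times shared by every grid point)
#' keep the objective surface smooth, and the whole fit is deterministic
#' under a fixed seed.
#'
#' The growth rate \code{r} is not fitted: it is independently known from
#' plating or imaging time series and endpoint statistics at horizons of a
#' day or more are insensitive to it.
#'
#' @param observed an [endpoint_ensemble()] with a finite \code{t_final}.
#' @param r growth rate, 1/hr (default 0.6, the plating-derived value).
#' @param n0 initial abundance, cells (default 1e4, the mono-association
#'   plateau; endpoints at >= 24 hr are insensitive because relaxation to K
#'   takes a few hours).
#' @param grid_logK,grid_z grid values for log10(K) and z (1/hr).
#' @param n_sim simulated trajectories per grid point.
#' @param p_c collapse rate used inside the fixed-f parameterization, 1/hr.
#' @param extinction_threshold cells; populations below it are absorbed at 0.
#' @param seed integer seed (the fit is exactly reproducible under it).
#' @param weights length-2 weights on the (mean, SD) coordinates of the
#'   objective.
#' @param n_boot bootstrap replicates used to attach a Monte-Carlo standard
#'   error to the objective at its minimum (defines the uncertainty region
#'   \code{objective <= min + SE}).
#' @return An object of class \code{collapse_fit} with components
#'   \code{coefficients} (named \code{log10_K}, \code{z}), \code{K_hat},
#'   \code{surface} (data frame: log10_K, z, mean_log, sd_log, distance),
#'   \code{observed} (the endpoint statistics fitted to), \code{uncertainty}
#'   (objective tolerance and the grid ranges it admits), and
#'   \code{settings}. Supports \code{print}, \code{summary}, \code{coef},
#'   \code{predict}, \code{plot} and \code{simulate}.
#' @examples
#' \donttest{
#' p <- collapse_params(K = 10^3.5, p_c = 0.07, mu_logf = -0.1 / 0.07)
#' obs <- simulate_ensemble(p, n0 = 1e4, horizon = 24, n_hosts = 30, seed = 7)
#' fit <- fit_collapse_model(obs, n_sim = 500, seed = 1)
#' coef(fit)
#' }
#' @export
fit_collapse_model <- function(observed, r = 0.6, n0 = 1e4,
                               grid_logK = seq(2, 5, by = 0.1),
                               grid_z = seq(0, 0.4, by = 0.01),
                               n_sim = 2000, p_c = 0.07,
                               extinction_threshold = 1, seed = 1L,
                               weights = c(1, 1), n_boot = 200) {
  stopifnot(inherits(observed, "endpoint_ensemble"))
  if (!is.finite(observed$t_final)) {
    stop("'observed$t_final' must be set to fit the model")
  }
  if (length(grid_logK) < 1 || length(grid_z) < 1) stop("empty grid")
  if (n_sim < 1) stop("'n_sim' must be at least 1")
  t_final <- observed$t_final
  obs <- endpoint_stats(observed)

  # common random numbers: one Poisson event-time draw shared by all grid
  # points (the fixed-f parameterization keeps p_c, hence the event-time law,
  # constant across the grid)
  set.seed(seed)
  m <- stats::rpois(n_sim, p_c * t_final)
  max_m <- max(m, 1L)
  ev <- matrix(NA_real_, nrow = n_sim, ncol = max_m)
  for (i in which(m > 0)) ev[i, seq_len(m[i])] <- sort(stats::runif(m[i], 0, t_final))

  surface <- expand.grid(log10_K = grid_logK, z = grid_z,
                         KEEP.OUT.ATTRS = FALSE)
  surface$mean_log <- surface$sd_log <- surface$distance <- NA_real_
  lod <- observed$lod

  for (iz in seq_along(grid_z)) {
    z <- grid_z[iz]
    f_fix <- if (p_c > 0) 10^(-z / p_c) else 1
    for (ik in seq_along(grid_logK)) {
      K <- 10^grid_logK[ik]
      endpts <- .endpoints_fixed_f(ev, m, n0 = n0, r = r, K = K, f = f_fix,
                                   t_final = t_final,
                                   ext = extinction_threshold)
      lx <- log10(pmax(endpts, lod) + 1)
      row <- (iz - 1L) * length(grid_logK) + ik
      surface$mean_log[row] <- mean(lx)
      surface$sd_log[row] <- stats::sd(lx)
      surface$distance[row] <- sqrt(
        weights[1] * (surface$mean_log[row] - obs$mean_log)^2 +
        weights[2] * (surface$sd_log[row] - obs$sd_log)^2)
    }
  }

  best <- which.min(surface$distance)
  logK_hat <- surface$log10_K[best]
  z_hat <- surface$z[best]
  if (length(grid_logK) > 1 && logK_hat %in% range(grid_logK)) {
    warning("fitted log10(K) = ", logK_hat,
            " lies on the grid boundary; widen 'grid_logK'")
  }
  if (length(grid_z) > 1 && z_hat %in% range(grid_z)) {
    warning("fitted z = ", z_hat, " lies on the grid boundary; widen 'grid_z'")
  }

  # Monte-Carlo SE of the objective at the minimum, by bootstrapping the
  # simulated endpoints; the uncertainty region is objective <= min + SE
  f_best <- if (p_c > 0) 10^(-z_hat / p_c) else 1
  endpts <- .endpoints_fixed_f(ev, m, n0 = n0, r = r, K = 10^logK_hat,
                               f = f_best, t_final = t_final,
                               ext = extinction_threshold)
  lx <- log10(pmax(endpts, lod) + 1)
  boot_obj <- vapply(seq_len(n_boot), function(b) {
    bx <- lx[sample.int(length(lx), replace = TRUE)]
    sqrt(weights[1] * (mean(bx) - obs$mean_log)^2 +
         weights[2] * (stats::sd(bx) - obs$sd_log)^2)
  }, numeric(1))
  tol <- stats::sd(boot_obj)
  region <- surface[surface$distance <= surface$distance[best] + tol, ,
                    drop = FALSE]

  structure(list(
    coefficients = c(log10_K = logK_hat, z = z_hat),
    K_hat = 10^logK_hat,
    surface = surface,
    observed = obs,
    uncertainty = list(
      objective_tol = tol,
      logK_range = range(region$log10_K),
      z_range = range(region$z),
      logK_halfwidth = diff(range(region$log10_K)) / 2,
      z_halfwidth = diff(range(region$z)) / 2),
    settings = list(r = r, n0 = n0, p_c = p_c,
                    extinction_threshold = extinction_threshold,
                    grid_logK = grid_logK, grid_z = grid_z,
                    n_sim = n_sim, seed = seed, weights = weights,
                    t_final = t_final, lod = lod, loq = observed$loq,
                    n_hosts = obs$n, condition = observed$condition),
    call = match.call()),
    class = "collapse_fit")
}

# vectorized fixed-f endpoint engine: ev is an n_sim x max_m matrix of sorted
# event times (NA-padded), m the per-trajectory event counts; between events
# the logistic closed form is applied, at events the abundance is multiplied
# by f with extinction absorption
.endpoints_fixed_f <- function(ev, m, n0, r, K, f, t_final, ext) {
  n <- nrow(ev)
  N <- rep(as.numeric(n0), n)
  if (n0 < ext) N[] <- 0
  tprev <- numeric(n)
  if (f < 1 && any(m > 0)) {
    for (k in seq_len(ncol(ev))) {
      idx <- which(m >= k & N > 0)
      if (!length(idx)) next
      dt <- ev[idx, k] - tprev[idx]
      Nk <- .logistic(N[idx], r, K, dt) * f
      Nk[Nk < ext] <- 0
      N[idx] <- Nk
      tprev[idx] <- ev[idx, k]
    }
  }
  alive <- N > 0
  N[alive] <- .logistic(N[alive], r, K, t_final - tprev[alive])
  N
}

#' Predict endpoint statistics of the model at a horizon
#'
#' Simulates \code{n_sim} trajectories of the model to time \code{t} and
#' returns the mean and SD of \code{log10(N+1)} over the ensemble, with
#' bootstrap Monte-Carlo standard errors. This is the out-of-sample check
#' used on the challenge best fit: parameters fitted at 24 hr predict the
#' 48-hr plating statistics.
#'
#' By default the statistics are those of the simulated populations
#' themselves: extinct hosts enter as \code{log10(0+1) = 0} (the +1 exists
#' precisely to admit zeros). To emulate a plating assay instead, pass the
#' assay's limit of detection as \code{lod}; abundances below it are then
#' replaced by it before the log transform, as [endpoint_stats()] does for
#' observed data.
#'
#' @param params a [collapse_params()] object.
#' @param n0 initial abundance, cells.
#' @param t horizon, hours.
#' @param n_sim number of trajectories (>= 1000 recommended).
#' @param seed integer seed.
#' @param lod limit of detection, CFU; 0 (the default) reports uncensored
#'   population statistics.
#' @param n_boot bootstrap replicates for the Monte-Carlo SEs.
#' @return list with \code{mean_log}, \code{sd_log}, \code{mean_se},
#'   \code{sd_se}, \code{n_sim}.
#' @examples
#' \donttest{
#' p <- collapse_params(r = 0.6, K = 10^3.2, p_c = 0.07, mu_logf = -1.9,
#'                      sigma_logf = 1)
#' predict_endpoint(p, n0 = 1e4, t = 48, n_sim = 2000, seed = 1)
#' }
#' @export
predict_endpoint <- function(params, n0, t, n_sim = 10000, seed = 1L,
                             lod = 0, n_boot = 200) {
  if (n_sim < 2) stop("'n_sim' must be at least 2")
  ens <- simulate_ensemble(params, n0 = n0, horizon = t, n_hosts = n_sim,
                           seed = seed, lod = max(lod, 5))
  lx <- log10(pmax(ens$abundances, lod) + 1)
  boot <- vapply(seq_len(n_boot), function(b) {
    bx <- lx[sample.int(length(lx), replace = TRUE)]
    c(mean(bx), stats::sd(bx))
  }, numeric(2))
  list(mean_log = mean(lx), sd_log = stats::sd(lx),
       mean_se = stats::sd(boot[1, ]), sd_se = stats::sd(boot[2, ]),
       n_sim = n_sim)
}

#' @export
print.collapse_fit <- function(x, digits = 3, ...) {
  cat("Stochastic collapse-logistic model fit (grid search)\n")
  cat(sprintf("  observed: %d hosts at t = %g hr, mean(log10(N+1)) = %.*g, SD = %.*g\n",
              x$settings$n_hosts, x$settings$t_final,
              digits, x$observed$mean_log, digits, x$observed$sd_log))
  cat(sprintf("  log10(K) = %.*g   z = %.*g /hr   (objective %.3g)\n",
              digits, x$coefficients[["log10_K"]],
              digits, x$coefficients[["z"]],
              min(x$surface$distance)))
  cat(sprintf("  near-optimal region (obj <= min + %.2g): log10(K) in [%g, %g], z in [%g, %g]\n",
              x$uncertainty$objective_tol,
              x$uncertainty$logK_range[1], x$uncertainty$logK_range[2],
              x$uncertainty$z_range[1], x$uncertainty$z_range[2]))
  invisible(x)
}

#' @export
coef.collapse_fit <- function(object, ...) object$coefficients

#' @export
summary.collapse_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.collapse_fit")
}

#' @export
print.summary.collapse_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  s <- f$settings
  cat(sprintf("  settings: r = %g /hr, n0 = %g, p_c = %g /hr (fixed-f), lod = %g\n",
              s$r, s$n0, s$p_c, s$lod))
  cat(sprintf("  grid: log10(K) in [%g, %g] (%d), z in [%g, %g] (%d); %d sims/point; seed %s\n",
              min(s$grid_logK), max(s$grid_logK), length(s$grid_logK),
              min(s$grid_z), max(s$grid_z), length(s$grid_z),
              s$n_sim, format(s$seed)))
  best <- which.min(f$surface$distance)
  cat(sprintf("  simulated at optimum: mean(log10(N+1)) = %.3g, SD = %.3g\n",
              f$surface$mean_log[best], f$surface$sd_log[best]))
  invisible(x)
}

#' Predict method for collapse-model fits
#'
#' Forwards the fitted \code{(K, z)} to [predict_endpoint()] at a new
#' horizon, using the fit's fixed-f parameterization
#' (\code{mu_logf = -z / p_c}) unless a collapse-magnitude spread
#' \code{sigma_logf} is supplied.
#'
#' @param object a \code{collapse_fit}.
#' @param t horizon, hours (default: the horizon the fit used).
#' @param n_sim,seed,lod,n_boot passed to [predict_endpoint()].
#' @param sigma_logf SD of log10(f), decades (0 keeps the fixed-f form).
#' @param ... unused.
#' @return see [predict_endpoint()].
#' @export
predict.collapse_fit <- function(object, t = object$settings$t_final,
                                 n_sim = 10000, seed = 1L, sigma_logf = 0,
                                 lod = 0, n_boot = 200, ...) {
  s <- object$settings
  z <- object$coefficients[["z"]]
  mu_logf <- if (s$p_c > 0) -z / s$p_c else 0
  params <- collapse_params(r = s$r, K = object$K_hat, p_c = s$p_c,
                            mu_logf = mu_logf, sigma_logf = sigma_logf,
                            extinction_threshold = s$extinction_threshold)
  predict_endpoint(params, n0 = s$n0, t = t, n_sim = n_sim, seed = seed,
                   lod = lod, n_boot = n_boot)
}

#' Simulate endpoint ensembles from a fitted model
#'
#' @param object a \code{collapse_fit}.
#' @param nsim number of hosts to simulate.
#' @param seed integer seed.
#' @param horizon hours (default: the fit's horizon).
#' @param ... unused.
#' @return an [endpoint_ensemble()].
#' @export
simulate.collapse_fit <- function(object, nsim = 1, seed = 1L,
                                  horizon = object$settings$t_final, ...) {
  s <- object$settings
  z <- object$coefficients[["z"]]
  mu_logf <- if (s$p_c > 0) -z / s$p_c else 0
  params <- collapse_params(r = s$r, K = object$K_hat, p_c = s$p_c,
                            mu_logf = mu_logf,
                            extinction_threshold = s$extinction_threshold)
  simulate_ensemble(params, n0 = s$n0, horizon = horizon, n_hosts = nsim,
                    seed = seed, lod = s$lod, loq = s$loq,
                    condition = "simulated from fit")
}

#' Objective-surface image for a collapse-model fit
#'
#' Displays the grid-search objective as an image in (log10 K, z) space with
#' the fitted minimum marked.
#'
#' @param x a \code{collapse_fit}.
#' @param ... passed to [graphics::image()].
#' @export
plot.collapse_fit <- function(x, ...) {
  s <- x$settings
  zmat <- matrix(x$surface$distance, nrow = length(s$grid_logK),
                 ncol = length(s$grid_z))
  if (length(s$grid_logK) > 1 && length(s$grid_z) > 1) {
    graphics::image(s$grid_logK, s$grid_z, zmat,
                    col = grDevices::hcl.colors(64, "viridis", rev = TRUE),
                    xlab = "log10(K)", ylab = "z (1/hr)",
                    main = "grid-search objective", ...)
    graphics::contour(s$grid_logK, s$grid_z, zmat, add = TRUE,
                      col = "grey40", nlevels = 8)
  } else {
    graphics::plot(x$surface$z + x$surface$log10_K * 0, x$surface$distance,
                   xlab = "grid", ylab = "objective")
  }
  graphics::points(x$coefficients[["log10_K"]], x$coefficients[["z"]],
                   pch = 4, cex = 1.5, lwd = 2, col = "red")
  invisible(x)
}
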