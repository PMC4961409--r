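#' Specification for synthetic study data
#'
#' Bundles a collapse-model parameterization with the observation process of
#' the two experimental assays: imaging-style sampling every 20 min
#' (\code{sampling_dt = 1/3} hr) with multiplicative log-normal enumeration
#' noise and random QC dropout of time points, and plating-style terminal
#' censoring at the limits of detection (5 CFU) and quantification (100 CFU).
#' Every generator built on a spec is reproducible under its seed, with
#' per-host substreams from [split_seed()].
#'
#' @param model a [collapse_params()] object (the ground truth).
#' @param n_hosts number of hosts.
#' @param horizon observed duration, hours.
#' @param n0 initial abundance per host, cells.
#' @param sampling_dt imaging sampling interval, hours.
#' @param noise_cv coefficient of variation of multiplicative log-normal
#'   measurement noise (0 disables; default 0.2, a realistic enumeration
#'   error for image-derived counts).
#' @param dropout_prob per-timepoint probability a point is removed by QC.
#' @param lod,loq plating limits of detection / quantification, CFU.
#' @param seed integer seed.
#' @return object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(model = collapse_params(), n_hosts = 10,
                           horizon = 14, n0 = 1e4, sampling_dt = 1/3,
                           noise_cv = 0.2, dropout_prob = 0, lod = 5,
                           loq = 100, seed = 1L) {
  stopifnot(inherits(model, "collapse_params"))
  if (noise_cv < 0) stop("'noise_cv' must be non-negative")
  if (dropout_prob < 0 || dropout_prob >= 1) {
    stop("'dropout_prob' must be in [0, 1)")
  }
  if (sampling_dt <= 0) stop("'sampling_dt' must be positive")
  if (n_hosts < 1) stop("'n_hosts' must be at least 1")
  structure(list(model = model, n_hosts = n_hosts, horizon = horizon,
                 n0 = n0, sampling_dt = sampling_dt, noise_cv = noise_cv,
                 dropout_prob = dropout_prob, lod = lod, loq = loq,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("synthetic_spec: %d host(s), %g hr at dt = %.3g hr, n0 = %g\n",
              x$n_hosts, x$horizon, x$sampling_dt, x$n0))
  cat(sprintf("  noise CV %g, dropout %g, lod/loq %g/%g, seed %d\n",
              x$noise_cv, x$dropout_prob, x$lod, x$loq, x$seed))
  print(x$model)
  invisible(x)
}

#' Generate imaging-style abundance time series with known ground truth
#'
#' Simulates one trajectory per host, samples it on the imaging grid, applies
#' mean-one multiplicative log-normal measurement noise of the requested CV,
#' and removes time points at random with the dropout probability. The true
#' (noise-free) event lists and parameters are returned alongside for
#' recovery tests.
#'
#' @param spec a [synthetic_spec()].
#' @param species species label written on the series.
#' @return list with \code{series} (list of [abundance_series()]),
#'   \code{events} (row-bound true collapse events across hosts),
#'   \code{trajectories} (the noise-free [simulate_trajectory()] objects) and
#'   \code{spec}.
#' @export
gen_timeseries <- function(spec, species = "focal") {
  stopifnot(inherits(spec, "synthetic_spec"))
  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  series <- vector("list", spec$n_hosts)
  trajs <- vector("list", spec$n_hosts)
  events <- list()
  for (i in seq_len(spec$n_hosts)) {
    s_i <- split_seed(spec$seed, i)
    tr <- simulate_trajectory(spec$model, n0 = spec$n0,
                              horizon = spec$horizon,
                              output_dt = spec$sampling_dt, seed = s_i,
                              host_id = paste0("host", i))
    # observation draws continue the per-host stream seeded above
    obs <- tr$abundance
    if (spec$noise_cv > 0) {
      obs <- obs * stats::rlnorm(length(obs), meanlog = -sdlog^2 / 2,
                                 sdlog = sdlog)
    }
    keep <- rep(TRUE, length(tr$times))
    if (spec$dropout_prob > 0) {
      keep <- stats::runif(length(tr$times)) >= spec$dropout_prob
      if (!any(keep)) keep[1] <- TRUE
    }
    series[[i]] <- abundance_series(
      host_id = paste0("host", i), species = species,
      times = tr$times[keep], abundance = obs[keep],
      excluded_times = if (all(keep)) NULL else tr$times[!keep])
    trajs[[i]] <- tr
    if (nrow(tr$events) > 0) events[[length(events) + 1]] <- tr$events
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(host_id = character(0), time = numeric(0),
               n_before = numeric(0), n_after = numeric(0), f = numeric(0))
  list(series = series, events = events, trajectories = trajs, spec = spec)
}

#' Generate a plating-style endpoint ensemble with known ground truth
#'
#' Simulates terminal abundances at \code{t_final}, applies enumeration noise
#' if requested, and records sub-LOD values as 0 (raw plating zeros; they are
#' only replaced by the LOD inside [endpoint_stats()], mirroring the plating
#' protocol's order of operations). Ground-truth \code{(log10 K, z)} are
#' attached.
#'
#' @param spec a [synthetic_spec()].
#' @param t_final harvest time, hours (default: the spec horizon).
#' @param condition label for the ensemble.
#' @return list with \code{ensemble} (an [endpoint_ensemble()]) and
#'   \code{truth} (list: log10_K, z, params).
#' @export
gen_endpoint_ensemble <- function(spec, t_final = spec$horizon,
                                  condition = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  ens <- simulate_ensemble(spec$model, n0 = spec$n0, horizon = t_final,
                           n_hosts = spec$n_hosts, seed = spec$seed,
                           condition = condition, lod = spec$lod,
                           loq = spec$loq)
  ab <- ens$abundances
  if (spec$noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    set.seed(split_seed(spec$seed, 0))
    ab <- ab * stats::rlnorm(length(ab), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  ab[ab < spec$lod] <- 0  # below detection: plated as zero colonies
  ens$abundances <- ab
  list(ensemble = ens,
       truth = list(log10_K = log10(spec$model$K),
                    z = compute_z(spec$model$p_c, spec$model$mu_logf),
                    params = spec$model))
}

#' Generate synthetic spatial frames with a known wall bias
#'
#' Builds masks of a named geometry (a disk, a filled rectangle, or a 3-D
#' tube, i.e. a cylinder along the axis) and draws bacterial positions inside
#' them either uniformly or with an exponential bias in distance to the wall:
#' wall-enriched points are accepted with probability \code{exp(-d / scale)},
#' wall-depleted with \code{1 - exp(-d / scale)}. The first coordinate serves
#' as the gut-axis coordinate.
#'
#' @param geometry one of "disk", "rectangle", "tube".
#' @param bias one of "uniform", "wall-depleted", "wall-enriched".
#' @param n_points positions per frame.
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param size characteristic size, micrometers: disk radius, rectangle
#'   width (height is half), or tube radius (length is 4x).
#' @param voxel_size mask voxel edge, micrometers.
#' @param bias_scale exponential scale of the wall bias, micrometers.
#' @return list of [spatial_frame()] objects.
#' @export
gen_spatial_frames <- function(geometry = c("disk", "rectangle", "tube"),
                               bias = c("uniform", "wall-depleted",
                                        "wall-enriched"),
                               n_points = 1000, n_frames = 1, seed = 1L,
                               size = 50, voxel_size = 1, bias_scale = 5) {
  geometry <- match.arg(geometry)
  bias <- match.arg(bias)
  if (n_points < 1 || n_frames < 1) {
    stop("'n_points' and 'n_frames' must be at least 1")
  }
  mask <- switch(geometry,
    disk = {
      n <- ceiling(2 * size / voxel_size) + 2
      ctr <- n / 2 * voxel_size
      cx <- (seq_len(n) - 0.5) * voxel_size
      outer(cx, cx, function(x, y) (x - ctr)^2 + (y - ctr)^2 <= size^2)
    },
    rectangle = {
      nx <- ceiling(size / voxel_size) + 2
      ny <- ceiling(size / 2 / voxel_size) + 2
      m <- matrix(FALSE, nx, ny)
      m[2:(nx - 1), 2:(ny - 1)] <- TRUE
      m
    },
    tube = {
      len <- 4 * size
      nx <- ceiling(len / voxel_size)
      nyz <- ceiling(2 * size / voxel_size) + 2
      ctr <- nyz / 2 * voxel_size
      cyz <- (seq_len(nyz) - 0.5) * voxel_size
      circ <- outer(cyz, cyz, function(y, z) (y - ctr)^2 + (z - ctr)^2 <= size^2)
      array(rep(circ, each = nx), dim = c(nx, nyz, nyz))
    })

  lapply(seq_len(n_frames), function(fr) {
    set.seed(split_seed(seed, fr))
    pts <- matrix(numeric(0), ncol = length(dim(mask)))
    ref <- spatial_frame(matrix(0, 1, length(dim(mask))) + size, mask,
                         voxel_size)  # template for distance calls
    while (nrow(pts) < n_points) {
      cand <- .sample_uniform_in_mask(mask, voxel_size,
                                      max(2L * n_points, 64L))
      if (bias != "uniform") {
        ref$positions <- cand
        dist <- wall_distances(ref)
        p_acc <- if (bias == "wall-enriched") {
          exp(-dist / bias_scale)
        } else {
          1 - exp(-dist / bias_scale)
        }
        cand <- cand[stats::runif(nrow(cand)) < p_acc, , drop = FALSE]
      }
      pts <- rbind(pts, cand)
    }
    pts <- pts[seq_len(n_points), , drop = FALSE]
    spatial_frame(pts, mask, voxel_size, axis_coord = pts[, 1],
                  frame_time = fr)
  })
}
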